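# Internal numerical helpers shared across modules.

# Evaluate `expr` with a private, reproducible RNG stream; the caller's RNG
# state is untouched so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Rotation matrix for angle `theta` (radians) about unit axis `u` (Rodrigues).
rotation_about <- function(u, theta) {
  u <- unit(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Angle (degrees) between two vectors.
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# Dihedral angle (degrees) for points a-b-c-d, in (-180, 180].
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# NeRF atom placement: position D with |C-D| = dist, angle(B,C,D) = ang and
# dihedral(A,B,C,D) = dih (degrees).
place_atom <- function(a, b, c, dist, ang, dih) {
  ang <- deg2rad(ang); dih <- deg2rad(dih)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- dist * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
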