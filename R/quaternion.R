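## Quaternion and rotation helpers shared by loaders, fixtures, culling,
## rendering and camera interpolation. Convention: quaternions are numeric
## length-4 vectors c(x, y, z, w), w the scalar part; rotations are active
## (they rotate points, not frames); matrices are 3x3 row-major R objects.

#' Normalize a quaternion to unit length
#' @param q numeric(4), (x, y, z, w)
#' @return numeric(4) with unit norm
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Hamilton product of two quaternions
#'
#' `quat_multiply(a, b)` is the rotation b followed by a (matching matrix
#' composition R(a) %*% R(b)).
#' @param a,b numeric(4), (x, y, z, w)
#' @return numeric(4)
#' @export
quat_multiply <- function(a, b) {
  c(
    a[4] * b[1] + a[1] * b[4] + a[2] * b[3] - a[3] * b[2],
    a[4] * b[2] - a[1] * b[3] + a[2] * b[4] + a[3] * b[1],
    a[4] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[4],
    a[4] * b[4] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3]
  )
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#' @param q numeric(4), (x, y, z, w), assumed unit
#' @return 3x3 orthonormal matrix
#' @export
quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Shepperd's method; the returned quaternion has non-negative scalar part.
#' @param m 3x3 orthonormal matrix, det +1
#' @return numeric(4), (x, y, z, w)
#' @export
matrix_to_quat <- function(m) {
  tr <- m[1, 1] + m[2, 2] + m[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s, 0.25 * s)
  } else if (m[1, 1] > m[2, 2] && m[1, 1] > m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c(0.25 * s, (m[1, 2] + m[2, 1]) / s,
           (m[1, 3] + m[3, 1]) / s, (m[3, 2] - m[2, 3]) / s)
  } else if (m[2, 2] > m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 2] + m[2, 1]) / s, 0.25 * s,
           (m[2, 3] + m[3, 2]) / s, (m[1, 3] - m[3, 1]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[1, 3] + m[3, 1]) / s, (m[2, 3] + m[3, 2]) / s,
           0.25 * s, (m[2, 1] - m[1, 2]) / s)
  }
  if (q[4] < 0) q <- -q
  quat_normalize(q)
}

#' Rotate points by a unit quaternion
#' @param q numeric(4) unit quaternion
#' @param p N x 3 matrix of points (or numeric(3))
#' @return rotated points, same shape
#' @export
quat_rotate <- function(q, p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p %*% t(quat_to_matrix(q))
}

#' Spherical linear interpolation between unit quaternions
#'
#' Takes the short arc: if the dot product is negative one endpoint is
#' negated, so slerp(q, -q, t) is the identity path.
#' @param a,b numeric(4) unit quaternions
#' @param t interpolation parameter in [0, 1]
#' @return numeric(4) unit quaternion
#' @export
quat_slerp <- function(a, b, t) {
  d <- sum(a * b)
  if (d < 0) { b <- -b; d <- -d }
  if (d > 1 - 1e-10) {          # nearly parallel: nlerp is stable
    return(quat_normalize(a + t * (b - a)))
  }
  th <- acos(min(1, d))
  quat_normalize((sin((1 - t) * th) * a + sin(t * th) * b) / sin(th))
}

#' Draw quaternions uniformly distributed on the rotation group
#'
#' Shoemake's subgroup-algorithm construction from three uniforms; draws
#' from the current RNG stream.
#' @param n number of quaternions
#' @return n x 4 matrix, rows (x, y, z, w), unit norm
#' @export
uniform_rotation <- function(n = 1) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  s1 <- sqrt(1 - u1); s2 <- sqrt(u1)
  cbind(
    s1 * sin(2 * pi * u2),
    s1 * cos(2 * pi * u2),
    s2 * sin(2 * pi * u3),
    s2 * cos(2 * pi * u3)
  )
}

## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
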