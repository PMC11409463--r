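## Signed-distance clipping. Five primitives — plane, sphere, cube,
## cylinder, infinite cone — each an exact signed distance function in its
## local frame (negative inside, positive outside, zero on the surface),
## posed in the world by a rigid transform and optionally inverted.
## Clipping keeps the INSIDE of each primitive: a sphere is removed when
## its center lies outside at least one applicable clip. Groups with
## clip_enabled = FALSE are never removed, so e.g. a genome can stay fully
## visible while the capsid around it is peeled away.

#' Create a clipping primitive
#'
#' @param kind one of `"plane"`, `"sphere"`, `"cube"`, `"cylinder"`,
#'   `"infinite-cone"`
#' @param rotation unit quaternion (x,y,z,w) posing the primitive's local
#'   frame in the world
#' @param translation numeric(3), world position of the local origin
#'   (Angstrom)
#' @param params per-kind sizes: plane none; sphere `radius`; cube
#'   `half_extents` (numeric(3)); cylinder `radius` and `half_height`;
#'   infinite-cone `half_angle` in degrees, open interval (0, 90). The
#'   plane's inside is the local half-space z < 0; the cone's apex is the
#'   local origin with the cone opening along -z.
#' @param invert swap inside and outside
#' @param applies_to character vector of `"a/b"` group paths this clip is
#'   restricted to; empty means all clip-enabled groups
#' @return an object of class `meso_clip`
#' @export
meso_clip <- function(kind, rotation = c(0, 0, 0, 1),
                      translation = c(0, 0, 0), params = list(),
                      invert = FALSE, applies_to = character()) {
  kinds <- c("plane", "sphere", "cube", "cylinder", "infinite-cone")
  if (!kind %in% kinds)
    stop("unknown clip kind '", kind, "'; expected one of ",
         paste(kinds, collapse = ", "))
  p <- params
  chk <- function(ok, what) if (!ok) stop("clip '", kind, "': ", what)
  switch(kind,
    sphere = chk(is.numeric(p$radius) && p$radius > 0, "needs radius > 0"),
    cube = chk(length(p$half_extents) == 3 && all(p$half_extents > 0),
               "needs positive half_extents (3)"),
    cylinder = chk(is.numeric(p$radius) && p$radius > 0 &&
                   is.numeric(p$half_height) && p$half_height > 0,
                   "needs radius > 0 and half_height > 0"),
    `infinite-cone` = chk(is.numeric(p$half_angle) && p$half_angle > 0 &&
                          p$half_angle < 90,
                          "needs half_angle in (0, 90) degrees"),
    plane = invisible(NULL))
  structure(list(kind = kind, rotation = quat_normalize(as.numeric(rotation)),
                 translation = as.numeric(translation), params = p,
                 invert = isTRUE(invert),
                 applies_to = as.character(applies_to)),
            class = "meso_clip")
}

## Local-frame SDFs on an N x 3 point matrix (vectorized).
sdf_local <- function(p, kind, params) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  switch(kind,
    plane = z,
    sphere = sqrt(x^2 + y^2 + z^2) - params$radius,
    cube = {
      h <- params$half_extents
      qx <- abs(x) - h[1]; qy <- abs(y) - h[2]; qz <- abs(z) - h[3]
      outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2)
      inside <- pmin(pmax(qx, pmax(qy, qz)), 0)
      outside + inside
    },
    cylinder = {
      dr <- sqrt(x^2 + y^2) - params$radius
      dz <- abs(z) - params$half_height
      sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2) + pmin(pmax(dr, dz), 0)
    },
    `infinite-cone` = {
      ## Exact 2D profile distance in the (radial, axial) plane. The
      ## surface is the ray from the apex (local origin) along
      ## (sin a, -cos a), revolved about -z; inside is z < 0 within the
      ## opening angle.
      a <- params$half_angle * pi / 180
      rho <- sqrt(x^2 + y^2)
      ex <- sin(a); ez <- -cos(a)
      tproj <- pmax(rho * ex + z * ez, 0)
      d <- sqrt((rho - tproj * ex)^2 + (z - tproj * ez)^2)
      inside <- z < 0 & rho <= -z * tan(a)
      ifelse(inside, -d, d)
    },
    stop("unknown clip kind '", kind, "'"))
}

#' Signed distance from points to a clip primitive
#'
#' Points are mapped into the primitive's local frame (inverse pose) and
#' evaluated against the exact local SDF; `invert` negates the sign.
#'
#' @param points N x 3 matrix (or numeric(3)), world Angstrom
#' @param clip a [meso_clip()]
#' @return numeric(N): negative inside, positive outside (Angstrom)
#' @export
sdf <- function(points, clip) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  R <- quat_to_matrix(clip$rotation)
  local <- (points - matrix(clip$translation, nrow(points), 3,
                            byrow = TRUE)) %*% R   # R^-1 = t(R); p %*% R == t(R) p
  d <- sdf_local(local, clip$kind, clip$params)
  if (clip$invert) -d else d
}

#' Sphere keep mask under a set of clips
#'
#' A sphere is removed iff its group is clip-enabled and its CENTER lies
#' outside (signed distance > 0) at least one clip whose scope includes
#' the group. Multiple clips combine as the union of removed regions.
#' The center-only test gives crisp whole-sphere cuts with no popping
#' ambiguity; offset the primitive by a mean radius if a surface-accurate
#' cut is needed.
#'
#' @param centers N x 3 world sphere centers
#' @param clips list of [meso_clip()]
#' @param groups character(N): `"a/b"` group path per sphere
#' @param styles named list of [meso_style()] keyed by group path
#' @return logical(N) keep mask
#' @export
clip_mask <- function(centers, clips, groups, styles) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  keep <- rep(TRUE, n)
  if (length(clips) == 0 || n == 0) return(keep)
  clip_on <- vapply(unique(groups), function(g) {
    s <- styles[[g]]
    is.null(s) || isTRUE(s$clip_enabled)
  }, TRUE)
  enabled <- clip_on[groups]
  for (cl in clips) {
    scoped <- if (length(cl$applies_to) == 0) rep(TRUE, n)
              else groups %in% cl$applies_to
    idx <- which(enabled & scoped)
    if (length(idx) == 0) next
    d <- sdf(centers[idx, , drop = FALSE], cl)
    keep[idx[d > 0]] <- FALSE
  }
  keep
}
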