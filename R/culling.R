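## Visibility culling. Frustum culling tests per-instance bounding
## spheres against the six camera planes; occlusion culling renders an
## exact depth prepass of the largest instances, reduces it to a
## max-depth pyramid (hierarchical Z) and culls any instance whose
## nearest possible depth is strictly farther than everything the camera
## already sees over its whole screen footprint. Both tests are
## conservative: the opaque image with culling enabled is pixel-identical
## to the reference render.

#' Build the view frustum of a camera
#'
#' @param camera a [meso_camera()]
#' @param width,height image size in pixels (fixes the aspect ratio)
#' @return object of class `meso_frustum`: 6 x 4 matrix of inward planes
#'   `(nx, ny, nz, d)` with `n . p + d >= 0` inside
#' @export
make_frustum <- function(camera, width, height) {
  b <- camera_basis(camera)
  p0 <- camera$position
  tan_v <- tan(camera$fov_y / 2 * pi / 180)
  tan_h <- tan_v * width / height
  plane <- function(n, pt) { n <- n / sqrt(sum(n^2)); c(n, -sum(n * pt)) }
  m <- rbind(
    plane(b$forward, p0 + camera$near * b$forward),   # near
    plane(-b$forward, p0 + camera$far * b$forward),   # far
    plane(b$right + tan_h * b$forward, p0),           # left
    plane(-b$right + tan_h * b$forward, p0),          # right
    plane(-b$up + tan_v * b$forward, p0),             # top
    plane(b$up + tan_v * b$forward, p0))              # bottom
  structure(m, class = "meso_frustum")
}

#' Frustum-cull bounding spheres
#'
#' @param bounds data frame `cx,cy,cz,r` (from [instance_bounds()])
#' @param frustum a [make_frustum()]
#' @return logical keep mask: `TRUE` iff the bounding sphere intersects
#'   or touches the frustum
#' @export
frustum_cull <- function(bounds, frustum) {
  keep <- rep(TRUE, nrow(bounds))
  P <- as.matrix(bounds[, c("cx", "cy", "cz")])
  for (k in seq_len(nrow(frustum))) {
    d <- as.numeric(P %*% frustum[k, 1:3]) + frustum[k, 4]
    keep <- keep & (d >= -bounds$r)
  }
  keep
}

#' Max-reduction depth pyramid
#'
#' Level 0 is the input raster; each coarser texel is the maximum of its
#' (up to) 2x2 children; level count is `floor(log2(max dimension)) + 1`.
#'
#' @param depth H x W matrix of normalized depths (background 1)
#' @return list of matrices, finest first
#' @export
build_depth_pyramid <- function(depth) {
  cpp_depth_pyramid(depth)
}

## view-space axial distance + screen bbox of a bounding sphere; NULL when
## the sphere reaches the near plane (never occlusion-culled then).
sphere_footprint <- function(bound, camera, basis, fpix, width, height) {
  w <- c(bound$cx, bound$cy, bound$cz) - camera$position
  cx <- sum(w * basis$right); cy <- sum(w * basis$up); cz <- sum(w * basis$forward)
  r <- bound$r
  if (cz - r <= camera$near) return(NULL)
  corners <- expand.grid(x = c(-r, r), y = c(-r, r), z = c(-r, r))
  sx <- width / 2 + fpix * (cx + corners$x) / (cz + corners$z)
  sy <- height / 2 - fpix * (cy + corners$y) / (cz + corners$z)
  list(cz = cz, x0 = floor(min(sx)) - 1, x1 = ceiling(max(sx)) + 1,
       y0 = floor(min(sy)) - 1, y1 = ceiling(max(sy)) + 1)
}

#' Occlusion-cull bounding spheres against a depth pyramid
#'
#' An instance is culled only when the near face of its bounding sphere
#' is strictly farther than the pyramid's maximum depth over its full
#' screen footprint — i.e. the prepass geometry provably covers it.
#'
#' @param bounds data frame `cx,cy,cz,r`
#' @param pyramid a [build_depth_pyramid()] built from an exact depth
#'   prepass of real scene geometry at the same resolution
#' @param camera a [meso_camera()]
#' @param width,height raster size of pyramid level 0
#' @return logical keep mask
#' @export
occlusion_cull <- function(bounds, pyramid, camera, width, height) {
  basis <- camera_basis(camera)
  fpix <- (height / 2) / tan(camera$fov_y / 2 * pi / 180)
  nlev <- length(pyramid)
  keep <- rep(TRUE, nrow(bounds))
  for (i in seq_len(nrow(bounds))) {
    fp <- sphere_footprint(bounds[i, ], camera, basis, fpix, width, height)
    if (is.null(fp)) next
    x0 <- max(0, fp$x0); x1 <- min(width - 1, fp$x1)
    y0 <- max(0, fp$y0); y1 <- min(height - 1, fp$y1)
    if (x0 > x1 || y0 > y1) next              # off-screen: frustum's job
    near_face <- (fp$cz - bounds$r[i] - camera$near) / (camera$far - camera$near)
    near_face <- min(1, max(0, near_face))
    ## coarsest level whose texel span covers the footprint with a few texels
    lev <- min(nlev - 1, max(0, ceiling(log2(max(x1 - x0 + 1, y1 - y0 + 1)))))
    tex <- pyramid[[lev + 1]]
    sc <- 2^lev
    tx <- seq(floor(x0 / sc), floor(x1 / sc)) + 1
    ty <- seq(floor(y0 / sc), floor(y1 / sc)) + 1
    tx <- tx[tx >= 1 & tx <= ncol(tex)]
    ty <- ty[ty >= 1 & ty <= nrow(tex)]
    if (length(tx) == 0 || length(ty) == 0) next
    maxd <- max(tex[ty, tx])
    if (near_face > maxd) keep[i] <- FALSE
  }
  keep
}
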