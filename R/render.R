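## The offline renderer. For each frame: select an LOD level per instance
## from its camera distance and the quality preset, cull instances
## (frustum, then hierarchical-Z occlusion against an exact depth prepass
## of the largest instances), clip spheres against the active
## signed-distance primitives, rasterize ray-cast sphere impostors into
## color/depth/normal/object-id buffers, then run the screen-space
## passes: contact shadows (depth-march toward the light), multiscale
## SSAO (hemisphere occlusion at several radii, bilaterally blurred) and
## normal-dependent transparency compositing. Everything is deterministic
## given scene + settings + seed.

#' Renderer settings
#'
#' @param width,height output image size in pixels
#' @param preset quality preset name or a [quality_preset()] list
#' @param background background RGB in \[0, 1\]
#' @param light_dir view-space unit vector pointing from surfaces TOWARD
#'   the light; the default places the light up-right behind the camera
#' @param ambient constant ambient term of the Lambert shading, \[0, 1\]
#' @param ssao list: `radii` (Angstrom, increasing; `NULL` = 2/8/32 x the
#'   median sphere radius), `samples` per scale, `strength`, `bias`
#'   (normalized-depth units... given in eye units internally),
#'   `blur_radius` (pixels), `depth_sigma` (normalized depth)
#' @param shadows list: `steps`, `max_frac` (max march as a fraction of
#'   the image diagonal), `bias` (normalized depth), `strength`
#' @param gamma transparency falloff exponent (alpha_eff =
#'   alpha * (n.v)^gamma)
#' @param seed integer driving the SSAO sample kernel
#' @param cull enable frustum + occlusion culling
#' @param occluder_count how many largest-footprint instances form the
#'   occlusion prepass
#' @return a list of class `meso_settings`
#' @export
meso_settings <- function(width = 256, height = 256, preset = "quality",
                          background = c(1, 1, 1),
                          light_dir = c(0.35, 0.45, -0.82),
                          ambient = 0.3,
                          ssao = list(), shadows = list(), gamma = 1,
                          seed = 1L, cull = TRUE, occluder_count = 64L) {
  if (is.character(preset)) preset <- quality_preset(preset)
  ssao_def <- list(radii = NULL, samples = 16L, strength = 1.0,
                   blur_radius = 2L, depth_sigma = 0.01)
  shadows_def <- list(steps = 16L, max_frac = 0.1, bias = 0.002,
                      strength = 0.5)
  ssao <- utils::modifyList(ssao_def, ssao)
  shadows <- utils::modifyList(shadows_def, shadows)
  if (!is.null(ssao$radii) && is.unsorted(ssao$radii, strictly = TRUE))
    stop("ssao radii must be strictly increasing")
  if (shadows$steps < 1) stop("shadows steps must be >= 1")
  ld <- as.numeric(light_dir); ld <- ld / sqrt(sum(ld^2))
  structure(list(width = as.integer(width), height = as.integer(height),
                 preset = preset, background = as.numeric(background),
                 light_dir = ld, ambient = ambient, ssao = ssao,
                 shadows = shadows, gamma = gamma, seed = as.integer(seed),
                 cull = isTRUE(cull),
                 occluder_count = as.integer(occluder_count)),
            class = "meso_settings")
}

#' Analytic ray-sphere intersection
#'
#' Smallest `t >= 0` with `|o + t d - c| = r`; the hit normal is the unit
#' outward radial direction.
#'
#' @param origin,dir ray origin and unit direction
#' @param center,radius sphere
#' @return `NULL` on a miss, else list `t`, `point`, `normal`
#' @export
ray_sphere <- function(origin, dir, center, radius) {
  oc <- center - origin
  b <- sum(dir * oc)
  disc <- b^2 - (sum(oc * oc) - radius^2)
  if (disc < 0) return(NULL)
  sq <- sqrt(disc)
  t <- b - sq
  if (t < 0) t <- b + sq
  if (t < 0) return(NULL)
  p <- origin + t * dir
  list(t = t, point = p, normal = (p - center) / radius)
}

## mode code for the rasterizer
sphere_mode_code <- function(mode) {
  switch(mode, exact = 0L, approximate = 1L, `flat-disc` = 2L,
         stop("unknown sphere mode '", mode, "'"))
}

## Flatten the drawable spheres of selected instances at their LOD level:
## world centers, radii, instance index, per-sphere color/opacity/group.
gather_spheres <- function(scene, camera, settings, clips, instance_keep,
                           lod_cache) {
  inst <- scene$instances
  cols <- list(centers = list(), radii = list(), oid = list(),
               rgb = list(), alpha = list())
  for (i in which(instance_keep)) {
    row <- inst[i, ]
    e <- scene$entities[[row$entity_id]]
    g <- group_key(e$group)
    st <- scene$styles[[g]]
    if (is.null(st)) st <- meso_style()
    if (!st$visible) next
    levels <- lod_cache[[row$entity_id]]
    ext <- attr(levels, "extent")
    dist <- sqrt(sum((c(row$tx, row$ty, row$tz) - camera$position)^2))
    lv <- select_level(dist, ext, settings$preset,
                       n_levels = length(levels), extra_bias = st$lod_bias)
    lev <- levels[[lv + 1]]
    q <- c(row$qx, row$qy, row$qz, row$qw)
    ctr <- quat_rotate(q, lev$centers)
    ctr[, 1] <- ctr[, 1] + row$tx
    ctr[, 2] <- ctr[, 2] + row$ty
    ctr[, 3] <- ctr[, 3] + row$tz
    m <- nrow(ctr)
    keep <- clip_mask(ctr, clips, rep(g, m), scene$styles)
    if (!any(keep)) next
    k <- length(cols$centers) + 1
    cols$centers[[k]] <- ctr[keep, , drop = FALSE]
    cols$radii[[k]] <- lev$radii[keep]
    cols$oid[[k]] <- rep(i - 1L, sum(keep))
    cols$rgb[[k]] <- matrix(st$color, sum(keep), 3, byrow = TRUE)
    cols$alpha[[k]] <- rep(st$opacity, sum(keep))
  }
  if (length(cols$centers) == 0)
    return(list(centers = matrix(0, 0, 3), radii = numeric(),
                oid = integer(), rgb = matrix(0, 0, 3), alpha = numeric()))
  list(centers = do.call(rbind, cols$centers),
       radii = unlist(cols$radii), oid = unlist(cols$oid),
       rgb = do.call(rbind, cols$rgb), alpha = unlist(cols$alpha))
}

## per-entity LOD hierarchies + extents, built once per render call
build_lod_cache <- function(scene, n_levels = 4) {
  out <- list()
  for (e in scene$entities) {
    levels <- build_lod(e, n_levels = n_levels)
    c0 <- colMeans(e$centers)
    attr(levels, "extent") <-
      2 * max(sqrt(rowSums((e$centers - matrix(c0, nrow(e$centers), 3,
                                               byrow = TRUE))^2)) + e$radii)
    out[[e$id]] <- levels
  }
  out
}

rasterize_set <- function(sph, camera, basis, fpix, rw, rh, mode_code,
                          settings) {
  cpp_rasterize(sph$centers, sph$radii, as.integer(sph$oid),
                as.numeric(sph$rgb), camera$position, basis$right,
                basis$up, basis$forward, fpix, camera$near, camera$far,
                rw, rh, mode_code, settings$light_dir, settings$ambient)
}

#' Render the opaque geometry of a scene into frame buffers
#'
#' Runs LOD selection, culling and clipping, then rasterizes ray-cast
#' sphere impostors at the preset's internal resolution.
#'
#' @param scene a [meso_scene()]
#' @param camera a [meso_camera()]
#' @param settings a [meso_settings()]
#' @param clips list of [meso_clip()] (may be empty)
#' @return a list of class `meso_framebuffers`: `color` (H x W x 3),
#'   `depth`, `nx,ny,nz`, `oid` (-1 background), the render resolution
#'   `rw,rh`, `fpix`, the camera, settings, and culling statistics
#' @export
render_opaque <- function(scene, camera, settings, clips = list()) {
  preset <- settings$preset
  rw <- max(1L, as.integer(round(settings$width * preset$resolution_scale)))
  rh <- max(1L, as.integer(round(settings$height * preset$resolution_scale)))
  basis <- camera_basis(camera)
  fpix <- (rh / 2) / tan(camera$fov_y / 2 * pi / 180)
  lod_cache <- build_lod_cache(scene)
  nins <- nrow(scene$instances)
  keep <- rep(TRUE, nins)

  ## opacity split: opaque groups only in this pass
  opac <- vapply(seq_len(nins), function(i) {
    e <- scene$entities[[scene$instances$entity_id[i]]]
    st <- scene$styles[[group_key(e$group)]]
    if (is.null(st)) 1 else st$opacity
  }, 0)
  opaque_i <- opac >= 1

  stats <- list(frustum_culled = 0L, occlusion_culled = 0L)
  if (settings$cull && nins > 0) {
    bounds <- instance_bounds(scene)
    fr <- make_frustum(camera, rw, rh)
    keep <- frustum_cull(bounds, fr)
    stats$frustum_culled <- sum(!keep)
    ## occlusion prepass: K largest-by-screen-area kept opaque instances
    cand <- which(keep & opaque_i)
    if (length(cand) > 1) {
      dist <- sqrt((bounds$cx - camera$position[1])^2 +
                   (bounds$cy - camera$position[2])^2 +
                   (bounds$cz - camera$position[3])^2)
      area <- (bounds$r / pmax(dist, 1e-9))^2
      occl <- cand[order(area[cand], decreasing = TRUE)]
      occl <- occl[seq_len(min(settings$occluder_count, length(occl)))]
      pre_keep <- rep(FALSE, nins); pre_keep[occl] <- TRUE
      pre <- gather_spheres(scene, camera, settings, clips, pre_keep,
                            lod_cache)
      if (nrow(pre$centers) > 0) {
        buf <- rasterize_set(pre, camera, basis, fpix, rw, rh,
                             sphere_mode_code(preset$sphere_mode), settings)
        pyr <- build_depth_pyramid(buf$depth)
        test <- setdiff(which(keep), occl)
        if (length(test) > 0) {
          okeep <- occlusion_cull(bounds[test, , drop = FALSE], pyr,
                                  camera, rw, rh)
          keep[test[!okeep]] <- FALSE
          stats$occlusion_culled <- sum(!okeep)
        }
      }
    }
  }

  sph <- gather_spheres(scene, camera, settings, clips, keep & opaque_i,
                        lod_cache)
  buf <- rasterize_set(sph, camera, basis, fpix, rw, rh,
                       sphere_mode_code(preset$sphere_mode), settings)
  color <- array(0, c(rh, rw, 3))
  bgmask <- buf$oid < 0
  cr <- matrix(buf$r, rh, rw); cg <- matrix(buf$g, rh, rw)
  cb <- matrix(buf$b, rh, rw)
  cr[bgmask] <- settings$background[1]
  cg[bgmask] <- settings$background[2]
  cb[bgmask] <- settings$background[3]
  color[, , 1] <- cr; color[, , 2] <- cg; color[, , 3] <- cb
  structure(list(color = color, depth = buf$depth, nx = buf$nx,
                 ny = buf$ny, nz = buf$nz, oid = buf$oid, rw = rw, rh = rh,
                 fpix = fpix, camera = camera, settings = settings,
                 clips = clips, keep = keep, lod_cache = lod_cache,
                 stats = stats),
            class = "meso_framebuffers")
}

#' Screen-space contact shadows
#'
#' Marches from each covered pixel's view-space position toward the
#' light; when a marched sample's depth exceeds the depth the camera
#' recorded at that screen location (by more than `bias`), something lies
#' between the pixel and the light and the pixel is shadowed.
#'
#' @param buffers a [render_opaque()] result
#' @param settings a [meso_settings()]
#' @return H x W matrix of shadow factors in \[0, 1\] (background 1)
#' @export
contact_shadows <- function(buffers, settings = buffers$settings) {
  s <- settings$shadows
  cpp_contact_shadows(buffers$depth, buffers$oid, buffers$fpix,
                      buffers$camera$near, buffers$camera$far,
                      settings$light_dir, as.integer(s$steps), s$max_frac,
                      s$bias, s$strength)
}

## Deterministic hemisphere kernel with length jitter. The minimum
## elevation (z >= 0.25) is an angle bias: near-tangent samples mostly
## measure the surface's own curvature (every sphere wall would
## self-darken), not true cavity occlusion.
ssao_kernel <- function(n, seed) {
  with_seed(seed, {
    z <- stats::runif(n, 0.25, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    rr <- sqrt(pmax(0, 1 - z^2))
    len <- stats::runif(n, 0.3, 1)
    cbind(rr * cos(phi) * len, rr * sin(phi) * len, z * len)
  })
}

#' Multiscale screen-space ambient occlusion
#'
#' Hemisphere-samples occlusion around each covered pixel at several
#' radii — small radii darken atom-contact crevices, large radii capture
#' complex-scale cavities — averages the scales with equal weight,
#' applies `strength`, and smooths with a depth-aware bilateral blur.
#'
#' @param buffers a [render_opaque()] result
#' @param settings a [meso_settings()]
#' @param median_radius median drawn sphere radius (Angstrom), used for
#'   the default radius schedule
#' @return H x W matrix of ambient factors in \[0, 1\] (background 1)
#' @export
ssao_multiscale <- function(buffers, settings = buffers$settings,
                            median_radius = NULL) {
  s <- settings$ssao
  radii <- s$radii
  if (is.null(radii)) {
    if (is.null(median_radius)) median_radius <- 1.7
    radii <- c(2, 8, 32) * median_radius
  }
  if (s$strength == 0)
    return(matrix(1, buffers$rh, buffers$rw))
  kern <- ssao_kernel(s$samples, settings$seed)
  ## depth bias in eye units, scaled to the smallest radius: suppresses
  ## self-occlusion from sphere-scale surface bumps while leaving
  ## cavity-scale depth differences (many radii deep) untouched
  bias <- 0.2 * radii[1]
  fac <- cpp_ssao(buffers$depth, buffers$oid, buffers$nx, buffers$ny,
                  buffers$nz, buffers$fpix, buffers$camera$near,
                  buffers$camera$far, radii, kern, s$strength, bias)
  fac <- cpp_bilateral(fac, buffers$depth, as.integer(s$blur_radius),
                       s$depth_sigma)
  fac[buffers$oid < 0] <- 1
  fac
}

#' Composite shading factors and transparent layers into the final image
#'
#' Final opaque color is `color x shadow x ambient`; spheres of groups
#' with opacity below 1 are then composited back-to-front per pixel with
#' `alpha_eff = alpha_group * clamp(n.v, 0, 1)^gamma` — a sphere grows
#' more transparent as its normal turns away from the viewer.
#'
#' @param buffers a [render_opaque()] result
#' @param shadow,ambient H x W factor matrices (or `NULL` to skip)
#' @param settings a [meso_settings()]
#' @return H x W x 3 color array in \[0, 1\] at the internal resolution
#' @export
composite <- function(buffers, shadow = NULL, ambient = NULL,
                      settings = buffers$settings) {
  img <- buffers$color
  if (!is.null(shadow)) for (k in 1:3) img[, , k] <- img[, , k] * shadow
  if (!is.null(ambient)) for (k in 1:3) img[, , k] <- img[, , k] * ambient
  ## transparent layers
  scene <- attr(buffers, "scene")
  if (!is.null(scene)) {
    trans <- gather_transparent(scene, buffers)
    if (nrow(trans$centers) > 0) {
      basis <- camera_basis(buffers$camera)
      out <- cpp_composite_transparent(
        as.numeric(img[, , 1]), as.numeric(img[, , 2]),
        as.numeric(img[, , 3]), buffers$depth, trans$centers, trans$radii,
        trans$alpha, rep(settings$gamma, length(trans$alpha)),
        as.numeric(trans$rgb), buffers$camera$position, basis$right,
        basis$up, basis$forward, buffers$fpix, buffers$camera$near,
        buffers$camera$far, buffers$rw, buffers$rh, settings$light_dir,
        settings$ambient)
      img[, , 1] <- matrix(out$r, buffers$rh, buffers$rw)
      img[, , 2] <- matrix(out$g, buffers$rh, buffers$rw)
      img[, , 3] <- matrix(out$b, buffers$rh, buffers$rw)
    }
  }
  pmin(pmax(img, 0), 1)
}

gather_transparent <- function(scene, buffers) {
  nins <- nrow(scene$instances)
  opac <- vapply(seq_len(nins), function(i) {
    e <- scene$entities[[scene$instances$entity_id[i]]]
    st <- scene$styles[[group_key(e$group)]]
    if (is.null(st)) 1 else st$opacity
  }, 0)
  sel <- buffers$keep & opac < 1 & opac > 0
  sph <- gather_spheres(scene, buffers$camera, buffers$settings,
                        buffers$clips, sel, buffers$lod_cache)
  sph
}

## nearest-neighbour upsample to the requested output size
upsample_nearest <- function(img, W, H) {
  rh <- dim(img)[1]; rw <- dim(img)[2]
  if (rh == H && rw == W) return(img)
  yi <- pmin(rh, floor((seq_len(H) - 0.5) * rh / H) + 1)
  xi <- pmin(rw, floor((seq_len(W) - 0.5) * rw / W) + 1)
  img[yi, xi, , drop = FALSE]
}

#' Render a full frame
#'
#' The complete pipeline: opaque pass (LOD + culling + clipping +
#' impostor rasterization), contact shadows, multiscale SSAO,
#' transparency compositing, and nearest upsampling from the preset's
#' internal resolution to the requested size.
#'
#' @param scene a [meso_scene()]
#' @param camera a [meso_camera()]; `NULL` auto-frames the scene
#' @param settings a [meso_settings()]
#' @param clips list of [meso_clip()]
#' @return H x W x 3 array in \[0, 1\]; culling statistics attached as
#'   attribute `"stats"`
#' @export
render_scene <- function(scene, camera = NULL, settings = meso_settings(),
                         clips = list()) {
  if (is.null(camera)) camera <- auto_frame(scene)
  buf <- render_opaque(scene, camera, settings, clips)
  attr(buf, "scene") <- scene
  med <- stats::median(unlist(lapply(scene$entities, `[[`, "radii")))
  sh <- contact_shadows(buf, settings)
  ao <- ssao_multiscale(buf, settings, median_radius = med)
  img <- composite(buf, sh, ao, settings)
  img <- upsample_nearest(img, settings$width, settings$height)
  attr(img, "stats") <- buf$stats
  img
}

#' Write an image array as an 8-bit RGB PNG
#'
#' @param img H x W x 3 array in \[0, 1\]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_png_image <- function(img, path) {
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  attributes(img) <- attributes(img)["dim"]
  png::writePNG(img, path)
  invisible(path)
}
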