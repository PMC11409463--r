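## Sphere-merging level of detail. Distant instances do not need per-atom
## spheres: level l (l >= 1) buckets the entity's sphere centers into a
## uniform grid of cell size base_cell * 2^l and replaces each non-empty
## cell with a single enclosing sphere (volume-weighted centroid, radius
## max_i(|p_i - c| + r_i)), so the union of spheres at any level contains
## the union at level 0 and silhouettes never shrink. Level 0 is the
## untouched input.

#' Build a sphere-merging LOD hierarchy for one entity
#'
#' @param entity a [meso_entity()]
#' @param n_levels number of levels including level 0
#' @param base_cell grid cell size seed (Angstrom); level l uses
#'   `base_cell * 2^l`. Default: twice the median input radius.
#' @return list of `n_levels` levels, each a list with `level`, `centers`
#'   (M x 3), `radii` (M) and `source_count`
#' @export
build_lod <- function(entity, n_levels = 4, base_cell = NULL) {
  stopifnot(n_levels >= 1)
  if (is.null(base_cell)) base_cell <- 2 * stats::median(entity$radii)
  stopifnot(base_cell > 0)
  n <- nrow(entity$centers)
  levels <- vector("list", n_levels)
  levels[[1]] <- list(level = 0L, centers = entity$centers,
                      radii = entity$radii, source_count = n)
  if (n_levels == 1) return(levels)
  p <- entity$centers; r <- entity$radii
  w <- r^3                                   # volume weights
  for (l in seq_len(n_levels - 1)) {
    cell <- base_cell * 2^l
    ## bucket by integer grid coordinates anchored at the world origin so
    ## the result is independent of input ordering
    key <- paste(floor(p[, 1] / cell), floor(p[, 2] / cell),
                 floor(p[, 3] / cell), sep = ",")
    idx <- split(seq_len(n), key)
    m <- length(idx)
    ctr <- matrix(0, m, 3); rad <- numeric(m)
    for (j in seq_len(m)) {
      ii <- idx[[j]]
      wj <- w[ii] / sum(w[ii])
      cj <- c(sum(p[ii, 1] * wj), sum(p[ii, 2] * wj), sum(p[ii, 3] * wj))
      dj <- sqrt((p[ii, 1] - cj[1])^2 + (p[ii, 2] - cj[2])^2 +
                 (p[ii, 3] - cj[3])^2)
      ctr[j, ] <- cj
      rad[j] <- max(dj + r[ii])              # enclosing radius
    }
    ord <- order(ctr[, 1], ctr[, 2], ctr[, 3])  # canonical order
    levels[[l + 1]] <- list(level = l, centers = ctr[ord, , drop = FALSE],
                            radii = rad[ord], source_count = n)
  }
  levels
}

#' Quality preset table
#'
#' Four preset modes trading detail for speed: Ultra (most detailed,
#' exact impostors), Quality (default), Balanced (approximate-sphere
#' impostors), Performance (flat-disc impostors at half resolution).
#'
#' @param name `"ultra"`, `"quality"`, `"balanced"` or `"performance"`
#'   (case-insensitive)
#' @return list with `name`, `lod_bias` (integer), `resolution_scale` in
#'   (0, 1\] and `sphere_mode` in `{"exact","approximate","flat-disc"}`
#' @export
quality_preset <- function(name = "quality") {
  tab <- list(
    ultra       = list(name = "ultra", lod_bias = -1L,
                       resolution_scale = 1.0, sphere_mode = "exact"),
    quality     = list(name = "quality", lod_bias = 0L,
                       resolution_scale = 1.0, sphere_mode = "exact"),
    balanced    = list(name = "balanced", lod_bias = 1L,
                       resolution_scale = 1.0, sphere_mode = "approximate"),
    performance = list(name = "performance", lod_bias = 2L,
                       resolution_scale = 0.5, sphere_mode = "flat-disc"))
  key <- tolower(name)
  if (is.null(tab[[key]]))
    stop("unknown quality preset '", name, "'; valid: ",
         paste(names(tab), collapse = ", "))
  tab[[key]]
}

#' Select an LOD level by camera distance
#'
#' The base level counts how many normalized-distance thresholds the
#' instance has passed; the preset (plus any group bias) shifts it; the
#' result is clamped to the available levels. Monotone non-decreasing in
#' distance, and ordered Ultra <= Quality <= Balanced <= Performance at
#' any fixed distance.
#'
#' @param distance camera-to-instance distance (Angstrom), >= 0
#' @param entity_extent characteristic entity size (Angstrom), > 0
#' @param preset a [quality_preset()]
#' @param thresholds increasing normalized distances at which the level
#'   steps up
#' @param n_levels number of available levels
#' @param extra_bias additional integer bias (e.g. a group's `lod_bias`)
#' @return integer level index in `[0, n_levels - 1]`
#' @export
select_level <- function(distance, entity_extent, preset = quality_preset(),
                         thresholds = c(4, 16, 64), n_levels = 4,
                         extra_bias = 0L) {
  stopifnot(distance >= 0)
  nd <- distance / max(entity_extent, .Machine$double.eps)
  base <- sum(nd >= thresholds)
  lv <- base + preset$lod_bias + extra_bias
  max(0L, min(as.integer(n_levels) - 1L, as.integer(lv)))
}
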