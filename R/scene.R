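## The instanced scene graph. A mesoscale model stores ONE coordinate set
## per molecular entity (a bag of spheres) and places copies with rigid
## per-instance transforms, so a billion-sphere cytoplasm is represented by
## a few thousand canonical entities plus a table of quaternions and
## translations. Styling (color, visibility, opacity, clip opt-out) is per
## hierarchical group, never per instance.

#' Create a molecular entity
#'
#' An entity is one canonical set of sphere coordinates shared by all of
#' its placed instances.
#'
#' @param id unique entity identifier (text)
#' @param centers N x 3 matrix of sphere centers (Angstrom)
#' @param radii numeric(N), strictly positive sphere radii (Angstrom)
#' @param label human-readable name; defaults to `id`
#' @param group character vector: the entity's group path, outermost level
#'   first (e.g. `c("capsid", "pentamer")`)
#' @param description optional markdown description shown in tours
#' @return an object of class `meso_entity`
#' @export
meso_entity <- function(id, centers, radii, label = id,
                        group = c("all", id), description = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("centers must be N x 3")
  radii <- as.numeric(radii)
  if (nrow(centers) < 1) stop("entity '", id, "' has no spheres")
  if (length(radii) != nrow(centers))
    stop("radii length must match centers rows")
  if (any(!is.finite(centers))) stop("entity '", id, "' has non-finite centers")
  if (any(radii <= 0)) stop("entity '", id, "' has non-positive radii")
  structure(list(id = as.character(id), label = as.character(label),
                 centers = unname(centers), radii = radii,
                 group = as.character(group), description = description),
            class = "meso_entity")
}

#' Create a group style
#'
#' @param color RGB triple in \[0, 1\]
#' @param visible draw members of this group at all
#' @param opacity group opacity in \[0, 1\]; below 1 the group is rendered
#'   in the normal-dependent transparency pass
#' @param clip_enabled when `FALSE`, clipping primitives never remove this
#'   group's spheres (it stays "highlighted and fully visible")
#' @param lod_bias integer added to the preset's level-of-detail bias
#' @return an object of class `meso_style`
#' @export
meso_style <- function(color = c(0.7, 0.7, 0.7), visible = TRUE,
                       opacity = 1, clip_enabled = TRUE, lod_bias = 0L) {
  stopifnot(length(color) == 3, all(color >= 0 & color <= 1),
            opacity >= 0, opacity <= 1)
  structure(list(color = as.numeric(color), visible = isTRUE(visible),
                 opacity = as.numeric(opacity),
                 clip_enabled = isTRUE(clip_enabled),
                 lod_bias = as.integer(lod_bias)),
            class = "meso_style")
}

group_key <- function(path) paste(path, collapse = "/")

#' Assemble a scene from entities and an instance table
#'
#' @param entities list of [meso_entity()] objects
#' @param instances data frame with columns `entity_id`, `qx,qy,qz,qw`
#'   (unit quaternion) and `tx,ty,tz` (Angstrom). `NULL` places one
#'   identity instance per entity.
#' @param name scene name
#' @param group_keys names of the group hierarchy levels, outermost first
#' @param styles named list of [meso_style()] keyed by `"a/b"` group
#'   paths; missing groups get defaults
#' @return an object of class `meso_scene`
#' @export
meso_scene <- function(entities, instances = NULL, name = "scene",
                       group_keys = c("compartment", "class"),
                       styles = NULL) {
  if (inherits(entities, "meso_entity")) entities <- list(entities)
  names(entities) <- vapply(entities, `[[`, "", "id")
  if (anyDuplicated(names(entities))) stop("duplicate entity ids")
  if (is.null(instances)) {
    instances <- data.frame(entity_id = names(entities),
                            qx = 0, qy = 0, qz = 0, qw = 1,
                            tx = 0, ty = 0, tz = 0,
                            stringsAsFactors = FALSE)
  }
  instances <- as.data.frame(instances)
  need <- c("entity_id", "qx", "qy", "qz", "qw", "tx", "ty", "tz")
  if (!all(need %in% names(instances)))
    stop("instance table must have columns ", paste(need, collapse = ", "))
  sc <- structure(list(name = name, entities = entities,
                       instances = instances[, need],
                       group_keys = as.character(group_keys),
                       styles = if (is.null(styles)) list() else styles),
                  class = "meso_scene")
  ## every leaf group present in the data gets a style slot
  for (g in scene_groups(sc))
    if (is.null(sc$styles[[g]])) sc$styles[[g]] <- meso_style()
  sc
}

#' Leaf group paths present in a scene
#' @param scene a `meso_scene`
#' @return character vector of `"a/b"` keys, sorted
#' @export
scene_groups <- function(scene) {
  sort(unique(vapply(scene$entities, function(e) group_key(e$group), "")))
}

#' Number of placed instances
#' @param scene a `meso_scene`
#' @return integer
#' @export
n_instances <- function(scene) nrow(scene$instances)

#' @export
print.meso_scene <- function(x, ...) {
  ns <- sum(vapply(x$entities, function(e) nrow(e$centers), 0))
  cat(sprintf("<meso_scene '%s': %d entities, %d instances, %d unique spheres>\n",
              x$name, length(x$entities), nrow(x$instances), ns))
  invisible(x)
}

#' Validate a scene
#'
#' Checks referential integrity and geometric sanity. Findings are
#' returned, not thrown: errors are dangling instance entity ids,
#' non-unit instance quaternions and empty/degenerate entities; unused
#' entities are warnings.
#'
#' @param scene a `meso_scene`
#' @return data frame with columns `severity` ("error"/"warning") and
#'   `message`; zero rows means the scene is valid
#' @export
validate_scene <- function(scene) {
  sev <- character(); msg <- character()
  note <- function(s, m) { sev <<- c(sev, s); msg <<- c(msg, m) }
  for (e in scene$entities) {
    if (nrow(e$centers) < 1) note("error", sprintf("entity '%s' is empty", e$id))
    if (any(!is.finite(e$centers)))
      note("error", sprintf("entity '%s' has non-finite centers", e$id))
    if (any(e$radii <= 0))
      note("error", sprintf("entity '%s' has non-positive radii", e$id))
  }
  known <- names(scene$entities)
  bad <- setdiff(unique(scene$instances$entity_id), known)
  for (b in bad)
    note("error", sprintf("instance references unknown entity '%s'", b))
  qn <- sqrt(scene$instances$qx^2 + scene$instances$qy^2 +
             scene$instances$qz^2 + scene$instances$qw^2)
  for (i in which(abs(qn - 1) > 1e-6))
    note("error", sprintf("instance %d quaternion norm %.6f is not 1", i, qn[i]))
  unused <- setdiff(known, unique(scene$instances$entity_id))
  for (u in unused)
    note("warning", sprintf("entity '%s' has no instances", u))
  data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
}

#' World-frame spheres of one instance
#'
#' Applies the instance's rigid transform to its entity's canonical
#' spheres: `centers' = R centers + t`; radii are unchanged (rigid
#' transforms are isometries).
#'
#' @param scene a `meso_scene`
#' @param instance one row of `scene$instances` (or its row index)
#' @return list with `centers` (N x 3, world Angstrom) and `radii`
#' @export
world_spheres <- function(scene, instance) {
  if (is.numeric(instance) && length(instance) == 1)
    instance <- scene$instances[instance, ]
  e <- scene$entities[[instance$entity_id]]
  if (is.null(e)) stop("unknown entity '", instance$entity_id, "'")
  q <- c(instance$qx, instance$qy, instance$qz, instance$qw)
  ctr <- quat_rotate(q, e$centers)
  ctr[, 1] <- ctr[, 1] + instance$tx
  ctr[, 2] <- ctr[, 2] + instance$ty
  ctr[, 3] <- ctr[, 3] + instance$tz
  list(centers = ctr, radii = e$radii)
}

#' Assign group colors
#'
#' @param scene a `meso_scene`
#' @param strategy `"by-group"` (distinct leaf groups get maximally spaced
#'   hues), `"by-entity"` (hash each entity id to a hue) or `"uniform"`
#' @param seed integer; rotates the hue wheel deterministically
#' @param color RGB triple used by the `"uniform"` strategy
#' @return the scene with updated styles
#' @export
assign_colors <- function(scene, strategy = "by-group", seed = 0L,
                          color = c(0.5, 0.5, 0.5)) {
  groups <- scene_groups(scene)
  if (strategy == "uniform") {
    for (g in groups) scene$styles[[g]]$color <- as.numeric(color)
  } else if (strategy == "by-group") {
    k <- length(groups)
    offset <- (seed %% 360) / 360
    hues <- (offset + (seq_len(k) - 1) / k) %% 1   # 1/k hue-circle spacing
    for (i in seq_len(k)) {
      rgb <- grDevices::hsv(hues[i], 0.65, 0.9)
      scene$styles[[groups[i]]]$color <- as.numeric(grDevices::col2rgb(rgb)) / 255
    }
  } else if (strategy == "by-entity") {
    for (e in scene$entities) {
      h <- (sum(utf8ToInt(e$id) * seq_along(utf8ToInt(e$id))) + seed) %% 360
      rgb <- grDevices::hsv(h / 360, 0.65, 0.9)
      scene$styles[[group_key(e$group)]]$color <-
        as.numeric(grDevices::col2rgb(rgb)) / 255
    }
  } else stop("unknown color strategy '", strategy, "'")
  scene
}

#' Per-instance bounding spheres
#'
#' One enclosing sphere per instance, shared by frustum and occlusion
#' culling at every preset. The bound encloses the spheres of EVERY LOD
#' level, not just level 0: merged LOD spheres carry enclosing radii that
#' can extend beyond the level-0 union, and a level-0-only bound would
#' let culling clip geometry that a coarse level makes visible.
#'
#' @param scene a `meso_scene`
#' @return data frame with `cx,cy,cz,r` per instance row
#' @export
instance_bounds <- function(scene) {
  ## per-entity local bound first, shared by all its instances
  local <- lapply(scene$entities, function(e) {
    c0 <- colMeans(e$centers)
    r0 <- 0
    for (lev in build_lod(e)) {
      d <- sqrt(rowSums((lev$centers - matrix(c0, nrow(lev$centers), 3,
                                              byrow = TRUE))^2))
      r0 <- max(r0, d + lev$radii)
    }
    list(c = c0, r = r0)
  })
  n <- nrow(scene$instances)
  out <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    ins <- scene$instances[i, ]
    lb <- local[[ins$entity_id]]
    c_w <- quat_rotate(c(ins$qx, ins$qy, ins$qz, ins$qw), lb$c)[1, ] +
      c(ins$tx, ins$ty, ins$tz)
    out[i, ] <- c(c_w, lb$r)
  }
  data.frame(cx = out[, 1], cy = out[, 2], cz = out[, 3], r = out[, 4])
}

#' Bounding sphere of the whole scene
#' @param scene a `meso_scene`
#' @return list with `center` (numeric(3)) and `radius` (Angstrom)
#' @export
scene_bounds <- function(scene) {
  b <- instance_bounds(scene)
  ctr <- c(mean(range(b$cx)), mean(range(b$cy)), mean(range(b$cz)))
  rad <- max(sqrt((b$cx - ctr[1])^2 + (b$cy - ctr[2])^2 +
                  (b$cz - ctr[3])^2) + b$r)
  list(center = ctr, radius = rad)
}

#' Create a camera
#'
#' Right-handed world frame in Angstrom. The camera looks from `position`
#' toward `target`; `fov_y` is the vertical field of view in degrees; the
#' image origin is top-left with rows running downward; depth is mapped
#' linearly to \[0, 1\] with 0 at the near plane and 1 at/beyond far.
#'
#' @param position,target numeric(3), Angstrom
#' @param up approximate up vector (re-orthogonalized internally)
#' @param fov_y vertical field of view, degrees in (0, 180)
#' @param near,far clip distances, Angstrom, 0 < near < far
#' @return an object of class `meso_camera`
#' @export
meso_camera <- function(position, target, up = c(0, 1, 0), fov_y = 45,
                        near = 1, far = 1e4) {
  position <- as.numeric(position); target <- as.numeric(target)
  if (sqrt(sum((position - target)^2)) <= 0)
    stop("camera position and target coincide")
  if (!(fov_y > 0 && fov_y < 180)) stop("fov_y must be in (0, 180) degrees")
  if (!(near > 0 && near < far)) stop("require 0 < near < far")
  up <- as.numeric(up); up <- up / sqrt(sum(up^2))
  fwd <- (target - position) / sqrt(sum((target - position)^2))
  if (abs(sum(fwd * up)) > 1 - 1e-9) stop("up is parallel to the view direction")
  structure(list(position = position, target = target, up = up,
                 fov_y = as.numeric(fov_y), near = as.numeric(near),
                 far = as.numeric(far)),
            class = "meso_camera")
}

## Orthonormal camera basis: forward, right, true-up (all world frame).
camera_basis <- function(camera) {
  f <- camera$target - camera$position
  f <- f / sqrt(sum(f^2))
  r <- c(f[2] * camera$up[3] - f[3] * camera$up[2],
         f[3] * camera$up[1] - f[1] * camera$up[3],
         f[1] * camera$up[2] - f[2] * camera$up[1])
  r <- r / sqrt(sum(r^2))
  u <- c(r[2] * f[3] - r[3] * f[2],
         r[3] * f[1] - r[1] * f[3],
         r[1] * f[2] - r[2] * f[1])
  list(forward = f, right = r, up = u)
}

#' Frame a scene with a default overview camera
#'
#' Places the camera along the (1,1,1) diagonal from the scene center so
#' the scene bounding sphere fills about 90 percent of the vertical
#' image extent.
#'
#' @param scene a `meso_scene`
#' @param fov_y vertical field of view, degrees
#' @param direction view direction (camera placed at `center - d * dist`)
#' @return a `meso_camera`
#' @export
auto_frame <- function(scene, fov_y = 45, direction = c(1, 1, 1)) {
  if (length(scene$entities) == 0 || nrow(scene$instances) == 0)
    stop("auto-frame requires a non-empty scene")
  b <- scene_bounds(scene)
  d <- as.numeric(direction); d <- d / sqrt(sum(d^2))
  dist <- b$radius / (0.9 * tan(fov_y / 2 * pi / 180))
  dist <- max(dist, b$radius * 1.05)
  up <- if (abs(d[2]) > 0.99) c(0, 0, 1) else c(0, 1, 0)
  meso_camera(position = b$center + d * dist, target = b$center, up = up,
              fov_y = fov_y,
              near = max(dist - b$radius * 1.5, dist * 1e-3),
              far = dist + b$radius * 3)
}
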