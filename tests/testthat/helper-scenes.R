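## Shared builders for test scenes. Everything is generated in code from
## fixed seeds; no fixture files.

## a flat wall of overlapping spheres filling the view from wall_camera()
wall_scene <- function(radius = 2, spacing = 1.2 * radius, half = 60) {
  g <- as.matrix(expand.grid(x = seq(-half, half, spacing),
                             y = seq(-half, half, spacing)))
  wall <- meso_entity("wall", cbind(g, 0), rep(radius, nrow(g)),
                      group = c("test", "wall"))
  meso_scene(list(wall))
}

wall_camera <- function() {
  meso_camera(c(0, 0, -50), c(0, 0, 0), fov_y = 45, near = 1, far = 300)
}

## wall with a deep slit (floor at depth, side walls), camera-facing
slit_scene <- function(radius = 2, spacing = 1.2 * radius, half = 60,
                       gap = 6, depth = 24) {
  g <- as.matrix(expand.grid(x = seq(-half, half, spacing),
                             y = seq(-half, half, spacing)))
  lin <- as.matrix(expand.grid(y = seq(-half, half, spacing),
                               z = seq(0, depth, spacing)))
  geom <- rbind(cbind(g[abs(g[, 1]) > gap, 1], g[abs(g[, 1]) > gap, 2], 0),
                cbind(-gap, lin[, 1], lin[, 2]),
                cbind(gap, lin[, 1], lin[, 2]),
                as.matrix(expand.grid(x = seq(-gap, gap, spacing),
                                      y = seq(-half, half, spacing),
                                      z = depth)))
  meso_scene(list(meso_entity("slit", geom, rep(radius, nrow(geom)),
                              group = c("test", "wall"))))
}

## a large wall instance plus n small instances hidden behind it
occluded_scene <- function(n_hidden = 20, seed = 1) {
  grid <- as.matrix(expand.grid(x = seq(-40, 40, 4), y = seq(-40, 40, 4)))
  wall <- meso_entity("wall", cbind(grid, 0), rep(3, nrow(grid)),
                      group = c("front", "wall"))
  blob <- meso_entity("blob", matrix(0, 1, 3), 2, group = c("back", "blob"))
  pos <- mesoscene:::with_seed(seed, cbind(runif(n_hidden, -15, 15),
                                           runif(n_hidden, -15, 15),
                                           runif(n_hidden, 20, 60)))
  inst <- rbind(
    data.frame(entity_id = "wall", qx = 0, qy = 0, qz = 0, qw = 1,
               tx = 0, ty = 0, tz = 0),
    data.frame(entity_id = "blob", qx = 0, qy = 0, qz = 0, qw = 1,
               tx = pos[, 1], ty = pos[, 2], tz = pos[, 3]))
  meso_scene(list(wall, blob), inst)
}

occluded_camera <- function() {
  meso_camera(c(0, 0, -80), c(0, 0, 0), fov_y = 45, near = 1, far = 400)
}

## small packed scene for round-trip and render tests
small_packed <- function(seed = 7, copies = 8) {
  make_scene(fixture_spec("packed-interior", n_entities = 3,
                          copies = copies, spheres_per_entity = 20,
                          extent = 180, seed = seed))
}

quiet_settings <- function(w = 96, h = 96, ...) {
  meso_settings(width = w, height = h, ...)
}

## random rigid operator (rotation matrix + translation)
random_operator <- function() {
  q <- uniform_rotation(1)[1, ]
  list(rotation = quat_to_matrix(q), translation = rnorm(3, sd = 20))
}

expect_zero_findings <- function(findings) {
  expect_equal(nrow(findings[findings$severity == "error", ]), 0)
}
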