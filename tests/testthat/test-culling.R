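test_that("frustum culling removes what is behind and keeps what is aimed at", {
  cam <- meso_camera(c(0, 0, -50), c(0, 0, 0), fov_y = 45, near = 1,
                     far = 500)
  fr <- make_frustum(cam, 128, 128)
  bounds <- data.frame(cx = c(0, 0), cy = 0, cz = c(-100, 0), r = 5)
  keep <- frustum_cull(bounds, fr)
  expect_identical(keep, c(FALSE, TRUE))   # behind camera / at target
})

test_that("frustum culling never loses an instance with a visible sphere", {
  ## brute-force oracle: project EVERY sphere of every instance; any
  ## instance with a sphere whose disc reaches the image must be kept
  set.seed(55)
  cam <- meso_camera(c(0, 0, -60), c(0, 0, 0), fov_y = 50, near = 1,
                     far = 500)
  W <- 96; H <- 96
  fr <- make_frustum(cam, W, H)
  e <- meso_entity("e", matrix(rnorm(60, sd = 6), 20, 3),
                   runif(20, 0.5, 2))
  qs <- uniform_rotation(100)
  inst <- data.frame(entity_id = "e", qx = qs[, 1], qy = qs[, 2],
                     qz = qs[, 3], qw = qs[, 4],
                     tx = runif(100, -120, 120), ty = runif(100, -120, 120),
                     tz = runif(100, -40, 200))
  sc <- meso_scene(list(e), inst)
  keep <- frustum_cull(instance_bounds(sc), fr)
  fpix <- (H / 2) / tan(cam$fov_y / 2 * pi / 180)
  basis <- mesoscene:::camera_basis(cam)
  visible_oracle <- vapply(seq_len(100), function(i) {
    w <- world_spheres(sc, i)
    rel <- w$centers - matrix(cam$position, nrow(w$centers), 3, byrow = TRUE)
    cz <- rel %*% basis$forward
    cx <- rel %*% basis$right; cy <- rel %*% basis$up
    ok <- FALSE
    for (j in seq_along(w$radii)) {
      if (cz[j] + w$radii[j] < cam$near || cz[j] - w$radii[j] > cam$far) next
      if (cz[j] <= w$radii[j]) { ok <- TRUE; break }
      sx <- W / 2 + fpix * cx[j] / cz[j]
      sy <- H / 2 - fpix * cy[j] / cz[j]
      sr <- fpix * w$radii[j] / (cz[j] - w$radii[j])
      if (sx + sr >= 0 && sx - sr <= W && sy + sr >= 0 && sy - sr <= H) {
        ok <- TRUE; break
      }
    }
    ok
  }, TRUE)
  expect_true(all(keep[visible_oracle]))   # kept set contains the oracle set
})

test_that("depth pyramid is an exact max reduction", {
  const <- matrix(0.42, 17, 23)
  pyr <- build_depth_pyramid(const)
  expect_equal(length(pyr), floor(log2(23)) + 1)
  for (l in pyr) expect_true(all(l == 0.42))
  set.seed(3)
  d <- matrix(runif(64 * 48), 48, 64)
  pyr <- build_depth_pyramid(d)
  expect_identical(pyr[[1]], d)
  for (lev in 2:length(pyr)) {
    cur <- pyr[[lev]]; prev <- pyr[[lev - 1]]
    for (y in seq_len(nrow(cur))) {
      for (x in seq_len(ncol(cur))) {
        ys <- (2 * y - 1):min(2 * y, nrow(prev))
        xs <- (2 * x - 1):min(2 * x, ncol(prev))
        expect_identical(cur[y, x], max(prev[ys, xs]))
      }
    }
  }
  ## top level is the global maximum
  expect_equal(pyr[[length(pyr)]][1, 1], max(d))
})

test_that("an empty prepass culls nothing", {
  cam <- occluded_camera()
  pyr <- build_depth_pyramid(matrix(1, 64, 64))
  bounds <- data.frame(cx = runif(20, -20, 20), cy = runif(20, -20, 20),
                       cz = runif(20, 0, 100), r = 2)
  expect_true(all(occlusion_cull(bounds, pyr, cam, 64, 64)))
})

test_that("spheres hidden behind a wall are culled without changing a pixel", {
  sc <- occluded_scene(n_hidden = 20, seed = 1)
  cam <- occluded_camera()
  on <- render_scene(sc, cam, quiet_settings(seed = 2, cull = TRUE,
                                             occluder_count = 1))
  off <- render_scene(sc, cam, quiet_settings(seed = 2, cull = FALSE))
  st <- attr(on, "stats")
  expect_equal(st$occlusion_culled, 20)
  expect_identical(as.numeric(on), as.numeric(off))
})

test_that("culling is conservative for random packed scenes at every preset", {
  for (seed in c(101, 202)) {
    sc <- make_scene(fixture_spec("packed-interior", n_entities = 3,
                                  copies = 10, spheres_per_entity = 25,
                                  extent = 200, seed = seed))
    b <- scene_bounds(sc)
    cam <- meso_camera(b$center + c(0, 0, 0.5 * b$radius), b$center,
                       fov_y = 45, near = 1, far = 5 * b$radius)
    for (p in c("ultra", "quality", "balanced", "performance")) {
      on <- render_scene(sc, cam, quiet_settings(preset = p, seed = 4,
                                                 cull = TRUE,
                                                 occluder_count = 8))
      off <- render_scene(sc, cam, quiet_settings(preset = p, seed = 4,
                                                  cull = FALSE))
      expect_identical(as.numeric(on), as.numeric(off))
    }
  }
})
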