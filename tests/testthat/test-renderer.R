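test_that("ray_sphere matches analytic and quadratic-formula oracles", {
  hit <- ray_sphere(c(0, 0, 5), c(0, 0, -1), c(0, 0, 0), 1)
  expect_equal(hit$t, 4)
  expect_equal(hit$normal, c(0, 0, 1))
  expect_null(ray_sphere(c(0, 0, 5), c(0, 0, -1), c(10, 0, 0), 1))
  set.seed(71)
  nfail_t <- 0; nfail_surf <- 0; nhit <- 0
  for (k in 1:1e4) {
    o <- rnorm(3, sd = 10)
    c0 <- rnorm(3, sd = 10); r <- runif(1, 0.5, 3)
    ## aim near the sphere with angular jitter so hits and misses both occur
    d <- (c0 - o) + rnorm(3, sd = r)
    d <- d / sqrt(sum(d^2))
    got <- ray_sphere(o, d, c0, r)
    ## independent discriminant oracle
    oc <- o - c0
    A <- 1; B <- 2 * sum(d * oc); C <- sum(oc^2) - r^2
    disc <- B^2 - 4 * C
    roots <- if (disc < 0) numeric() else
      (c(-B - sqrt(disc), -B + sqrt(disc)) / 2)
    roots <- roots[roots >= 0]
    if (length(roots) == 0) {
      if (!is.null(got)) nfail_t <- nfail_t + 1
    } else {
      nhit <- nhit + 1
      if (abs(got$t - min(roots)) > 1e-6) nfail_t <- nfail_t + 1
      if (abs(sqrt(sum((got$point - c0)^2)) - r) > 1e-6)
        nfail_surf <- nfail_surf + 1
    }
  }
  expect_gt(nhit, 100)
  expect_equal(nfail_t, 0)
  expect_equal(nfail_surf, 0)
})

test_that("empty scenes render pure background with depth 1", {
  sc <- meso_scene(list(meso_entity("e", matrix(0, 1, 3), 1)))
  sc$styles[[scene_groups(sc)]]$visible <- FALSE
  cam <- wall_camera()
  buf <- render_opaque(sc, cam, quiet_settings())
  expect_true(all(buf$depth == 1))
  expect_true(all(buf$oid == -1))
  img <- render_scene(sc, cam, quiet_settings())
  expect_true(all(img == 1))               # white background
})

test_that("a centered sphere has minimal depth at center, non-decreasing outward", {
  sc <- meso_scene(list(meso_entity("e", matrix(0, 1, 3), 10)))
  cam <- meso_camera(c(0, 0, -40), c(0, 0, 0), fov_y = 45, near = 1,
                     far = 100)
  buf <- render_opaque(sc, cam, quiet_settings(128, 128))
  mid <- 64
  prof <- buf$depth[mid, ]
  covered <- which(buf$oid[mid, ] >= 0)
  expect_equal(which.min(prof), mid, tolerance = 1)
  right <- prof[covered[covered >= mid]]
  expect_true(all(diff(right) >= -1e-12))
  ## analytic depth at the center pixel: (dist - r - near) / (far - near)
  expect_equal(buf$depth[mid, mid], (40 - 10 - 1) / 99, tolerance = 1e-3)
  ## buffer invariants
  expect_true(all(buf$depth[buf$oid < 0] == 1))
  nrm <- sqrt(buf$nx^2 + buf$ny^2 + buf$nz^2)
  expect_equal(max(abs(nrm[buf$oid >= 0] - 1)), 0, tolerance = 1e-9)
})

test_that("flat-disc mode keeps the exact silhouette but flattens normals", {
  sc <- meso_scene(list(meso_entity("e", matrix(0, 1, 3), 10)))
  cam <- meso_camera(c(0, 0, -40), c(0, 0, 0), fov_y = 45, near = 1,
                     far = 100)
  ex <- render_opaque(sc, cam, quiet_settings(preset = "quality"))
  ## flat-disc at full resolution for a pixel-wise comparison
  fd_preset <- quality_preset("performance")
  fd_preset$resolution_scale <- 1
  fd <- render_opaque(sc, cam, quiet_settings(preset = fd_preset))
  expect_identical(ex$oid >= 0, fd$oid >= 0)
  on <- fd$oid >= 0
  expect_true(all(fd$nz[on] == -1))
  expect_false(all(ex$nz[on] == -1))
})

test_that("rendering is bit-for-bit deterministic", {
  sc <- small_packed(seed = 7)
  s <- quiet_settings(seed = 5)
  i1 <- render_scene(sc, settings = s)
  i2 <- render_scene(sc, settings = s)
  expect_identical(i1[, , ], i2[, , ])
})

test_that("shadow and AO factors only ever darken", {
  sc <- small_packed(seed = 7)
  cam <- auto_frame(sc)
  s <- quiet_settings(seed = 5)
  buf <- render_opaque(sc, cam, s)
  attr(buf, "scene") <- sc
  sh <- contact_shadows(buf, s)
  ao <- ssao_multiscale(buf, s)
  expect_true(all(sh >= 0 & sh <= 1))
  expect_true(all(ao >= 0 & ao <= 1))
  final <- composite(buf, sh, ao, s)
  for (k in 1:3) expect_true(all(final[, , k] <= buf$color[, , k] + 1e-12))
})

test_that("head-on light casts no contact shadow; empty scenes stay lit", {
  sc <- wall_scene()
  buf <- render_opaque(sc, wall_camera(), quiet_settings(128, 128))
  sh <- contact_shadows(buf, meso_settings(128, 128,
                                           light_dir = c(0, 0, -1)))
  expect_true(all(sh == 1))
  ## empty scene: all ones
  empty <- meso_scene(list(meso_entity("e", matrix(0, 1, 3), 1)))
  empty$styles[[scene_groups(empty)]]$visible <- FALSE
  b2 <- render_opaque(empty, wall_camera(), quiet_settings())
  expect_true(all(contact_shadows(b2, quiet_settings()) == 1))
})

test_that("oblique shadows fall on the side opposite the light", {
  wall <- wall_scene()
  ball <- meso_entity("ball", matrix(c(0, 0, -18), 1, 3), 6,
                      group = c("test", "ball"))
  sc <- meso_scene(list(wall$entities[[1]], ball))
  buf <- render_opaque(sc, wall_camera(), quiet_settings(128, 128))
  ## light toward +x in view space
  sh <- contact_shadows(buf, meso_settings(128, 128,
                                           light_dir = c(0.6, 0, -0.8)))
  shadowed <- which(sh < 1 & buf$oid == 0, arr.ind = TRUE)
  expect_gt(nrow(shadowed), 20)
  ## +x light means +x screen direction; shadow centroid left of center
  expect_lt(mean(shadowed[, 2]), 64)
})

test_that("SSAO darkens slits, leaves flat walls, and obeys strength 0", {
  set <- quiet_settings(128, 128, seed = 4)
  wall <- render_opaque(wall_scene(), wall_camera(), set)
  ao_wall <- ssao_multiscale(wall, set, median_radius = 2)
  expect_lt(mean(1 - ao_wall[wall$oid >= 0]), 0.05)
  slit <- render_opaque(slit_scene(), wall_camera(), set)
  ao_slit <- ssao_multiscale(slit, set, median_radius = 2)
  expect_lt(ao_slit[64, 64], ao_wall[64, 64] - 0.05)  # slit bottom darker
  s0 <- meso_settings(128, 128, seed = 4, ssao = list(strength = 0))
  expect_true(all(ssao_multiscale(wall, s0, median_radius = 2) == 1))
})

test_that("normal-dependent transparency has exact endpoints and is monotone", {
  ## direct alpha_eff law on a sweep of n.v values
  a_eff <- function(alpha, ndv, gamma) alpha * pmax(0, pmin(1, ndv))^gamma
  expect_equal(a_eff(1, 1, 3.7), 1)
  expect_equal(a_eff(0.8, 1, 1), 0.8)
  expect_true(all(a_eff(0, seq(0, 1, 0.1), 2) == 0))
  sweep <- a_eff(0.7, seq(1, 0, -0.05), 1.5)
  expect_true(all(diff(sweep) <= 0))
  ## rendered check: alpha 0 leaves the opaque image untouched
  sc <- small_packed(seed = 7)
  g <- scene_groups(sc)[1]
  img0 <- render_scene(sc, settings = quiet_settings(seed = 3))
  sc$styles[[g]]$opacity <- 0
  imgA <- render_scene(sc, settings = quiet_settings(seed = 3))
  sc$styles[[g]]$opacity <- 1e-9
  imgB <- render_scene(sc, settings = quiet_settings(seed = 3))
  expect_identical(dim(imgA), dim(img0))
  expect_lt(max(abs(imgA - imgB)), 1e-6)
  ## a semi-transparent front sphere blends, does not replace
  wallsc <- wall_scene()
  veil <- meso_entity("veil", matrix(c(0, 0, -20), 1, 3), 8,
                      group = c("test", "veil"))
  sc2 <- meso_scene(list(wallsc$entities[[1]], veil))
  sc2$styles[["test/veil"]]$opacity <- 0.5
  sc2$styles[["test/veil"]]$color <- c(1, 0, 0)
  img <- render_scene(sc2, wall_camera(), quiet_settings(128, 128, seed = 2))
  center <- img[64, 64, ]
  expect_gt(center[1], center[2])          # reddened by the veil
  expect_gt(center[2], 0.05)               # wall still visible through it
})

test_that("resolution scaling renders smaller then upsamples to the request", {
  sc <- small_packed(seed = 7, copies = 4)
  img <- render_scene(sc, settings = quiet_settings(100, 80,
                                                    preset = "performance"))
  expect_equal(dim(img)[1:2], c(80, 100))
  ## nearest upsampling duplicates 2x2 blocks
  expect_identical(img[1, 1, ], img[2, 2, ])
})
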