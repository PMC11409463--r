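test_that("plane, sphere, cylinder and cone SDFs match analytic values", {
  pl <- meso_clip("plane")
  expect_equal(sdf(c(0, 0, 2), pl), 2)
  expect_equal(sdf(c(5, -3, -1.5), pl), -1.5)
  sp <- meso_clip("sphere", params = list(radius = 1))
  expect_equal(sdf(c(0, 0, 0), sp), -1)
  expect_equal(sdf(c(3, 0, 0), sp), 2)
  cy <- meso_clip("cylinder", params = list(radius = 1, half_height = 2))
  expect_equal(sdf(c(0, 0, 0), cy), -1)
  expect_equal(sdf(c(3, 0, 0), cy), 2)
  expect_equal(sdf(c(0, 0, 5), cy), 3)
  co <- meso_clip("infinite-cone", params = list(half_angle = 45))
  expect_equal(sdf(c(0, 0, -5), co), -5 / sqrt(2), tolerance = 1e-12)
  expect_equal(sdf(c(0, 0, 3), co), 3, tolerance = 1e-12)   # behind apex
  ## pose: translated plane
  pl2 <- meso_clip("plane", translation = c(0, 0, 4))
  expect_equal(sdf(c(0, 0, 2), pl2), -2)
  ## pose: rotated plane (normal now +x after 90deg rotation about y)
  q <- c(0, sin(pi / 4), 0, cos(pi / 4))
  pl3 <- meso_clip("plane", rotation = q)
  expect_equal(sdf(c(3, 0, 0), pl3), 3, tolerance = 1e-9)
})

test_that("cube SDF agrees with membership and surface-sampling oracles", {
  cube <- meso_clip("cube", params = list(half_extents = c(1, 1, 1)))
  set.seed(41)
  pts <- matrix(runif(3e4, -2, 2), ncol = 3)
  d <- sdf(pts, cube)
  inside <- rowSums(abs(pts) <= 1) == 3
  expect_identical(d <= 0, inside)
  ## magnitude vs brute-force distance to sampled surface points
  ns <- 1e5
  face <- sample(1:6, ns, replace = TRUE)
  sp <- matrix(runif(3 * ns, -1, 1), ncol = 3)
  ax <- (face - 1) %/% 2 + 1
  sgn <- ifelse(face %% 2 == 0, 1, -1)
  sp[cbind(seq_len(ns), ax)] <- sgn
  sub <- pts[1:500, ]
  dd <- sdf(sub, cube)
  err <- vapply(seq_len(nrow(sub)), function(i) {
    brute <- sqrt(min(colSums((t(sp) - sub[i, ])^2)))
    abs(abs(dd[i]) - brute)
  }, 0)
  expect_lt(max(err), 2e-2)
})

test_that("SDF gradients have unit magnitude away from edges", {
  set.seed(6)
  h <- 1e-3
  shapes <- list(meso_clip("plane"),
                 meso_clip("sphere", params = list(radius = 2)),
                 meso_clip("cube", params = list(half_extents = c(1, 2, 1))),
                 meso_clip("cylinder", params = list(radius = 1.5,
                                                     half_height = 2)))
  for (cl in shapes) {
    pts <- matrix(runif(900, -4, 4), ncol = 3)
    d0 <- sdf(pts, cl)
    ## keep points away from the surface/edge neighbourhood
    pts <- pts[abs(d0) > 0.15, , drop = FALSE]
    g <- sapply(1:3, function(k) {
      e <- matrix(0, nrow(pts), 3); e[, k] <- h
      (sdf(pts + e, cl) - sdf(pts - e, cl)) / (2 * h)
    })
    mag <- sqrt(rowSums(g^2))
    if (cl$kind %in% c("plane", "sphere")) {
      expect_equal(mag, rep(1, length(mag)), tolerance = 1e-6)
    } else {
      ## cube/cylinder: unit a.e.; tolerate the measure-zero edge cones
      expect_gt(mean(abs(mag - 1) < 1e-4), 0.95)
    }
  }
})

test_that("inversion flips the sign and is an involution on masks", {
  sp <- meso_clip("sphere", params = list(radius = 3))
  spi <- meso_clip("sphere", params = list(radius = 3), invert = TRUE)
  set.seed(9)
  pts <- matrix(rnorm(300, sd = 3), ncol = 3)
  expect_equal(sdf(pts, spi), -sdf(pts, sp))
  styles <- list(`a/b` = meso_style())
  groups <- rep("a/b", nrow(pts))
  m0 <- clip_mask(pts, list(sp), groups, styles)
  spii <- spi; spii$invert <- FALSE
  expect_identical(clip_mask(pts, list(spii), groups, styles), m0)
})

test_that("clip_mask keeps insides, honours scope and clip-disabled groups", {
  styles <- list(`a/x` = meso_style(),
                 `a/y` = meso_style(clip_enabled = FALSE))
  centers <- rbind(c(0, 0, 5), c(0, 0, -5))
  groups <- c("a/x", "a/x")
  expect_identical(clip_mask(centers, list(), groups, styles), c(TRUE, TRUE))
  pl <- meso_clip("plane")         # inside = z < 0
  expect_identical(clip_mask(centers, list(pl), groups, styles),
                   c(FALSE, TRUE))
  ## clip-disabled group is never removed
  expect_identical(clip_mask(centers, list(pl), c("a/y", "a/y"), styles),
                   c(TRUE, TRUE))
  ## scope restriction: clip applies only to a/x
  pl2 <- meso_clip("plane", applies_to = "a/x")
  mixed <- c("a/x", "a/x")
  expect_identical(clip_mask(centers, list(pl2), mixed, styles),
                   c(FALSE, TRUE))
  pl3 <- meso_clip("plane", applies_to = "other/group")
  expect_identical(clip_mask(centers, list(pl3), mixed, styles),
                   c(TRUE, TRUE))
})

test_that("random clip sets match a brute-force per-sphere oracle", {
  set.seed(77)
  styles <- list(`g/1` = meso_style(), `g/2` = meso_style(),
                 `g/3` = meso_style(clip_enabled = FALSE))
  for (trial in 1:10) {
    n <- 200
    centers <- matrix(runif(3 * n, -10, 10), ncol = 3)
    groups <- sample(names(styles), n, replace = TRUE)
    clips <- lapply(seq_len(sample(1:4, 1)), function(i) {
      kind <- sample(c("plane", "sphere", "cube", "cylinder",
                       "infinite-cone"), 1)
      params <- switch(kind, plane = list(),
                       sphere = list(radius = runif(1, 2, 8)),
                       cube = list(half_extents = runif(3, 2, 6)),
                       cylinder = list(radius = runif(1, 2, 6),
                                       half_height = runif(1, 2, 6)),
                       `infinite-cone` = list(half_angle = runif(1, 20, 70)))
      meso_clip(kind, rotation = uniform_rotation(1)[1, ],
                translation = runif(3, -5, 5), params = params,
                invert = sample(c(TRUE, FALSE), 1),
                applies_to = if (runif(1) < 0.3) "g/1" else character())
    })
    got <- clip_mask(centers, clips, groups, styles)
    want <- vapply(seq_len(n), function(i) {
      if (!styles[[groups[i]]]$clip_enabled) return(TRUE)
      for (cl in clips) {
        scoped <- length(cl$applies_to) == 0 || groups[i] %in% cl$applies_to
        if (scoped && sdf(centers[i, ], cl) > 0) return(FALSE)
      }
      TRUE
    }, TRUE)
    expect_identical(got, want)
  }
})

test_that("adding clips shrinks and growing a sphere clip nests the kept set", {
  set.seed(13)
  centers <- matrix(rnorm(600, sd = 8), ncol = 3)
  groups <- rep("g/1", nrow(centers))
  styles <- list(`g/1` = meso_style())
  c1 <- meso_clip("sphere", params = list(radius = 6))
  c2 <- meso_clip("plane")
  m1 <- clip_mask(centers, list(c1), groups, styles)
  m12 <- clip_mask(centers, list(c1, c2), groups, styles)
  expect_true(all(m12 <= m1))       # composition is monotone
  ## progressive peeling: larger clip radius keeps a superset
  prev <- rep(FALSE, nrow(centers))
  for (r in c(2, 4, 8, 16)) {
    m <- clip_mask(centers, list(meso_clip("sphere",
                                           params = list(radius = r))),
                   groups, styles)
    expect_true(all(prev <= m))
    prev <- m
  }
})
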