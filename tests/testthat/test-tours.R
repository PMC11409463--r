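two_snapshot_tour <- function(sc) {
  b <- scene_bounds(sc)
  cam1 <- auto_frame(sc)
  cam2 <- meso_camera(b$center + c(0, 0.4 * b$radius, 1.6 * b$radius),
                      b$center, fov_y = 40, near = 1, far = 6 * b$radius)
  s1 <- capture_snapshot(sc, cam1, "overview", name = "Overview",
                         description = "Start, then [zoom in](#closeup).")
  s2 <- capture_snapshot(sc, cam2, "closeup", name = "Close-up",
                         preset = "balanced",
                         clips = list(meso_clip("sphere",
                                                translation = b$center,
                                                params = list(radius = b$radius))),
                         labels = list(meso_label("Back to overview",
                                                  b$center,
                                                  snapshot_key = "overview")))
  meso_tour(list(s1, s2), name = "demo")
}

test_that("snapshots reproduce the capture-time render exactly", {
  sc <- small_packed(seed = 7, copies = 4)
  tour <- two_snapshot_tour(sc)
  set <- quiet_settings(seed = 11)
  at_capture <- render_snapshot(sc, tour$snapshots[[1]], set)
  ## mutate the live scene afterwards; the snapshot must still win
  sc_mut <- assign_colors(sc, "uniform", color = c(0, 0, 0))
  replay <- render_snapshot(sc_mut, tour$snapshots[[1]], set)
  expect_identical(at_capture[, , ], replay[, , ])
  ## two captures with different cameras differ only in camera
  a <- tour$snapshots[[1]]; b <- tour$snapshots[[2]]
  expect_false(identical(a$camera, b$camera))
  expect_identical(a$styles, b$styles)
  expect_error(capture_snapshot(sc, a$camera, "overview",
                                existing_keys = c("overview")),
               "duplicate")
})

test_that("serialize -> deserialize -> apply is render-identical", {
  sc <- small_packed(seed = 7, copies = 4)
  tour <- two_snapshot_tour(sc)
  set <- quiet_settings(seed = 11)
  f <- tempfile(fileext = ".json")
  write_tour(tour, f)
  tour2 <- read_tour(f)
  for (i in 1:2)
    expect_identical(render_snapshot(sc, tour$snapshots[[i]], set)[, , ],
                     render_snapshot(sc, tour2$snapshots[[i]], set)[, , ])
  ## canonical serialization: rewrite is byte-identical
  f2 <- tempfile(fileext = ".json")
  write_tour(tour2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("camera interpolation is exact at endpoints and antipodal-safe", {
  set.seed(44)
  for (k in 1:100) {
    p1 <- rnorm(3, sd = 50); p2 <- rnorm(3, sd = 50)
    t1 <- rnorm(3, sd = 5); t2 <- rnorm(3, sd = 5)
    a <- meso_camera(p1, t1, fov_y = runif(1, 30, 70),
                     near = 1, far = 500)
    b <- meso_camera(p2, t2, fov_y = runif(1, 30, 70),
                     near = 2, far = 800)
    expect_identical(interpolate_camera(a, b, 0), a)
    expect_identical(interpolate_camera(a, b, 1), b)
    mid <- interpolate_camera(a, b, runif(1, 0.05, 0.95))
    expect_equal(sum(mid$up^2), 1, tolerance = 1e-9)
  }
  ## smoothstep easing slows the start relative to linear
  a <- meso_camera(c(0, 0, 0), c(0, 0, 10))
  b <- meso_camera(c(100, 0, 0), c(100, 0, 10))
  lin <- interpolate_camera(a, b, 0.1, "linear")
  smo <- interpolate_camera(a, b, 0.1, "smoothstep")
  expect_lt(smo$position[1], lin$position[1])
})

test_that("markdown action links parse to the three navigation kinds", {
  acts <- parse_markdown_actions(
    "[Look at Genome](#genome), then hover [proteins](highlight:interior-protein) or [the capsid](group:capsid/pentamer). [Docs](https://example.org) stay plain.")
  expect_equal(nrow(acts), 3)
  expect_equal(acts$kind, c("goto-snapshot", "highlight-entity",
                            "highlight-group"))
  expect_equal(acts$target[1], "genome")
  expect_equal(acts$target[2], "interior-protein")
  expect_equal(acts$target[3], "capsid/pentamer")
  expect_equal(acts$link_text[1], "Look at Genome")
  expect_equal(nrow(parse_markdown_actions("no links here")), 0)
  expect_equal(nrow(parse_markdown_actions("broken [link(#x) stays text")), 0)
})

test_that("playback emits the configured frames with exact endpoints", {
  sc <- small_packed(seed = 7, copies = 4)
  tour <- two_snapshot_tour(sc)
  set <- quiet_settings(64, 64, seed = 3)
  solo <- capture_snapshot(sc, auto_frame(sc), "solo")
  one <- play_tour(meso_tour(list(solo)), sc, frames = 1, settings = set)
  expect_equal(length(one$frames), 1)
  res <- play_tour(tour, sc, frames = 3, settings = set)
  expect_equal(length(res$frames), 3)
  expect_identical(res$frames[[1]][, , ],
                   render_snapshot(sc, tour$snapshots[[1]], set)[, , ])
  expect_identical(res$frames[[3]][, , ],
                   render_snapshot(sc, tour$snapshots[[2]], set)[, , ])
  ## interactable label resolves to the target snapshot's frame
  expect_equal(unname(res$index_map["Back to overview"]), 1L)
  expect_equal(unname(res$snapshot_frames["closeup"]), 3L)
  expect_error(play_tour(meso_tour(list()), sc), "empty")
})

test_that("validation catches every injected dangling reference", {
  sc <- small_packed(seed = 7, copies = 2)
  cam <- auto_frame(sc)
  good <- capture_snapshot(sc, cam, "a")
  n_caught <- 0
  for (k in 1:20) {
    bad_key <- sprintf("missing-%d", k)
    snap <- if (k %% 2 == 0) {
      capture_snapshot(sc, cam, "b",
                       description = sprintf("go [here](#%s)", bad_key))
    } else {
      capture_snapshot(sc, cam, "b",
                       labels = list(meso_label("x", c(0, 0, 0),
                                                snapshot_key = bad_key)))
    }
    v <- validate_tour(meso_tour(list(good, snap)), sc)
    if (any(v$severity == "error" & grepl(bad_key, v$message)))
      n_caught <- n_caught + 1
  }
  expect_equal(n_caught, 20)
  ## and a valid tour passes
  expect_equal(nrow(validate_tour(two_snapshot_tour(sc), sc)), 0)
})

test_that("the HTML storyboard has one section per snapshot", {
  sc <- small_packed(seed = 7, copies = 2)
  tour <- two_snapshot_tour(sc)
  f <- tempfile(fileext = ".html")
  storyboard_html(tour, c("s1.png", "s2.png"), f)
  html <- paste(readLines(f), collapse = "\n")
  expect_equal(lengths(regmatches(html, gregexpr("<section", html))), 2)
  expect_match(html, "zoom in")
  expect_match(html, "s2.png", fixed = TRUE)
})
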