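test_that("make_plane produces orthonormal tilted bases", {
  p0 <- make_plane(60)
  expect_equal(p0$origin, c(0, 0, 60))
  expect_equal(p0$e_u, c(1, 0, 0))
  expect_equal(p0$e_v, c(0, 1, 0))

  p1 <- make_plane(60, 10, 0)
  expect_point_equal(p1$e_v, c(0, cos(10 * pi / 180), sin(10 * pi / 180)), 1e-12)

  set.seed(1)
  for (k in 1:20) {
    p <- make_plane(runif(1, 5, 115), runif(1, -10, 10), runif(1, -10, 10))
    expect_lt(abs(sum(p$e_u * p$e_v)), 1e-12)
    expect_lt(abs(norm3(p$e_u) - 1), 1e-12)
    expect_lt(abs(norm3(p$e_v) - 1), 1e-12)
  }
})

test_that("bar/plane intersection handles spans half-open and matches the oracle", {
  fr <- build_preset("m")
  axial <- make_plane(60)
  v1 <- fr$bars[fr$bars$panel == "left" & fr$bars$bar == "V1", ]
  expect_point_equal(intersect_bar_plane(v1, axial), c(-95, -60, 60), 1e-12)
  d1 <- fr$bars[fr$bars$panel == "left" & fr$bars$bar == "D1", ]
  expect_point_equal(intersect_bar_plane(d1, axial), c(-95, -30, 60), 1e-12)
  expect_null(intersect_bar_plane(d1, make_plane(130)))

  # a zig-zag junction belongs to exactly one of the two abutting segments
  fz <- build_preset("z")
  za1 <- fz$bars[fz$bars$panel == "left" & fz$bars$bar == "ZA1", ]
  za2 <- fz$bars[fz$bars$panel == "left" & fz$bars$bar == "ZA2", ]
  at30 <- list(intersect_bar_plane(za1, make_plane(30)),
               intersect_bar_plane(za2, make_plane(30)))
  expect_equal(sum(!vapply(at30, is.null, logical(1))), 1)

  # tilted planes agree with the independent 3x3 solve
  set.seed(2)
  for (k in 1:25) {
    pl <- make_plane(runif(1, 10, 110), runif(1, -10, 10), runif(1, -10, 10))
    i <- sample(nrow(fz$bars), 1)
    ours <- intersect_bar_plane(fz$bars[i, ], pl)
    oracle <- oracle_intersect(fz$bars[i, ], pl)
    if (is.null(oracle)) {
      expect_null(ours)
    } else {
      expect_point_equal(ours, oracle$point, 1e-9)
    }
  }
})

test_that("projection inverts the plane parameterization", {
  pl <- make_plane(60)
  expect_point_equal(project_point(pl, c(-95, -30, 60)), c(-95, -30), 1e-12)
  expect_point_equal(project_point(pl, pl$origin), c(0, 0), 1e-12)
  tilted <- make_plane(44, 7, -9)
  set.seed(3)
  for (k in 1:20) {
    uv <- runif(2, -80, 80)
    p <- oracle_plane_point(tilted, uv[1], uv[2])
    expect_point_equal(project_point(tilted, p), uv, 1e-12)
  }
  expect_error(project_point(pl, c(0, 0, 61)), class = "stereoloc_off_plane")
})

test_that("observe_fiducials labels every cut bar and merges close groups", {
  fr <- build_preset("m")
  f <- observe_fiducials(fr, make_plane(60), merge_threshold = 2)
  expect_equal(nrow(f), 10)
  expect_false(any(f$merged))
  # self-consistency with intersect + project
  for (i in seq_len(nrow(f))) {
    bar <- fr$bars[fr$bars$panel == f$panel[i] & fr$bars$bar == f$bar[i], ]
    uv <- project_point(make_plane(60), intersect_bar_plane(bar, make_plane(60)))
    expect_point_equal(c(f$u[i], f$v[i]), uv, 1e-12)
  }

  low <- observe_fiducials(fr, make_plane(2), merge_threshold = 2)
  apex <- low[low$merged & low$panel == "left", ]
  expect_equal(nrow(apex), 1)
  expect_equal(apex$members, "D1,D2,VC")

  raw <- observe_fiducials(fr, make_plane(2), merge_threshold = 0)
  expect_equal(nrow(raw), 10)
  expect_false(any(raw$merged))
})

test_that("perturbation is bounded, seed-reproducible, and unbiased", {
  fr <- build_preset("f")
  f <- observe_fiducials(fr, make_plane(40))
  expect_identical(perturb_fiducials(f, 0), f)
  a <- perturb_fiducials(f, 1, seed = 42)
  b <- perturb_fiducials(f, 1, seed = 42)
  expect_identical(a, b)
  shift <- sqrt((a$u - f$u)^2 + (a$v - f$v)^2)
  expect_true(all(shift <= sqrt(2) + 1e-12))

  one <- f[1, ]
  n <- 1e5
  hw <- 1
  reps <- with_seed(7, replicate(2, {
    mean(perturb_fiducials(one[rep(1, n), ], hw)$u) - one$u
  }))
  expect_true(all(abs(reps) < 3 * (hw / sqrt(3)) / sqrt(n)))
})

test_that("render/detect round trip recovers centroids to a quarter pixel", {
  for (case in list(list(p = "m", z = 60, tu = 0, tv = 0),
                    list(p = "m", z = 35, tu = 8, tv = -5),
                    list(p = "f", z = 52, tu = 2, tv = 1))) {
    fr <- build_preset(case$p)
    pl <- make_plane(case$z, case$tu, case$tv)
    img <- render_ct(fr, pl)
    det <- detect_fiducials(img)
    obs <- observe_fiducials(fr, pl)
    expect_equal(nrow(det), nrow(obs))
    err <- vapply(seq_len(nrow(det)), function(i)
      min(sqrt((obs$u - det$u[i])^2 + (obs$v - det$v[i])^2)), numeric(1))
    expect_lt(max(err), 0.25 * img$pixel_spacing)
  }
})

test_that("blended rods are flagged merged and empty images error", {
  fr <- build_preset("m")
  det <- detect_fiducials(render_ct(fr, make_plane(2)))
  # right panel: outer verticals sit 1 mm from the inverted diagonals
  right <- det[det$u > 0, ]
  expect_equal(sum(right$merged), 2)
  left_blob <- det[det$u < 0 & abs(det$v) < 5, ]
  expect_true(all(left_blob$merged))

  blank <- render_ct(fr, make_plane(60))
  blank$pixels[] <- blank$background_value
  expect_error(detect_fiducials(blank), class = "stereoloc_no_fiducials")

  expect_warning(render_ct(fr, make_plane(200)), "background")
})

test_that("DICOM write/read round-trips pixels and plane pose", {
  fr <- build_preset("z")
  pl <- make_plane(47, 6, -4)
  img <- render_ct(fr, pl, rows = 280, cols = 280, pixel_spacing = 0.8)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_ct(img, path)
  back <- read_dicom_ct(path)
  expect_equal(back$pixels, round(img$pixels), ignore_attr = TRUE)
  expect_equal(back$pixel_spacing, img$pixel_spacing)
  expect_point_equal(back$plane$origin, pl$origin, 1e-9)
  expect_point_equal(back$plane$e_u, pl$e_u, 1e-12)
  expect_point_equal(back$plane$e_v, pl$e_v, 1e-12)
})

test_that("fiducial JSON interchange round-trips labels and merge flags", {
  fr <- build_preset("z")
  f <- observe_fiducials(fr, make_plane(30))
  path <- withr::local_tempfile(fileext = ".json")
  write_fiducials(f, path, plane_hint = list(z = 30))
  back <- read_fiducials(path)
  expect_equal(nrow(back), nrow(f))
  expect_equal(back$u, f$u)
  expect_equal(back$v, f$v)
  expect_equal(back$merged, f$merged)
  expect_equal(back$bar, f$bar)
})
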