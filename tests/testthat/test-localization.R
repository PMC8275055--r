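m_set <- function(panel = "left", a = "V1", b = "D1", c_ = "VC") {
  s <- enumerate_sets(build_preset("m"), 60, panel = panel)
  s[s$bar_a == a & s$bar_b == b & s$bar_c == c_, ]
}

fid_of <- function(fids, panel, bar) {
  fids[!is.na(fids$bar) & fids$panel == panel & fids$bar == bar, ]
}

test_that("n_point reproduces the distance-ratio construction", {
  fr <- build_preset("m")
  set <- m_set()
  f60 <- observe_fiducials(fr, make_plane(60))
  corr <- n_point(set, fid_of(f60, "left", "V1"), fid_of(f60, "left", "D1"),
                  fid_of(f60, "left", "VC"))
  expect_point_equal(c(corr$x, corr$y, corr$z), c(-95, -30, 60), 1e-12)

  f30 <- observe_fiducials(fr, make_plane(30))
  corr30 <- n_point(set, fid_of(f30, "left", "V1"), fid_of(f30, "left", "D1"),
                    fid_of(f30, "left", "VC"))
  expect_point_equal(c(corr30$x, corr30$y, corr30$z), c(-95, -15, 30), 1e-12)

  # exactness under tilt: the point must land on the oracle bar/plane cut
  pl <- make_plane(58, 10, 4)
  ft <- observe_fiducials(fr, pl)
  corrt <- n_point(set, fid_of(ft, "left", "V1"), fid_of(ft, "left", "D1"),
                   fid_of(ft, "left", "VC"))
  d1 <- fr$bars[fr$bars$panel == "left" & fr$bars$bar == "D1", ]
  expect_point_equal(c(corrt$x, corrt$y, corrt$z),
                     oracle_intersect(d1, pl)$point, 1e-9)

  # degenerate outers and out-of-slab ratios are rejected
  expect_error(n_point(set, c(0, 0), c(0, 1), c(0, 0.2)),
               class = "stereoloc_degenerate_set")
  expect_error(n_point(set, c(0, 0), c(0, 100), c(0, 60)),
               class = "stereoloc_set_rejected")
})

test_that("steeper transversals receive lower weights", {
  ff <- build_preset("f")
  s45 <- enumerate_sets(ff, 45, panel = "left")
  f45 <- observe_fiducials(ff, make_plane(45))
  w_of <- function(bar_b) {
    s <- s45[s45$bar_a == "V1" & s45$bar_b == bar_b & s45$bar_c == "V2", ]
    n_point(s, fid_of(f45, "left", "V1"), fid_of(f45, "left", bar_b),
            fid_of(f45, "left", "V2"))$w
  }
  # D1 runs at 45 degrees; D2 is much closer to vertical (steeper)
  expect_gt(w_of("D1"), w_of("D2"))
  expect_gt(w_of("D1"), w_of("D4"))
})

test_that("sp_point recovers slice height on the centre vertical", {
  fr <- build_preset("m")
  sets <- candidate_sets(fr)
  sp_l <- sets[sets$kind == "sp" & sets$panel == "left", ]
  sp_r <- sets[sets$kind == "sp" & sets$panel == "right", ]
  for (z in c(60, 90)) {
    f <- observe_fiducials(fr, make_plane(z))
    cl <- sp_point(sp_l, fid_of(f, "left", "D1"), fid_of(f, "left", "VC"),
                   fid_of(f, "left", "D2"))
    expect_point_equal(c(cl$x, cl$y, cl$z), c(-95, 0, z), 1e-12)
    cr <- sp_point(sp_r, fid_of(f, "right", "D1"), fid_of(f, "right", "VC"),
                   fid_of(f, "right", "D2"))
    expect_point_equal(c(cr$x, cr$y, cr$z), c(95, 0, z), 1e-12)
  }

  # tilt error is small (second order): |z_est - z_true| <= 2% z + 0.1 mm
  pl6 <- make_plane(60, 6, 0)
  f6 <- observe_fiducials(fr, pl6)
  c6 <- sp_point(sp_l, fid_of(f6, "left", "D1"), fid_of(f6, "left", "VC"),
                 fid_of(f6, "left", "D2"))
  vc <- fr$bars[fr$bars$panel == "left" & fr$bars$bar == "VC", ]
  z_true <- oracle_intersect(vc, pl6)$point[3]
  expect_lt(abs(c6$z - z_true), 0.02 * z_true + 0.1)
})

test_that("fit_transform solves exact and weighted overdetermined systems", {
  tri <- data.frame(u = c(0, 1, 0), v = c(0, 0, 1),
                    x = c(0, 1, 0), y = c(0, 0, 1), z = 60, w = 1)
  t3 <- fit_transform(tri)
  expect_point_equal(image_to_frame(t3, 0.3, -0.7), c(0.3, -0.7, 60), 1e-12)
  expect_lt(t3$rms_residual, 1e-12)

  # consistent overdetermined data keeps a ~zero residual
  pl <- make_plane(52, 5, -8)
  set.seed(8)
  uv <- matrix(runif(20, -70, 70), ncol = 2)
  pts <- t(apply(uv, 1, function(r) oracle_plane_point(pl, r[1], r[2])))
  corr <- data.frame(u = uv[, 1], v = uv[, 2], x = pts[, 1], y = pts[, 2],
                     z = pts[, 3], w = runif(10, 0.2, 2))
  tt <- fit_transform(corr)
  expect_lt(tt$rms_residual, 1e-9)

  # noisy weighted solution equals the brute-force normal equations
  noisy <- corr
  noisy$x <- noisy$x + rnorm(10, 0, 0.5)
  noisy$z <- noisy$z + rnorm(10, 0, 0.5)
  tn <- fit_transform(noisy)
  expect_lt(max(abs(tn$M - oracle_fit(noisy))), 1e-9)
  tu <- fit_transform(noisy, weighted = FALSE)
  expect_lt(max(abs(tu$M - oracle_fit(noisy, weighted = FALSE))), 1e-9)

  expect_error(fit_transform(tri[1:2, ]), class = "stereoloc_insufficient")
  coll <- data.frame(u = 1:4, v = 2 * (1:4) + 3, x = 0, y = 0, z = 0, w = 1)
  expect_error(fit_transform(coll), class = "stereoloc_singular")
})

test_that("frame_to_image inverts image_to_frame and measures off-plane distance", {
  fr <- build_preset("m")
  pl <- make_plane(70, -6, 3)
  t <- localize_image(fr, observe_fiducials(fr, pl))
  uv <- c(23.5, -41)
  p <- image_to_frame(t, uv[1], uv[2])
  back <- frame_to_image(t, p)
  expect_point_equal(back[1:2], uv, 1e-9)
  expect_lt(back[3], 1e-9)

  n <- cross3(t$M[1, ], t$M[2, ])
  off <- frame_to_image(t, p + 5 * n / norm3(n))
  expect_lt(abs(off[3] - 5), 1e-9)
  expect_point_equal(frame_to_image(t, pl$origin)[1:2], c(0, 0), 1e-9)
})

test_that("identification checks catch label swaps and off-line fiducials", {
  fr <- build_preset("m")
  f <- observe_fiducials(fr, make_plane(60, 4, 2))
  g <- function(b) fid_of(f, "left", b)
  expect_true(check_m_symmetry(g("V1"), g("VC"), g("V2"))$pass)
  expect_lt(check_m_symmetry(g("V1"), g("VC"), g("V2"))$asymmetry, 1e-9)
  # V1 swapped with D1
  expect_false(check_m_symmetry(g("D1"), g("VC"), g("V2"), tol = 1)$pass)
  expect_true(check_m_symmetry(g("D1"), g("VC"), g("V2"), tol = Inf)$pass)

  left <- f[f$panel == "left", ]
  cl <- check_panel_collinearity(left, tol = 1)
  expect_true(cl$pass)
  expect_lt(cl$max_residual, 1e-9)
  bent <- left
  bent$u[2] <- bent$u[2] + 5 * cl$direction[2]  # orthogonal to the line
  bent$v[2] <- bent$v[2] - 5 * cl$direction[1]
  expect_false(check_panel_collinearity(bent, tol = 1)$pass)
  expect_error(check_panel_collinearity(left[1:2, ]),
               class = "stereoloc_insufficient")

  # a gross swap makes localize_image fail its checks
  swapped <- f
  i <- which(swapped$panel == "left" & swapped$bar == "V1")
  j <- which(swapped$panel == "left" & swapped$bar == "D1")
  swapped$bar[c(i, j)] <- c("D1", "V1")
  expect_error(localize_image(fr, swapped), class = "stereoloc_identification")
})

test_that("short-bar assignment labels every visible Z bar from the initial fit", {
  fr <- build_preset("z")
  pl <- make_plane(50)
  truth <- observe_fiducials(fr, pl)
  part <- truth
  full_ids <- c("V1", "V2", "D1", "D2")
  drop <- !(part$bar %in% full_ids)
  part$bar[drop] <- NA; part$role[drop] <- NA
  t0 <- localize_image(fr, truth[truth$bar %in% full_ids, ],
                       localize_options(tol_line = Inf))
  out <- assign_z_fiducials(fr, part, t0, gate = 2)
  labeled <- out[!is.na(out$bar), ]
  key <- paste(labeled$panel, labeled$bar)
  true_key <- paste(truth$panel, truth$bar)
  expect_true(all(key %in% true_key))
  # everything non-support that the slice cuts ends up labeled
  expect_setequal(key[!labeled$bar %in% c("S1", "S2", "S3", "S4")],
                  true_key[truth$role != "support"])
  expect_identical(assign_z_fiducials(fr, part, t0, gate = 0), part)
})

test_that("a classic N bipanel yields two points and an insufficiency error", {
  fr <- build_preset("n")
  err <- tryCatch(localize_image(fr, observe_fiducials(fr, make_plane(55))),
                  stereoloc_insufficient = function(e) e)
  expect_s3_class(err, "stereoloc_insufficient")
  expect_equal(nrow(err$points), 2)
  # the two points are exact N-localizer reconstructions all the same
  d <- build_preset("n")$bars
  d1 <- d[d$panel == "left" & d$bar == "D1", ]
  expect_point_equal(unlist(err$points[err$points$panel == "left",
                                       c("x", "y", "z")]),
                     oracle_intersect(d1, make_plane(55))$point, 1e-9)
})

test_that("noise-free localization reproduces the plane over presets, heights and tilts", {
  grid <- expand.grid(u = seq(-60, 60, 30), v = seq(-60, 60, 30))
  for (p in c("m", "f", "z")) {
    fr <- build_preset(p)
    for (z in c(20, 50, 95)) for (tilt in list(c(0, 0), c(7, -9))) {
      pl <- make_plane(z, tilt[1], tilt[2])
      f <- observe_fiducials(fr, pl, merge_threshold = 0)
      t <- localize_image(fr, f)
      pred <- image_to_frame(t, grid$u, grid$v)
      truth <- t(apply(grid, 1, function(r) oracle_plane_point(pl, r[1], r[2])))
      expect_lt(max(abs(pred - truth)), 1e-6)
      expect_lt(t$rms_residual, 1e-9)
    }
  }
})

test_that("the staged Z pipeline refits with at least as many correspondences", {
  fr <- build_preset("z")
  f <- observe_fiducials(fr, make_plane(50))
  t <- localize_image(fr, strip_labels(f))
  expect_gte(t$diagnostics$n_final, t$diagnostics$n_initial)
  expect_equal(t$diagnostics$n_initial, 4)
  expect_lt(t$rms_residual, 1e-9)
})

test_that("unlabeled fiducials from detection localize all rich presets", {
  grid <- expand.grid(u = c(-50, 0, 50), v = c(-50, 0, 50))
  for (p in c("m", "f", "z")) {
    fr <- build_preset(p)
    pl <- make_plane(52, 2, 1)
    det <- detect_fiducials(render_ct(fr, pl))
    t <- localize_image(fr, det)
    truth <- t(apply(grid, 1, function(r) oracle_plane_point(pl, r[1], r[2])))
    expect_lt(max(abs(image_to_frame(t, grid$u, grid$v) - truth)), 0.3)
  }
})

test_that("adding a consistent correspondence never worsens a noise-free fit", {
  fr <- build_preset("f")
  f <- observe_fiducials(fr, make_plane(45))
  full <- localize_image(fr, f)
  for (n in 3:full$n_used) {
    t <- localize_image(fr, f, localize_options(use_first_n = n))
    expect_lt(t$rms_residual, 1e-9)
  }
})

test_that("with exactly three correspondences the weights are irrelevant", {
  fr <- build_preset("m")
  f <- perturb_fiducials(observe_fiducials(fr, make_plane(65)), 1, seed = 5)
  ow <- localize_options(use_first_n = 3, tol_sym = Inf, tol_line = Inf)
  ou <- ow; ou$weighted <- FALSE
  tw <- localize_image(fr, f, ow)
  tu <- localize_image(fr, f, ou)
  expect_equal(tw$M, tu$M)
})

test_that("transform JSON interchange round-trips", {
  fr <- build_preset("m")
  t <- localize_image(fr, observe_fiducials(fr, make_plane(60)))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(t, path, provenance = list(preset = "m"))
  back <- read_transform(path)
  expect_equal(back$M, t$M)
  expect_equal(back$n_used, t$n_used)
})
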