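# Reconstruction of 3D frame points from three-bar fiducial sets and the
# weighted overdetermined fit of the image-to-frame transform.
#
# N-localizer principle: where the slice cuts two parallel bars and a
# transversal, the image distance ratio f = |AB| / |AC| locates the cut
# point along the transversal between its junctions with the two outer
# lines, because the in-plane affine coordinate that is 0 on one outer
# line and 1 on the other is linear both along the slice line and along
# the transversal. The reconstruction is therefore exact for any slice
# pose, tilted or not.

#' Tuning options for [localize_image()] and [run_mc()]
#'
#' @param use_sp include Sturm-Pastyr correspondences (M-style mirror
#'   diagonal pairs). These are exact only for untilted slices, with a
#'   second-order height error under gantry tilt; they enter the fit with
#'   the fixed weight `sp_weight` and only while the in-image tilt proxy
#'   stays below `sp_tilt_limit_deg`.
#' @param sp_weight weight of a Sturm-Pastyr correspondence.
#' @param sp_tilt_limit_deg maximum in-image panel-line inclination (from
#'   the image v axis, degrees) at which sp correspondences are used.
#' @param tol_sym tolerance (mm) for the M vertical-spacing symmetry
#'   check; `Inf` disables it. The default (3 mm, about three times the
#'   expected fiducial noise) flags gross label swaps without tripping on
#'   measurement noise.
#' @param tol_line tolerance (mm) for the per-panel collinearity check;
#'   `Inf` disables it (default 2 mm, same rationale).
#' @param gate matching radius (mm) for assigning predicted short-bar
#'   fiducials to observed ones.
#' @param max_iter maximum short-bar assignment/refit iterations.
#' @param weighted use the per-set error-amplification weights in the
#'   overdetermined fit (unweighted least squares otherwise).
#' @param f_window tolerated overshoot of the N-localizer ratio f outside
#'   [0, 1] before a set is rejected as lying outside its slab.
#' @param degeneracy_tol minimum image separation (mm) of the two outer
#'   fiducials of an N-kind set.
#' @param use_first_n restrict the fit to the first n correspondences (in
#'   deterministic set order); mainly for studying the overdetermination
#'   benefit.
#' @return A named list of options.
#' @export
localize_options <- function(use_sp = FALSE, sp_weight = 0.5,
                             sp_tilt_limit_deg = 10, tol_sym = 3,
                             tol_line = 2, gate = 2, max_iter = 5,
                             weighted = TRUE, f_window = 0.1,
                             degeneracy_tol = 0.5, use_first_n = NULL) {
  list(use_sp = use_sp, sp_weight = sp_weight,
       sp_tilt_limit_deg = sp_tilt_limit_deg, tol_sym = tol_sym,
       tol_line = tol_line, gate = gate, max_iter = max_iter,
       weighted = weighted, f_window = f_window,
       degeneracy_tol = degeneracy_tol, use_first_n = use_first_n)
}

#' Reconstruct a 3D point from an N-kind set of three fiducials
#'
#' Computes the distance ratio `f = |AB| / |AC|` of the three image
#' fiducials and places the reconstructed point at
#' `J_A + f (J_C - J_A)` along the transversal bar, where `J_A`, `J_C`
#' are the (precomputed) junctions of the transversal's line with the two
#' outer bars' lines. The correspondence carries the transversal
#' fiducial's (u, v), and a weight equal to the image outer separation
#' divided by the 3D junction-to-junction length — the inverse of the
#' set's error amplification, so that steep transversals (long junction
#' spans) contribute less to the fit.
#'
#' @param set one N-kind row from [enumerate_sets()] / internal set
#'   tables.
#' @param fid_a,fid_b,fid_c fiducials (one-row data frames or `(u, v)`
#'   vectors) for the first outer, the transversal, and the second outer.
#' @param f_window,degeneracy_tol see [localize_options()].
#' @return A one-row correspondence data frame (`u, v, x, y, z, w`).
#' @export
n_point <- function(set, fid_a, fid_b, fid_c, f_window = 0.1,
                    degeneracy_tol = 0.5) {
  a <- fid_uv(fid_a); b <- fid_uv(fid_b); c_ <- fid_uv(fid_c)
  ac <- c_ - a
  d_ac <- sqrt(sum(ac^2))
  if (d_ac <= degeneracy_tol)
    stop_classed("stereoloc_degenerate_set",
                 "outer fiducials are too close together")
  f <- sqrt(sum((b - a)^2)) / d_ac
  f_proj <- sum((b - a) * ac) / d_ac^2   # signed, detects overshoot side
  if (f > 1 + f_window || f_proj < -f_window)
    stop_classed("stereoloc_set_rejected",
                 sprintf("ratio f=%.3f outside the accepted slab window", f))
  if (f_proj < 0) f <- 0
  f <- min(f, 1)
  ja <- c(set$x, set$ja_y, set$ja_z)
  jc <- c(set$x, set$jc_y, set$jc_z)
  p <- ja + f * (jc - ja)
  data.frame(u = b[1], v = b[2], x = p[1], y = p[2], z = p[3],
             w = d_ac / set$span3, stringsAsFactors = FALSE)
}

#' Reconstruct a 3D point from a Sturm-Pastyr kind set
#'
#' For two mirror-image diagonals about a centre vertical, the image
#' distances `d1`, `d2` from the vertical's fiducial to the two diagonal
#' fiducials grow linearly with height above the apex where the diagonals
#' (extended) meet the vertical, so `(d1 + d2) / (2 s)` (with `s` the
#' diagonals' |dy/dz| slope) recovers the slice height on the vertical
#' bar. Exact for untilted slices; second-order height error under tilt.
#'
#' @param set one sp-kind set row.
#' @param fid_d1,fid_vc,fid_d2 fiducials of the first diagonal, centre
#'   vertical, and mirror diagonal.
#' @param sp_weight fixed fit weight of the correspondence.
#' @param H panel height, mm (for the validity window on the estimate).
#' @return A one-row correspondence data frame.
#' @export
sp_point <- function(set, fid_d1, fid_vc, fid_d2, sp_weight = 0.5, H = 120) {
  d1 <- fid_uv(fid_d1); vc <- fid_uv(fid_vc); d2 <- fid_uv(fid_d2)
  dist1 <- sqrt(sum((d1 - vc)^2)); dist2 <- sqrt(sum((d2 - vc)^2))
  z_est <- set$z_apex + set$sense * (dist1 + dist2) / (2 * set$slope)
  if (z_est < -1e-9 || z_est > H + 1e-9)
    stop_classed("stereoloc_set_rejected",
                 sprintf("Sturm-Pastyr height %.2f outside [0, %g]", z_est, H))
  data.frame(u = vc[1], v = vc[2], x = set$x, y = set$y_vc, z = z_est,
             w = sp_weight, stringsAsFactors = FALSE)
}

fid_uv <- function(f) {
  if (is.data.frame(f)) c(f$u[1], f$v[1]) else as.numeric(f[1:2])
}

#' Fit the stereotactic transform from 2D-3D correspondences
#'
#' Solves the affine system `(u_i, v_i, 1) %*% M = (x_i, y_i, z_i)` for
#' the 3x3 stereotactic matrix `M`: exactly when three correspondences
#' are given, otherwise by weighted least squares minimising
#' `sum w_i^2 ||(u_i,v_i,1) M - p_i||^2`. With exactly three
#' correspondences the weights have no effect.
#'
#' @param correspondences data frame with columns `u, v, x, y, z, w`.
#' @param weighted use the `w` column (ignored for an exact solve).
#' @return A `stereo_transform`: list with `M` (3x3), `rms_residual`
#'   (unweighted RMS of the 3D residual norms) and `n_used`.
#' @export
fit_transform <- function(correspondences, weighted = TRUE) {
  n <- nrow(correspondences)
  if (is.null(n) || n < 3)
    stop_classed("stereoloc_insufficient",
                 sprintf("%d correspondence(s); at least 3 are required", n %||% 0),
                 points = correspondences)
  A <- cbind(correspondences$u, correspondences$v, 1)
  B <- cbind(correspondences$x, correspondences$y, correspondences$z)
  if (qr(A)$rank < 3)
    stop_classed("stereoloc_singular",
                 "image fiducial positions are collinear; transform is singular")
  if (n == 3) {
    M <- solve(A, B)
  } else {
    w <- if (weighted) correspondences$w else rep(1, n)
    Aw <- A * w
    M <- solve(crossprod(Aw), crossprod(Aw, B * w))
  }
  res <- A %*% M - B
  structure(list(M = unname(M),
                 rms_residual = sqrt(mean(rowSums(res^2))),
                 n_used = n),
            class = "stereo_transform")
}

#' @export
print.stereo_transform <- function(x, ...) {
  cat(sprintf("<stereo_transform> n_used=%d  rms_residual=%.3g mm\n",
              x$n_used, x$rms_residual))
  print(signif(x$M, 6))
  invisible(x)
}

#' Map image coordinates to frame coordinates
#' @param transform a `stereo_transform`.
#' @param u,v image coordinates, mm (vectors allowed).
#' @return A matrix with columns `x, y, z` (a vector for scalar input).
#' @export
image_to_frame <- function(transform, u, v) {
  out <- cbind(u, v, 1) %*% transform$M
  colnames(out) <- c("x", "y", "z")
  if (length(u) == 1) out[1, ] else out
}

#' Map a frame point to image coordinates
#'
#' Least-squares inversion of the affine map: returns the in-plane
#' coordinates minimising `||(u,v,1) M - p||` plus the out-of-plane
#' residual distance.
#'
#' @param transform a `stereo_transform`.
#' @param p frame point `(x, y, z)`.
#' @return Named vector `(u, v, off_plane)`.
#' @export
frame_to_image <- function(transform, p) {
  D <- transform$M[1:2, , drop = FALSE]     # rows: action of u and v
  q <- as.numeric(p) - transform$M[3, ]
  uv <- qr.solve(t(D), q)
  off <- norm3(as.numeric(t(D) %*% uv) - q)
  c(u = uv[1], v = uv[2], off_plane = off)
}

# Plane implied by a fitted transform (used to predict short-bar fiducials).
plane_from_transform <- function(transform) {
  e_u <- unit3(transform$M[1, ])
  e_v <- transform$M[2, ] - sum(transform$M[2, ] * e_u) * e_u
  e_v <- unit3(e_v)
  structure(list(origin = transform$M[3, ], e_u = e_u, e_v = e_v,
                 normal = cross3(e_u, e_v)),
            class = "stereo_plane")
}

# ---- identification checks --------------------------------------------------

#' Vertical-spacing symmetry check for M-style panels
#'
#' With three correctly identified vertical fiducials the image distance
#' from the centre vertical to each outer vertical must be equal (bars
#' cut by a plane keep their panel symmetry in the image); a large
#' asymmetry signals mislabeled fiducials.
#'
#' @param fid_v1,fid_vc,fid_v2 the outer, centre, outer vertical
#'   fiducials.
#' @param tol pass tolerance, mm.
#' @return List with `pass` and `asymmetry` (mm).
#' @export
check_m_symmetry <- function(fid_v1, fid_vc, fid_v2, tol = 1) {
  a <- fid_uv(fid_v1); c0 <- fid_uv(fid_vc); b <- fid_uv(fid_v2)
  asym <- abs(sqrt(sum((a - c0)^2)) - sqrt(sum((b - c0)^2)))
  list(pass = asym <= tol, asymmetry = asym)
}

#' Collinearity check of one panel's fiducials
#'
#' Coplanar bars cut by a plane produce collinear image fiducials; this
#' fits a total-least-squares line through one panel's fiducials and
#' reports the maximum orthogonal residual. A fiducial far off the line
#' is mis-assigned (or belongs to the other panel).
#'
#' @param fiducials fiducial data frame rows of one panel.
#' @param tol pass tolerance, mm.
#' @return List with `pass`, `max_residual`, the line `centre` and unit
#'   `direction`.
#' @export
check_panel_collinearity <- function(fiducials, tol = 1) {
  X <- cbind(fiducials$u, fiducials$v)
  if (nrow(X) < 3)
    stop_classed("stereoloc_insufficient",
                 "at least 3 fiducials are needed for the collinearity check")
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr))
  dir <- sv$v[, 1]
  res <- abs(sweep(X, 2, ctr) %*% sv$v[, 2])
  list(pass = max(res) <= tol, max_residual = max(res),
       centre = ctr, direction = dir)
}

# ---- correspondence assembly ------------------------------------------------

# In-image inclination (degrees, from the image v axis) of a panel's
# fiducial line; the tilt proxy gating Sturm-Pastyr use.
panel_line_tilt <- function(fiducials) {
  X <- cbind(fiducials$u, fiducials$v)
  if (nrow(X) < 2) return(0)
  sv <- svd(sweep(X, 2, colMeans(X)))
  dir <- sv$v[, 1]
  atan2(abs(dir[1]), abs(dir[2])) * 180 / pi
}

# Build correspondences for the given set rows from labeled fiducials.
# Sets with missing/merged fiducials, failed bracketing, or rejected
# ratios are skipped.
build_correspondences <- function(sets, fiducials, options, H,
                                  sp_allowed = c(left = TRUE, right = TRUE)) {
  usable <- fiducials[!fiducials$merged & !is.na(fiducials$bar), ]
  if (!nrow(sets) || !nrow(usable)) return(empty_correspondences())
  key <- paste(usable$panel, usable$bar)
  out <- vector("list", nrow(sets))
  for (r in seq_len(nrow(sets))) {
    s <- sets[r, ]
    ia <- match(paste(s$panel, s$bar_a), key)
    ib <- match(paste(s$panel, s$bar_b), key)
    ic <- match(paste(s$panel, s$bar_c), key)
    if (anyNA(c(ia, ib, ic))) next
    fa <- usable[ia, ]; fb <- usable[ib, ]; fc <- usable[ic, ]
    if (s$kind == "n") {
      # bracketing: transversal fiducial strictly between the outers
      if (sum((c(fb$u, fb$v) - c(fa$u, fa$v)) *
              (c(fc$u, fc$v) - c(fb$u, fb$v))) <= 0) next
      corr <- tryCatch(
        n_point(s, fa, fb, fc, options$f_window, options$degeneracy_tol),
        stereoloc_error = function(e) NULL)
    } else {
      if (!options$use_sp || !isTRUE(sp_allowed[[s$panel]])) next
      corr <- tryCatch(
        sp_point(s, fa, fb, fc, options$sp_weight, H),
        stereoloc_error = function(e) NULL)
    }
    if (is.null(corr)) next
    corr$panel <- s$panel; corr$kind <- s$kind; corr$bar <- s$bar_b
    corr$full_span <- s$full_span
    out[[r]] <- corr
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_correspondences())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_correspondences <- function() {
  data.frame(u = numeric(), v = numeric(), x = numeric(), y = numeric(),
             z = numeric(), w = numeric(), panel = character(),
             kind = character(), bar = character(), full_span = logical(),
             stringsAsFactors = FALSE)
}

#' Label short-bar fiducials using an initial transform
#'
#' Predicts where each not-yet-labeled, non-support bar should appear in
#' the image (by intersecting it with the plane implied by `transform`
#' and mapping through [frame_to_image()]), then assigns the nearest
#' unlabeled, unmerged observed fiducial within `gate` millimetres.
#' Candidate bars are processed in sorted id order, nearest first, so the
#' assignment is deterministic.
#'
#' @param frame a `stereo_frame`.
#' @param fiducials fiducial data frame (mixed labeled/unlabeled).
#' @param transform an initial `stereo_transform` fitted from full-span
#'   bars.
#' @param gate matching radius, mm (> 0; 0 assigns nothing).
#' @return The fiducial data frame with newly labeled rows.
#' @export
assign_z_fiducials <- function(frame, fiducials, transform, gate = 2) {
  if (gate <= 0) return(fiducials)
  plane <- plane_from_transform(transform)
  have <- paste(fiducials$panel, fiducials$bar)[!is.na(fiducials$bar)]
  b <- frame$bars[frame$bars$role != "support", ]
  b <- b[!(paste(b$panel, b$bar) %in% have), ]
  b <- b[order(b$panel, b$bar), ]
  free <- which(is.na(fiducials$bar) & !fiducials$merged)
  for (i in seq_len(nrow(b))) {
    if (!length(free)) break
    p <- intersect_bar_plane(b[i, ], plane)
    if (is.null(p)) next
    uv <- frame_to_image(transform, p)
    d <- sqrt((fiducials$u[free] - uv[1])^2 + (fiducials$v[free] - uv[2])^2)
    j <- which.min(d)
    if (d[j] < gate) {
      k <- free[j]
      fiducials$bar[k] <- b$bar[i]
      fiducials$panel[k] <- b$panel[i]
      fiducials$role[k] <- b$role[i]
      fiducials$members[k] <- b$bar[i]
      free <- free[-j]
    }
  }
  fiducials
}

# ---- full pipeline ----------------------------------------------------------

#' Localize a single image from its fiducials
#'
#' The complete single-image pipeline: (1) unlabeled fiducials are first
#' identified by clustering them onto the two panel regression lines and
#' matching the along-line pattern of the full-span bars (see the
#' bootstrap notes in the package vignette); (2) per-panel collinearity
#' and, for the M preset, vertical-symmetry identification checks;
#' (3) correspondences from all valid full-span three-bar sets give an
#' initial transform; (4) remaining short bars (Z-style panels) are
#' labeled against that transform with [assign_z_fiducials()] and the
#' fit is repeated until the assignment is stable; (5) the final weighted
#' overdetermined fit over every valid set.
#'
#' A classic N bipanel reaches step (3) with only two reconstructed 3D
#' points and raises a `stereoloc_insufficient` error carrying them —
#' two panels of plain N-localizers cannot localize a single image.
#'
#' @param frame a `stereo_frame`.
#' @param fiducials fiducial data frame, labeled (from
#'   [observe_fiducials()]) or unlabeled (from [detect_fiducials()]).
#' @param options a [localize_options()] list.
#' @return A `stereo_transform` with a `diagnostics` element: counts of
#'   initial/final correspondences, the full-span transversal bars used
#'   by the initial fit, check results, and the number of assignment
#'   iterations.
#' @export
localize_image <- function(frame, fiducials, options = localize_options()) {
  stopifnot(inherits(frame, "stereo_frame"))
  fids <- fiducials
  unlabeled <- any(is.na(fids$bar) & !fids$merged)
  if (unlabeled) fids <- bootstrap_labels(frame, fids, options)

  checks <- run_identification_checks(frame, fids, options)
  sets <- candidate_sets(frame)
  sp_allowed <- sp_gate_by_tilt(fids, options)

  corr_full <- build_correspondences(sets[sets$full_span, ], fids, options,
                                     frame$H, sp_allowed)
  t_init <- NULL
  if (nrow(corr_full) >= 3)
    t_init <- tryCatch(fit_transform(corr_full, options$weighted),
                       stereoloc_error = function(e) NULL)

  iterations <- 0
  has_short <- any(frame$bars$role == "diagonal" &
                   (frame$bars$z1 - frame$bars$z0) < frame$H - 1e-9)
  if (unlabeled && has_short && !is.null(t_init)) {
    t_cur <- t_init
    repeat {
      iterations <- iterations + 1
      before <- sum(!is.na(fids$bar))
      fids <- assign_z_fiducials(frame, fids, t_cur, options$gate)
      corr <- build_correspondences(sets, fids, options, frame$H, sp_allowed)
      if (nrow(corr) >= 3)
        t_cur <- tryCatch(fit_transform(corr, options$weighted),
                          error = function(e) t_cur)
      if (sum(!is.na(fids$bar)) == before || iterations >= options$max_iter)
        break
    }
  }

  corr_all <- build_correspondences(sets, fids, options, frame$H, sp_allowed)
  if (!is.null(options$use_first_n) && nrow(corr_all)) {
    sel <- select_first_n(corr_all$panel, corr_all$bar, options$use_first_n)
    corr_all <- corr_all[sel, ]
  }
  if (nrow(corr_all) < 3)
    stop_classed("stereoloc_insufficient",
                 sprintf(paste("only %d 3D point(s) could be reconstructed;",
                               "at least 3 are required to solve the",
                               "stereotactic matrix"), nrow(corr_all)),
                 points = corr_all)
  t_final <- fit_transform(corr_all, options$weighted)
  init_bars <- unique(corr_full[corr_full$kind == "n", c("panel", "bar")])
  t_final$diagnostics <- list(
    n_initial = nrow(corr_full),
    initial_transversals = init_bars,
    n_final = nrow(corr_all),
    checks = checks,
    iterations = iterations,
    correspondences = corr_all)
  t_final
}

run_identification_checks <- function(frame, fids, options) {
  checks <- list()
  for (side in c("left", "right")) {
    pf <- fids[!fids$merged & !is.na(fids$panel) & fids$panel == side, ]
    if (nrow(pf) >= 3 && is.finite(options$tol_line)) {
      cl <- check_panel_collinearity(pf, options$tol_line)
      checks[[paste0("line_", side)]] <- cl
      if (!cl$pass)
        stop_classed("stereoloc_identification",
                     sprintf("panel %s fiducials deviate %.2f mm from their regression line",
                             side, cl$max_residual))
    }
    if (frame$preset == "m" && is.finite(options$tol_sym)) {
      v <- lapply(c("V1", "VC", "V2"), function(id)
        pf[!is.na(pf$bar) & pf$bar == id, ])
      if (all(vapply(v, nrow, integer(1)) == 1)) {
        sym <- check_m_symmetry(v[[1]], v[[2]], v[[3]], options$tol_sym)
        checks[[paste0("sym_", side)]] <- sym
        if (!sym$pass)
          stop_classed("stereoloc_identification",
                       sprintf("panel %s vertical fiducial spacing asymmetric by %.2f mm",
                               side, sym$asymmetry))
      }
    }
  }
  checks
}

sp_gate_by_tilt <- function(fids, options) {
  sapply(c("left", "right"), function(side) {
    pf <- fids[!fids$merged & !is.na(fids$panel) & fids$panel == side, ]
    if (nrow(pf) < 2) return(TRUE)
    panel_line_tilt(pf) <= options$sp_tilt_limit_deg
  }, simplify = FALSE)
}

# Deterministic choice of n correspondences for restricted ("determined")
# fits: alternate panels and prefer distinct transversal fiducials so a
# 3-element subset stays geometrically non-degenerate.
select_first_n <- function(panels, bars, n) {
  r <- stats::ave(seq_along(panels), panels, FUN = seq_along)
  ord <- order(r, panels)
  seen <- character(); pick <- integer()
  for (i in ord) {
    key <- paste(panels[i], bars[i])
    if (key %in% seen) next
    pick <- c(pick, i); seen <- c(seen, key)
    if (length(pick) == n) return(pick)
  }
  utils::head(c(pick, setdiff(ord, pick)), n)
}

# ---- unlabeled bootstrap ----------------------------------------------------

# Identify fiducials without labels.  Panels separate cleanly in u for
# realistic tilts, and along the panel's cut line the frame y coordinate
# is an affine function of arc length; anchoring that affine map on the
# two outermost fiducials (the verticals at y = -W/2 and +W/2 — every
# other usable bar stays strictly inside) turns each observed fiducial
# into an estimated panel y.  Scanning candidate slice heights and
# matching estimated against predicted bar positions then labels the
# full-span bars; short bars are labeled later against the initial
# transform.  Ambiguity (two height windows explaining the pattern with
# conflicting labels) raises an identification error instead of guessing.
bootstrap_labels <- function(frame, fids, options) {
  ok <- !fids$merged
  if (sum(ok) < 6)
    stop_classed("stereoloc_insufficient",
                 "too few usable fiducials to identify the panels")
  side <- ifelse(fids$u < stats::median(fids$u[ok]), "left", "right")
  for (it in 1:2) {  # refine the split against the two TLS lines
    lines <- lapply(c("left", "right"), function(s) {
      X <- cbind(fids$u[ok & side == s], fids$v[ok & side == s])
      ctr <- colMeans(X); sv <- svd(sweep(X, 2, ctr))
      list(ctr = ctr, n = sv$v[, 2])
    })
    d1 <- abs((cbind(fids$u, fids$v) - rep(lines[[1]]$ctr, each = nrow(fids))) %*% lines[[1]]$n)
    d2 <- abs((cbind(fids$u, fids$v) - rep(lines[[2]]$ctr, each = nrow(fids))) %*% lines[[2]]$n)
    side <- ifelse(d1 <= d2, "left", "right")
  }
  if (mean(fids$u[ok & side == "left"]) > mean(fids$u[ok & side == "right"]))
    side <- ifelse(side == "left", "right", "left")

  for (s in c("left", "right")) {
    idx <- which(ok & side == s)
    if (length(idx) < 3)
      stop_classed("stereoloc_insufficient",
                   sprintf("panel %s shows fewer than 3 usable fiducials", s))
    lab <- bootstrap_panel(frame, fids[idx, ], s, options)
    fids$panel[idx] <- s
    fids$bar[idx] <- lab$bar
    fids$role[idx] <- lab$role
    fids$members[idx] <- lab$bar
  }
  fids
}

bootstrap_panel <- function(frame, pf, side, options) {
  b <- frame$bars[frame$bars$panel == side, ]
  usable <- b[b$role != "support", ]
  full <- usable[usable$z0 <= 1e-9 & usable$z1 >= frame$H - 1e-9, ]
  X <- cbind(pf$u, pf$v)
  ctr <- colMeans(X); sv <- svd(sweep(X, 2, ctr))
  dir <- sv$v[, 1]
  if (dir[2] < 0) dir <- -dir           # +v correlates with +y
  if (abs(dir[2]) < 0.3)
    stop_classed("stereoloc_identification",
                 "panel line orientation too far from axial; cannot order fiducials")
  t <- as.numeric(sweep(X, 2, ctr) %*% dir)
  o <- order(t)
  # outermost fiducials anchor the verticals at y = -W/2 and +W/2
  yhat <- -frame$W / 2 +
    (t - t[o[1]]) / (t[o[length(o)]] - t[o[1]]) * frame$W

  zg <- seq(0.5, frame$H - 0.5, by = 0.5)
  best <- NULL
  for (z in zg) {
    pres <- bar_present_at(b, z)   # supports do appear in the image
    if (sum(pres) != nrow(pf)) next
    yp <- bar_y_at(b[pres, ], z)
    po <- order(yp)
    cost <- mean(abs(sort(yhat) - yp[po]))
    if (cost > 3) next
    labs <- character(nrow(pf))
    labs[order(yhat)] <- b$bar[pres][po]
    best[[length(best) + 1]] <- list(z = z, cost = cost, labs = labs)
  }
  if (!length(best))
    stop_classed("stereoloc_identification",
                 sprintf("no slice height explains the %s-panel fiducial pattern", side))
  costs <- vapply(best, `[[`, numeric(1), "cost")
  top <- best[[which.min(costs)]]
  # ambiguity: a clearly-fitting alternative labeling of the FULL-SPAN bars
  lab_full <- function(cand) {
    sel <- cand$labs %in% full$bar
    paste(cand$labs[sel][order(cand$labs[sel])],
          which(sel)[order(cand$labs[sel])], collapse = ";")
  }
  close_enough <- costs <= max(2 * min(costs), 0.5)
  alts <- unique(vapply(best[close_enough], lab_full, character(1)))
  if (length(alts) > 1)
    stop_classed("stereoloc_identification",
                 sprintf("ambiguous fiducial ordering on the %s panel", side))
  roles <- b$role[match(top$labs, b$bar)]
  keep_full <- top$labs %in% full$bar
  labs <- ifelse(keep_full, top$labs, NA_character_)
  roles <- ifelse(keep_full, roles, NA_character_)
  list(bar = labs, role = roles)
}
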