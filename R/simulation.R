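# Monte Carlo propagation of fiducial localization noise into target
# error: perturb the fiducial pattern of an axial slice, refit the
# stereotactic transform, map targets through it, and report the RMSE of
# the 3D target error across trials, per localizer, slice height and
# target position.

#' Default Monte Carlo target positions
#'
#' The six in-image targets of the error study: centre (0,0), right
#' (50,0), left (-50,0), anterior (0,50), posterior (0,-50) and
#' anterolateral (50,50), in image millimetres.
#' @return A 6 x 2 matrix of (u, v) targets.
#' @export
mc_default_targets <- function() {
  matrix(c(0, 0,  50, 0,  -50, 0,  0, 50,  0, -50,  50, 50),
         ncol = 2, byrow = TRUE, dimnames = list(NULL, c("u", "v")))
}

#' Run the Monte Carlo target-error study
#'
#' For every preset and slice height: observe the noise-free fiducial
#' pattern of the untilted axial slice (with realistic blob merging),
#' then repeatedly perturb each usable fiducial with independent uniform
#' noise on `[-noise_half_width, +noise_half_width]` per coordinate,
#' rebuild all valid three-bar correspondences, refit the weighted
#' transform, and map each target (u, v) through it. The reported RMSE
#' is the root mean squared 3D error-vector norm against the true plane
#' point, over accepted trials; trials where localization fails (too few
#' valid sets, singular fit) are counted in `n_rejected` and excluded.
#'
#' Noise cells are seeded as a pure function of `seed` and `z`, so runs
#' over different presets at the same heights see matched noise streams
#' and are directly comparable. The whole result is reproducible from
#' the configuration alone.
#'
#' @param presets character vector of preset names.
#' @param z_grid slice heights, mm.
#' @param targets matrix/data frame of (u, v) targets, mm.
#' @param n_trials trials per (preset, z) cell.
#' @param noise_half_width uniform noise half-width, mm.
#' @param seed integer master seed.
#' @param options a [localize_options()] list (the fast path mirrors the
#'   labeled route of [localize_image()]).
#' @param merge_threshold blob-merging distance passed to
#'   [observe_fiducials()], mm.
#' @return A `stereo_mc` data frame: `preset`, `z_mm`, `target_u_mm`,
#'   `target_v_mm`, `rmse_mm`, `n_trials`, `n_rejected`, `seed`. Cells
#'   whose every trial was rejected report `rmse_mm = NA`.
#' @export
run_mc <- function(presets, z_grid, targets = mc_default_targets(),
                   n_trials = 1e5, noise_half_width = 1, seed = 1,
                   options = localize_options(), merge_threshold = 2) {
  stopifnot(n_trials >= 1, noise_half_width >= 0)
  targets <- as.matrix(targets)
  rows <- list()
  for (preset in presets) {
    frame <- build_preset(preset)
    for (z in z_grid) {
      cell <- mc_cell(frame, z, targets, n_trials, noise_half_width,
                      seed, options, merge_threshold)
      rows[[length(rows) + 1]] <- data.frame(
        preset = preset, z_mm = z,
        target_u_mm = targets[, 1], target_v_mm = targets[, 2],
        rmse_mm = cell$rmse, n_trials = n_trials,
        n_rejected = cell$n_rejected, seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stereo_mc", "data.frame")
  out
}

# One (frame, z) Monte Carlo cell.  Precomputes the set geometry once and
# replays, per trial, exactly the correspondence rules of the labeled
# localize_image() route (bracketing, ratio window, degeneracy, weights).
mc_cell <- function(frame, z, targets, n_trials, hw, seed, options,
                    merge_threshold) {
  plane <- make_plane(z)
  fids0 <- observe_fiducials(frame, plane, merge_threshold)
  unm <- which(!fids0$merged)
  sets <- candidate_sets(frame)
  key <- paste(fids0$panel, fids0$bar)
  usable_key <- ifelse(fids0$merged | is.na(fids0$bar), NA, key)
  ia <- match(paste(sets$panel, sets$bar_a), usable_key)
  ib <- match(paste(sets$panel, sets$bar_b), usable_key)
  ic <- match(paste(sets$panel, sets$bar_c), usable_key)
  have <- !(is.na(ia) | is.na(ib) | is.na(ic))
  if (!options$use_sp) have <- have & sets$kind == "n"
  sets <- sets[have, ]; ia <- ia[have]; ib <- ib[have]; ic <- ic[have]
  is_n <- sets$kind == "n"
  ntar <- nrow(targets)
  A_t <- cbind(targets, 1)
  truth <- cbind(targets[, 1], targets[, 2], z)  # untilted axial plane
  sumsq <- numeric(ntar)
  n_rejected <- 0L
  if (!nrow(sets)) {
    return(list(rmse = rep(NA_real_, ntar), n_rejected = n_trials))
  }
  cell_seed <- as.integer((as.numeric(seed) + 131071 * round(z)) %% 2147483647)
  set.seed(cell_seed)
  n_acc <- 0L
  for (trial in seq_len(n_trials)) {
    U <- fids0$u; V <- fids0$v
    if (hw > 0 && length(unm)) {
      U[unm] <- U[unm] + stats::runif(length(unm), -hw, hw)
      V[unm] <- V[unm] + stats::runif(length(unm), -hw, hw)
    }
    au <- U[ia]; av <- V[ia]; bu <- U[ib]; bv <- V[ib]; cu <- U[ic]; cv <- V[ic]
    keep <- rep(TRUE, nrow(sets))
    f <- w <- px <- py <- pz <- numeric(nrow(sets))
    if (any(is_n)) {
      dacu <- cu - au; dacv <- cv - av
      dac <- sqrt(dacu^2 + dacv^2)
      fr <- sqrt((bu - au)^2 + (bv - av)^2) / dac
      fproj <- ((bu - au) * dacu + (bv - av) * dacv) / dac^2
      brack <- (bu - au) * (cu - bu) + (bv - av) * (cv - bv) > 0
      okn <- dac > options$degeneracy_tol & fr <= 1 + options$f_window &
        fproj >= -options$f_window & brack
      fcl <- pmin(ifelse(fproj < 0, 0, fr), 1)
      keep[is_n] <- okn[is_n]
      f[is_n] <- fcl[is_n]
      w[is_n] <- (dac / sets$span3)[is_n]
      px[is_n] <- sets$x[is_n]
      py[is_n] <- (sets$ja_y + fcl * (sets$jc_y - sets$ja_y))[is_n]
      pz[is_n] <- (sets$ja_z + fcl * (sets$jc_z - sets$ja_z))[is_n]
    }
    if (any(!is_n)) {
      sp <- !is_n
      d1 <- sqrt((au - bu)^2 + (av - bv)^2)
      d2 <- sqrt((cu - bu)^2 + (cv - bv)^2)
      zest <- sets$z_apex + sets$sense * (d1 + d2) / (2 * sets$slope)
      keep[sp] <- zest[sp] >= -1e-9 & zest[sp] <= frame$H + 1e-9
      w[sp] <- options$sp_weight
      px[sp] <- sets$x[sp]; py[sp] <- sets$y_vc[sp]; pz[sp] <- zest[sp]
    }
    ki <- which(keep)
    if (!is.null(options$use_first_n))
      ki <- ki[select_first_n(sets$panel[ki], sets$bar_b[ki],
                              options$use_first_n)]
    if (length(ki) < 3) { n_rejected <- n_rejected + 1L; next }
    A <- cbind(bu[ki], bv[ki], 1)  # correspondence uv = transversal / centre-vertical fiducial
    B <- cbind(px[ki], py[ki], pz[ki])
    wt <- if (options$weighted) w[ki] else rep(1, length(ki))
    M <- tryCatch({
      if (length(ki) == 3) solve(A, B)
      else { Aw <- A * wt; solve(crossprod(Aw), crossprod(Aw, B * wt)) }
    }, error = function(e) NULL)
    if (is.null(M)) { n_rejected <- n_rejected + 1L; next }
    err <- A_t %*% M - truth
    sumsq <- sumsq + rowSums(err^2)
    n_acc <- n_acc + 1L
  }
  rmse <- if (n_acc > 0) sqrt(sumsq / n_acc) else rep(NA_real_, ntar)
  list(rmse = rmse, n_rejected = n_rejected)
}

#' Rank localizer presets by Monte Carlo target error
#'
#' Pivots a [run_mc()] result to one row per (z, target) cell with each
#' preset's RMSE and its rank, and — when the m, f and z presets are all
#' present — the fraction of cells obeying the expected ordering
#' RMSE(Z) <= RMSE(M) <= RMSE(F). Cells where a preset rejected every
#' trial count as worst for that preset.
#'
#' @param mc a `stereo_mc` result with matched `z`/targets/trials/seed
#'   across presets.
#' @return List with `cells` (wide data frame), `fraction_zmf` (or `NA`
#'   if the three presets are not all present) and a one-line `verdict`.
#' @export
compare_presets <- function(mc) {
  stopifnot(inherits(mc, "data.frame"))
  presets <- unique(mc$preset)
  by_cfg <- split(mc, list(mc$z_mm, mc$target_u_mm, mc$target_v_mm),
                  drop = TRUE)
  cells <- lapply(by_cfg, function(g) {
    if (length(unique(g$n_trials)) != 1 || length(unique(g$seed)) != 1)
      stop_classed("stereoloc_config_mismatch",
                   "presets were run with different trials or seeds")
    r <- stats::setNames(g$rmse_mm, g$preset)[presets]
    rr <- ifelse(is.na(r), Inf, r)
    out <- data.frame(z_mm = g$z_mm[1], target_u_mm = g$target_u_mm[1],
                      target_v_mm = g$target_v_mm[1])
    for (p in presets) out[[paste0("rmse_", p)]] <- unname(r[p])
    out$best <- presets[which.min(rr)]
    if (all(c("z", "m", "f") %in% presets))
      out$zmf_ordered <- rr["z"] <= rr["m"] && rr["m"] <= rr["f"]
    out
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  cells <- cells[order(cells$z_mm, cells$target_u_mm, cells$target_v_mm), ]
  frac <- if ("zmf_ordered" %in% names(cells)) mean(cells$zmf_ordered) else NA
  verdict <- if (!is.na(frac)) {
    sprintf("RMSE(Z) <= RMSE(M) <= RMSE(F) in %.0f%% of %d cells%s",
            100 * frac, nrow(cells),
            if (frac > 0.5) " - ordering holds in the majority" else
              " - ordering does NOT hold in the majority")
  } else {
    sprintf("best preset per cell: %s",
            paste(names(sort(table(cells$best), decreasing = TRUE)),
                  collapse = " > "))
  }
  list(cells = cells, fraction_zmf = frac, verdict = verdict)
}

#' Write a Monte Carlo result to CSV
#'
#' @param mc a `stereo_mc` data frame.
#' @param path output CSV path.
#' @export
write_mc_csv <- function(mc, path) {
  utils::write.csv(as.data.frame(mc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
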