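# Localizer frame geometry: panel presets, bar bookkeeping, and enumeration
# of the three-bar localization sets available in a given axial slice.
#
# Frame coordinates are right-handed millimetres: +x patient-right,
# +y anterior, +z superior, origin at the frame centre with z = 0 at the
# bottom edge of the panels.  Each panel is planar (x = -R for the left
# panel, x = +R for the right) and is described in panel-local (y, z)
# coordinates with y in [-W/2, +W/2] and z in [0, H].  The right panel is
# the left panel inverted top-to-bottom ("antiparallel"): panel-local
# (y, z) maps to frame (+R, y, H - z).

#' Build a bipanel localizer frame from a named preset
#'
#' Constructs one of the built-in rod layouts as a full bipanel frame:
#' the classic N-localizer (`"n"`) and the richer `"m"`, `"f"` and `"z"`
#' panels. All presets place one panel at `x = -R` (left) and the same
#' panel, inverted top-to-bottom, at `x = +R` (right).
#'
#' Bar layouts per panel (default `W = H = 120` mm; all coordinates scale
#' proportionally with `W` and `H`):
#' \describe{
#'   \item{n}{verticals at `y = -W/2, +W/2` and one full diagonal.}
#'   \item{m}{three verticals (`-W/2, 0, +W/2`) and two diagonals meeting
#'     at a bottom-centre apex, tracing the letter M.}
#'   \item{f}{two verticals, one 45-degree primary diagonal, and two
#'     mirror pairs of steeper diagonals (slope 1/3 from vertical).}
#'   \item{z}{two usable verticals, two full-height 45-degree diagonals,
#'     ten short 45-degree zig-zag segments in three columns, and four
#'     supporting verticals (`role = "support"`) that terminate the short
#'     segments and are excluded from localization.}
#' }
#'
#' @param name preset name, one of `"n"`, `"m"`, `"f"`, `"z"`.
#' @param W panel width (outer vertical separation), mm.
#' @param H panel height, mm.
#' @param R half-separation of the two panel planes, mm.
#' @return A `stereo_frame` object: a list with `preset`, `W`, `H`, `R`
#'   and a `bars` data frame (columns `panel`, `bar`, `role`, and the
#'   frame-coordinate endpoints `x0,y0,z0,x1,y1,z1` with `z0 <= z1`).
#' @examples
#' fr <- build_preset("m")
#' table(fr$bars$panel, fr$bars$role)
#' @export
build_preset <- function(name, W = 120, H = 120, R = 95) {
  name <- tolower(name)
  if (!name %in% c("n", "m", "f", "z"))
    stop_classed("stereoloc_bad_preset", sprintf("unknown preset '%s'", name))
  if (!all(is.finite(c(W, H, R))) || W <= 0 || H <= 0 || R <= 0)
    stop_classed("stereoloc_bad_preset", "frame dimensions W, H, R must be positive")
  local <- preset_panel_local(name)
  # layouts are written for a 120 x 120 panel; scale to W x H
  sy <- W / 120; sz <- H / 120
  local$y0 <- local$y0 * sy; local$y1 <- local$y1 * sy
  local$z0 <- local$z0 * sz; local$z1 <- local$z1 * sz
  frame_from_panel_local(name, local, W, H, R)
}

# Panel-local bar table for one panel of each preset (120 x 120 units).
preset_panel_local <- function(name) {
  seg <- function(bar, role, y0, z0, y1, z1)
    data.frame(bar = bar, role = role, y0 = y0, z0 = z0, y1 = y1, z1 = z1,
               stringsAsFactors = FALSE)
  switch(name,
    n = rbind(
      seg("V1", "vertical", -60, 0, -60, 120),
      seg("V2", "vertical",  60, 0,  60, 120),
      seg("D1", "diagonal", -60, 0,  60, 120)),
    m = rbind(
      seg("V1", "vertical", -60, 0, -60, 120),
      seg("VC", "vertical",   0, 0,   0, 120),
      seg("V2", "vertical",  60, 0,  60, 120),
      seg("D1", "diagonal", -60, 120, 0,   0),
      seg("D2", "diagonal",   0,   0, 60, 120)),
    f = rbind(
      seg("V1", "vertical", -60, 0, -60, 120),
      seg("V2", "vertical",  60, 0,  60, 120),
      seg("D1", "diagonal", -60, 0,  60, 120),
      seg("D2", "diagonal", -50, 0, -10, 120),
      seg("D3", "diagonal",  10, 0,  50, 120),
      seg("D4", "diagonal",  50, 0,  10, 120),
      seg("D5", "diagonal", -10, 0, -50, 120)),
    z = rbind(
      seg("V1", "vertical", -60, 0, -60, 120),
      seg("V2", "vertical",  60, 0,  60, 120),
      seg("D1", "diagonal", -60, 0,  60, 120),
      seg("D2", "diagonal", -60, 120, 60, 0),
      # zig-zag column A, y in [-60, -30]
      seg("ZA1", "diagonal", -30,  0, -60,  30),
      seg("ZA2", "diagonal", -60, 30, -30,  60),
      seg("ZA3", "diagonal", -30, 60, -60,  90),
      seg("ZA4", "diagonal", -60, 90, -30, 120),
      # zig-zag column B, y in [-25, 15]
      seg("ZB1", "diagonal", -25,  0,  15,  40),
      seg("ZB2", "diagonal",  15, 40, -25,  80),
      seg("ZB3", "diagonal", -25, 80,  15, 120),
      # zig-zag column C, y in [15, 55]
      seg("ZC1", "diagonal",  15,  0,  55,  40),
      seg("ZC2", "diagonal",  55, 40,  15,  80),
      seg("ZC3", "diagonal",  15, 80,  55, 120),
      seg("S1", "support", -30, 0, -30, 120),
      seg("S2", "support", -25, 0, -25, 120),
      seg("S3", "support",  15, 0,  15, 120),
      seg("S4", "support",  55, 0,  55, 120)))
}

# Map one panel-local bar table onto both panel planes (antiparallel pair).
frame_from_panel_local <- function(preset, local, W, H, R) {
  span <- abs(local$z1 - local$z0)
  if (any(span < 1e-9))
    stop_classed("stereoloc_bad_geometry", "bars may not be horizontal")
  mk <- function(side) {
    x <- if (side == "left") -R else R
    z0 <- if (side == "left") local$z0 else H - local$z0
    z1 <- if (side == "left") local$z1 else H - local$z1
    b <- data.frame(panel = side, bar = local$bar, role = local$role,
                    x0 = x, y0 = local$y0, z0 = z0,
                    x1 = x, y1 = local$y1, z1 = z1,
                    stringsAsFactors = FALSE)
    swap <- b$z0 > b$z1
    if (any(swap)) {
      tmp <- b[swap, c("y0", "z0")]
      b[swap, c("y0", "z0")] <- b[swap, c("y1", "z1")]
      b[swap, c("y1", "z1")] <- tmp
    }
    b
  }
  bars <- rbind(mk("left"), mk("right"))
  rownames(bars) <- NULL
  structure(list(preset = preset, W = W, H = H, R = R, bars = bars),
            class = "stereo_frame")
}

#' @export
print.stereo_frame <- function(x, ...) {
  cat(sprintf("<stereo_frame> preset '%s'  W=%g H=%g R=%g mm\n",
              x$preset, x$W, x$H, x$R))
  tab <- table(x$bars$panel, x$bars$role)
  print(tab)
  invisible(x)
}

# ---- per-bar helpers (all in frame coordinates) -----------------------------

# Is the bar present in the axial slice at height z?  Spans are half-open
# [z0, z1): the lower endpoint belongs to the bar, the upper does not, so a
# zig-zag junction contributes exactly one fiducial.
bar_present_at <- function(bars, z) z >= bars$z0 & z < bars$z1

# Panel-plane y position of each bar at height z (bars must be present).
bar_y_at <- function(bars, z) {
  bars$y0 + (z - bars$z0) / (bars$z1 - bars$z0) * (bars$y1 - bars$y0)
}

# Unit in-plane direction (dy, dz) of each bar.
bar_dir2 <- function(bars) {
  d <- cbind(bars$y1 - bars$y0, bars$z1 - bars$z0)
  d / sqrt(rowSums(d^2))
}

# ---- localization sets ------------------------------------------------------

# All structurally possible three-bar sets for every panel, without reference
# to a slice height.  N-kind sets pair two parallel bars (the outers) with a
# non-parallel transversal; the junctions J_A, J_C of the transversal's line
# with the two outer lines are precomputed, along with their 3D separation.
# Sturm-Pastyr (sp) kind sets pair two mirror-image diagonals with the
# vertical bar on their mirror axis.  Support bars never participate.
candidate_sets <- function(frame) {
  out <- list()
  for (side in c("left", "right")) {
    b <- frame$bars[frame$bars$panel == side & frame$bars$role != "support", ]
    b <- b[order(b$bar), ]
    n <- nrow(b)
    if (n < 3) next
    dirs <- bar_dir2(b)
    x <- b$x0[1]
    par <- abs(outer(dirs[, 1], dirs[, 2]) - outer(dirs[, 2], dirs[, 1])) < 1e-9
    # n-kind
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      if (!par[i, j]) next
      for (k in seq_len(n)) {
        if (k == i || k == j || par[i, k]) next
        ja <- line_intersect2(b[k, ], b[i, ])
        jc <- line_intersect2(b[k, ], b[j, ])
        out[[length(out) + 1]] <- data.frame(
          panel = side, kind = "n",
          bar_a = b$bar[i], bar_b = b$bar[k], bar_c = b$bar[j],
          x = x, ja_y = ja[1], ja_z = ja[2], jc_y = jc[1], jc_z = jc[2],
          span3 = sqrt(sum((jc - ja)^2)),
          y_vc = NA_real_, slope = NA_real_, z_apex = NA_real_,
          sense = NA_real_,
          full_span = all(b$z0[c(i, j, k)] <= 1e-9) &&
                      all(b$z1[c(i, j, k)] >= frame$H - 1e-9),
          stringsAsFactors = FALSE)
      }
    }
    # sp-kind: mirror diagonal pairs about a usable vertical
    vs <- which(b$role == "vertical")
    ds <- which(b$role == "diagonal")
    for (v in vs) {
      yv <- b$y0[v]
      if (length(ds) < 2) next
      for (i in ds) for (j in ds) {
        if (i >= j) next
        m0 <- c(2 * yv - b$y0[i], b$z0[i]); m1 <- c(2 * yv - b$y1[i], b$z1[i])
        e0 <- c(b$y0[j], b$z0[j]); e1 <- c(b$y1[j], b$z1[j])
        mirror <- (max(abs(m0 - e0), abs(m1 - e1)) < 1e-9) ||
                  (max(abs(m0 - e1), abs(m1 - e0)) < 1e-9)
        if (!mirror) next
        dzi <- b$z1[i] - b$z0[i]; dyi <- b$y1[i] - b$y0[i]
        if (abs(dyi) < 1e-12) next
        slope <- abs(dyi / dzi)            # |dy/dz| of each diagonal
        z_apex <- b$z0[i] + (yv - b$y0[i]) * dzi / dyi
        sense <- sign((b$z0[i] + b$z1[i]) / 2 - z_apex)
        out[[length(out) + 1]] <- data.frame(
          panel = side, kind = "sp",
          bar_a = b$bar[i], bar_b = b$bar[v], bar_c = b$bar[j],
          x = x, ja_y = NA_real_, ja_z = NA_real_,
          jc_y = NA_real_, jc_z = NA_real_, span3 = NA_real_,
          y_vc = yv, slope = slope, z_apex = z_apex, sense = sense,
          full_span = all(b$z0[c(i, j, v)] <= 1e-9) &&
                      all(b$z1[c(i, j, v)] >= frame$H - 1e-9),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_sets())
  sets <- do.call(rbind, out)
  sets <- sets[order(sets$panel, sets$kind, sets$bar_a, sets$bar_b, sets$bar_c), ]
  rownames(sets) <- NULL
  sets
}

empty_sets <- function() {
  data.frame(panel = character(), kind = character(), bar_a = character(),
             bar_b = character(), bar_c = character(), x = numeric(),
             ja_y = numeric(), ja_z = numeric(), jc_y = numeric(),
             jc_z = numeric(), span3 = numeric(), y_vc = numeric(),
             slope = numeric(), z_apex = numeric(), sense = numeric(),
             full_span = logical(), stringsAsFactors = FALSE)
}

# Intersection (y, z) of the infinite lines through two bars (rows of the
# bars table), in the common panel plane.
line_intersect2 <- function(t, o) {
  pt <- c(t$y0, t$z0); dt <- c(t$y1 - t$y0, t$z1 - t$z0)
  po <- c(o$y0, o$z0); do <- c(o$y1 - o$y0, o$z1 - o$z0)
  den <- dt[1] * do[2] - dt[2] * do[1]
  if (abs(den) < 1e-12)
    stop_classed("stereoloc_bad_geometry", "parallel lines do not intersect")
  s <- ((po[1] - pt[1]) * do[2] - (po[2] - pt[2]) * do[1]) / den
  pt + s * dt
}

#' Enumerate usable three-bar localization sets in an axial slice
#'
#' Lists every three-bar set a panel offers at slice height `z`.  An
#' N-kind set consists of two parallel bars (the outers) and a
#' non-parallel transversal whose intersection with the slice lies
#' strictly between the outers'; a Sturm-Pastyr (sp) kind set consists of
#' two mirror-image diagonals and the vertical bar on their mirror axis.
#' All three bars must be physically cut by the slice (half-open spans:
#' a bar owns its lower endpoint but not its upper). Support bars never
#' appear in a set.
#'
#' @param frame a `stereo_frame`.
#' @param z axial slice height, mm, strictly inside `(0, H)`.
#' @param panel optionally restrict to `"left"` or `"right"`.
#' @return A data frame with one row per set: `panel`, `kind` (`"n"` or
#'   `"sp"`), the bar ids `bar_a`, `bar_b`, `bar_c` (for N-kind `bar_b`
#'   is the transversal; for sp-kind it is the centre vertical), and the
#'   precomputed junction geometry used by [n_point()] / [sp_point()].
#'   Rows are sorted by panel, kind and bar ids.
#' @examples
#' nrow(enumerate_sets(build_preset("m"), 60, panel = "left"))  # 5
#' @export
enumerate_sets <- function(frame, z, panel = NULL) {
  stopifnot(inherits(frame, "stereo_frame"))
  if (!is.finite(z) || z <= 0 || z >= frame$H)
    stop_classed("stereoloc_bad_slice",
                 sprintf("slice height z=%g outside (0, %g)", z, frame$H))
  sets <- candidate_sets(frame)
  if (!is.null(panel)) sets <- sets[sets$panel == panel, ]
  keep <- vapply(seq_len(nrow(sets)), function(r) {
    set_valid_at(frame, sets[r, ], z)
  }, logical(1))
  sets <- sets[keep, ]
  rownames(sets) <- NULL
  sets
}

# Geometric validity of one set at axial height z: all three bars present
# and, for n-kind, transversal y strictly between the outers' y.
set_valid_at <- function(frame, set, z) {
  b <- frame$bars
  idx <- match(paste(set$panel, c(set$bar_a, set$bar_b, set$bar_c)),
               paste(b$panel, b$bar))
  bb <- b[idx, ]
  if (!all(bar_present_at(bb, z))) return(FALSE)
  if (set$kind == "n") {
    y <- bar_y_at(bb, z)
    return(y[2] > min(y[1], y[3]) + 1e-12 && y[2] < max(y[1], y[3]) - 1e-12)
  }
  TRUE
}

#' Check a frame for fiducial merge zones and degenerate bars
#'
#' At each height in `z_grid`, flags every pair of bars whose axial
#' intersection points lie closer than `min_sep` (their image fiducials
#' would blend into one blob and become unusable).  Independently of the
#' grid, any two distinct bars lying on the same line are reported as a
#' fatal geometry error.
#'
#' @param frame a `stereo_frame`.
#' @param z_grid heights to check, mm.
#' @param min_sep minimum resolvable fiducial separation, mm (default 2,
#'   the approximate CT blob-merging scale).
#' @return A list with `merges` (data frame `z`, `panel`, `bar1`, `bar2`,
#'   `dist`) and `collinear` (data frame `panel`, `bar1`, `bar2`,
#'   `severity = "fatal"`).
#' @export
validate_geometry <- function(frame, z_grid, min_sep = 2) {
  stopifnot(inherits(frame, "stereo_frame"), min_sep >= 0)
  merges <- list()
  for (z in z_grid) {
    for (side in c("left", "right")) {
      b <- frame$bars[frame$bars$panel == side, ]
      b <- b[bar_present_at(b, z), ]
      if (nrow(b) < 2) next
      y <- bar_y_at(b, z)
      for (i in seq_len(nrow(b) - 1)) for (j in seq((i + 1), nrow(b))) {
        d <- abs(y[i] - y[j])
        if (d < min_sep)
          merges[[length(merges) + 1]] <- data.frame(
            z = z, panel = side, bar1 = b$bar[i], bar2 = b$bar[j], dist = d,
            stringsAsFactors = FALSE)
      }
    }
  }
  coll <- list()
  for (side in c("left", "right")) {
    b <- frame$bars[frame$bars$panel == side, ]
    dirs <- bar_dir2(b)
    for (i in seq_len(nrow(b) - 1)) for (j in seq((i + 1), nrow(b))) {
      if (abs(dirs[i, 1] * dirs[j, 2] - dirs[i, 2] * dirs[j, 1]) >= 1e-9) next
      # parallel: collinear iff bar j's start lies on bar i's line
      w <- c(b$y0[j] - b$y0[i], b$z0[j] - b$z0[i])
      off <- abs(w[1] * dirs[i, 2] - w[2] * dirs[i, 1])
      if (off < 1e-9)
        coll[[length(coll) + 1]] <- data.frame(
          panel = side, bar1 = b$bar[i], bar2 = b$bar[j], severity = "fatal",
          stringsAsFactors = FALSE)
    }
  }
  list(
    merges = if (length(merges)) do.call(rbind, merges) else
      data.frame(z = numeric(), panel = character(), bar1 = character(),
                 bar2 = character(), dist = numeric(), stringsAsFactors = FALSE),
    collinear = if (length(coll)) do.call(rbind, coll) else
      data.frame(panel = character(), bar1 = character(), bar2 = character(),
                 severity = character(), stringsAsFactors = FALSE),
    min_sep = min_sep)
}

# ---- geometry interchange ---------------------------------------------------

#' Export a localizer frame to a JSON document
#'
#' Writes the frame as structured JSON (`preset`, `params`, and per-panel
#' bar lists with `p_low`/`p_high` endpoints in frame millimetres), the
#' interchange format read back by [import_geometry()].
#'
#' @param frame a `stereo_frame`.
#' @param path file path; if `NULL` the JSON string is returned.
#' @export
export_geometry <- function(frame, path = NULL) {
  panels <- lapply(c("left", "right"), function(side) {
    b <- frame$bars[frame$bars$panel == side, ]
    list(id = side, side = side,
         bars = lapply(seq_len(nrow(b)), function(i) list(
           id = b$bar[i], role = b$role[i],
           p_low = c(b$x0[i], b$y0[i], b$z0[i]),
           p_high = c(b$x1[i], b$y1[i], b$z1[i]))))
  })
  doc <- list(preset = frame$preset,
              params = list(W = frame$W, H = frame$H, R = frame$R),
              panels = panels)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a localizer frame from its JSON interchange document
#'
#' @param path file path or a JSON string produced by [export_geometry()].
#' @return A `stereo_frame`.
#' @export
import_geometry <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- list()
  for (p in doc$panels) for (b in p$bars) {
    lo <- unlist(b$p_low); hi <- unlist(b$p_high)
    if (lo[3] > hi[3]) { tmp <- lo; lo <- hi; hi <- tmp }
    rows[[length(rows) + 1]] <- data.frame(
      panel = p$id, bar = b$id, role = b$role,
      x0 = lo[1], y0 = lo[2], z0 = lo[3],
      x1 = hi[1], y1 = hi[2], z1 = hi[3], stringsAsFactors = FALSE)
  }
  bars <- do.call(rbind, rows)
  rownames(bars) <- NULL
  structure(list(preset = doc$preset %||% "custom",
                 W = doc$params$W, H = doc$params$H, R = doc$params$R,
                 bars = bars),
            class = "stereo_frame")
}
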