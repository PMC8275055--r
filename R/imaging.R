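# Image-plane forward model: pose an image plane in frame space, intersect
# bars with it, project intersections to in-plane (u, v) millimetre
# coordinates, add measurement noise, rasterise synthetic CT slices and
# detect fiducial centroids in them.

#' Construct an image plane
#'
#' An axial plane at height `z` (origin `(0,0,z)`, `e_u = (1,0,0)`,
#' `e_v = (0,1,0)`), optionally tilted: first by `tilt_u` degrees about
#' `e_u`, then by `tilt_v` degrees about the (already tilted) `e_v`,
#' both about the plane origin — modelling gantry tilt.
#'
#' @param z slice height, mm.
#' @param tilt_u,tilt_v tilt angles in degrees.
#' @return A `stereo_plane`: list with `origin`, unit vectors `e_u`,
#'   `e_v`, and `normal`.
#' @examples
#' make_plane(60, 10, 0)$e_v  # (0, cos10, sin10)
#' @export
make_plane <- function(z, tilt_u = 0, tilt_v = 0) {
  e_u <- c(1, 0, 0); e_v <- c(0, 1, 0)
  if (tilt_u != 0) e_v <- rotate_about(e_v, e_u, tilt_u)
  if (tilt_v != 0) e_u <- rotate_about(e_u, e_v, tilt_v)
  structure(list(origin = c(0, 0, z), e_u = e_u, e_v = e_v,
                 normal = cross3(e_u, e_v)),
            class = "stereo_plane")
}

#' Intersect one bar with an image plane
#'
#' Returns the unique point where the bar's segment crosses the plane, or
#' `NULL` when the segment does not reach it. Spans are half-open: the
#' `p_low` endpoint belongs to the bar, `p_high` does not, so two
#' segments sharing a junction produce exactly one intersection. A bar
#' parallel to the plane yields `NULL`.
#'
#' @param bar one row of a frame's `bars` table.
#' @param plane a `stereo_plane`.
#' @return Numeric `(x, y, z)` or `NULL`.
#' @export
intersect_bar_plane <- function(bar, plane) {
  p0 <- c(bar$x0, bar$y0, bar$z0)
  p1 <- c(bar$x1, bar$y1, bar$z1)
  d <- p1 - p0
  den <- sum(plane$normal * d)
  if (abs(den) < 1e-12) return(NULL)
  t <- sum(plane$normal * (plane$origin - p0)) / den
  if (t < 0 || t >= 1) return(NULL)
  p0 + t * d
}

#' Project an on-plane 3D point to image (u, v) coordinates
#'
#' @param plane a `stereo_plane`.
#' @param p frame-coordinate point lying on the plane (out-of-plane
#'   distance below 1e-9 mm).
#' @return Numeric `(u, v)` in mm.
#' @export
project_point <- function(plane, p) {
  w <- p - plane$origin
  if (abs(sum(w * plane$normal)) > 1e-9)
    stop_classed("stereoloc_off_plane", "point does not lie on the image plane")
  c(u = sum(w * plane$e_u), v = sum(w * plane$e_v))
}

#' Compute the fiducial pattern a frame produces in an image plane
#'
#' Intersects every bar (supports included) with the plane and projects
#' the hits to image coordinates. Any group of fiducials closer than
#' `merge_threshold` (single-linkage) is replaced by one unlabeled
#' fiducial at the group centroid with `merged = TRUE`; merged blobs
#' model the resolution limit of real images and are never used in
#' localization.
#'
#' @param frame a `stereo_frame`.
#' @param plane a `stereo_plane`.
#' @param merge_threshold blob-merging distance, mm; 0 disables merging.
#' @return A fiducial data frame: `u`, `v`, `panel`, `bar` (NA when
#'   merged), `role`, `merged`, `members` (comma-joined contributing bar
#'   ids).
#' @export
observe_fiducials <- function(frame, plane, merge_threshold = 2) {
  stopifnot(merge_threshold >= 0)
  rows <- list()
  for (i in seq_len(nrow(frame$bars))) {
    p <- intersect_bar_plane(frame$bars[i, ], plane)
    if (is.null(p)) next
    uv <- project_point(plane, p)
    rows[[length(rows) + 1]] <- data.frame(
      u = uv[1], v = uv[2], panel = frame$bars$panel[i],
      bar = frame$bars$bar[i], role = frame$bars$role[i],
      merged = FALSE, members = frame$bars$bar[i], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_fiducials())
  f <- do.call(rbind, rows)
  rownames(f) <- NULL
  if (merge_threshold > 0 && nrow(f) > 1) f <- merge_fiducials(f, merge_threshold)
  f
}

empty_fiducials <- function() {
  data.frame(u = numeric(), v = numeric(), panel = character(),
             bar = character(), role = character(), merged = logical(),
             members = character(), stringsAsFactors = FALSE)
}

# Single-linkage grouping of fiducials with pairwise distance < threshold.
merge_fiducials <- function(f, threshold) {
  n <- nrow(f)
  d <- as.matrix(stats::dist(cbind(f$u, f$v)))
  adj <- d < threshold
  comp <- rep(NA_integer_, n); cur <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    queue <- i
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[k])) next
      comp[k] <- cur
      queue <- c(queue, which(adj[k, ] & is.na(comp)))
    }
  }
  out <- lapply(unique(comp), function(g) {
    idx <- which(comp == g)
    if (length(idx) == 1) return(f[idx, ])
    data.frame(u = mean(f$u[idx]), v = mean(f$v[idx]),
               panel = if (length(unique(f$panel[idx])) == 1) f$panel[idx][1] else NA_character_,
               bar = NA_character_, role = "merged", merged = TRUE,
               members = paste(sort(f$bar[idx]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Add uniform measurement noise to fiducial coordinates
#'
#' Shifts `u` and `v` of every non-merged fiducial independently by
#' uniform noise on `[-half_width, +half_width]`, emulating fiducial
#' localization error. Merged fiducials are left untouched (they are
#' excluded from localization rather than measured).
#'
#' @param fiducials a fiducial data frame.
#' @param half_width noise half-width, mm.
#' @param seed optional integer; when given the perturbation is
#'   reproducible and the caller's RNG state is preserved.
#' @export
perturb_fiducials <- function(fiducials, half_width, seed = NULL) {
  stopifnot(half_width >= 0)
  idx <- which(!fiducials$merged)
  n <- length(idx)
  if (n == 0 || half_width == 0) return(fiducials)
  with_seed(seed, {
    fiducials$u[idx] <- fiducials$u[idx] + stats::runif(n, -half_width, half_width)
    fiducials$v[idx] <- fiducials$v[idx] + stats::runif(n, -half_width, half_width)
    fiducials
  })
}

# ---- synthetic CT rendering -------------------------------------------------

# Pixel (row i, col j, 1-based) <-> (u, v): the centre pixel
# (floor(rows/2)+1, floor(cols/2)+1) sits at (u, v) = (0, 0); u grows with
# the column index, v decreases with the row index (image rows run
# posterior-ward for an axial slice).
pixel_centre <- function(rows, cols) c(floor(rows / 2) + 1, floor(cols / 2) + 1)

uv_to_pixel <- function(u, v, rows, cols, spacing) {
  ctr <- pixel_centre(rows, cols)
  cbind(i = ctr[1] - v / spacing, j = ctr[2] + u / spacing)
}

pixel_to_uv <- function(i, j, rows, cols, spacing) {
  ctr <- pixel_centre(rows, cols)
  cbind(u = (j - ctr[2]) * spacing, v = (ctr[1] - i) * spacing)
}

#' Render a synthetic CT slice of a localizer frame
#'
#' Rasterises each rod intersected by the plane as a filled disc at its
#' projected (u, v) position, with area-weighted antialiasing at the disc
#' edge (supersampling).  Values are HU-like: air background, bright rods,
#' optionally a soft-tissue ellipse standing in for the head.
#'
#' @param frame a `stereo_frame`.
#' @param plane a `stereo_plane`.
#' @param rows,cols image matrix size in pixels.
#' @param pixel_spacing pixel size, mm (default 0.7, a typical CT value).
#' @param rod_diameter rendered rod diameter, mm.
#' @param rod_value,background_value stored pixel values (HU).
#' @param tissue draw a soft-tissue ellipse (semi-axes 70 x 85 mm) at
#'   `tissue_value` HU.
#' @param tissue_value HU of the tissue ellipse.
#' @param supersample antialiasing subsamples per pixel edge.
#' @return A `stereo_image`: list with the pixel matrix (`pixels`), the
#'   `plane`, and the raster parameters.
#' @export
render_ct <- function(frame, plane, rows = 512, cols = 512,
                      pixel_spacing = 0.7, rod_diameter = 3,
                      rod_value = 3000, background_value = -1000,
                      tissue = FALSE, tissue_value = 40, supersample = 4) {
  stopifnot(rows > 0, cols > 0, pixel_spacing > 0, rod_diameter > 0,
            rod_value > background_value)
  img <- matrix(background_value, rows, cols)
  if (tissue) {
    uv <- pixel_to_uv(row(img), col(img), rows, cols, pixel_spacing)
    inside <- (uv[, 1] / 70)^2 + (uv[, 2] / 85)^2 <= 1
    img[matrix(inside, rows, cols)] <- tissue_value
  }
  pts <- observe_fiducials(frame, plane, merge_threshold = 0)
  if (nrow(pts) == 0) {
    warning("image plane misses every bar; rendering pure background")
  } else {
    cov <- matrix(0, rows, cols)
    r_px <- (rod_diameter / 2) / pixel_spacing
    offs <- (seq_len(supersample) - 0.5) / supersample - 0.5
    for (k in seq_len(nrow(pts))) {
      c_px <- uv_to_pixel(pts$u[k], pts$v[k], rows, cols, pixel_spacing)
      i0 <- max(1, floor(c_px[1] - r_px - 1)); i1 <- min(rows, ceiling(c_px[1] + r_px + 1))
      j0 <- max(1, floor(c_px[2] - r_px - 1)); j1 <- min(cols, ceiling(c_px[2] + r_px + 1))
      if (i0 > i1 || j0 > j1) next   # rod outside the field of view
      ii <- i0:i1; jj <- j0:j1
      local <- matrix(0, length(ii), length(jj))
      for (oi in offs) for (oj in offs) {
        di <- outer(ii + oi - c_px[1], rep(1, length(jj)))
        dj <- outer(rep(1, length(ii)), jj + oj - c_px[2])
        local <- local + (di^2 + dj^2 <= r_px^2)
      }
      local <- local / supersample^2
      cov[ii, jj] <- pmax(cov[ii, jj], local)
    }
    img <- img + cov * (rod_value - img)
  }
  structure(list(pixels = img, plane = plane, pixel_spacing = pixel_spacing,
                 rod_diameter = rod_diameter, rod_value = rod_value,
                 background_value = background_value),
            class = "stereo_image")
}

#' Detect fiducial centroids in a rendered CT slice
#'
#' Thresholds the image, labels connected components
#' (via \pkg{EBImage}), and reports each component's intensity-weighted
#' centroid in (u, v) millimetres. A component is flagged `merged` when
#' its above-threshold pixel count exceeds 1.25 times that of an isolated
#' rod disc rasterised the same way (two rods blended into one blob), or
#' when another component's centroid lies within `merge_threshold`.
#' Blends at sub-pixel rod separations may escape the area test, but at
#' such separations the centroid bias is below the pixel scale anyway.
#'
#' @param image a `stereo_image` (or a plain pixel matrix, in which case
#'   the raster parameters must be supplied).
#' @param threshold detection threshold; defaults to midway between
#'   background and rod value.
#' @param merge_threshold proximity flagging distance, mm.
#' @param pixel_spacing,rod_diameter,background_value raster parameters,
#'   taken from the `stereo_image` when available.
#' @return An unlabeled fiducial data frame (columns as in
#'   [observe_fiducials()], `bar = NA`) plus `n_pixels`.
#' @export
detect_fiducials <- function(image, threshold = NULL, merge_threshold = 2,
                             pixel_spacing = NULL, rod_diameter = NULL,
                             background_value = NULL) {
  if (inherits(image, "stereo_image")) {
    px <- image$pixels
    pixel_spacing <- pixel_spacing %||% image$pixel_spacing
    rod_diameter <- rod_diameter %||% image$rod_diameter
    background_value <- background_value %||% image$background_value
    threshold <- threshold %||% ((image$rod_value + image$background_value) / 2)
  } else {
    px <- image
    if (is.null(pixel_spacing) || is.null(threshold))
      stop("pixel_spacing and threshold are required for a bare matrix")
    background_value <- background_value %||% min(px)
    rod_diameter <- rod_diameter %||% 3
  }
  mask <- px > threshold
  if (!any(mask))
    stop_classed("stereoloc_no_fiducials", "no pixels above threshold")
  # reference above-threshold pixel count of one isolated rod, rasterised
  # exactly as render_ct() does (mean over sub-pixel phases)
  q <- (threshold - background_value) / (max(px) - background_value)
  ref_px <- disc_pixel_count((rod_diameter / 2) / pixel_spacing, q)
  lab <- EBImage::bwlabel(mask * 1L)
  rows <- nrow(px); cols <- ncol(px)
  ids <- sort(unique(lab[lab > 0]))
  out <- lapply(ids, function(g) {
    idx <- which(lab == g)
    i <- ((idx - 1) %% rows) + 1
    j <- ((idx - 1) %/% rows) + 1
    w <- px[idx] - background_value
    ci <- sum(i * w) / sum(w); cj <- sum(j * w) / sum(w)
    uv <- pixel_to_uv(ci, cj, rows, cols, pixel_spacing)
    data.frame(u = uv[1], v = uv[2], panel = NA_character_,
               bar = NA_character_, role = NA_character_,
               merged = length(idx) > 1.25 * ref_px,
               members = NA_character_, n_pixels = length(idx),
               stringsAsFactors = FALSE)
  })
  f <- do.call(rbind, out)
  if (nrow(f) > 1 && merge_threshold > 0) {
    d <- as.matrix(stats::dist(cbind(f$u, f$v)))
    diag(d) <- Inf
    f$merged <- f$merged | apply(d < merge_threshold, 1, any)
  }
  rownames(f) <- NULL
  f
}

# Above-threshold pixel count of one isolated antialiased disc of radius
# r_px (pixels) at coverage threshold q, averaged over sub-pixel phases.
disc_pixel_count <- function(r_px, q, supersample = 4) {
  offs <- (seq_len(supersample) - 0.5) / supersample - 0.5
  grid <- seq(-ceiling(r_px + 1), ceiling(r_px + 1))
  counts <- vapply(c(0, 0.25, 0.5), function(phase) {
    cov <- outer(grid + phase, grid + phase, function(a, b) {
      s <- 0
      for (oi in offs) for (oj in offs) s <- s + ((a + oi)^2 + (b + oj)^2 <= r_px^2)
      s / supersample^2
    })
    sum(cov > q)
  }, numeric(1))
  mean(counts)
}

# ---- fiducial interchange ---------------------------------------------------

#' Write fiducials to their JSON interchange format
#' @param fiducials a fiducial data frame.
#' @param path file path; if `NULL` the JSON string is returned.
#' @param plane_hint optional list (e.g. `list(z = 60)`) stored verbatim.
#' @export
write_fiducials <- function(fiducials, path = NULL, plane_hint = NULL) {
  fl <- lapply(seq_len(nrow(fiducials)), function(i) {
    x <- list(u = fiducials$u[i], v = fiducials$v[i],
              merged = fiducials$merged[i])
    if (!is.na(fiducials$bar[i])) {
      x$bar_id <- fiducials$bar[i]
      x$panel <- fiducials$panel[i]
    }
    x
  })
  doc <- list(fiducials = fl)
  if (!is.null(plane_hint)) doc$plane_hint <- plane_hint
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read fiducials from their JSON interchange format
#' @param path file path or JSON string.
#' @return A fiducial data frame.
#' @export
read_fiducials <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(doc$fiducials, function(x) data.frame(
    u = x$u, v = x$v,
    panel = x$panel %||% NA_character_,
    bar = x$bar_id %||% NA_character_,
    role = NA_character_,
    merged = isTRUE(x$merged),
    members = x$bar_id %||% NA_character_,
    stringsAsFactors = FALSE))
  f <- do.call(rbind, rows)
  rownames(f) <- NULL
  f
}
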