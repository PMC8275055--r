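# Command-line entry point tying the modules together.  The thin Rscript
# wrapper in inst/cli/stereoloc calls stereo_cli(); all parsing lives here
# so it is testable in-process.

#' Command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{`presets [name] --out file`}{list presets, or export one as
#'     geometry JSON.}
#'   \item{`render --preset p --z z1,z2,... --out-dir dir`}{render one
#'     DICOM CT slice per height (plus a ground-truth fiducial JSON
#'     sidecar); optional `--tilt-u`, `--tilt-v`, `--spacing`,
#'     `--matrix`, `--rod-diameter`.}
#'   \item{`detect --dicom file --out file`}{detect fiducial centroids in
#'     a DICOM slice and write fiducial JSON.}
#'   \item{`localize --preset p (--fiducials file | --dicom file) --out
#'     file`}{run the localization pipeline; writes transform JSON.
#'     Exit status 3 flags the classic bipanel-N insufficiency, 4 an
#'     identification failure.}
#'   \item{`simulate --config file.yaml --out file.csv`}{run the Monte
#'     Carlo study described by a YAML config (keys `presets`, `z_grid`,
#'     `targets`, `n_trials`, `noise_half_width`, `seed`, `use_sp`,
#'     `weighted`); writes the results CSV and, with several presets, a
#'     ranking verdict to `--verdict` (default stdout).}
#' }
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process's trailing arguments).
#' @return Integer exit status, invisibly (0 on success).
#' @export
stereo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      cli_log("usage: stereoloc <presets|render|detect|localize|simulate> [options]")
      return(invisible(1L))
    }
    cmd <- args[1]
    opts <- parse_cli_args(args[-1])
    switch(cmd,
      presets = cli_presets(opts),
      render = cli_render(opts),
      detect = cli_detect(opts),
      localize = cli_localize(opts),
      simulate = cli_simulate(opts),
      { cli_log(sprintf("unknown subcommand '%s'", cmd)); 1L })
  },
  stereoloc_insufficient = function(e) { cli_log(conditionMessage(e)); 3L },
  stereoloc_identification = function(e) { cli_log(conditionMessage(e)); 4L },
  stereoloc_error = function(e) { cli_log(conditionMessage(e)); 1L },
  error = function(e) { cli_log(conditionMessage(e)); 1L })
  invisible(as.integer(status %||% 0L))
}

cli_log <- function(...) message("[stereoloc] ", ...)

# "--key value" pairs plus bare positionals (returned under $positional).
parse_cli_args <- function(args) {
  opts <- list(positional = character())
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2
      } else {
        opts[[key]] <- TRUE; i <- i + 1
      }
    } else {
      opts$positional <- c(opts$positional, a); i <- i + 1
    }
  }
  opts
}

num_list <- function(x) as.numeric(strsplit(as.character(x), ",")[[1]])

cli_options_from <- function(opts) {
  localize_options(
    use_sp = isTRUE(as.logical(opts$use_sp %||% FALSE)),
    weighted = !isTRUE(as.logical(opts$unweighted %||% FALSE)),
    gate = as.numeric(opts$gate %||% 2),
    tol_sym = as.numeric(opts$tol_sym %||% 1),
    tol_line = as.numeric(opts$tol_line %||% 1))
}

cli_presets <- function(opts) {
  if (!length(opts$positional)) {
    cli_log("available presets: n, m, f, z")
    return(0L)
  }
  frame <- build_preset(opts$positional[1])
  out <- opts$out %||% paste0(frame$preset, "_geometry.json")
  export_geometry(frame, out)
  cli_log(sprintf("wrote geometry for preset '%s' to %s", frame$preset, out))
  0L
}

cli_render <- function(opts) {
  frame <- build_preset(opts$preset)
  zs <- num_list(opts$z)
  dir <- opts$out_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tu <- as.numeric(opts$tilt_u %||% 0); tv <- as.numeric(opts$tilt_v %||% 0)
  n <- as.integer(opts$matrix %||% 512)
  sp <- as.numeric(opts$spacing %||% 0.7)
  rd <- as.numeric(opts$rod_diameter %||% 3)
  for (k in seq_along(zs)) {
    plane <- make_plane(zs[k], tu, tv)
    img <- render_ct(frame, plane, rows = n, cols = n, pixel_spacing = sp,
                     rod_diameter = rd)
    base <- file.path(dir, sprintf("%s_z%03d", frame$preset, round(zs[k])))
    write_dicom_ct(img, paste0(base, ".dcm"), instance = k)
    write_fiducials(observe_fiducials(frame, plane),
                    paste0(base, "_fiducials.json"),
                    plane_hint = list(z = zs[k], tilt_u = tu, tilt_v = tv))
    cli_log(sprintf("preset=%s z=%g tilt=(%g,%g) -> %s.dcm",
                    frame$preset, zs[k], tu, tv, base))
  }
  0L
}

cli_detect <- function(opts) {
  img <- read_dicom_ct(opts$dicom)
  fids <- detect_fiducials(img,
    threshold = as.numeric(opts$threshold %||% 1000),
    rod_diameter = as.numeric(opts$rod_diameter %||% 3))
  out <- opts$out %||% sub("\\.dcm$", "_detected.json", opts$dicom)
  write_fiducials(fids, out)
  cli_log(sprintf("detected %d fiducials (%d merged) -> %s",
                  nrow(fids), sum(fids$merged), out))
  0L
}

cli_localize <- function(opts) {
  frame <- build_preset(opts$preset)
  fids <- if (!is.null(opts$fiducials)) {
    read_fiducials(opts$fiducials)
  } else if (!is.null(opts$dicom)) {
    detect_fiducials(read_dicom_ct(opts$dicom),
                     threshold = as.numeric(opts$threshold %||% 1000))
  } else stop("either --fiducials or --dicom is required")
  t <- localize_image(frame, fids, cli_options_from(opts))
  out <- opts$out %||% "transform.json"
  write_transform(t, out, provenance = list(preset = frame$preset,
                                            options = cli_options_from(opts)))
  cli_log(sprintf("localized: n_used=%d rms=%.4g mm -> %s",
                  t$n_used, t$rms_residual, out))
  0L
}

cli_simulate <- function(opts) {
  cfg <- yaml::read_yaml(opts$config)
  need <- c("presets", "z_grid", "n_trials", "noise_half_width", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop_classed("stereoloc_bad_config",
                 paste("config is missing:", paste(missing, collapse = ", ")))
  targets <- if (!is.null(cfg$targets))
    do.call(rbind, lapply(cfg$targets, as.numeric)) else mc_default_targets()
  lopts <- localize_options(use_sp = isTRUE(cfg$use_sp),
                            weighted = !isFALSE(cfg$weighted))
  cli_log(sprintf("simulate presets=%s z=%s trials=%d noise=%g seed=%d",
                  paste(cfg$presets, collapse = ","),
                  paste(cfg$z_grid, collapse = ","),
                  as.integer(cfg$n_trials), cfg$noise_half_width,
                  as.integer(cfg$seed)))
  mc <- run_mc(unlist(cfg$presets), unlist(cfg$z_grid), targets,
               n_trials = as.integer(cfg$n_trials),
               noise_half_width = cfg$noise_half_width,
               seed = as.integer(cfg$seed), options = lopts)
  out <- opts$out %||% "mc_results.csv"
  write_mc_csv(mc, out)
  cli_log(sprintf("wrote %d rows -> %s", nrow(mc), out))
  if (length(unique(mc$preset)) > 1) {
    cmp <- compare_presets(mc)
    if (!is.null(opts$verdict)) writeLines(cmp$verdict, opts$verdict)
    cli_log(cmp$verdict)
  }
  0L
}

#' Write a fitted transform as JSON
#'
#' @param transform a `stereo_transform`.
#' @param path output path; `NULL` returns the JSON string.
#' @param provenance optional list (preset, options, seed) stored
#'   alongside the coefficients.
#' @export
write_transform <- function(transform, path = NULL, provenance = NULL) {
  doc <- list(coefficients = transform$M,
              rms_residual = transform$rms_residual,
              n_used = transform$n_used)
  if (!is.null(provenance)) doc$provenance <- provenance
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path JSON file path.
#' @return A `stereo_transform`.
#' @export
read_transform <- function(path) {
  doc <- jsonlite::fromJSON(path)
  M <- doc$coefficients
  if (!is.matrix(M)) M <- matrix(unlist(M), 3, 3, byrow = TRUE)
  structure(list(M = unname(M), rms_residual = doc$rms_residual,
                 n_used = doc$n_used),
            class = "stereo_transform")
}
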