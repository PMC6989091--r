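#' Read a multi-page TIFF stack
#'
#' Reads a TYX multi-page TIFF into a `[y, x, t]` array, together with pixel
#' size and frame/slice metadata from a JSON sidecar (`<path>.json`) if
#' present. The sidecar (or explicit arguments) must provide the pixel size;
#' readers refuse to guess.
#'
#' @param path TIFF file path.
#' @param pixel_size_um pixel size, um (overrides the sidecar).
#' @param frame_interval_s frame interval, s (overrides the sidecar).
#' @param as one of `"array"`, `"bead_video"`.
#' @return An array or [bead_video()] depending on `as`.
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       as = c("array", "bead_video")) {
  as <- match.arg(as)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(frame_interval_s)) frame_interval_s <- meta$frame_interval_s
  if (as == "array") {
    attr(stack, "pixel_size_um") <- pixel_size_um
    attr(stack, "frame_interval_s") <- frame_interval_s
    return(stack)
  }
  if (is.null(pixel_size_um) || is.null(frame_interval_s)) {
    stop("pixel size / frame interval unknown: provide them as arguments ",
         "or in a `", basename(sidecar), "` sidecar", call. = FALSE)
  }
  bead_video(stack, pixel_size_um, frame_interval_s)
}

#' Write a stack as a multi-page TIFF (+ JSON sidecar)
#'
#' Values are scaled into [0, 1] for 32-bit float storage; the scale factor
#' and metadata go to the sidecar so [read_stack()] round-trips losslessly up
#' to float precision.
#'
#' @param stack array `[y, x, t]` or a `bead_video`.
#' @param path output TIFF path.
#' @param pixel_size_um,frame_interval_s metadata (taken from a `bead_video`
#'   automatically).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, pixel_size_um = NULL,
                        frame_interval_s = NULL) {
  if (inherits(stack, "bead_video")) {
    pixel_size_um <- stack$pixel_size_um
    frame_interval_s <- stack$frame_interval_s
    stack <- stack$stack
  }
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) (stack[, , f] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(pixel_size_um = pixel_size_um,
                            frame_interval_s = frame_interval_s,
                            value_offset = lo, value_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model/analysis configuration file
#'
#' YAML with per-stage sections; unit-suffixed keys (`d_um`, `f_hz`,
#' `fv_n_per_m3`, ...) keep units explicit.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

# model_params from a config section (keys: alpha, mu, f_hz, d_um, h_frac,
# fv_n_per_m3 optional)
config_model_params <- function(cfg) {
  d <- cfg$d_um * 1e-6
  model_params(alpha = cfg$alpha %||% 0.5, mu = cfg$mu %||% 1e-3,
               f = cfg$f_hz %||% 40, d = d,
               h = (cfg$h_frac %||% 0.5) * d,
               fv = cfg$fv_n_per_m3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Thin dispatcher over the package's analysis stages. Subcommands:
#' `simulate-flow` (closed-form profile -> CSV + features JSON),
#' `simulate-transport` (advection-diffusion -> marginals CSV, front CSV,
#' summary JSON), `analyze-kymo` (bead TIFF -> events/profile CSV, landmarks
#' JSON), `analyze-cilia` (cilia TIFF -> region table CSV, summary JSON), and
#' `make-synthetic` (bead video TIFF + ground-truth CSV). Every run writes a
#' `manifest.json` capturing the arguments, seed and package version.
#'
#' @param argv character vector of arguments (default `commandArgs`).
#' @return Exit code, invisibly: 0 on success, 2 for usage errors, 3 for
#'   parameter validation errors.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: csfflow <simulate-flow|simulate-transport|analyze-kymo|",
    "               analyze-cilia|make-synthetic> [--key value ...]",
    "common flags: --out DIR (default .), --seed INT (default 1),",
    "              --config FILE (YAML)", sep = "\n")
  if (length(argv) < 1) { message(usage); return(invisible(2L)) }
  cmd <- argv[1]
  opts <- parse_flags(argv[-1])
  if (inherits(opts, "cli_error")) { message(opts); return(invisible(2L)) }
  out_dir <- opts$out %||% "."
  seed <- as.integer(opts$seed %||% 1)
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- tryCatch(switch(
    cmd,
    "simulate-flow" = cli_simulate_flow(opts, cfg, out_dir),
    "simulate-transport" = cli_simulate_transport(opts, cfg, out_dir, seed),
    "analyze-kymo" = cli_analyze_kymo(opts, cfg, out_dir),
    "analyze-cilia" = cli_analyze_cilia(opts, cfg, out_dir),
    "make-synthetic" = cli_make_synthetic(opts, cfg, out_dir, seed),
    { message("unknown subcommand: ", cmd, "\n", usage); return(invisible(2L)) }
  ), error = function(e) { message("error: ", conditionMessage(e)); 3L })
  if (is.numeric(res) && res != 0) return(invisible(as.integer(res)))

  manifest <- list(command = cmd, options = opts, seed = seed,
                   package_version = as.character(utils::packageVersion("csfflow")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(0L)
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      return(structure(paste("unexpected argument:", a), class = "cli_error"))
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE; i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  opts
}

num_opt <- function(opts, key, default) {
  v <- opts[[key]]
  if (is.null(v)) default else as.numeric(v)
}

cli_simulate_flow <- function(opts, cfg, out_dir) {
  params <- if (length(cfg)) config_model_params(cfg) else
    model_params(alpha = num_opt(opts, "alpha", 0.5),
                 mu = num_opt(opts, "mu", 1e-3),
                 f = num_opt(opts, "f-hz", 40),
                 d = num_opt(opts, "d-um", 8.9) * 1e-6,
                 h = num_opt(opts, "h-frac", 0.5) * num_opt(opts, "d-um", 8.9) * 1e-6,
                 fv = if (!is.null(opts$`fv`)) as.numeric(opts$`fv`) else NULL)
  prof <- solve_two_region(params)
  utils::write.csv(profile_table(prof), file.path(out_dir, "profile.csv"),
                   row.names = FALSE)
  ft <- profile_features(prof)
  jsonlite::write_json(c(ft, list(dPdx_n_per_m3 = prof$dPdx,
                                  fv_n_per_m3 = prof$fv)),
                       file.path(out_dir, "profile_features.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_simulate_transport <- function(opts, cfg, out_dir, seed) {
  set.seed(seed)
  d <- num_opt(opts, "d-um", 8.9) * 1e-6
  r <- num_opt(opts, "r-nm", 20) * 1e-9
  V <- num_opt(opts, "v-um-s", 5) * 1e-6
  t_end <- num_opt(opts, "t-end-s", 100)
  D <- stokes_einstein(r)
  prof <- solve_two_region(model_params(d = d, h = d / 2, fv = 4000))
  cf <- simulate_transport(prof, D = D, t_end = t_end, V = V)
  marg <- data.frame(t_s = rep(cf$times, each = length(cf$x)),
                     x_um = rep(cf$x, length(cf$times)) * 1e6,
                     c = as.numeric(t(cf$marginals)))
  utils::write.csv(marg, file.path(out_dir, "marginals.csv"), row.names = FALSE)
  fr <- track_front(cf)
  utils::write.csv(fr$track, file.path(out_dir, "front.csv"), row.names = FALSE)
  Deff_fit <- tryCatch(fit_effective_diffusivity(cf), error = function(e) NA_real_)
  jsonlite::write_json(list(D = D, Pe = V * d / D,
                            Deff_analytic = cf$Deff_analytic,
                            Deff_fitted = Deff_fit,
                            front_slope = fr$slope),
                       file.path(out_dir, "transport_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_analyze_kymo <- function(opts, cfg, out_dir) {
  if (is.null(opts$input)) stop("--input TIFF required")
  video <- read_stack(opts$input,
                      pixel_size_um = if (!is.null(opts$`pixel-um`)) as.numeric(opts$`pixel-um`) else NULL,
                      frame_interval_s = if (!is.null(opts$`dt-s`)) as.numeric(opts$`dt-s`) else NULL,
                      as = "bead_video")
  rot <- if (!is.null(opts$rotate)) as.numeric(opts$rotate) else NULL
  video <- preprocess_video(video, rotate = rot)
  video <- denoise(video)
  events <- scan_video_events(video, window = as.integer(num_opt(opts, "window", 3)))
  utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  prof <- velocity_profile(events, video$pixel_size_um)
  utils::write.csv(as.data.frame(prof), file.path(out_dir, "profile.csv"),
                   row.names = FALSE)
  jsonlite::write_json(profile_landmarks(prof),
                       file.path(out_dir, "landmarks.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_analyze_cilia <- function(opts, cfg, out_dir) {
  if (is.null(opts$input)) stop("--input TIFF required")
  arr <- read_stack(opts$input)
  video <- structure(list(stack = arr,
                          frame_rate_hz = num_opt(opts, "rate-hz", 100),
                          pixel_size_um = num_opt(opts, "pixel-um", 0.189),
                          midline_row = as.integer(num_opt(opts, "midline-row",
                                                           dim(arr)[1] / 2))),
                     class = "cilia_video")
  regions <- map_cilia(video)
  utils::write.csv(regions, file.path(out_dir, "cilia_regions.csv"),
                   row.names = FALSE)
  sm <- summarize_cilia(regions)
  jsonlite::write_json(sm, file.path(out_dir, "cilia_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  0L
}

cli_make_synthetic <- function(opts, cfg, out_dir, seed) {
  spec <- bead_video_spec(seed = seed,
                          d_um = num_opt(opts, "d-um", 8.9),
                          duration_s = num_opt(opts, "duration-s", 30),
                          n_beads = as.integer(num_opt(opts, "n-beads", 60)))
  gen <- make_bead_video(spec)
  write_stack(gen$video, file.path(out_dir, "beads.tiff"))
  utils::write.csv(gen$truth, file.path(out_dir, "beads_truth.csv"),
                   row.names = FALSE)
  0L
}
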