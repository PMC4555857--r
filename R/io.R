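#' Write a result table to CSV or JSON
#'
#' CSV files carry a header row; JSON files carry the same columns as an
#' object of arrays, written at full double precision so a round trip
#' reproduces the values exactly.
#'
#' @param x A data frame (or an object coercible to one).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  x <- as.data.frame(x)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(as.list(x), path, digits = NA, auto_unbox = FALSE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path File path (.csv or .json).
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
}

# Write run metadata next to a result file (internal).
write_metadata <- function(path, params) {
  meta <- c(list(package = "sonarbeam",
                 version = as.character(utils::packageVersion("sonarbeam")),
                 created = format(Sys.time(), tz = "UTC")),
            params)
  mpath <- paste0(sub("\\.[^.]+$", "", path), "_meta.json")
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a signal specification from a YAML config file
#'
#' Recognized keys (all optional except the sweep limits):
#' `f_start_khz`, `f_terminal_khz`, `duration_ms`, `beta`, `sample_rate_hz`,
#' and `harmonics` — a list of maps with `f_start_khz`, `f_terminal_khz` and
#' optional `weight`.
#'
#' @param path Path to the YAML file.
#' @return A [signal_spec()].
#' @export
read_signal_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dur <- (cfg$duration_ms %||% 3) * 1e-3
  beta <- cfg$beta %||% 4
  fs <- cfg$sample_rate_hz %||% 5e5
  if (!is.null(cfg$harmonics)) {
    harm <- do.call(rbind, lapply(cfg$harmonics, function(h) {
      data.frame(f_start = h$f_start_khz * 1e3,
                 f_terminal = h$f_terminal_khz * 1e3,
                 weight = h$weight %||% 1)
    }))
    return(signal_spec(max(harm$f_start), min(harm$f_terminal),
                       duration = dur, window_beta = beta, sample_rate = fs,
                       harmonics = harm))
  }
  if (is.null(cfg$f_start_khz) || is.null(cfg$f_terminal_khz)) {
    stop("config must provide f_start_khz and f_terminal_khz (or harmonics)")
  }
  signal_spec(cfg$f_start_khz * 1e3, cfg$f_terminal_khz * 1e3,
              duration = dur, window_beta = beta, sample_rate = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a waveform as CSV
#'
#' @param ts A [time_series()].
#' @param path Output path; columns `time_s`, `amplitude`.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  n <- length(ts$samples)
  utils::write.csv(data.frame(time_s = (seq_len(n) - 1) / ts$sample_rate,
                              amplitude = ts$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Deterministic fixture bundle for tests and examples
#'
#' Regenerates, in memory, a small self-contained set of objects: the species
#' presets, a coarse-grid beam table for the M. emarginatus configuration
#' (6.3 mm radius, 130 to 40 kHz sweep), noiseless and 40 dB observations at
#' 5, 25 and 65 degrees, and the noiseless 25-degree correlation curve.
#'
#' @param seed Integer seed for the noisy observations.
#' @param step Angle-grid step in degrees (default 0.5; coarse, for speed).
#' @return A named list (`presets`, `table`, `observations`, `curve25`,
#'   `seed`).
#' @export
make_fixtures <- function(seed = 0, step = 0.5) {
  presets <- species_presets()
  cfg <- preset_configuration(presets[presets$species == "M. emarginatus", ])
  spec <- signal_spec(130e3, 40e3)
  tab <- angle_spectrum_table(spec, cfg$emitter, angle_grid(step = step),
                              mode = "per_band")
  sigma <- sigma_from_snr(40, tab)
  obs <- list()
  for (th in c(5, 25, 65)) {
    obs[[sprintf("noiseless_%d", th)]] <-
      make_observation(tab, th, noise_spec(Inf, 0, seed))
    obs[[sprintf("snr40_%d", th)]] <-
      make_observation(tab, th, noise_spec(40, sigma, seed))
  }
  list(presets = presets, table = tab, observations = obs,
       curve25 = correlation_curve(obs$noiseless_25, tab), seed = seed)
}
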