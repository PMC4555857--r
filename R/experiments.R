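#' Species presets for five vespertilionid bats
#'
#' Piston radius (mm), sweep terminal frequency (kHz) and bandwidth (kHz) for
#' the five vespertilionid species analysed in the comparative experiments.
#' The sweep start frequency is `terminal + bandwidth`; bandwidth follows a
#' 25 dB-drop support convention.
#'
#' @return A data frame of class `species_presets` with columns `species`,
#'   `radius_mm`, `terminal_khz`, `bandwidth_khz`.
#' @export
#' @examples
#' species_presets()
species_presets <- function() {
  out <- data.frame(
    species = c("M. nattereri", "M. emarginatus", "M. mystacinus",
                "M. daubentonii", "M. dasycneme"),
    radius_mm = c(7.6, 6.3, 5.4, 6.1, 8.0),
    terminal_khz = c(19, 42, 32, 33, 30),
    bandwidth_khz = c(119, 91, 75, 57, 44))
  structure(out, class = c("species_presets", "data.frame"))
}

#' Signal specification and emitter for a species preset
#'
#' @param preset One row of [species_presets()] (or a list with the same
#'   fields).
#' @param gape_factor Multiplier on the preset piston radius (default 1).
#' @param sound_speed Speed of sound in m/s.
#' @return A list with elements `spec` ([signal_spec()]) and `emitter`
#'   ([emitter()]).
#' @export
preset_configuration <- function(preset, gape_factor = 1, sound_speed = 343) {
  stopifnot(gape_factor > 0)
  f1 <- preset$terminal_khz * 1e3
  f0 <- (preset$terminal_khz + preset$bandwidth_khz) * 1e3
  list(spec = signal_spec(f0, f1),
       emitter = emitter(preset$radius_mm * 1e-3 * gape_factor,
                         sound_speed = sound_speed))
}

# Build a beam table for a preset at a gape factor (internal).
preset_table <- function(preset, gape_factor = 1, grid = angle_grid(),
                         mode = "per_band") {
  cfg <- preset_configuration(preset, gape_factor)
  angle_spectrum_table(cfg$spec, cfg$emitter, grid = grid, mode = mode)
}

#' Mouth-gape experiment for one species
#'
#' Compares localization metrics at the preset mouth gape ("half gape", the
#' Table-2 radius) and at a widened gape (`radius x gape_factor`, default 2,
#' "full gape"), with the species' signal held fixed. Reported values are the
#' angle-averaged peak width and PSLR from [metrics_profile()].
#'
#' @param preset One row of [species_presets()].
#' @param gape_factor Radius multiplier for the widened gape (default 2).
#' @param report_angles Report angles for the metric means.
#' @param grid Angle grid for the beam tables.
#' @param mode Beam synthesis mode (see [angle_spectrum_table()]).
#' @return A one-row data frame: `species`, `pw_half_gape`, `pw_full_gape`
#'   (degrees), `pslr_half_gape`, `pslr_full_gape` (dB).
#' @export
gape_experiment <- function(preset, gape_factor = 2, report_angles = 1:89,
                            grid = angle_grid(), mode = "per_band") {
  stopifnot(gape_factor >= 1)
  m_half <- summary(metrics_profile(preset_table(preset, 1, grid, mode),
                                    report_angles))
  m_full <- if (gape_factor == 1) m_half else
    summary(metrics_profile(preset_table(preset, gape_factor, grid, mode),
                            report_angles))
  data.frame(species = preset$species,
             pw_half_gape = m_half$mean_pw, pw_full_gape = m_full$mean_pw,
             pslr_half_gape = m_half$mean_pslr,
             pslr_full_gape = m_full$mean_pslr)
}

#' Gape experiment over all species presets
#'
#' @inheritParams gape_experiment
#' @param presets Data frame of presets (default [species_presets()]).
#' @return A data frame with one [gape_experiment()] row per species.
#' @export
gape_experiment_all <- function(presets = species_presets(), gape_factor = 2,
                                report_angles = 1:89, grid = angle_grid(),
                                mode = "per_band") {
  do.call(rbind, lapply(seq_len(nrow(presets)), function(i) {
    gape_experiment(presets[i, ], gape_factor, report_angles, grid, mode)
  }))
}

#' Signal-design sweep
#'
#' Evaluates the angle-averaged accuracy (peak width) and ambiguity (PSLR) of
#' equal-power 3 ms FM sweeps over a grid of terminal frequencies and
#' bandwidths at a fixed emitter radius. Pass a single bandwidth to study the
#' terminal-frequency effect, or a single terminal frequency to study the
#' bandwidth effect.
#'
#' @param radius_mm Piston radius in mm (fixed across the sweep).
#' @param terminal_khz Vector of terminal frequencies (kHz).
#' @param bandwidth_khz Vector of bandwidths (kHz); start frequency is
#'   `terminal + bandwidth`.
#' @inheritParams gape_experiment
#' @return Data frame with columns `terminal_khz`, `bandwidth_khz`,
#'   `mean_pw_deg`, `mean_pslr_db`.
#' @export
design_sweep <- function(radius_mm, terminal_khz, bandwidth_khz,
                         report_angles = 1:89, grid = angle_grid(),
                         mode = "per_band") {
  des <- expand.grid(terminal_khz = terminal_khz,
                     bandwidth_khz = bandwidth_khz)
  em <- emitter(radius_mm * 1e-3)
  res <- lapply(seq_len(nrow(des)), function(i) {
    spec <- signal_spec((des$terminal_khz[i] + des$bandwidth_khz[i]) * 1e3,
                        des$terminal_khz[i] * 1e3)
    m <- summary(metrics_profile(
      angle_spectrum_table(spec, em, grid = grid, mode = mode),
      report_angles))
    c(mean_pw_deg = m$mean_pw, mean_pslr_db = m$mean_pslr)
  })
  cbind(des, do.call(rbind, res))
}

#' Aperture-normalized effective bandwidth
#'
#' The dimensionless spectral span of the beam, `a / lambda2 - a / lambda1`,
#' where `lambda1` is the wavelength of the terminal (lowest) frequency and
#' `lambda2` that of the highest frequency. Widening the mouth (increasing
#' `a`) raises both the normalized terminal frequency `a / lambda1` (better
#' accuracy) and the effective bandwidth (lower side lobes).
#'
#' @param a Emitter radius (any length unit, consistently with the
#'   wavelengths).
#' @param lambda1 Wavelength of the terminal frequency (same unit).
#' @param lambda2 Wavelength of the highest frequency; `lambda2 <= lambda1`.
#' @return A list with `effective_bandwidth` (`a/lambda2 - a/lambda1`) and
#'   `normalized_terminal` (`a/lambda1`).
#' @export
#' @examples
#' effective_bandwidth(2, 1, 0.5)$effective_bandwidth  # 2
effective_bandwidth <- function(a, lambda1, lambda2) {
  stopifnot(a > 0, lambda1 > 0, lambda2 > 0)
  if (lambda2 > lambda1) {
    stop("lambda2 (highest-frequency wavelength) must not exceed lambda1")
  }
  list(effective_bandwidth = a / lambda2 - a / lambda1,
       normalized_terminal = a / lambda1)
}

#' Accuracy-ambiguity trade-off map
#'
#' Evaluates mean peak width (accuracy) and mean PSLR (ambiguity) over a grid
#' of signal designs at a fixed radius and indexes the surfaces by the
#' dimensionless coordinates normalized terminal frequency `a/lambda1` and
#' effective bandwidth `a/lambda2 - a/lambda1`. The species presets are
#' overlaid at their own radii, at half gape (preset radius) and full gape
#' (`radius x gape_factor`).
#'
#' @param radius_mm Fixed radius for the design surfaces (mm).
#' @param terminal_khz,bandwidth_khz Design grids (kHz).
#' @param gape_factor Full-gape multiplier for the species overlay.
#' @param presets Species presets for the overlay (`NULL` to skip).
#' @inheritParams gape_experiment
#' @param sound_speed Speed of sound (m/s) for wavelength conversion.
#' @return An object of class `tradeoff_map`: list with `surface` (data frame
#'   with design coordinates and metric surfaces) and `overlay` (data frame of
#'   species points at both gapes, or `NULL`).
#' @export
tradeoff_map <- function(radius_mm, terminal_khz, bandwidth_khz,
                         gape_factor = 2, presets = species_presets(),
                         report_angles = 1:89, grid = angle_grid(),
                         mode = "per_band", sound_speed = 343) {
  surf <- design_sweep(radius_mm, terminal_khz, bandwidth_khz,
                       report_angles, grid, mode)
  a_m <- radius_mm * 1e-3
  l1 <- sound_speed / (surf$terminal_khz * 1e3)
  l2 <- sound_speed / ((surf$terminal_khz + surf$bandwidth_khz) * 1e3)
  surf$a_over_lambda1 <- a_m / l1
  surf$eff_bandwidth <- a_m / l2 - a_m / l1
  overlay <- NULL
  if (!is.null(presets)) {
    rows <- lapply(seq_len(nrow(presets)), function(i) {
      p <- presets[i, ]
      do.call(rbind, lapply(c(1, gape_factor), function(gf) {
        a <- p$radius_mm * 1e-3 * gf
        l1p <- sound_speed / (p$terminal_khz * 1e3)
        l2p <- sound_speed / ((p$terminal_khz + p$bandwidth_khz) * 1e3)
        m <- summary(metrics_profile(preset_table(p, gf, grid, mode),
                                     report_angles))
        data.frame(species = p$species,
                   gape = if (gf == 1) "half" else "full",
                   a_over_lambda1 = a / l1p,
                   eff_bandwidth = a / l2p - a / l1p,
                   mean_pw_deg = m$mean_pw, mean_pslr_db = m$mean_pslr)
      }))
    })
    overlay <- do.call(rbind, rows)
  }
  structure(list(surface = surf, overlay = overlay, radius_mm = radius_mm,
                 gape_factor = gape_factor),
            class = "tradeoff_map")
}

#' @export
print.tradeoff_map <- function(x, ...) {
  cat(sprintf("<tradeoff_map> %d design points at radius %.1f mm%s\n",
              nrow(x$surface), x$radius_mm,
              if (is.null(x$overlay)) "" else
                sprintf(", %d overlay points", nrow(x$overlay))))
  invisible(x)
}

#' Normalize metric curves by their joint minimum
#'
#' Divides every curve in a list by the global minimum across all curves, so
#' that the smallest plotted value is exactly 1 and curves read as fold
#' changes relative to the best condition.
#'
#' @param curves A list of positive numeric vectors (or a single vector).
#' @return A list of rescaled vectors (same shapes), with attribute
#'   `global_min` holding the divisor.
#' @export
normalize_curves <- function(curves) {
  if (is.numeric(curves)) curves <- list(curves)
  stopifnot(is.list(curves), length(curves) >= 1)
  vals <- unlist(lapply(curves, function(v) v[is.finite(v)]))
  if (any(vals <= 0)) stop("curves must be positive to normalize")
  m <- min(vals)
  structure(lapply(curves, function(v) v / m), global_min = m)
}
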