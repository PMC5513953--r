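#' Pipeline configuration
#'
#' Builds the full set of tunables for the quality-assessment pipeline,
#' starting from documented defaults and overriding any subset by name.
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' The defaults encode the method's fixed constants: the 4 kHz working rate,
#' 3.75-s segments on a 3-s stride, the template-update correlation gate
#' (r >= 0.6 for at least 20 % of beats), the weighted-DTW penalty g = 0.02,
#' sample-entropy parameters m = 2 and r = 0.1 x SD, and the 160-660 Hz
#' Doppler power band.
#'
#' @param ... named overrides of any default key.
#'
#' @return A named list of class `dus_config`.
#'
#' @details Key groups:
#' \describe{
#'   \item{resampling}{`target_fs` (Hz), `antialias_order` (FIR taps - 1),
#'     `antialias_cutoff_frac` (fraction of the target Nyquist).}
#'   \item{segmentation}{`seg_len_s`, `seg_stride_s` (seconds).}
#'   \item{EMD / beats}{`emd_max_imfs`, `emd_sd_stop` (Cauchy sifting stop),
#'     `emd_max_sift`, `beat_window_s`, `beat_overlap_s`, `cwt_scale`
#'     (samples; the dyadic reading of the third wavelet level at 4 kHz),
#'     `cwt_window_s`, `smooth_cutoff_hz`, `bpm_min`, `bpm_max`.}
#'   \item{templates / SQI}{`template_window_s`, `corr_threshold`,
#'     `validity_fraction`, `wdtw_g`, `sqi2_mode` ("btbi" resamples the full
#'     beat-to-beat interval, "clipped" the length-L excerpt).}
#'   \item{features}{`entropy_m`, `entropy_r_frac`, `entropy_source`
#'     ("raw" or "envelope"), `psd_band` (Hz), `band_lo_range`,
#'     `band_hi_range`, `band_grid_step`, `welch_window_s`, `welch_overlap`.}
#'   \item{classifier}{`c_exponents`, `sigma_exponents` (base-2 grids),
#'     `n_folds`, `per_class`, `n_reps`.}
#' }
#'
#' @examples
#' cfg <- dus_config(cwt_scale = 4, n_reps = 10)
#' cfg$psd_band
#' @export
dus_config <- function(...) {
  defaults <- list(
    target_fs             = 4000,
    antialias_order       = 512,
    antialias_cutoff_frac = 0.9,
    seg_len_s             = 3.75,
    seg_stride_s          = 3.0,
    emd_max_imfs          = 4L,
    emd_sd_stop           = 0.2,
    emd_max_sift          = 100L,
    beat_window_s         = 4,
    beat_overlap_s        = 1,
    imf_env_smooth_hz     = 15,
    cwt_scale             = 8,
    cwt_window_s          = 25,
    smooth_cutoff_hz      = 25,
    envelope_fs           = 200,
    bpm_min               = 90,
    bpm_max               = 210,
    template_window_s     = 15,
    corr_threshold        = 0.6,
    validity_fraction     = 0.2,
    wdtw_g                = 0.02,
    sqi2_mode             = "btbi",
    entropy_m             = 2L,
    entropy_r_frac        = 0.1,
    entropy_source        = "raw",
    psd_band              = c(160, 660),
    band_lo_range         = c(80, 400),
    band_hi_range         = c(580, 900),
    band_grid_step        = 20,
    welch_window_s        = 1,
    welch_overlap         = 0.5,
    c_exponents           = c(-3, -1, 1, 3, 5),
    sigma_exponents       = c(-5, -2, 1, 2),
    n_folds               = 5L,
    per_class             = 60L,
    n_reps                = 100L
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("config overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
    defaults <- modifyList(defaults, overrides)
  }
  cfg <- defaults
  stopifnot(
    cfg$target_fs > 0, cfg$seg_len_s > 0, cfg$seg_stride_s > 0,
    cfg$emd_max_imfs >= 1, cfg$emd_sd_stop > 0,
    cfg$corr_threshold >= -1, cfg$corr_threshold <= 1,
    cfg$validity_fraction >= 0, cfg$validity_fraction <= 1,
    length(cfg$psd_band) == 2, cfg$psd_band[1] < cfg$psd_band[2],
    cfg$bpm_min > 0, cfg$bpm_min < cfg$bpm_max,
    cfg$n_folds >= 2, cfg$per_class >= 1, cfg$n_reps >= 1
  )
  class(cfg) <- "dus_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are `dus_config()` keys.
#' @param ... further overrides applied on top of the file.
#' @return A `dus_config` list.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a mapping", call. = FALSE)
  vals <- modifyList(vals, list(...))
  do.call(dus_config, vals)
}

#' @export
print.dus_config <- function(x, ...) {
  cat("DUS pipeline configuration (", length(x), " keys)\n", sep = "")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

# Short stable hash of a config, recorded in artifacts for provenance.
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v, digits = 12), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  raw <- utils::head(charToRaw(s), 10000)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251 + 1)) %% .Machine$integer.max)
}
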