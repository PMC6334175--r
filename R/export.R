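#' Write an RF/gradient pulse as columnar text with a JSON sidecar
#'
#' Columns: time_ms (sample midpoints), b1_ut (magnitude), phase_rad,
#' g_mtm. The sidecar (path + ".json") records the dwell, method and any
#' extra metadata; the round trip through [read_pulse()] is lossless to
#' better than 1e-9 relative.
#'
#' @param rf An [rf_waveform()] (or an `mb_design`, in which case `g` and
#'   metadata are taken from it).
#' @param g A [gradient_waveform()] on the same grid (ignored for designs).
#' @param path Output text file path.
#' @param meta Named list of extra metadata for the sidecar.
#' @export
write_pulse <- function(rf, g = NULL, path, meta = list()) {
  if (inherits(rf, "mb_design")) {
    d <- rf
    meta <- utils::modifyList(
      list(method = d$method, n_slices = d$n_slices, tbp = d$tbp,
           thickness_mm = d$thickness, separation_mm = d$separation,
           duration_ms = d$duration,
           b1_max = d$lim$b1_max, g_max = d$lim$g_max,
           slew_max = d$lim$slew_max,
           n_subpulses = if (!is.null(d$pins)) d$pins$n_subpulses else NULL,
           mixing_ratio = if (!is.null(d$mixing_ratio)) d$mixing_ratio
           else NULL),
      meta)
    g <- d$grad; rf <- d$rf
  }
  stopifnot(inherits(rf, "rf_waveform"), inherits(g, "gradient_waveform"),
            length(rf$samples) == length(g$samples))
  df <- data.frame(time_ms = wf_times(rf),
                   b1_ut = Mod(rf$samples),
                   phase_rad = Arg(rf$samples),
                   g_mtm = g$samples)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, row.names = FALSE, quote = FALSE, sep = "\t",
                     fileEncoding = "UTF-8")
  meta <- utils::modifyList(list(dwell_ms = rf$dt, n = length(rf$samples)),
                            meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pulse
#' @return `read_pulse` returns a list with `rf`, `grad` and `meta`.
#' @export
read_pulse <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rf <- rf_waveform(complex(modulus = df$b1_ut, argument = df$phase_rad),
                    meta$dwell_ms)
  list(rf = rf, grad = gradient_waveform(df$g_mtm, meta$dwell_ms),
       meta = meta)
}
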