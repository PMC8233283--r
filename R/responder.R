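#' Responder classification thresholds
#'
#' A cell is called a responder to an agonist when the calcium rise during
#' the application window exceeds `amplitude_min` (default 50 nM) and the
#' highest value of the trace derivative within that window exceeds
#' `derivative_sd_multiple` (default 3) times the SD of the derivative over
#' the baseline window. Both inequalities are strict ("exceeded").
#'
#' @param amplitude_min minimum calcium rise, nM.
#' @param derivative_sd_multiple multiple of the baseline-derivative SD the
#'   application-window peak derivative must exceed.
#' @param smoothing_window odd moving-average width (samples) applied
#'   before differentiation; 1 disables smoothing.
#' @param viability_filter if `TRUE`, cells whose ionomycin-window
#'   amplitude falls below `viability_min_amplitude` are excluded from all
#'   counts. Off by default: ionomycin is a positive control, not a stated
#'   exclusion rule.
#' @param viability_min_amplitude nM.
#' @param baseline_stat `"mean"` (default) or `"median"` baseline calcium.
#' @param sd_denominator `"population"` (default, divide by n) or
#'   `"sample"` (n - 1) for the baseline derivative SD.
#' @return A `responder_thresholds` list.
#' @export
responder_thresholds <- function(amplitude_min = 50,
                                 derivative_sd_multiple = 3,
                                 smoothing_window = 3,
                                 viability_filter = FALSE,
                                 viability_min_amplitude = 50,
                                 baseline_stat = c("mean", "median"),
                                 sd_denominator = c("population", "sample")) {
  if (amplitude_min <= 0) stop("amplitude_min must be > 0")
  if (derivative_sd_multiple <= 0) stop("derivative_sd_multiple must be > 0")
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    stop("smoothing_window must be odd and >= 1")
  }
  baseline_stat <- match.arg(baseline_stat)
  sd_denominator <- match.arg(sd_denominator)
  structure(list(amplitude_min = amplitude_min,
                 derivative_sd_multiple = derivative_sd_multiple,
                 smoothing_window = smoothing_window,
                 viability_filter = viability_filter,
                 viability_min_amplitude = viability_min_amplitude,
                 baseline_stat = baseline_stat,
                 sd_denominator = sd_denominator),
            class = "responder_thresholds")
}

# centered moving average with a symmetrically shrinking window at the
# edges (width 1 at the endpoints): exact on constants and linear ramps.
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- (width - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Estimate the time derivative of a calcium trace
#'
#' Applies moving-average smoothing of width `smoothing_window`, then
#' central finite differences (one-sided at the trace ends).
#'
#' @param time sample times in seconds (approximately uniform).
#' @param ca calcium values in nM.
#' @param smoothing_window odd integer >= 1.
#' @return Derivative in nM/s, same length as `ca`.
#' @export
estimate_derivative <- function(time, ca, smoothing_window = 3) {
  if (length(ca) < 3) stop("need at least 3 samples to differentiate")
  if (length(time) != length(ca)) stop("time and ca lengths differ")
  s <- moving_average(ca, smoothing_window)
  n <- length(s)
  d <- numeric(n)
  d[1] <- (s[2] - s[1]) / (time[2] - time[1])
  d[n] <- (s[n] - s[n - 1]) / (time[n] - time[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (s[i + 1] - s[i - 1]) / (time[i + 1] - time[i - 1])
  }
  d
}

pop_sd <- function(x, denominator = "population") {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (denominator == "sample") return(stats::sd(x))
  sqrt(mean((x - mean(x))^2))
}

classify_one <- function(time, ca, windows, thr, app_row, ion_row) {
  base_row <- windows[windows$label == "baseline", , drop = FALSE]
  bidx <- in_window(time, base_row) & !is.na(ca)
  aidx <- in_window(time, app_row) & !is.na(ca)
  if (sum(bidx) < 3) {
    return(list(excluded = TRUE, reason = "baseline_too_short"))
  }
  if (sum(aidx) == 0) {
    return(list(excluded = TRUE, reason = "no_valid_application_samples"))
  }
  ok <- !is.na(ca)
  if (sum(ok) < 3) return(list(excluded = TRUE, reason = "too_few_samples"))
  deriv <- rep(NA_real_, length(ca))
  deriv[ok] <- estimate_derivative(time[ok], ca[ok], thr$smoothing_window)

  baseline_ca <- if (thr$baseline_stat == "median") {
    stats::median(ca[bidx])
  } else mean(ca[bidx])
  base_sd <- pop_sd(deriv[bidx], thr$sd_denominator)
  peak_ca <- max(ca[aidx])
  amplitude <- peak_ca - baseline_ca
  max_deriv <- max(deriv[aidx], na.rm = TRUE)

  amp_met <- amplitude > thr$amplitude_min
  deriv_met <- max_deriv > thr$derivative_sd_multiple * base_sd

  viable <- NA
  if (!is.null(ion_row) && nrow(ion_row) == 1) {
    iidx <- in_window(time, ion_row) & !is.na(ca)
    if (sum(iidx) > 0) {
      viable <- (max(ca[iidx]) - baseline_ca) >= thr$viability_min_amplitude
    } else viable <- FALSE
  }

  list(excluded = FALSE, reason = NA_character_,
       baseline_ca = baseline_ca, peak_ca = peak_ca, amplitude = amplitude,
       max_derivative = max_deriv, baseline_derivative_sd = base_sd,
       amplitude_criterion_met = amp_met, derivative_criterion_met = deriv_met,
       is_responder = amp_met && deriv_met, viable = viable)
}

#' Classify cells as agonist responders
#'
#' Applies the two-part responder rule to every cell in a set of calibrated
#' calcium traces, one call per cell per application window.
#'
#' @param ca_traces a `calcium_traces` data frame from
#'   [calibrate_traces()] (columns `experiment_id`, `cell_id`, `time_s`,
#'   `ca_nM`).
#' @param windows a [protocol_windows()].
#' @param thresholds a [responder_thresholds()].
#' @param agonist optional agonist name; restricts calls to that
#'   application window (error if no such window exists).
#' @return A `responder_calls` data frame with per-cell amplitude,
#'   derivative statistics, the two criterion flags, `is_responder`,
#'   viability (if an ionomycin window exists) and exclusion reasons.
#' @export
classify_responders <- function(ca_traces, windows,
                                thresholds = responder_thresholds(),
                                agonist = NULL) {
  windows <- validate_windows(windows)
  stopifnot(inherits(thresholds, "responder_thresholds"))
  apps <- window_bounds(windows, "application", agonist)
  ion <- windows[windows$label == "ionomycin", , drop = FALSE]
  if (nrow(ion) == 0) ion <- NULL

  key <- interaction(ca_traces$experiment_id, ca_traces$cell_id, drop = TRUE)
  cells <- split(ca_traces, key)
  rows <- list()
  for (cell in cells) {
    cell <- cell[order(cell$time_s), ]
    for (a in seq_len(nrow(apps))) {
      app_row <- apps[a, , drop = FALSE]
      res <- classify_one(cell$time_s, cell$ca_nM, windows, thresholds,
                          app_row, ion)
      rows[[length(rows) + 1]] <- data.frame(
        experiment_id = cell$experiment_id[1],
        cell_id = cell$cell_id[1],
        agonist = app_row$agonist,
        excluded = res$excluded,
        exclusion_reason = if (res$excluded) res$reason else NA_character_,
        baseline_ca = if (res$excluded) NA_real_ else res$baseline_ca,
        peak_ca = if (res$excluded) NA_real_ else res$peak_ca,
        amplitude = if (res$excluded) NA_real_ else res$amplitude,
        max_derivative = if (res$excluded) NA_real_ else res$max_derivative,
        baseline_derivative_sd = if (res$excluded) NA_real_ else res$baseline_derivative_sd,
        amplitude_criterion_met = if (res$excluded) NA else res$amplitude_criterion_met,
        derivative_criterion_met = if (res$excluded) NA else res$derivative_criterion_met,
        is_responder = if (res$excluded) NA else res$is_responder,
        viable = if (res$excluded) NA else res$viable,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (thresholds$viability_filter && !is.null(ion)) {
    dead <- !is.na(out$viable) & !out$viable
    out$excluded[dead] <- TRUE
    out$exclusion_reason[dead] <- "failed_viability"
    out$is_responder[dead] <- NA
  }
  class(out) <- c("responder_calls", "data.frame")
  out
}

#' @export
print.responder_calls <- function(x, ...) {
  kept <- x[!x$excluded, , drop = FALSE]
  cat("Responder calls:", nrow(x), "cell x agonist entries (",
      sum(x$excluded), "excluded )\n")
  for (ag in unique(kept$agonist)) {
    sub <- kept[kept$agonist == ag, ]
    cat(sprintf("  %s: %d / %d responders (%.1f%%)\n", ag,
                sum(sub$is_responder), nrow(sub),
                100 * mean(sub$is_responder)))
  }
  invisible(x)
}

#' Tidy table of response amplitudes
#'
#' @param calls a `responder_calls` data frame.
#' @param responders_only keep only responding cells (the convention for
#'   reporting amplitudes).
#' @return Data frame `experiment_id`, `cell_id`, `agonist`, `amplitude`.
#' @export
amplitude_table <- function(calls, responders_only = TRUE) {
  stopifnot(inherits(calls, "responder_calls"))
  keep <- !calls$excluded
  if (responders_only) keep <- keep & !is.na(calls$is_responder) & calls$is_responder
  out <- calls[keep, c("experiment_id", "cell_id", "agonist", "amplitude")]
  rownames(out) <- NULL
  out
}
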