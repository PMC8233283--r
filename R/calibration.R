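#' Fura-2 calibration parameters
#'
#' Constants of the ratiometric calibration equation
#' \eqn{[\mathrm{Ca}^{2+}]_i = K_d\,\beta\,(R - R_{min})/(R_{max} - R)},
#' where \eqn{R = F_{340}/F_{380}} after background correction.
#'
#' @param Kd Fura-2/Ca dissociation constant in nM. Defaults to the
#'   literature in-cell value of 225 nM.
#' @param Rmin fluorescence ratio at zero calcium.
#' @param Rmax ratio at saturating calcium.
#' @param beta F380 at zero calcium divided by F380 at saturating calcium.
#'
#' @details `Rmin`, `Rmax` and `beta` are rig-dependent and normally come
#'   from an in-situ ionomycin/EGTA calibration; the defaults are typical
#'   values for a Fura-2 epifluorescence setup and are the ones used by the
#'   synthetic trace generator.
#'
#' @return A `calibration_params` list.
#' @export
calibration_params <- function(Kd = 225, Rmin = 0.5, Rmax = 6, beta = 8) {
  if (!is.numeric(Kd) || Kd <= 0) stop("Kd must be > 0")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!(Rmin > 0 && Rmax > Rmin)) stop("need 0 < Rmin < Rmax")
  structure(list(Kd = Kd, Rmin = Rmin, Rmax = Rmax, beta = beta),
            class = "calibration_params")
}

#' Build a fluorescence trace set
#'
#' @param traces data frame with columns `experiment_id`, `cell_id`,
#'   `time_s`, `F340`, `F380` (long format, one row per frame per cell).
#' @param background data frame with columns `experiment_id`,
#'   `background_340`, `background_380` (one row per experiment).
#' @param corrected logical, whether background has already been removed.
#' @return A `trace_set` object.
#' @export
trace_set <- function(traces, background, corrected = FALSE) {
  need <- c("experiment_id", "cell_id", "time_s", "F340", "F380")
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    stop("trace table missing column(s): ", paste(missing, collapse = ", "))
  }
  needb <- c("experiment_id", "background_340", "background_380")
  missingb <- setdiff(needb, names(background))
  if (length(missingb) > 0) {
    stop("background table missing column(s): ", paste(missingb, collapse = ", "))
  }
  absent <- setdiff(unique(traces$experiment_id), background$experiment_id)
  if (length(absent) > 0) {
    stop("no background levels for experiment(s): ",
         paste(absent, collapse = ", "))
  }
  if (!"valid" %in% names(traces)) traces$valid <- rep(TRUE, nrow(traces))
  structure(list(traces = traces, background = background,
                 corrected = corrected),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cells <- unique(x$traces[c("experiment_id", "cell_id")])
  cat("Fura-2 trace set:", nrow(cells), "cells in",
      length(unique(x$traces$experiment_id)), "experiment(s);",
      if (x$corrected) "background-corrected" else "raw", "\n")
  invisible(x)
}

#' Subtract per-experiment background fluorescence
#'
#' Removes the per-experiment background level from each wavelength
#' channel. Frames whose corrected F380 is not strictly positive cannot be
#' ratioed and are flagged invalid (`valid = FALSE`, channels set to `NA`)
#' rather than silently propagated.
#'
#' @param ts a [trace_set()].
#' @return The corrected `trace_set` (with `corrected = TRUE`).
#' @export
subtract_background <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  if (ts$corrected) stop("trace set is already background-corrected")
  tr <- ts$traces
  idx <- match(tr$experiment_id, ts$background$experiment_id)
  tr$F340 <- tr$F340 - ts$background$background_340[idx]
  tr$F380 <- tr$F380 - ts$background$background_380[idx]
  bad <- !is.na(tr$F380) & tr$F380 <= 0
  if (any(bad)) {
    tr$valid[bad] <- FALSE
    tr$F340[bad] <- NA_real_
    tr$F380[bad] <- NA_real_
  }
  ts$traces <- tr
  ts$corrected <- TRUE
  ts
}

#' F340/F380 ratio of a background-corrected trace set
#'
#' @param ts a background-corrected [trace_set()].
#' @return Data frame `experiment_id`, `cell_id`, `time_s`, `ratio`;
#'   invalid frames carry `NA`.
#' @export
compute_ratio <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  if (!ts$corrected) {
    stop("compute_ratio() requires a background-corrected trace set; ",
         "call subtract_background() first")
  }
  tr <- ts$traces
  out <- tr[c("experiment_id", "cell_id", "time_s")]
  out$ratio <- ifelse(tr$valid, tr$F340 / tr$F380, NA_real_)
  out
}

#' Convert fluorescence ratios to absolute calcium
#'
#' Applies \eqn{Ca = K_d \beta (R - R_{min})/(R_{max} - R)}. Ratios at or
#' below `Rmin` (rest-level noise) are clamped to 0 nM; ratios at or above
#' `Rmax` are saturated and returned as `NA` with a saturation flag so they
#' cannot corrupt derivative statistics downstream.
#'
#' @param R numeric vector of ratios (NA allowed).
#' @param params a [calibration_params()].
#' @return Numeric vector of calcium concentrations in nM, with attribute
#'   `saturated` (logical vector marking ratios >= Rmax).
#' @export
ratio_to_calcium <- function(R, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"))
  sat <- !is.na(R) & R >= params$Rmax
  ca <- params$Kd * params$beta * (R - params$Rmin) / (params$Rmax - R)
  ca[!is.na(R) & R <= params$Rmin] <- 0
  ca[sat] <- NA_real_
  attr(ca, "saturated") <- sat
  ca
}

#' Invert the calibration equation
#'
#' Maps calcium back to the fluorescence ratio:
#' \eqn{R = (Ca\,R_{max} + K_d\beta\,R_{min}) / (Ca + K_d\beta)}. Exact
#' algebraic inverse of [ratio_to_calcium()] on \eqn{[0, \infty)}.
#'
#' @param ca numeric vector of calcium concentrations (nM), >= 0.
#' @param params a [calibration_params()].
#' @return Numeric vector of ratios in `[Rmin, Rmax)`.
#' @export
calcium_to_ratio <- function(ca, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(ca < 0, na.rm = TRUE)) stop("calcium must be >= 0")
  (ca * params$Rmax + params$Kd * params$beta * params$Rmin) /
    (ca + params$Kd * params$beta)
}

#' Calibrate a raw trace set to calcium traces
#'
#' Convenience composition: [subtract_background()] (skipped if already
#' corrected), [compute_ratio()], [ratio_to_calcium()].
#'
#' @param ts a [trace_set()].
#' @param params a [calibration_params()].
#' @return A `calcium_traces` data frame with columns `experiment_id`,
#'   `cell_id`, `time_s`, `ca_nM`.
#' @export
calibrate_traces <- function(ts, params = calibration_params()) {
  if (!ts$corrected) ts <- subtract_background(ts)
  rt <- compute_ratio(ts)
  ca <- ratio_to_calcium(rt$ratio, params)
  out <- rt[c("experiment_id", "cell_id", "time_s")]
  out$ca_nM <- as.numeric(ca)
  class(out) <- c("calcium_traces", "data.frame")
  out
}

#' @export
plot.calcium_traces <- function(x, windows = NULL, max_cells = 30, ...) {
  ids <- unique(paste(x$experiment_id, x$cell_id, sep = "/"))
  keep <- ids[seq_len(min(length(ids), max_cells))]
  key <- paste(x$experiment_id, x$cell_id, sep = "/")
  sub <- x[key %in% keep, ]
  subkey <- paste(sub$experiment_id, sub$cell_id, sep = "/")
  tt <- sort(unique(sub$time_s))
  mat <- sapply(keep, function(id) {
    tr <- sub[subkey == id, ]
    tr$ca_nM[match(tt, tr$time_s)]
  })
  graphics::matplot(tt, mat, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "[Ca2+]i (nM)", ...)
  if (!is.null(windows)) {
    app <- windows[windows$label != "baseline", , drop = FALSE]
    graphics::abline(v = c(app$t_start, app$t_end), col = "grey60", lty = 2)
  }
  invisible(x)
}
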