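#' Protocol windows
#'
#' An ordered set of labeled time intervals describing one recording
#' protocol: a baseline window, one or more agonist application windows and
#' optionally a final ionomycin window (positive viability control).
#'
#' @param label character, each one of `"baseline"`, `"application"` or
#'   `"ionomycin"`.
#' @param t_start,t_end numeric, window bounds in seconds.
#' @param agonist character, agonist name for application windows (empty
#'   string otherwise).
#'
#' @details Windows must be non-overlapping with `t_start < t_end`; exactly
#'   one baseline window must precede the first application window; at most
#'   one ionomycin window is allowed and it must come last.
#'
#' @return A `protocol_windows` data frame with columns `label`, `agonist`,
#'   `t_start`, `t_end`, ordered by `t_start`.
#' @examples
#' protocol_windows(
#'   label   = c("baseline", "application", "ionomycin"),
#'   t_start = c(0, 60, 150),
#'   t_end   = c(60, 120, 180),
#'   agonist = c("", "THC", "")
#' )
#' @export
protocol_windows <- function(label, t_start, t_end, agonist = NULL) {
  if (is.null(agonist)) agonist <- rep("", length(label))
  w <- data.frame(
    label = as.character(label),
    agonist = as.character(agonist),
    t_start = as.numeric(t_start),
    t_end = as.numeric(t_end),
    stringsAsFactors = FALSE
  )
  validate_windows(w)
}

validate_windows <- function(w) {
  required <- c("label", "agonist", "t_start", "t_end")
  missing <- setdiff(required, names(w))
  if (length(missing) > 0) {
    stop("protocol windows missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(w$label, c("baseline", "application", "ionomycin"))
  if (length(bad) > 0) {
    stop("unknown window label(s): ", paste(unique(bad), collapse = ", "))
  }
  if (any(!is.finite(w$t_start)) || any(!is.finite(w$t_end))) {
    stop("window bounds must be finite")
  }
  if (any(w$t_start >= w$t_end)) stop("each window needs t_start < t_end")
  w <- w[order(w$t_start), , drop = FALSE]
  rownames(w) <- NULL
  if (nrow(w) > 1 && any(w$t_start[-1] < w$t_end[-nrow(w)])) {
    stop("protocol windows overlap")
  }
  n_base <- sum(w$label == "baseline")
  if (n_base != 1) stop("exactly one baseline window is required")
  apps <- which(w$label == "application")
  if (length(apps) == 0) stop("at least one application window is required")
  if (which(w$label == "baseline") > min(apps)) {
    stop("the baseline window must precede the first application window")
  }
  ion <- which(w$label == "ionomycin")
  if (length(ion) > 1) stop("at most one ionomycin window is allowed")
  if (length(ion) == 1 && ion != nrow(w)) {
    stop("the ionomycin window must be last")
  }
  class(w) <- c("protocol_windows", "data.frame")
  w
}

#' Default three-window protocol
#'
#' Baseline 0–60 s, a single agonist application 60–120 s and ionomycin
#' 150–180 s, mirroring a typical short agonist-challenge recording.
#'
#' @param agonist agonist name for the application window.
#' @return A [protocol_windows()] object.
#' @export
default_windows <- function(agonist = "THC") {
  protocol_windows(
    label   = c("baseline", "application", "ionomycin"),
    t_start = c(0, 60, 150),
    t_end   = c(60, 120, 180),
    agonist = c("", agonist, "")
  )
}

window_bounds <- function(windows, label, agonist = NULL) {
  rows <- windows[windows$label == label, , drop = FALSE]
  if (!is.null(agonist) && label == "application" && nzchar(agonist)) {
    rows <- rows[rows$agonist == agonist, , drop = FALSE]
  }
  if (nrow(rows) == 0) {
    stop("no '", label, "' window",
         if (!is.null(agonist) && nzchar(agonist)) paste0(" for agonist '", agonist, "'") else "",
         " in the protocol")
  }
  rows
}

in_window <- function(t, row) t >= row$t_start & t <= row$t_end
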