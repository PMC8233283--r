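#' Configuration for the synthetic Fura-2 trace generator
#'
#' The defaults emulate the recording conditions the downstream analysis
#' assumes: ~100 nM resting intracellular calcium, agonist-evoked rises
#' with first-order rise/decay kinetics, additive Gaussian measurement
#' noise on the latent calcium signal, and a universal ionomycin response
#' at the end of every experiment.
#'
#' @param n_cells cells per experiment.
#' @param n_experiments number of independent experiments (coverslips).
#' @param frame_interval acquisition interval in seconds.
#' @param baseline_ca resting calcium in nM.
#' @param baseline_noise_sd SD of additive Gaussian noise on the latent
#'   calcium signal, nM.
#' @param responder_fraction probability that a cell is a true responder.
#' @param amplitude_mean,amplitude_sd responder amplitude distribution
#'   (normal truncated at 0), nM.
#' @param nonresponder_max upper bound of the uniform non-responder
#'   amplitude band, nM. Kept well below the 50 nM classifier threshold so
#'   ground-truth labels are unambiguous at the default noise level.
#' @param rise_tau,decay_tau first-order rise/decay time constants, s.
#' @param ionomycin_ca calcium plateau reached during ionomycin, nM.
#' @param background_340,background_380 per-experiment background
#'   fluorescence added to each channel (arbitrary units).
#' @param photobleach_rate fractional intensity loss per second, applied
#'   multiplicatively to both channels (ratio-preserving).
#' @param f380_scale F380 level at saturating calcium (arbitrary units).
#' @param params [calibration_params()] used to invert latent calcium into
#'   fluorescence.
#' @param seed integer seed; identical seeds give identical output.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(n_cells = 50,
                             n_experiments = 1,
                             frame_interval = 2,
                             baseline_ca = 100,
                             baseline_noise_sd = 5,
                             responder_fraction = 0.65,
                             amplitude_mean = 150,
                             amplitude_sd = 25,
                             nonresponder_max = 25,
                             rise_tau = 2,
                             decay_tau = 20,
                             ionomycin_ca = 1000,
                             background_340 = 20,
                             background_380 = 15,
                             photobleach_rate = 0,
                             f380_scale = 200,
                             params = calibration_params(),
                             seed = NULL) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("responder_fraction must be in [0, 1]")
  }
  if (rise_tau <= 0 || decay_tau <= 0) stop("time constants must be > 0")
  if (baseline_ca < 0 || ionomycin_ca < 0) stop("calcium levels must be >= 0")
  if (photobleach_rate < 0) stop("photobleach_rate must be >= 0")
  structure(as.list(environment()), class = "trace_sim_config")
}

# First-order response kernel: 0 before onset, saturating exponential rise
# inside [t_on, t_off], exponential decay after t_off.
response_kernel <- function(t, t_on, t_off, rise_tau, decay_tau) {
  k <- numeric(length(t))
  rising <- t >= t_on & t <= t_off
  k[rising] <- 1 - exp(-(t[rising] - t_on) / rise_tau)
  after <- t > t_off
  peak <- 1 - exp(-(t_off - t_on) / rise_tau)
  k[after] <- peak * exp(-(t[after] - t_off) / decay_tau)
  k
}

#' Simulate ground-truth-labeled Fura-2 traces
#'
#' Builds a latent calcium trace per cell (baseline + noise; responders add
#' an agonist-locked first-order rise; every cell rises during ionomycin),
#' then inverts it through the calibration model to emit F340/F380 with
#' additive per-experiment background, so that
#' `calibrate_traces(simulate(...))` recovers the latent trace exactly when
#' noise and bleaching are zero.
#'
#' @param config a [trace_sim_config()].
#' @param windows a [protocol_windows()]; the simulated duration is the
#'   last window end.
#' @return A list with elements `traces` (a [trace_set()]) and `truth`
#'   (data frame `experiment_id`, `cell_id`, `is_responder`,
#'   `true_amplitude`, `onset_time`).
#' @export
simulate_calcium_traces <- function(config = trace_sim_config(),
                                    windows = default_windows()) {
  stopifnot(inherits(config, "trace_sim_config"))
  windows <- validate_windows(windows)
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$params
  tt <- seq(0, max(windows$t_end), by = config$frame_interval)
  apps <- windows[windows$label == "application", , drop = FALSE]
  ion <- windows[windows$label == "ionomycin", , drop = FALSE]

  trace_rows <- vector("list", config$n_experiments)
  truth_rows <- vector("list", config$n_experiments)
  for (e in seq_len(config$n_experiments)) {
    eid <- sprintf("exp%02d", e)
    n <- config$n_cells
    is_resp <- stats::runif(n) < config$responder_fraction
    amp <- numeric(n)
    if (any(is_resp)) {
      # truncated-at-zero normal via rejection
      k <- sum(is_resp)
      draws <- stats::rnorm(k, config$amplitude_mean, config$amplitude_sd)
      while (any(draws <= 0)) {
        bad <- draws <= 0
        draws[bad] <- stats::rnorm(sum(bad), config$amplitude_mean,
                                   config$amplitude_sd)
      }
      amp[is_resp] <- draws
    }
    amp[!is_resp] <- stats::runif(sum(!is_resp), 0, config$nonresponder_max)

    bleach <- exp(-config$photobleach_rate * tt)
    cell_frames <- vector("list", n)
    for (i in seq_len(n)) {
      ca <- rep(config$baseline_ca, length(tt))
      for (a in seq_len(nrow(apps))) {
        ca <- ca + amp[i] * response_kernel(tt, apps$t_start[a], apps$t_end[a],
                                            config$rise_tau, config$decay_tau)
      }
      if (nrow(ion) == 1) {
        ca <- ca + (config$ionomycin_ca - config$baseline_ca) *
          response_kernel(tt, ion$t_start, ion$t_end,
                          config$rise_tau, config$decay_tau)
      }
      if (config$baseline_noise_sd > 0) {
        ca <- ca + stats::rnorm(length(tt), 0, config$baseline_noise_sd)
      }
      ca <- pmax(ca, 0)
      R <- calcium_to_ratio(ca, p)
      # F380 declines from beta*scale (zero Ca) to scale (saturation)
      f380 <- config$f380_scale * (p$beta * p$Kd + ca) / (p$Kd + ca)
      f340 <- R * f380
      cell_frames[[i]] <- data.frame(
        experiment_id = eid,
        cell_id = sprintf("cell%03d", i),
        time_s = tt,
        F340 = f340 * bleach + config$background_340,
        F380 = f380 * bleach + config$background_380,
        stringsAsFactors = FALSE
      )
    }
    trace_rows[[e]] <- do.call(rbind, cell_frames)
    truth_rows[[e]] <- data.frame(
      experiment_id = eid,
      cell_id = sprintf("cell%03d", seq_len(n)),
      is_responder = is_resp,
      true_amplitude = amp,
      onset_time = if (nrow(apps) > 0) apps$t_start[1] else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  bg <- data.frame(
    experiment_id = sprintf("exp%02d", seq_len(config$n_experiments)),
    background_340 = config$background_340,
    background_380 = config$background_380,
    stringsAsFactors = FALSE
  )
  list(
    traces = trace_set(do.call(rbind, trace_rows), bg, corrected = FALSE),
    truth = do.call(rbind, truth_rows)
  )
}

#' Simulate a qPCR Ct table with known relative expression
#'
#' Generates replicate Ct values such that, at zero noise, the recovered
#' \eqn{2^{-\Delta Ct}} of each target gene equals the requested fraction of
#' the Trpm7 level, with housekeeping rows included.
#'
#' @param fractions either a named numeric vector (one condition) or a
#'   gene x condition numeric matrix of target expression as a fraction of
#'   Trpm7 (must be > 0).
#' @param housekeeping_cts named numeric vector of housekeeping-gene Ct
#'   values (e.g. `c(Actb = 18, Gapdh = 20)`).
#' @param trpm7_delta_ct Trpm7 Ct minus the geometric mean of the
#'   housekeeping Cts, in cycles (sets the Trpm7 level itself).
#' @param n_replicates technical replicates per (sample, gene); the study
#'   convention is triplicates.
#' @param ct_noise_sd replicate-to-replicate Ct noise, cycles.
#' @param n_samples biological samples per condition.
#' @param condition_name name of the condition column (e.g.
#'   `"gestational_day"`).
#' @param seed integer seed.
#' @return A [ct_table()] whose housekeeping set is
#'   `names(housekeeping_cts)` and whose reference gene is `"Trpm7"`.
#' @export
simulate_ct_table <- function(fractions,
                              housekeeping_cts = c(Actb = 18, Gapdh = 20),
                              trpm7_delta_ct = 5,
                              n_replicates = 3,
                              ct_noise_sd = 0,
                              n_samples = 1,
                              condition_name = "condition",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(names(housekeeping_cts)) || any(!nzchar(names(housekeeping_cts)))) {
    stop("housekeeping_cts must be a named vector")
  }
  if (is.matrix(fractions)) {
    if (is.null(rownames(fractions)) || is.null(colnames(fractions))) {
      stop("fraction matrix needs gene rownames and condition colnames")
    }
    frac_mat <- fractions
  } else {
    if (is.null(names(fractions))) stop("fractions must be named by gene")
    frac_mat <- matrix(fractions, ncol = 1,
                       dimnames = list(names(fractions), "c1"))
  }
  if (any(frac_mat <= 0)) stop("all target fractions must be > 0")
  if ("Trpm7" %in% rownames(frac_mat)) {
    stop("do not list Trpm7 in fractions; it is generated as the reference")
  }
  g_hk <- exp(mean(log(housekeeping_cts)))
  rows <- list()
  for (cond in colnames(frac_mat)) {
    for (s in seq_len(n_samples)) {
      sid <- paste0(cond, "_s", s)
      genes <- c(names(housekeeping_cts), "Trpm7", rownames(frac_mat))
      base_ct <- c(
        unname(housekeeping_cts),
        g_hk + trpm7_delta_ct,
        g_hk + trpm7_delta_ct - log2(frac_mat[, cond])
      )
      for (gi in seq_along(genes)) {
        ct <- base_ct[gi] + if (ct_noise_sd > 0) {
          stats::rnorm(n_replicates, 0, ct_noise_sd)
        } else rep(0, n_replicates)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, condition = cond, gene = genes[gi],
          replicate = seq_len(n_replicates), ct = ct,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "condition"] <- condition_name
  ct_table(out, housekeeping = names(housekeeping_cts),
           reference = "Trpm7", condition = condition_name)
}

#' Simulate an RNA-seq count matrix
#'
#' Draws gene x sample counts from a negative binomial distribution
#' (overdispersed Poisson) with expected values consistent with per-gene
#' base expression, gene length and library size, the structure RPKM
#' normalization assumes.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param gene_lengths transcript lengths in bp (recycled to `n_genes`).
#' @param library_sizes total mapped reads per sample (recycled to
#'   `n_samples`).
#' @param mean_rpkm per-gene expected RPKM (recycled); defaults to
#'   log-normal draws around 10 RPKM.
#' @param dispersion negative binomial dispersion (size = 1/dispersion).
#' @param seed integer seed.
#' @return A [count_matrix()].
#' @export
simulate_count_matrix <- function(n_genes = 100, n_samples = 6,
                                  gene_lengths = 2000,
                                  library_sizes = 1e6,
                                  mean_rpkm = NULL,
                                  dispersion = 0.1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_lengths <- rep_len(gene_lengths, n_genes)
  library_sizes <- rep_len(library_sizes, n_samples)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (is.null(mean_rpkm)) {
    mean_rpkm <- stats::rlnorm(n_genes, meanlog = log(10), sdlog = 1)
  }
  mean_rpkm <- rep_len(mean_rpkm, n_genes)
  mu <- outer(mean_rpkm * gene_lengths / 1000, library_sizes / 1e6)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
    nrow = n_genes,
    dimnames = list(sprintf("gene%03d", seq_len(n_genes)),
                    sprintf("sample%02d", seq_len(n_samples)))
  )
  count_matrix(counts, gene_lengths, total_reads = library_sizes)
}
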