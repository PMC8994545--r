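# ---- epoch container --------------------------------------------------------

#' Construct an epoch set
#'
#' Container for epoched source time series: a trials x sources x time array
#' with per-trial condition labels and a time axis in seconds.
#'
#' @param data 3-D numeric array, trials x sources x time.
#' @param condition Character vector, one label per trial (`"standard"` or a
#'   deviant dimension).
#' @param time Numeric time axis in seconds (length = dim 3).
#' @param sfreq Sampling rate in Hz.
#' @param source_labels Character vector of source names (length = dim 2).
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, condition, time, sfreq, source_labels) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(condition),
            dim(data)[2] == length(source_labels),
            dim(data)[3] == length(time))
  if (!all(is.finite(data))) stop("epoch data must be finite")
  structure(list(data = data, condition = condition, time = time,
                 sfreq = sfreq, source_labels = source_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d sources x %d samples @ %g Hz, t in [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq,
              min(x$time), max(x$time)))
  invisible(x)
}

# Closed-interval window -> sample index vector (rounding toward the interior
# via a small tolerance so that endpoint samples are included).
.window_idx <- function(time, window_s, tol = 1e-9) {
  which(time >= window_s[1] - tol & time <= window_s[2] + tol)
}

#' Epoch a continuous recording and baseline-correct
#'
#' Cuts epochs around analysed event onsets from a continuous multi-source
#' recording and subtracts the per-trial, per-source mean of the baseline
#' period (the pre-stimulus part of the window). Events whose epoch would
#' extend beyond the recording are dropped and counted. When `ts` is already
#' an `epoch_set`, only the baseline correction is (re)applied.
#'
#' @param ts Either a list with `data` (sources x time matrix) and `sfreq`,
#'   or an `epoch_set`.
#' @param events A `stimulus_sequence` or a data.frame with columns `onset`,
#'   `analyzed` and `dimension` (or `tone_type`).
#' @param window_s Epoch window in seconds relative to onset
#'   (default c(-0.1, 0.5)).
#' @param baseline_s Baseline window (default c(window_s[1], 0), i.e. up to
#'   but excluding stimulus onset).
#' @param source_labels Labels for the continuous-input case.
#' @return An `epoch_set`; attribute `n_dropped` counts edge-dropped events.
#' @export
epoch_and_baseline <- function(ts, events = NULL, window_s = c(-0.1, 0.5),
                               baseline_s = NULL, source_labels = NULL) {
  if (is.null(baseline_s)) baseline_s <- c(window_s[1], 0)
  if (inherits(ts, "epoch_set")) {
    return(.baseline_correct(ts, baseline_s))
  }
  stopifnot(is.matrix(ts$data), !is.null(ts$sfreq), !is.null(events))
  if (inherits(events, "stimulus_sequence")) events <- events$events
  if (is.null(events$dimension)) events$dimension <- tone_dimension(events$tone_type)
  events <- events[events$analyzed, , drop = FALSE]
  fs <- ts$sfreq
  n_time_total <- ncol(ts$data)
  rel <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  time <- rel / fs
  onset_smp <- round(events$onset * fs) + 1L
  keep <- onset_smp + min(rel) >= 1 & onset_smp + max(rel) <= n_time_total
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " event(s) too close to the recording edge; dropped")
  }
  onset_smp <- onset_smp[keep]
  if (length(onset_smp) == 0) stop("no epochs inside the recording")
  labels <- source_labels %||% ts$source_labels %||%
    paste0("S", seq_len(nrow(ts$data)))
  n_src <- nrow(ts$data)
  data <- array(0, c(length(onset_smp), n_src, length(rel)))
  for (i in seq_along(onset_smp)) {
    data[i, , ] <- ts$data[, onset_smp[i] + rel, drop = FALSE]
  }
  ep <- epoch_set(data, events$dimension[keep], time, fs, labels)
  ep <- .baseline_correct(ep, baseline_s)
  attr(ep, "n_dropped") <- n_dropped
  ep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subtract the per-trial/source mean over [baseline_s[1], baseline_s[2]).
.baseline_correct <- function(ep, baseline_s) {
  idx <- which(ep$time >= baseline_s[1] - 1e-9 & ep$time < baseline_s[2] - 1e-9)
  if (!length(idx)) stop("baseline window contains no samples")
  bl <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(bl)  # recycles over the time dimension
  ep
}

# ---- filtering --------------------------------------------------------------

#' Zero-phase low-pass plus band-stop filter of a signal
#'
#' Forward-backward (zero-phase) Butterworth filtering: a low-pass at
#' `low_pass_hz` followed by a band-stop over `notch_hz`, mirroring standard
#' MEG preprocessing (line noise at 50 Hz).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param low_pass_hz Low-pass cutoff (default 100).
#' @param notch_hz Band-stop edges (default c(48, 52)); `NULL` to skip.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered vector of the same length.
#' @export
zero_phase_filter <- function(x, fs, low_pass_hz = 100, notch_hz = c(48, 52),
                              order = 4) {
  nyq <- fs / 2
  if (low_pass_hz >= nyq) stop("low-pass cutoff must be below Nyquist (", nyq, " Hz)")
  lp <- signal::butter(order, low_pass_hz / nyq, type = "low")
  y <- signal::filtfilt(lp, x)
  if (!is.null(notch_hz)) {
    if (max(notch_hz) >= nyq) stop("notch edges must be below Nyquist")
    bs <- signal::butter(order, notch_hz / nyq, type = "stop")
    y <- signal::filtfilt(bs, y)
  }
  y
}

#' Filter all epochs of an epoch set
#'
#' Applies [zero_phase_filter()] along the time axis of every trial and
#' source. Zero-phase filtering leaves the group delay at zero, so evoked
#' latencies are not shifted.
#'
#' @param ep An `epoch_set`.
#' @inheritParams zero_phase_filter
#' @return Filtered `epoch_set`.
#' @export
filter_epochs <- function(ep, low_pass_hz = 100, notch_hz = c(48, 52),
                          order = 4) {
  stopifnot(inherits(ep, "epoch_set"))
  if (ep$sfreq <= 200 && low_pass_hz == 100) {
    stop("sample rate must exceed 200 Hz for the default 100-Hz low-pass")
  }
  d <- ep$data
  n_trial <- dim(d)[1]; n_src <- dim(d)[2]
  for (i in seq_len(n_trial)) {
    for (s in seq_len(n_src)) {
      d[i, s, ] <- zero_phase_filter(d[i, s, ], ep$sfreq, low_pass_hz,
                                     notch_hz, order)
    }
  }
  ep$data <- d
  ep
}

# ---- robust averaging -------------------------------------------------------

# Vectorised column medians: one radix sort over (column, value) pairs.
.col_medians <- function(X) {
  n <- nrow(X)
  Xs <- matrix(X[order(col(X), X)], n)
  if (n %% 2 == 1) Xs[(n + 1) / 2, ] else
    (Xs[n / 2, ] + Xs[n / 2 + 1, ]) / 2
}

# Columnwise iteratively reweighted mean with Tukey bisquare weights.
# X: trials x m matrix. Returns list(mean = length-m vector,
# weights = trials x m matrix, fallback = logical length m).
.bisquare_mean <- function(X, c_tukey = 4.685, max_iter = 20, tol = 1e-6) {
  n <- nrow(X); m <- ncol(X)
  mu <- .col_medians(X)
  W <- matrix(1, n, m)
  fallback <- logical(m)
  for (it in seq_len(max_iter)) {
    R <- X - rep(mu, each = n)
    s <- 1.4826 * .col_medians(abs(R))
    active <- s > 0
    U <- R / rep(ifelse(active, c_tukey * s, 1), each = n)
    W <- ifelse(abs(U) < 1, (1 - U^2)^2, 0)
    W[, !active] <- 1  # identical trials: plain mean
    sw <- colSums(W)
    dead <- sw == 0
    if (any(dead)) {
      # all trials rejected at these points: fall back to the median
      fallback[dead] <- TRUE
      W[, dead] <- 1
      mu_new <- colSums(W * X) / colSums(W)
      mu_new[dead] <- .col_medians(X[, dead, drop = FALSE])
    } else {
      mu_new <- colSums(W * X) / sw
    }
    delta <- max(abs(mu_new - mu) / pmax(abs(mu), 1e-12))
    mu <- mu_new
    if (delta < tol) break
  }
  list(mean = mu, weights = W, fallback = fallback)
}

#' Robust (iteratively reweighted) trial averaging
#'
#' Per condition, source and time point, computes an iteratively reweighted
#' mean across trials with Tukey bisquare weights (tuning constant
#' `c_tukey` x MAD, median start, at most `max_iter` iterations). Identical
#' trials yield the arithmetic mean with unit weights; time points where all
#' trials are down-weighted to zero fall back to the median and are counted.
#' Optionally re-applies a zero-phase low-pass to the averaged waveforms to
#' remove the high-frequency noise that robust weighting introduces.
#'
#' @param ep An `epoch_set` (>= 2 trials per condition).
#' @param c_tukey Bisquare tuning constant in MAD units (default 4.685).
#' @param max_iter Maximum IRLS iterations (default 20).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param relowpass_hz Cutoff of the post-averaging zero-phase low-pass;
#'   `NULL` (default) skips it.
#' @return Object of class `evoked_set`: `waveforms` (condition x source x
#'   time array), `weights` (list per condition of trials x source x time
#'   arrays in \[0, 1\]), `conditions`, `time`, `sfreq`, `source_labels`,
#'   `n_fallback`.
#' @export
robust_average <- function(ep, c_tukey = 4.685, max_iter = 20, tol = 1e-6,
                           relowpass_hz = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  conds <- unique(ep$condition)
  n_src <- dim(ep$data)[2]; n_t <- dim(ep$data)[3]
  waveforms <- array(0, c(length(conds), n_src, n_t),
                     dimnames = list(conds, ep$source_labels, NULL))
  weights <- stats::setNames(vector("list", length(conds)), conds)
  n_fallback <- 0L
  for (ci in seq_along(conds)) {
    rows <- which(ep$condition == conds[ci])
    if (length(rows) < 2) stop("condition '", conds[ci], "' has fewer than 2 trials")
    X <- matrix(ep$data[rows, , , drop = FALSE], nrow = length(rows))
    fit <- .bisquare_mean(X, c_tukey, max_iter, tol)
    waveforms[ci, , ] <- matrix(fit$mean, n_src, n_t)
    weights[[ci]] <- array(fit$weights, c(length(rows), n_src, n_t))
    n_fallback <- n_fallback + sum(fit$fallback)
  }
  if (n_fallback > 0) {
    message(n_fallback, " (source, time) point(s) fell back to the median")
  }
  if (!is.null(relowpass_hz)) {
    for (ci in seq_along(conds)) {
      for (s in seq_len(n_src)) {
        waveforms[ci, s, ] <- zero_phase_filter(waveforms[ci, s, ], ep$sfreq,
                                                low_pass_hz = relowpass_hz,
                                                notch_hz = NULL)
      }
    }
  }
  structure(list(waveforms = waveforms, weights = weights, conditions = conds,
                 time = ep$time, sfreq = ep$sfreq,
                 source_labels = ep$source_labels, n_fallback = n_fallback),
            class = "evoked_set")
}

# ---- MMN quantification -----------------------------------------------------

#' Quantify the MMN and M100 from an evoked set
#'
#' The mismatch waveform is the average of the deviant-condition waveforms
#' minus the standard waveform, per source. MMN amplitude is the signed mean
#' of the mismatch waveform in the region of interest over the MMN window
#' (100-200 ms); per-deviant-dimension amplitudes are computed the same way.
#' The M100 control amplitude is the magnitude of the peak deflection of the
#' standard response in the M100 window (50-150 ms). All windows are closed
#' intervals in seconds.
#'
#' @param ev An `evoked_set` containing `"standard"` and at least one deviant
#'   condition.
#' @param roi Source label used for amplitude quantification (default left
#'   primary auditory cortex).
#' @param mmn_window_s MMN averaging window (default c(0.1, 0.2)).
#' @param m100_window_s M100 peak window (default c(0.05, 0.15)).
#' @return Object of class `mmn_result`: `mmn_waveform` (source x time),
#'   `mmn_amplitude`, `m100_amplitude`, `per_dimension` (named vector),
#'   `roi`, windows, `time`, `source_labels`.
#' @export
compute_mmn <- function(ev, roi = "A1_L", mmn_window_s = c(0.1, 0.2),
                        m100_window_s = c(0.05, 0.15)) {
  stopifnot(inherits(ev, "evoked_set"))
  if (!"standard" %in% ev$conditions) stop("missing 'standard' condition")
  dev_conds <- setdiff(ev$conditions, "standard")
  if (!length(dev_conds)) stop("no deviant condition present")
  if (!roi %in% ev$source_labels) stop("unknown ROI '", roi, "'")
  std <- ev$waveforms["standard", , , drop = TRUE]
  if (is.null(dim(std))) std <- matrix(std, nrow = length(ev$source_labels))
  dev_mean <- apply(ev$waveforms[dev_conds, , , drop = FALSE], c(2, 3), mean)
  mmn <- dev_mean - std
  rownames(mmn) <- ev$source_labels

  mmn_idx <- .window_idx(ev$time, mmn_window_s)
  m100_idx <- .window_idx(ev$time, m100_window_s)
  roi_i <- match(roi, ev$source_labels)
  amplitude <- mean(mmn[roi_i, mmn_idx])
  per_dim <- vapply(dev_conds, function(dc) {
    w <- ev$waveforms[dc, roi_i, ] - std[roi_i, ]
    mean(w[mmn_idx])
  }, numeric(1))
  m100 <- max(abs(std[roi_i, m100_idx]))

  structure(list(mmn_waveform = mmn, mmn_amplitude = amplitude,
                 m100_amplitude = m100, per_dimension = per_dim,
                 roi = roi, mmn_window_s = mmn_window_s,
                 m100_window_s = m100_window_s, time = ev$time,
                 source_labels = ev$source_labels),
            class = "mmn_result")
}

#' Per-subject MMN from epoched data
#'
#' Convenience wrapper over the standard evoked path: optional zero-phase
#' filtering, robust averaging with post-average 100-Hz low-pass, and MMN/M100
#' quantification.
#'
#' @param ep An `epoch_set`.
#' @param filter Apply the default low-pass + notch first (default TRUE).
#' @param ... Passed to [compute_mmn()].
#' @return An `mmn_result`.
#' @export
subject_mmn <- function(ep, filter = TRUE, ...) {
  if (filter) ep <- filter_epochs(ep)
  ev <- robust_average(ep, relowpass_hz = if (filter) 100 else NULL)
  compute_mmn(ev, ...)
}

# ---- group statistics -------------------------------------------------------

#' Group statistics on MMN amplitudes and waveforms
#'
#' One-way ANOVA of MMN amplitude across groups, pairwise Welch post hoc
#' comparisons with Holm correction, and per-timepoint Welch comparisons of
#' each patient group's ROI mismatch waveform against controls with
#' Benjamini-Hochberg FDR correction across time points.
#'
#' @param results List of `mmn_result`s, one per subject.
#' @param groups Character vector of group labels (same order).
#' @param control_label Label of the control group (default `"controls"`,
#'   falling back to the first label).
#' @param q FDR level for the timepoint masks (default 0.05).
#' @param amplitudes Optional amplitude override (default: the stored
#'   `mmn_amplitude`s).
#' @return Object of class `group_evoked_stats`: `anova` (`F`, `p`, `df`),
#'   `posthoc` (pairwise Welch/Holm p-value matrix), `timepoint` (per patient
#'   group: raw `p`, `p_fdr`, logical `mask`), `group_means`, `q`.
#' @export
group_evoked_stats <- function(results, groups, control_label = NULL,
                               q = 0.05, amplitudes = NULL) {
  stopifnot(length(results) == length(groups))
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 subjects")
  if (is.null(amplitudes)) {
    amplitudes <- vapply(results, `[[`, numeric(1), "mmn_amplitude")
  }
  for (g in names(tab)) {
    if (stats::var(amplitudes[groups == g]) == 0) {
      stop("group '", g, "' has zero amplitude variance")
    }
  }
  control_label <- control_label %||%
    (if ("controls" %in% groups) "controls" else groups[1])

  fit <- stats::aov(amplitudes ~ factor(groups))
  an <- summary(fit)[[1]]
  anova <- list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                df = c(an$Df[1], an$Df[2]))
  posthoc <- stats::pairwise.t.test(amplitudes, groups, pool.sd = FALSE,
                                    p.adjust.method = "holm")$p.value

  roi_i <- match(results[[1]]$roi, results[[1]]$source_labels)
  wave <- t(vapply(results, function(r) r$mmn_waveform[roi_i, ],
                   numeric(ncol(results[[1]]$mmn_waveform))))
  ctrl_rows <- which(groups == control_label)
  timepoint <- list()
  for (g in setdiff(names(tab), control_label)) {
    rows <- which(groups == g)
    p <- vapply(seq_len(ncol(wave)), function(j) {
      stats::t.test(wave[ctrl_rows, j], wave[rows, j])$p.value
    }, numeric(1))
    p_fdr <- stats::p.adjust(p, method = "BH")
    timepoint[[g]] <- list(p = p, p_fdr = p_fdr, mask = p_fdr < q)
  }

  structure(list(anova = anova, posthoc = posthoc, timepoint = timepoint,
                 group_means = tapply(amplitudes, groups, mean), q = q,
                 control_label = control_label),
            class = "group_evoked_stats")
}
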