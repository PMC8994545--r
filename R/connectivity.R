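# ---- network definition -----------------------------------------------------

#' The eight source regions
#'
#' Bilateral primary auditory cortex (A1), superior temporal gyrus (STG),
#' inferior frontal gyrus (IFG) and inferior parietal cortex (IPC), with the
#' literature MNI coordinates attached as an attribute.
#'
#' @format Character vector of length 8.
#' @export
SOURCE_LABELS <- structure(
  c("A1_L", "A1_R", "STG_L", "STG_R", "IFG_L", "IFG_R", "IPC_L", "IPC_R"),
  mni = rbind(
    A1_L = c(-42, -22, 7), A1_R = c(46, -14, 8),
    STG_L = c(-61, -32, 8), STG_R = c(59, -25, 8),
    IFG_L = c(-46, 20, 8), IFG_R = c(46, 20, 8),
    IPC_L = c(-49, -38, 38), IPC_R = c(57, -38, 42)
  )
)

#' The 11 analysed connections
#'
#' MD-to-auditory connections (STG-IPC and STG-IFG on each side),
#' cross-hemispheric connections (STG-STG, IPC-IPC, IFG-IFG), within-auditory
#' connections (A1-STG each side) and MD-region connections (IPC-IFG each
#' side).
#'
#' @format Character vector of length 11 (`"label-label"`).
#' @export
CONNECTIONS_11 <- c(
  "STG_L-IPC_L", "STG_R-IPC_R", "STG_L-IFG_L", "STG_R-IFG_R",
  "STG_L-STG_R", "IPC_L-IPC_R", "IFG_L-IFG_R",
  "A1_L-STG_L", "A1_R-STG_R", "IPC_L-IFG_L", "IPC_R-IFG_R"
)

#' Frequency bands
#'
#' Theta 4-8, alpha 8-20, beta 20-30, low gamma 30-45 and high gamma
#' 55-70 Hz. Intervals are half-open `[low, high)` except the final band,
#' closed at 70 Hz; the 45-55 Hz gap guards the 50-Hz line-noise notch.
#'
#' @format Named list of `c(low, high)` pairs.
#' @export
DEFAULT_BANDS <- list(theta = c(4, 8), alpha = c(8, 20), beta = c(20, 30),
                      low_gamma = c(30, 45), high_gamma = c(55, 70))

#' Source-index pairs of connection names
#'
#' @param connections Character vector like `"STG_L-IPC_L"`.
#' @param labels Source labels defining the index space.
#' @return Integer matrix, one row per connection, columns `i`, `j`.
#' @export
connection_index <- function(connections, labels = SOURCE_LABELS) {
  if (!length(connections)) return(matrix(integer(0), 0, 2))
  parts <- strsplit(connections, "-", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    idx <- match(p, labels)
    if (any(is.na(idx))) stop("unknown source in connection: ",
                              paste(p, collapse = "-"))
    idx
  }, integer(2)))
  colnames(out) <- c("i", "j")
  out
}

# ---- Slepian tapers ---------------------------------------------------------

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` Slepian sequences of length `n` for time-bandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' matrix whose eigenvalue order matches the spectral concentration order.
#' Tapers have unit energy; polarity follows the convention that each
#' taper's mean (or, for odd tapers, its leading lobe) is positive.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (window length x half-bandwidth in Hz /
#'   sampling rate x n; i.e. `T * W`).
#' @param k Number of tapers.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  t0 <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  diag_off <- t0[-1] * (n - t0[-1]) / 2
  A <- diag(diag_main)
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    s <- sum(v)
    pol <- if (abs(s) > 1e-8) sign(s) else sign(v[which.max(abs(cumsum(v)))])
    tapers[, j] <- v / sqrt(sum(v^2)) * pol
  }
  tapers
}

# ---- multitaper decomposition -----------------------------------------------

#' Multitaper Fourier decomposition of epoched data
#'
#' Slepian-tapered Fourier coefficients of every trial and source over an
#' analysis window, with a +/- `half_bandwidth_hz` smoothing box. The taper
#' count is `K = 2 T W - 1` (0.5-s window at 4 Hz half-bandwidth gives 3
#' tapers). The window is half-open `[start, end)`.
#'
#' @param ep An `epoch_set`.
#' @param window_s Analysis window in seconds (default c(0, 0.5); the MMN
#'   variant uses c(0, 0.25)).
#' @param half_bandwidth_hz Multitaper half-bandwidth W in Hz (default 4).
#' @return Object of class `spectral_decomposition`: complex `coef` array of
#'   dimension (trials x tapers) x sources x frequencies (taper fastest
#'   within trial), `freq_hz`, `n_trials`, `n_tapers`, `half_bandwidth_hz`,
#'   `window_s`, `source_labels`, `condition`.
#' @export
multitaper_spectra <- function(ep, window_s = c(0, 0.5),
                               half_bandwidth_hz = 4) {
  stopifnot(inherits(ep, "epoch_set"))
  if (window_s[1] < min(ep$time) - 1e-9 || window_s[2] > max(ep$time) + 1 / ep$sfreq) {
    stop("analysis window outside the epoch")
  }
  idx <- which(ep$time >= window_s[1] - 1e-9 & ep$time < window_s[2] - 1e-9)
  n <- length(idx)
  if (n < 8) stop("too few samples in the analysis window")
  T_dur <- n / ep$sfreq
  tw <- T_dur * half_bandwidth_hz
  if (tw < 1) stop("window length x half-bandwidth must be at least 1")
  K <- max(1L, as.integer(round(2 * tw - 1)))
  tapers <- dpss_tapers(n, tw, K)

  n_trials <- dim(ep$data)[1]
  n_src <- dim(ep$data)[2]
  freq_all <- (seq_len(n) - 1) * ep$sfreq / n
  keep_f <- which(freq_all > 0 & freq_all <= ep$sfreq / 2)
  n_f <- length(keep_f)

  # samples x (trials * sources), trial-major columns
  X2 <- matrix(aperm(ep$data[, , idx, drop = FALSE], c(3, 1, 2)), nrow = n)
  coef <- array(complex(real = 0), c(n_trials * K, n_src, n_f))
  for (k in seq_len(K)) {
    Fk <- stats::mvfft(X2 * tapers[, k])[keep_f, , drop = FALSE]
    # Fk: freq x (trial, source); scatter into rows (trial-1)*K + k
    Fk <- array(Fk, c(n_f, n_trials, n_src))
    coef[seq(k, by = K, length.out = n_trials), , ] <-
      aperm(Fk, c(2, 3, 1))
  }
  structure(list(coef = coef, freq_hz = freq_all[keep_f], n_trials = n_trials,
                 n_tapers = K, half_bandwidth_hz = half_bandwidth_hz,
                 window_s = window_s, source_labels = ep$source_labels,
                 condition = ep$condition),
            class = "spectral_decomposition")
}

# ---- partialized connectivity -----------------------------------------------

# Partial coupling values for chosen source pairs at every frequency.
# A: complex (rows x sources x freqs) coefficient array (already
# unit-normalized for the PLV variant). Returns pairs x freqs matrix.
# Thin wrapper over the compiled core.
.partial_values <- function(A, pair_idx, imaginary, ridge_scale = 1e-8) {
  .cpp_partial_values(A, pair_idx - 1L, imaginary, ridge_scale)
}

# Unit-normalize complex coefficients (phase-only), guarding zeros.
.unit_normalize <- function(A) {
  m <- Mod(A)
  m[m == 0] <- 1
  A / m
}

#' Partialized frequency-resolved connectivity
#'
#' Computes partial phase-locking value or partial imaginary coherence for a
#' set of connections at every frequency of a multitaper decomposition. The
#' cross-spectral matrix (of phase-normalized coefficients for the PLV
#' variant) is averaged over trials and tapers, a small ridge is added, and
#' the matrix is inverted; the partial coherency is
#' `K_ij = -P_ij / sqrt(P_ii P_jj)`. The measure is `|K_ij|` (partial PLV)
#' or `|Im K_ij|` (partial imaginary coherence), clipped to \[0, 1\]. With
#' two sources the partialization set is empty and partial PLV reduces to
#' the classical PLV.
#'
#' @param spec A `spectral_decomposition`.
#' @param measure `"partial_plv"` or `"partial_icoh"`.
#' @param connections Character vector of `"label-label"` connections
#'   (default the 11 network connections when 8 sources are present, else all
#'   pairs).
#' @param ridge_scale Ridge as a fraction of the mean cross-spectral diagonal
#'   (default 1e-8).
#' @return Object of class `connectivity_spectrum`: `values` (connections x
#'   frequencies matrix), `freq_hz`, `measure`, `connections`.
#' @export
partial_connectivity <- function(spec, measure = c("partial_plv", "partial_icoh"),
                                 connections = NULL, ridge_scale = 1e-8) {
  measure <- match.arg(measure)
  stopifnot(inherits(spec, "spectral_decomposition"))
  n_src <- dim(spec$coef)[2]
  if (nrow(spec$coef) < n_src) {
    stop("trials x tapers must be at least the number of sources")
  }
  if (is.null(connections)) {
    connections <- if (n_src == 8 &&
                       all(SOURCE_LABELS %in% spec$source_labels)) {
      CONNECTIONS_11
    } else {
      pairs <- utils::combn(spec$source_labels, 2)
      paste(pairs[1, ], pairs[2, ], sep = "-")
    }
  }
  pair_idx <- connection_index(connections, spec$source_labels)
  A <- if (measure == "partial_plv") .unit_normalize(spec$coef) else spec$coef
  vals <- .partial_values(A, pair_idx, imaginary = measure == "partial_icoh",
                          ridge_scale = ridge_scale)
  rownames(vals) <- connections
  structure(list(values = vals, freq_hz = spec$freq_hz, measure = measure,
                 connections = connections),
            class = "connectivity_spectrum")
}

#' Average a connectivity spectrum into frequency bands
#'
#' Arithmetic mean of the per-frequency values whose frequency falls in each
#' band. Bands are half-open `[low, high)`; the band with the highest upper
#' edge is closed there.
#'
#' @param cs A `connectivity_spectrum` (or plain connections x frequencies
#'   matrix with a `freq_hz` argument).
#' @param bands Named list of `c(low, high)` (default [DEFAULT_BANDS]).
#' @param freq_hz Frequency axis when `cs` is a plain matrix.
#' @return Object of class `connectivity_result`: bands x connections matrix
#'   with attribute `measure`.
#' @export
band_average <- function(cs, bands = DEFAULT_BANDS, freq_hz = NULL) {
  if (inherits(cs, "connectivity_spectrum")) {
    vals <- cs$values; freq_hz <- cs$freq_hz; measure <- cs$measure
  } else {
    vals <- cs; measure <- NA_character_
    if (is.null(freq_hz)) stop("freq_hz required for a plain matrix")
  }
  hi_max <- max(vapply(bands, `[`, numeric(1), 2))
  out <- matrix(NA_real_, length(bands), nrow(vals),
                dimnames = list(names(bands), rownames(vals)))
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- freq_hz >= lo - 1e-9 &
      (freq_hz < hi - 1e-9 | (hi == hi_max & freq_hz <= hi + 1e-9))
    if (!any(sel)) stop("band '", b, "' contains no frequencies")
    out[b, ] <- rowMeans(vals[, sel, drop = FALSE])
  }
  structure(out, measure = measure, class = c("connectivity_result", "matrix"))
}

#' Per-band spectral power
#'
#' Descriptive mean power (`|coef|^2` averaged over trials and tapers) per
#' source and band; used to verify that coupling manipulations leave marginal
#' power unchanged.
#'
#' @param spec A `spectral_decomposition`.
#' @param bands Band definition list.
#' @return bands x sources matrix.
#' @export
band_power <- function(spec, bands = DEFAULT_BANDS) {
  pw <- apply(Mod(spec$coef)^2, c(2, 3), mean)  # sources x freqs
  hi_max <- max(vapply(bands, `[`, numeric(1), 2))
  out <- matrix(NA_real_, length(bands), dim(pw)[1],
                dimnames = list(names(bands), spec$source_labels))
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- spec$freq_hz >= lo - 1e-9 &
      (spec$freq_hz < hi - 1e-9 | (hi == hi_max & spec$freq_hz <= hi + 1e-9))
    out[b, ] <- rowMeans(pw[, sel, drop = FALSE])
  }
  out
}

# ---- evoked subtraction -----------------------------------------------------

#' Subtract the condition-averaged evoked response from every trial
#'
#' After subtraction, the mean across trials is exactly zero per condition,
#' source and time point, leaving induced (non-phase-locked) activity. A
#' condition with a single trial is zeroed entirely and counted.
#'
#' @param ep An `epoch_set`.
#' @return An `epoch_set` of induced activity; attribute `n_zeroed_conditions`
#'   counts single-trial conditions.
#' @export
subtract_evoked <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  n_zeroed <- 0L
  for (cond in unique(ep$condition)) {
    rows <- which(ep$condition == cond)
    if (length(rows) == 1) {
      ep$data[rows, , ] <- 0
      n_zeroed <- n_zeroed + 1L
      next
    }
    avg <- apply(ep$data[rows, , , drop = FALSE], c(2, 3), mean)
    ep$data[rows, , ] <- sweep(ep$data[rows, , , drop = FALSE],
                               c(2, 3), avg, "-")
  }
  if (n_zeroed > 0) {
    message(n_zeroed, " single-trial condition(s) zeroed")
  }
  attr(ep, "n_zeroed_conditions") <- n_zeroed
  ep
}

# ---- trial-shuffled null ----------------------------------------------------

# Union of the frequency bins any band uses (half-open bands, top band
# closed); returns the index vector.
.band_freq_union <- function(freq_hz, bands) {
  hi_max <- max(vapply(bands, `[`, numeric(1), 2))
  sel <- rep(FALSE, length(freq_hz))
  for (b in bands) {
    sel <- sel | (freq_hz >= b[1] - 1e-9 &
                    (freq_hz < b[2] - 1e-9 |
                       (b[2] == hi_max & freq_hz <= b[2] + 1e-9)))
  }
  which(sel)
}

#' Trial-shuffled permutation null for partialized connectivity
#'
#' For each iteration, the trial order of the Fourier coefficients is
#' permuted independently for every source (destroying cross-trial phase
#' alignment while preserving every marginal spectrum exactly), the full
#' partial-connectivity computation is repeated, and the result is
#' band-averaged. Per-iteration seeds are derived from the master seed by
#' counter splitting, so the null is reproducible.
#'
#' @param x An `epoch_set` (decomposed internally) or a
#'   `spectral_decomposition`.
#' @param n_iterations Number of shuffles (default 100).
#' @param seed Master seed.
#' @param measure,connections,bands,window_s,half_bandwidth_hz As in
#'   [partial_connectivity()] / [multitaper_spectra()] / [band_average()].
#' @return Object of class `null_distribution`: array bands x connections x
#'   iterations, with attributes `measure` and `n_iterations`. Pooling a
#'   band's slice gives `n_connections * n_iterations` null values.
#' @export
trial_shuffle_null <- function(x, n_iterations = 100, seed = 1,
                               measure = "partial_plv", connections = NULL,
                               bands = DEFAULT_BANDS, window_s = c(0, 0.5),
                               half_bandwidth_hz = 4) {
  if (n_iterations < 1) stop("n_iterations must be at least 1")
  spec <- if (inherits(x, "spectral_decomposition")) x else
    multitaper_spectra(x, window_s, half_bandwidth_hz)
  if (spec$n_trials < 10) stop("need at least 10 trials for the shuffle null")
  if (is.null(connections)) {
    connections <- if (dim(spec$coef)[2] == 8) CONNECTIONS_11 else NULL
  }
  if (is.null(connections)) {
    pairs <- utils::combn(spec$source_labels, 2)
    connections <- paste(pairs[1, ], pairs[2, ], sep = "-")
  }
  pair_idx <- connection_index(connections, spec$source_labels)
  A <- if (measure == "partial_plv") .unit_normalize(spec$coef) else spec$coef
  imag <- measure == "partial_icoh"

  # only the frequency bins a band will consume need recomputation
  f_sel <- .band_freq_union(spec$freq_hz, bands)
  A <- A[, , f_sel, drop = FALSE]
  freq_hz <- spec$freq_hz[f_sel]

  # per-iteration permutations from counter-split seeds (reproducible)
  n_src <- dim(A)[2]
  perms <- matrix(0L, spec$n_trials, n_src * n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(seed + 7717L * it)
    for (s in seq_len(n_src)) {
      perms[, (it - 1L) * n_src + s] <- sample.int(spec$n_trials)
    }
  }
  vals <- .cpp_shuffle_null(A, pair_idx - 1L, imag, 1e-8, perms,
                            spec$n_trials, spec$n_tapers)
  out <- array(NA_real_, c(length(bands), length(connections), n_iterations),
               dimnames = list(names(bands), connections, NULL))
  hi_max <- max(vapply(bands, `[`, numeric(1), 2))
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- freq_hz >= lo - 1e-9 &
      (freq_hz < hi - 1e-9 | (hi == hi_max & freq_hz <= hi + 1e-9))
    if (!any(sel)) stop("band '", b, "' contains no frequencies")
    out[b, , ] <- apply(vals[, sel, , drop = FALSE], c(1, 3), mean)
  }
  structure(out, measure = measure, n_iterations = n_iterations,
            class = c("null_distribution", "array"))
}

#' Null distribution of group connectivity differences
#'
#' Pairs iteration `i` of every subject's trial-shuffled null and forms the
#' control-minus-patient group mean difference, yielding the permutation
#' null of the observed group difference (`n_connections x n_iterations`
#' values per band when pooled).
#'
#' @param ctrl_nulls,pat_nulls Lists of per-subject `null_distribution`s
#'   (same bands, connections, iteration count).
#' @param n_pairings Number of cyclic iteration pairings pooled (default 1).
#'   Iterations are exchangeable, so pairing control iteration `i` with
#'   patient iteration `i + k` (cyclically) for several offsets `k` yields a
#'   larger pool of valid null differences — the single-comparison analogue
#'   of pooling the per-connection null across several group comparisons, as
#'   the outside-null connection rule does in a multi-group cohort.
#' @return Array bands x connections x (iterations * n_pairings) of null
#'   differences.
#' @export
null_group_difference <- function(ctrl_nulls, pat_nulls, n_pairings = 1) {
  stopifnot(length(ctrl_nulls) > 0, length(pat_nulls) > 0, n_pairings >= 1)
  d <- dim(ctrl_nulls[[1]])
  mean_of <- function(lst) {
    acc <- array(0, d)
    for (x in lst) {
      stopifnot(identical(dim(x), d))
      acc <- acc + x
    }
    acc / length(lst)
  }
  cm <- mean_of(ctrl_nulls)
  pm <- mean_of(pat_nulls)
  n_iter <- d[3]
  offsets <- floor((seq_len(n_pairings) - 1) * n_iter / n_pairings)
  slices <- lapply(offsets, function(k) {
    idx <- ((seq_len(n_iter) - 1 + k) %% n_iter) + 1
    cm - pm[, , idx, drop = FALSE]
  })
  out <- array(unlist(slices), c(d[1], d[2], n_iter * n_pairings))
  dimnames(out) <- c(dimnames(ctrl_nulls[[1]])[1:2], list(NULL))
  structure(out, class = c("null_distribution", "array"))
}

# ---- group comparison -------------------------------------------------------

#' Compare group connectivity against a permutation null
#'
#' Per band, the observed control-minus-patient mean difference is formed for
#' every connection; the vector of differences is compared against the pooled
#' null-difference values with a two-sided Welch t test, and each connection
#' is flagged when its observed difference lies strictly outside the full
#' range of that connection's null values (with nulls pooled per connection,
#' this corresponds to a small permutation p after Bonferroni correction
#' across the frequency bands).
#'
#' @param ctrl_values,pat_values Arrays subjects x bands x connections of
#'   per-subject band-averaged connectivity (see [stack_connectivity()]).
#' @param null_diff Array bands x connections x iterations of null group
#'   differences ([null_group_difference()]).
#' @param per_connection_null Optional larger pool for the outside-null rule
#'   (e.g. concatenated across patient groups); default `null_diff`.
#' @param alpha Welch test level recorded in the result (default 0.05).
#' @return Object of class `group_connectivity_comparison`: `observed_diff`
#'   (bands x connections), `welch` (data.frame band, t, p), `flags` (bands x
#'   connections logical), `alpha`.
#' @export
group_comparison <- function(ctrl_values, pat_values, null_diff,
                             per_connection_null = NULL, alpha = 0.05) {
  if (is.null(per_connection_null)) per_connection_null <- null_diff
  if (length(null_diff) == 0) stop("null distribution is empty")
  bands <- dimnames(null_diff)[[1]]
  conns <- dimnames(null_diff)[[2]]
  if (!identical(dimnames(ctrl_values)[[3]], conns) ||
      !identical(dimnames(pat_values)[[3]], conns)) {
    stop("mismatched connection sets between groups and null")
  }
  obs <- apply(ctrl_values, c(2, 3), mean) - apply(pat_values, c(2, 3), mean)
  welch <- data.frame(band = bands, t = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  flags <- matrix(FALSE, length(bands), length(conns),
                  dimnames = list(bands, conns))
  for (bi in seq_along(bands)) {
    pool <- as.vector(null_diff[bi, , ])
    tt <- stats::t.test(obs[bi, ], pool)
    welch$t[bi] <- unname(tt$statistic)
    welch$p[bi] <- tt$p.value
    for (ci in seq_along(conns)) {
      rng <- range(per_connection_null[bi, ci, ])
      flags[bi, ci] <- obs[bi, ci] < rng[1] | obs[bi, ci] > rng[2]
    }
  }
  structure(list(observed_diff = obs, welch = welch, flags = flags,
                 alpha = alpha),
            class = "group_connectivity_comparison")
}

#' Stack per-subject connectivity results
#'
#' @param results List of `connectivity_result` matrices (bands x
#'   connections).
#' @return Array subjects x bands x connections.
#' @export
stack_connectivity <- function(results) {
  d <- dim(results[[1]])
  arr <- array(NA_real_, c(length(results), d),
               dimnames = c(list(NULL), dimnames(results[[1]])))
  for (i in seq_along(results)) arr[i, , ] <- results[[i]]
  arr
}
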