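# Shared fixture builders. Everything is generated in code at test time.

# Epoch set of pure sinusoids with per-trial, per-source phases.
# phases: n_trials x n_sources matrix; freq in Hz.
sine_epochs <- function(phases, freq = 10, fs = 250,
                        t_axis = seq(-0.1, 0.5, by = 1 / fs),
                        noise_sd = 0, labels = NULL, amplitude = 1) {
  n_trials <- nrow(phases); n_src <- ncol(phases)
  labels <- labels %||% paste0("S", seq_len(n_src))
  dat <- array(stats::rnorm(n_trials * n_src * length(t_axis), sd = noise_sd),
               c(n_trials, n_src, length(t_axis)))
  for (s in seq_len(n_src)) {
    dat[, s, ] <- dat[, s, ] +
      amplitude * sin(outer(phases[, s], 2 * pi * freq * t_axis, "+"))
  }
  epoch_set(dat, rep("standard", n_trials), t_axis, fs, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phase matrix for a coupled chain S1 -> S2 -> ... with given edge PLVs.
chain_phases <- function(n_trials, edge_plv, lag = pi / 2) {
  n_src <- length(edge_plv) + 1
  phi <- matrix(NA_real_, n_trials, n_src)
  phi[, 1] <- stats::runif(n_trials, -pi, pi)
  for (e in seq_along(edge_plv)) {
    kappa <- plv_to_kappa(edge_plv[e])
    phi[, e + 1] <- phi[, e] + lag + rvonmises(n_trials, kappa)
  }
  phi
}

# Brute-force classical PLV between two coefficient vectors over rows.
oracle_plv <- function(z1, z2) {
  Mod(mean(exp(1i * (Arg(z1) - Arg(z2)))))
}

# Brute-force magnitude-squared -> |Im| coherence between two coefficient
# vectors over rows.
oracle_icoh <- function(z1, z2) {
  s12 <- mean(Conj(z1) * z2)
  abs(Im(s12 / sqrt(mean(Mod(z1)^2) * mean(Mod(z2)^2))))
}

# Small two-group simulation config with quiet defaults for fast tests.
small_config <- function(n_per_group = 4, n_trials = 8, seed = 1,
                         coupling_baseline = 0, coupling_delta = 0,
                         attenuation = c(controls = 0, patients = 0.5),
                         ...) {
  grp <- c(controls = n_per_group, patients = n_per_group)
  simulation_config(
    groups = grp,
    n_trials_per_condition = n_trials,
    mmn_attenuation = attenuation,
    coupling_table = default_coupling_table(names(grp),
                                            baseline = coupling_baseline,
                                            delta = coupling_delta),
    atrophy_foci = list(controls = list(),
                        patients = list(list(center = c(6, 23, 9),
                                             radius = 2.5, depth = 0.25))),
    seed = seed,
    ...
  )
}
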