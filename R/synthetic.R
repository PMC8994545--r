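# ---- von Mises phase jitter -------------------------------------------------

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler, vectorised over batches. Used by the
#' coupling generator to jitter oscillator phases; concentration 0 degrades
#' gracefully to the circular uniform.
#'
#' @param n Number of draws.
#' @param kappa Concentration (>= 0).
#' @param mu Mean direction in radians.
#' @return Numeric vector of angles.
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-6) return(mu + stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.6) + 8
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  mu + out[seq_len(n)]
}

#' Concentration giving a requested phase-locking value
#'
#' Inverts the von Mises mean resultant length `A(kappa) = I1(kappa)/I0(kappa)`
#' so that a coupled pair with this jitter concentration has expected PLV
#' equal to `plv`.
#'
#' @param plv Target phase-locking value in \[0, 1\].
#' @return Concentration `kappa` (0 for `plv = 0`).
#' @export
plv_to_kappa <- function(plv) {
  stopifnot(plv >= 0, plv <= 1)
  if (plv < 1e-6) return(0)
  if (plv > 0.9985) return(1 / (2 * (1 - plv)))  # large-kappa asymptote
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) A(k) - plv, c(1e-8, 400), tol = 1e-10)$root
}

# ---- configuration ----------------------------------------------------------

#' Default band-specific coupling table
#'
#' Baseline phase coupling on all 11 network connections in every band for
#' every group, plus group-specific increases emulating the study's
#' qualitative pattern: fronto-temporal degeneration (bvFTD, nfvPPA) raises
#' theta-band coupling on the MD-auditory connections (STG-IPC and STG-IFG,
#' each side), while Alzheimer-pathology groups (PCA, ADMCI) raise high-gamma
#' coupling on the same connections.
#'
#' @param groups Character vector of group labels (first label = controls).
#' @param baseline Baseline coupling strength (default 0.3).
#' @param delta Group-specific coupling increase (default 0.25).
#' @return data.frame with columns `connection`, `band`, `group`, `strength`.
#' @export
default_coupling_table <- function(groups, baseline = 0.3, delta = 0.25) {
  tab <- expand.grid(connection = CONNECTIONS_11, band = names(DEFAULT_BANDS),
                     group = groups, stringsAsFactors = FALSE)
  attr(tab, "out.attrs") <- NULL
  tab$strength <- baseline
  md_aud <- c("STG_L-IPC_L", "STG_R-IPC_R", "STG_L-IFG_L", "STG_R-IFG_R")
  low_groups <- intersect(c("bvFTD", "nfvPPA"), groups)
  high_groups <- intersect(c("PCA", "ADMCI"), groups)
  sel <- tab$connection %in% md_aud & tab$band == "theta" &
    tab$group %in% low_groups
  tab$strength[sel] <- tab$strength[sel] + delta
  sel <- tab$connection %in% md_aud & tab$band == "high_gamma" &
    tab$group %in% high_groups
  tab$strength[sel] <- tab$strength[sel] + delta
  tab
}

#' Default group-specific atrophy foci
#'
#' Focal volume-loss centres (voxel coordinates on the default 24 x 28 x 24
#' grid) placed at caricatured disease loci, all outside the generative MD
#' network cores: anterior temporal/frontal for bvFTD, left frontal for
#' nfvPPA, occipital for PCA, medial temporal for ADMCI.
#'
#' @return Named list; per group a list of foci, each
#'   `list(center, radius, depth)` (radius in voxels, depth = fractional
#'   volume loss at the centre).
#' @export
default_atrophy_foci <- function() {
  f <- function(center, radius = 2.5, depth = 0.25) {
    list(center = center, radius = radius, depth = depth)
  }
  list(
    controls = list(),
    bvFTD = list(f(c(6, 23, 9)), f(c(19, 23, 9))),
    nfvPPA = list(f(c(8, 22, 10))),
    PCA = list(f(c(10, 4, 12)), f(c(15, 4, 12))),
    ADMCI = list(f(c(10, 13, 7)), f(c(15, 13, 7)))
  )
}

#' Build a synthetic-cohort simulation configuration
#'
#' All defaults emulate the study conditions: five groups with the published
#' sample sizes and age distributions, 250-Hz source time series epoched
#' -100 to 500 ms, a control MMN of -1 arbitrary unit attenuated per group,
#' an M100 common to all trials, band-specific phase coupling at a 90-degree
#' lag, and gray-matter volume at multiple-demand (MD) voxels linked to each
#' subject's MMN deficit.
#'
#' @param groups Named integer vector: subjects per group (>= 2 each).
#' @param sample_rate_hz Sampling rate of the source time series.
#' @param n_trials_per_condition Trials per condition (standard + 5 deviant
#'   dimensions).
#' @param mmn_amp_control Signed MMN window-mean amplitude of controls
#'   (negative).
#' @param mmn_attenuation Named map group -> fractional MMN attenuation in
#'   \[0, 1\].
#' @param subject_amp_sd Between-subject SD of the true MMN amplitude.
#' @param m100_amp Peak amplitude of the M100 deflection (all trials).
#' @param coupling_table data.frame (`connection`, `band`, `group`,
#'   `strength` in \[0, 1\]).
#' @param coupling_lag_deg Phase lag of coupled pairs in degrees (default 90
#'   so that imaginary coherence sees the coupling).
#' @param osc_amp Amplitude of each band-limited oscillation.
#' @param band_freqs Named vector of oscillator centre frequencies (Hz).
#' @param noise_sd SD of additive white noise.
#' @param grid_shape,voxel_mm Voxel grid for the volume maps.
#' @param atrophy_foci Named list of group foci (see
#'   [default_atrophy_foci()]).
#' @param beta_struct Volume lost per unit of MMN-magnitude deficit at MD
#'   voxels.
#' @param network_overlap Thresholded Jaccard overlap between the generative
#'   MD map and the control network map.
#' @param age_mean,age_sd Named vectors of group age distributions (years).
#' @param tiv_mean,tiv_sd Total intracranial volume distribution (ml).
#' @param age_slope,tiv_slope Volume change per year of age / per ml of TIV.
#' @param voxel_noise_sd SD of voxelwise volume noise.
#' @param epoch_window_s Epoch window (seconds relative to tone onset).
#' @param seed Master seed; the whole cohort is a pure function of the
#'   configuration.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    groups = c(controls = 48, bvFTD = 23, nfvPPA = 10, PCA = 15, ADMCI = 27),
    sample_rate_hz = 250,
    n_trials_per_condition = 150,
    mmn_amp_control = -1.0,
    mmn_attenuation = c(controls = 0, bvFTD = 0.45, nfvPPA = 0.35,
                        PCA = 0.55, ADMCI = 0.5),
    subject_amp_sd = 0.15,
    m100_amp = 1.5,
    coupling_table = default_coupling_table(names(groups)),
    coupling_lag_deg = 90,
    osc_amp = 1.0,
    band_freqs = c(theta = 6, alpha = 12, beta = 25, low_gamma = 37,
                   high_gamma = 62),
    noise_sd = 1.0,
    grid_shape = c(24, 28, 24),
    voxel_mm = 4,
    atrophy_foci = default_atrophy_foci(),
    beta_struct = 0.08,
    network_overlap = 0.15,
    age_mean = c(controls = 63.6, bvFTD = 61.8, nfvPPA = 71.6, PCA = 62.5,
                 ADMCI = 73.4),
    age_sd = c(controls = 8.19, bvFTD = 5.45, nfvPPA = 9.11, PCA = 8.43,
               ADMCI = 8.68),
    tiv_mean = 1450, tiv_sd = 130,
    age_slope = -0.002, tiv_slope = 2e-4,
    voxel_noise_sd = 0.02,
    epoch_window_s = c(-0.1, 0.5),
    seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Errors before any generation when a field is out of range: fewer than two
#' subjects in a group, coupling strengths or attenuations outside \[0, 1\],
#' atrophy foci outside the grid, or missing attenuation entries.
#'
#' @param cfg A `simulation_config`.
#' @return `cfg`, invisibly.
#' @export
validate_simulation_config <- function(cfg) {
  if (is.null(names(cfg$groups)) || any(names(cfg$groups) == "")) {
    stop("groups must be a named vector")
  }
  if (any(cfg$groups < 2)) stop("every group needs at least 2 subjects")
  if (!all(names(cfg$groups) %in% names(cfg$mmn_attenuation))) {
    stop("mmn_attenuation must cover every group")
  }
  if (any(cfg$mmn_attenuation < 0 | cfg$mmn_attenuation > 1)) {
    stop("mmn_attenuation must lie in [0, 1]")
  }
  if (any(cfg$coupling_table$strength < 0 | cfg$coupling_table$strength > 1)) {
    stop("coupling strengths must lie in [0, 1]")
  }
  for (g in names(cfg$atrophy_foci)) {
    for (focus in cfg$atrophy_foci[[g]]) {
      if (any(focus$center < 1) || any(focus$center > cfg$grid_shape)) {
        stop("atrophy focus outside grid for group ", g)
      }
    }
  }
  if (cfg$sample_rate_hz <= 0 || cfg$n_trials_per_condition < 1) {
    stop("invalid sampling rate or trial count")
  }
  invisible(cfg)
}

# ---- time-series generation -------------------------------------------------

# Assign per-trial oscillator phases over the coupling graph. Edges are
# applied in table order; an edge whose endpoints are both already assigned
# contributes no additional constraint (the graph is treated as a spanning
# structure). Returns an n_trials x n_sources matrix.
.assign_phases <- function(n_trials, edges, strengths, lag_rad, n_sources) {
  phi <- matrix(NA_real_, n_trials, n_sources)
  if (length(strengths)) {
    # invert strength -> concentration once per unique strength
    uniq <- unique(strengths)
    kappa_tab <- vapply(uniq, plv_to_kappa, numeric(1))
    for (e in seq_along(strengths)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      kappa <- kappa_tab[match(strengths[e], uniq)]
      i_set <- !is.na(phi[1, i]); j_set <- !is.na(phi[1, j])
      if (!i_set && !j_set) {
        phi[, i] <- stats::runif(n_trials, -pi, pi)
        phi[, j] <- phi[, i] + lag_rad + rvonmises(n_trials, kappa)
      } else if (i_set && !j_set) {
        phi[, j] <- phi[, i] + lag_rad + rvonmises(n_trials, kappa)
      } else if (!i_set && j_set) {
        phi[, i] <- phi[, j] - lag_rad - rvonmises(n_trials, kappa)
      }
    }
  }
  for (s in seq_len(n_sources)) {
    if (is.na(phi[1, s])) phi[, s] <- stats::runif(n_trials, -pi, pi)
  }
  phi
}

# Simulate one subject's epoched source time series.
.simulate_subject_epochs <- function(cfg, group, amp_subject) {
  fs <- cfg$sample_rate_hz
  t_axis <- seq(cfg$epoch_window_s[1], cfg$epoch_window_s[2], by = 1 / fs)
  n_t <- length(t_axis)
  conditions <- c("standard", DEVIANT_DIMENSIONS)
  n_per <- cfg$n_trials_per_condition
  n_trials <- n_per * length(conditions)
  condition <- rep(conditions, each = n_per)
  n_src <- length(SOURCE_LABELS)

  data <- array(stats::rnorm(n_trials * n_src * n_t, sd = cfg$noise_sd),
                dim = c(n_trials, n_src, n_t))

  # evoked content: M100 on every trial, MMN deflection on deviant trials
  auditory_w <- c(A1_L = 1, A1_R = 1, STG_L = 0.8, STG_R = 0.8,
                  IFG_L = 0, IFG_R = 0, IPC_L = 0, IPC_R = 0)
  m100_shape <- exp(-(t_axis - 0.1)^2 / (2 * 0.02^2))
  in_win <- t_axis >= 0.1 & t_axis <= 0.2
  mmn_shape <- ifelse(in_win, sin(pi * (t_axis - 0.1) / 0.1), 0)
  mmn_shape <- mmn_shape / mean(mmn_shape[in_win])  # window mean = 1
  is_dev <- condition != "standard"
  for (s in which(auditory_w > 0)) {
    evoked_std <- cfg$m100_amp * auditory_w[s] * m100_shape
    evoked_dev <- evoked_std + amp_subject * auditory_w[s] * mmn_shape
    data[!is_dev, s, ] <- sweep(data[!is_dev, s, , drop = FALSE], 3,
                                evoked_std, "+")
    data[is_dev, s, ] <- sweep(data[is_dev, s, , drop = FALSE], 3,
                               evoked_dev, "+")
  }

  # induced content: band-limited oscillations with phase coupling
  lag_rad <- cfg$coupling_lag_deg * pi / 180
  for (b in names(cfg$band_freqs)) {
    rows <- cfg$coupling_table[cfg$coupling_table$band == b &
                                 cfg$coupling_table$group == group &
                                 cfg$coupling_table$strength > 0, ,
                               drop = FALSE]
    edges <- connection_index(rows$connection)
    phi <- .assign_phases(n_trials, edges, rows$strength, lag_rad, n_src)
    carrier <- 2 * pi * cfg$band_freqs[[b]] * t_axis
    for (s in seq_len(n_src)) {
      data[, s, ] <- data[, s, ] +
        cfg$osc_amp * sin(outer(phi[, s], carrier, "+"))
    }
  }

  epoch_set(data, condition, t_axis, fs, SOURCE_LABELS)
}

# ---- cohort -----------------------------------------------------------------

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates, deterministically from the configuration seed, a multi-group
#' cohort of source-level trial time series (group-attenuated MMN, common
#' M100, band-specific phase coupling, white noise), per-subject gray-matter
#' volume maps with group-specific focal atrophy and an MD-voxel volume
#' deficit proportional to each subject's MMN deficit, and the generative
#' ground truth needed to score recovery.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `mmn_cohort`: `subjects` (each with `id`, `group`,
#'   `age`, `tiv`, `mmn_amp_true`, `epochs`, `volume`) and `ground_truth`
#'   (`md_map`, `control_map`, `group_mmn_amplitude`, `coupling_table`,
#'   `subject_table`, `config`).
#' @export
simulate_cohort <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  maps <- make_network_maps(cfg$grid_shape, seed = cfg$seed,
                            overlap = cfg$network_overlap,
                            voxel_mm = cfg$voxel_mm)

  groups <- rep(names(cfg$groups), times = cfg$groups)
  n <- length(groups)
  group_amp <- cfg$mmn_amp_control *
    (1 - cfg$mmn_attenuation[names(cfg$groups)])
  ages <- tivs <- amps <- numeric(n)
  for (i in seq_len(n)) {
    g <- groups[i]
    am <- if (g %in% names(cfg$age_mean)) cfg$age_mean[[g]] else 70
    asd <- if (g %in% names(cfg$age_sd)) cfg$age_sd[[g]] else 8
    ages[i] <- stats::rnorm(1, am, asd)
    tivs[i] <- stats::rnorm(1, cfg$tiv_mean, cfg$tiv_sd)
    amps[i] <- group_amp[[g]] + stats::rnorm(1, 0, cfg$subject_amp_sd)
  }

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(cfg$seed + 7919L * i)
    subjects[[i]] <- list(
      id = sprintf("sub-%03d", i), group = groups[i],
      age = ages[i], tiv = tivs[i], mmn_amp_true = amps[i],
      epochs = .simulate_subject_epochs(cfg, groups[i], amps[i])
    )
  }

  subject_table <- data.frame(
    id = vapply(subjects, `[[`, character(1), "id"),
    group = groups, age = ages, tiv = tivs, mmn_amp_true = amps,
    stringsAsFactors = FALSE
  )
  ground_truth <- list(
    md_map = maps$MD, control_map = maps$control_network,
    group_mmn_amplitude = group_amp,
    coupling_table = cfg$coupling_table,
    subject_table = subject_table,
    config = cfg
  )
  volumes <- simulate_atrophy_maps(cfg, ground_truth, amps, ages, tivs, groups)
  for (i in seq_len(n)) subjects[[i]]$volume <- volumes[[i]]

  structure(list(subjects = subjects, ground_truth = ground_truth),
            class = "mmn_cohort")
}

#' Simulate per-subject gray-matter volume maps
#'
#' Volume = smooth unit baseline, minus the group's focal atrophy
#' (Gaussian-profiled volume loss around each focus), minus
#' `beta_struct` x (subject MMN-magnitude deficit) at voxels where the
#' generative MD probability exceeds 0.5, plus linear age and TIV effects and
#' voxelwise noise. Deterministic given the configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @param ground_truth Ground-truth list holding the generative `md_map` (as
#'   returned by [simulate_cohort()] or [make_network_maps()]).
#' @param mmn_amplitudes Per-subject signed MMN amplitudes.
#' @param ages,tivs,groups Per-subject covariates and group labels; default
#'   from `ground_truth$subject_table`.
#' @return List of `voxel_map`s (semantics `"volume"`), one per subject.
#' @export
simulate_atrophy_maps <- function(cfg, ground_truth, mmn_amplitudes,
                                  ages = ground_truth$subject_table$age,
                                  tivs = ground_truth$subject_table$tiv,
                                  groups = ground_truth$subject_table$group) {
  validate_simulation_config(cfg)
  n <- length(mmn_amplitudes)
  stopifnot(length(ages) == n, length(tivs) == n, length(groups) == n)
  mask <- .ellipsoid_mask(cfg$grid_shape)
  md_core <- ground_truth$md_map$grid > 0.5

  # group atrophy fields (deterministic, shared across the group)
  atrophy <- list()
  for (g in unique(groups)) {
    field <- array(0, cfg$grid_shape)
    for (focus in cfg$atrophy_foci[[g]]) {
      field <- field + focus$depth *
        exp(-.distance_sq(cfg$grid_shape, focus$center) /
              (2 * focus$radius^2))
    }
    atrophy[[g]] <- field
  }

  set.seed(cfg$seed + 104729L)
  # MMN-magnitude deficit relative to the configured control amplitude
  deficit <- mmn_amplitudes - cfg$mmn_amp_control
  out <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- array(1, cfg$grid_shape) - atrophy[[groups[i]]]
    vol[md_core] <- vol[md_core] - cfg$beta_struct * deficit[i]
    vol <- vol + cfg$age_slope * (ages[i] - 70) +
      cfg$tiv_slope * (tivs[i] - cfg$tiv_mean) +
      array(stats::rnorm(prod(cfg$grid_shape), sd = cfg$voxel_noise_sd),
            cfg$grid_shape)
    out[[i]] <- voxel_map(vol, mask, voxel_mm = cfg$voxel_mm,
                          semantics = "volume")
  }
  out
}

#' Generate synthetic probabilistic network maps
#'
#' Two smooth probability fields on a shared grid: a bilateral fronto-parietal
#' "MD" map (the generative map used by [simulate_atrophy_maps()]) and a
#' control network of the same shape translated posteriorly. The translation
#' distance is chosen by brute-force search so that the Jaccard overlap of the
#' supports thresholded at `prob_threshold` matches `overlap` (1 = identical
#' maps, 0 = disjoint supports).
#'
#' @param grid_shape Integer vector of length 3.
#' @param seed Unused by the deterministic construction; kept for interface
#'   stability.
#' @param overlap Requested thresholded Jaccard overlap in \[0, 1\].
#' @param voxel_mm Voxel size.
#' @param prob_threshold Probability threshold defining the supports.
#' @param sigma Bump width in voxels.
#' @param peak Peak probability.
#' @return List `MD`, `control_network` of `voxel_map`s (semantics
#'   `"probability"`).
#' @export
make_network_maps <- function(grid_shape = c(24, 28, 24), seed = 1,
                              overlap = 0.15, voxel_mm = 4,
                              prob_threshold = 0.05, sigma = 2.2,
                              peak = 0.9) {
  stopifnot(overlap >= 0, overlap <= 1)
  centers <- rbind(c(7, 16, 16), c(grid_shape[1] - 6, 16, 16))
  md <- pmin(.gaussian_bumps(grid_shape, centers, sigma, peak), 1)
  md_support <- md > prob_threshold

  field_at <- function(d) {
    sh <- centers; sh[, 2] <- sh[, 2] - d
    pmin(.gaussian_bumps(grid_shape, sh, sigma, peak), 1)
  }
  if (overlap >= 1) {
    d_star <- 0
  } else {
    jaccard <- function(d) {
      sup <- field_at(d) > prob_threshold
      inter <- sum(sup & md_support)
      inter / (sum(sup) + sum(md_support) - inter)
    }
    cand <- seq(0, 14, by = 0.05)
    js <- vapply(cand, jaccard, numeric(1))
    if (overlap == 0) {
      d_star <- cand[which(js == 0)[1]]
    } else {
      d_star <- cand[which.min(abs(js - overlap))]
    }
  }
  ctrl <- field_at(d_star)
  list(
    MD = voxel_map(md, voxel_mm = voxel_mm, semantics = "probability"),
    control_network = voxel_map(ctrl, voxel_mm = voxel_mm,
                                semantics = "probability")
  )
}
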