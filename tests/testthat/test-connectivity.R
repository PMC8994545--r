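test_that("taper count follows K = 2TW - 1 and tapers are orthonormal", {
  ep <- sine_epochs(matrix(0, 12, 2))
  s500 <- multitaper_spectra(ep, c(0, 0.5), 4)
  expect_equal(s500$n_tapers, 3L)  # 0.5 s x 4 Hz -> K = 3
  s250 <- multitaper_spectra(ep, c(0, 0.25), 4)
  expect_equal(s250$n_tapers, 1L)

  tp <- dpss_tapers(125, 2, 3)
  expect_equal(crossprod(tp), diag(3), tolerance = 1e-10)
  expect_error(multitaper_spectra(ep, c(0, 0.1), 4), "at least 1")
})

test_that("a 20-Hz sine concentrates its spectral mass within the smoothing box", {
  set.seed(5)
  ph <- matrix(runif(30, -pi, pi), 30, 1)
  ep <- sine_epochs(ph, freq = 20, noise_sd = 0.01)
  spec <- multitaper_spectra(ep)
  pw <- apply(Mod(spec$coef)^2, 3, mean)
  inside <- spec$freq_hz >= 16 & spec$freq_hz <= 24
  expect_gt(sum(pw[inside]) / sum(pw), 0.95)
})

test_that("white noise has a flat multitaper spectrum", {
  set.seed(6)
  dat <- array(rnorm(100 * 1 * 151), c(100, 1, 151))
  ep <- epoch_set(dat, rep("standard", 100), seq(-0.1, 0.5, by = 1 / 250),
                  250, "S1")
  spec <- multitaper_spectra(ep)
  pw <- apply(Mod(spec$coef)^2, 3, mean)
  fit <- stats::lm(log(pw) ~ spec$freq_hz)
  # slope of log-power vs frequency indistinguishable from zero
  expect_lt(abs(unname(stats::coef(fit)[2])), 2e-3)
})

test_that("evoked subtraction zeroes the per-condition trial mean exactly", {
  set.seed(7)
  dat <- array(rnorm(20 * 2 * 50), c(20, 2, 50))
  cond <- rep(c("standard", "duration"), each = 10)
  ep <- epoch_set(dat, cond, seq_len(50) / 100, 100, c("S1", "S2"))
  ind <- subtract_evoked(ep)
  for (cd in c("standard", "duration")) {
    m <- apply(ind$data[cond == cd, , , drop = FALSE], c(2, 3), mean)
    expect_lt(max(abs(m)), 1e-12)
  }
  # identical trials (pure evoked) -> all zero
  pure <- epoch_set(array(rep(rnorm(50), each = 5), c(5, 1, 50)),
                    rep("standard", 5), seq_len(50) / 100, 100, "S1")
  expect_true(all(subtract_evoked(pure)$data == 0))
  # single-trial condition zeroed with a message
  one <- epoch_set(dat[1:3, , , drop = FALSE], c("standard", "standard", "gap"),
                   seq_len(50) / 100, 100, c("S1", "S2"))
  expect_message(z <- subtract_evoked(one), "single-trial")
  expect_true(all(z$data[3, , ] == 0))
})

test_that("induced power is preserved when the evoked component is removed", {
  set.seed(8)
  fs <- 250
  t_axis <- seq(-0.1, 0.5, by = 1 / fs)
  n_tr <- 40
  evoked <- 2 * exp(-(t_axis - 0.15)^2 / (2 * 0.03^2))
  ph <- runif(n_tr, -pi, pi)
  osc <- sin(outer(ph, 2 * pi * 15 * t_axis, "+"))
  both <- array(0, c(n_tr, 1, length(t_axis)))
  only_osc <- array(0, c(n_tr, 1, length(t_axis)))
  for (i in seq_len(n_tr)) {
    both[i, 1, ] <- evoked + osc[i, ]
    only_osc[i, 1, ] <- osc[i, ]
  }
  ep_both <- epoch_set(both, rep("standard", n_tr), t_axis, fs, "S1")
  ep_osc <- epoch_set(only_osc, rep("standard", n_tr), t_axis, fs, "S1")
  p_sub <- apply(Mod(multitaper_spectra(subtract_evoked(ep_both))$coef)^2, 3, mean)
  p_osc <- apply(Mod(multitaper_spectra(subtract_evoked(ep_osc))$coef)^2, 3, mean)
  expect_equal(sum(p_sub), sum(p_osc), tolerance = 0.05)
})

test_that("with two sources, partial PLV reduces to the classical PLV", {
  set.seed(9)
  phases <- cbind(runif(50, -pi, pi), 0)
  phases[, 2] <- phases[, 1] + pi / 2 + rvonmises(50, plv_to_kappa(0.7))
  ep <- sine_epochs(phases, freq = 10, noise_sd = 0.05)
  spec <- multitaper_spectra(ep)
  pc <- partial_connectivity(spec, "partial_plv")
  # independent brute-force loop over rows at every frequency
  for (f in seq(1, length(spec$freq_hz), by = 7)) {
    expect_equal(unname(pc$values["S1-S2", f]),
                 oracle_plv(spec$coef[, 1, f], spec$coef[, 2, f]),
                 tolerance = 1e-6)  # exact up to the 1e-8 ridge
  }
})

test_that("a perfectly locked pair gives partial PLV of 1", {
  # coefficients constructed directly: constant phase difference, no noise
  set.seed(10)
  n_rows <- 60
  z1 <- exp(1i * runif(n_rows, -pi, pi))
  z2 <- z1 * exp(1i * pi / 3)
  coef <- array(complex(real = 0), c(n_rows, 2, 3))
  for (f in 1:3) { coef[, 1, f] <- z1; coef[, 2, f] <- z2 }
  spec <- structure(list(coef = coef, freq_hz = c(6, 10, 14), n_trials = n_rows,
                         n_tapers = 1L, half_bandwidth_hz = 4,
                         window_s = c(0, 0.5), source_labels = c("S1", "S2"),
                         condition = rep("standard", n_rows)),
                    class = "spectral_decomposition")
  pc <- partial_connectivity(spec, "partial_plv")
  expect_equal(max(pc$values), 1, tolerance = 1e-6)
  expect_equal(min(pc$values), 1, tolerance = 1e-6)
})

test_that("zero-lag coupling is invisible to partial imaginary coherence", {
  rejected <- 0
  for (seed in 1:10) {
    set.seed(seed)
    phases <- cbind(runif(40, -pi, pi), 0)
    phases[, 2] <- phases[, 1] + rvonmises(40, plv_to_kappa(0.9))  # 0 deg lag
    ep <- sine_epochs(phases, freq = 10, noise_sd = 0.2)
    spec <- multitaper_spectra(ep)
    obs <- band_average(partial_connectivity(spec, "partial_icoh"))
    null <- trial_shuffle_null(spec, 50, seed = seed * 31,
                               measure = "partial_icoh",
                               connections = "S1-S2")
    q95 <- stats::quantile(null["alpha", 1, ], 0.95)
    if (obs["alpha", "S1-S2"] > q95) rejected <- rejected + 1
  }
  expect_lte(rejected, 3)  # at most chance-level detections
})

test_that("both measures are invariant to per-source amplitude rescaling", {
  set.seed(12)
  phases <- matrix(runif(40 * 3, -pi, pi), 40, 3)
  phases[, 2] <- phases[, 1] + pi / 2 + rvonmises(40, plv_to_kappa(0.6))
  ep <- sine_epochs(phases, freq = 12, noise_sd = 0.1)
  ep10 <- ep
  ep10$data[, 2, ] <- 10 * ep10$data[, 2, ]
  for (m in c("partial_plv", "partial_icoh")) {
    a <- partial_connectivity(multitaper_spectra(ep), m)
    b <- partial_connectivity(multitaper_spectra(ep10), m)
    expect_equal(a$values, b$values, tolerance = 1e-5)  # ridge rescales too
  }
})

test_that("partial measures lie in [0, 1] for arbitrary inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    dat <- array(rnorm(30 * 4 * 151, sd = runif(1, 0.1, 10)), c(30, 4, 151))
    ep <- epoch_set(dat, rep("standard", 30), seq(-0.1, 0.5, 1 / 250), 250,
                    paste0("S", 1:4))
    spec <- multitaper_spectra(ep)
    for (m in c("partial_plv", "partial_icoh")) {
      v <- partial_connectivity(spec, m)$values
      expect_true(all(v >= 0 & v <= 1))
    }
  }
})

test_that("band averaging uses exactly the in-band grid points", {
  vals <- matrix(0, 1, 34, dimnames = list("S1-S2", NULL))
  freq <- seq(4, 70, by = 2)
  vals[1, freq == 6] <- 1
  ba <- band_average(vals, freq_hz = freq)
  # theta covers {4, 6} on this grid: brute-force index check
  expect_equal(unname(ba["theta", 1]), mean(c(0, 1)))
  expect_equal(unname(ba["alpha", 1]), 0)
  # constant value -> every band equals it
  ba2 <- band_average(matrix(0.7, 1, 34, dimnames = list("S1-S2", NULL)),
                      freq_hz = freq)
  expect_true(all(ba2 == 0.7))
  # the top band is closed at its upper edge
  vals70 <- matrix(0, 1, 34, dimnames = list("S1-S2", NULL))
  vals70[1, freq == 70] <- 1
  expect_gt(band_average(vals70, freq_hz = freq)["high_gamma", 1], 0)
  # a band with no frequencies errors by name
  expect_error(band_average(vals, bands = list(theta = c(4, 8),
                                               subhz = c(0.1, 0.5)),
                            freq_hz = freq), "subhz")
})

test_that("the shuffle null has the stated structure and is reproducible", {
  set.seed(13)
  dat <- array(rnorm(20 * 8 * 151), c(20, 8, 151))
  ep <- epoch_set(dat, rep("standard", 20), seq(-0.1, 0.5, 1 / 250), 250,
                  SOURCE_LABELS)
  spec <- multitaper_spectra(ep)
  nd <- trial_shuffle_null(spec, 25, seed = 99)
  expect_equal(dim(nd), c(5, 11, 25))
  expect_equal(length(as.vector(nd["theta", , ])), 11 * 25)
  nd2 <- trial_shuffle_null(spec, 25, seed = 99)
  expect_identical(unclass(nd), unclass(nd2))
  expect_error(trial_shuffle_null(spec, 0), "at least 1")
  short <- epoch_set(dat[1:5, , , drop = FALSE], rep("standard", 5),
                     seq(-0.1, 0.5, 1 / 250), 250, SOURCE_LABELS)
  expect_error(trial_shuffle_null(short, 10), "at least 10 trials")
})

test_that("trial shuffling preserves per-source marginal spectra exactly", {
  set.seed(14)
  dat <- array(rnorm(15 * 3 * 151), c(15, 3, 151))
  ep <- epoch_set(dat, rep("standard", 15), seq(-0.1, 0.5, 1 / 250), 250,
                  paste0("S", 1:3))
  spec <- multitaper_spectra(ep)
  # apply the shuffle convention by hand and compare coefficient multisets
  K <- spec$n_tapers
  perm <- sample.int(15)
  rows <- rep((perm - 1L) * K, each = K) + rep(seq_len(K), 15)
  shuffled <- spec$coef[rows, 2, ]
  expect_equal(apply(Mod(shuffled)^2, 2, sum),
               apply(Mod(spec$coef[, 2, ])^2, 2, sum), tolerance = 1e-12)
})

test_that("group comparison flags follow the strict outside-range rule", {
  bands <- c("theta", "alpha")
  conns <- c("A-B", "C-D")
  null_diff <- array(0, c(2, 2, 50), dimnames = list(bands, conns, NULL))
  null_diff[] <- stats::runif(length(null_diff), -0.1, 0.1)
  mk <- function(vals) {
    arr <- array(vals, c(3, 2, 2), dimnames = list(NULL, bands, conns))
    arr
  }
  ctrl <- mk(0.5)
  pat <- mk(0.5)
  pat[, "theta", "A-B"] <- 0.2  # observed diff 0.3, far outside [-0.1, 0.1]
  cmp <- group_comparison(ctrl, pat, null_diff)
  expect_true(cmp$flags["theta", "A-B"])
  expect_false(cmp$flags["theta", "C-D"])
  expect_false(any(cmp$flags["alpha", ]))
  expect_equal(cmp$observed_diff["theta", "A-B"], 0.3, tolerance = 1e-12)

  bad <- ctrl
  dimnames(bad)[[3]] <- c("A-B", "X-Y")
  expect_error(group_comparison(bad, pat, null_diff), "mismatched")
  expect_error(group_comparison(ctrl, pat, array(numeric(0), c(2, 2, 0),
                                                 dimnames = list(bands, conns, NULL))),
               "empty")
})

test_that("null group differences pair iterations across subjects", {
  d <- c(2, 2, 4)
  dn <- list(c("theta", "alpha"), c("A-B", "C-D"), NULL)
  n1 <- array(1, d, dn); n2 <- array(3, d, dn)
  p1 <- array(2, d, dn)
  nd <- null_group_difference(list(n1, n2), list(p1))
  expect_true(all(nd == 0))  # (1+3)/2 - 2
  expect_equal(dim(nd), d)
})
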