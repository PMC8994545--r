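test_that("epoching yields 151-sample epochs and zero baselines", {
  fs <- 250
  set.seed(1)
  n_events <- 20
  # continuous recording long enough for 20 analysed events at 0.5-s SOA
  rec_len <- round((n_events * 0.5 + 2) * fs)
  rec <- list(data = matrix(rnorm(2 * rec_len), 2, rec_len), sfreq = fs)
  events <- data.frame(
    onset = 0.5 + (seq_len(n_events) - 1) * 0.5,
    tone_type = rep(c("standard", "duration"), n_events / 2),
    analyzed = TRUE
  )
  ep <- epoch_and_baseline(rec, events)
  expect_equal(dim(ep$data), c(n_events, 2, 151))  # -100..500 ms at 4-ms steps
  expect_equal(range(ep$time), c(-0.1, 0.5))
  # baseline window mean is zero per epoch and source
  bl <- which(ep$time >= -0.1 & ep$time < 0)
  expect_lt(max(abs(apply(ep$data[, , bl], c(1, 2), mean))), 1e-12)
})

test_that("constant input epochs are identically zero after baseline subtraction", {
  fs <- 250
  rec <- list(data = matrix(7.3, 1, 5 * fs), sfreq = fs)
  events <- data.frame(onset = c(1, 2, 3), tone_type = "standard",
                       analyzed = TRUE)
  ep <- epoch_and_baseline(rec, events)
  expect_true(all(ep$data == 0))
})

test_that("events too close to the recording edge are dropped and counted", {
  fs <- 250
  rec <- list(data = matrix(rnorm(2 * fs), 1, 2 * fs), sfreq = fs)
  events <- data.frame(onset = c(0.05, 1.0, 1.9), tone_type = "standard",
                       analyzed = TRUE)
  expect_message(ep <- epoch_and_baseline(rec, events), "dropped")
  expect_equal(dim(ep$data)[1], 1)  # only the middle event fits
  expect_equal(attr(ep, "n_dropped"), 2)
})

test_that("only analysed events are epoched", {
  fs <- 250
  rec <- list(data = matrix(rnorm(3 * fs), 1, 3 * fs), sfreq = fs)
  events <- data.frame(onset = c(0.5, 1.0, 1.5, 2.0),
                       tone_type = "standard",
                       analyzed = c(FALSE, TRUE, TRUE, FALSE))
  ep <- epoch_and_baseline(rec, events)
  expect_equal(dim(ep$data)[1], 2)
})

test_that("the zero-phase filter meets its passband and stopband contract", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  s50 <- sin(2 * pi * 50 * t)
  y50 <- zero_phase_filter(s50, fs)
  core <- seq(round(0.5 * fs), round(1.5 * fs))  # avoid edge transients
  atten_db <- 10 * log10(mean(y50[core]^2) / mean(s50[core]^2))
  expect_lt(atten_db, -40)

  s10 <- sin(2 * pi * 10 * t)
  y10 <- zero_phase_filter(s10, fs)
  expect_equal(sqrt(mean(y10[core]^2)) / sqrt(mean(s10[core]^2)), 1,
               tolerance = 0.01)
  # zero group delay: cross-correlation of filtered vs raw peaks at lag 0
  cc <- stats::ccf(y10[core], s10[core], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_true(all(zero_phase_filter(numeric(100), fs) == 0))
  expect_error(zero_phase_filter(s10, fs, low_pass_hz = 300), "Nyquist")
})

test_that("filter_epochs requires headroom above the cutoff", {
  ep <- sine_epochs(matrix(0, 3, 1), fs = 100,
                    t_axis = seq(-0.1, 0.5, by = 0.01))
  expect_error(filter_epochs(ep), "200 Hz")
})

test_that("robust averaging equals the mean for identical trials, with unit weights", {
  shape <- sin(seq(0, 2 * pi, length.out = 40))
  dat <- array(rep(shape, each = 6), c(6, 1, 40))
  ep <- epoch_set(dat, rep("standard", 6), seq(0, 0.39, 0.01) - 0.1, 100, "S1")
  ev <- robust_average(ep)
  expect_equal(as.vector(ev$waveforms["standard", 1, ]), shape)
  expect_true(all(ev$weights$standard == 1))
})

test_that("robust averaging of two opposite trials is zero by symmetry", {
  v <- rnorm(30)
  dat <- array(c(v, -v), c(2, 1, 30))  # trial-major filling: +v then -v
  dat[1, 1, ] <- v; dat[2, 1, ] <- -v
  ep <- epoch_set(dat, rep("standard", 2), seq_len(30) / 100, 100, "S1")
  ev <- robust_average(ep)
  expect_equal(as.vector(ev$waveforms["standard", 1, ]), rep(0, 30))
})

test_that("robust averaging rejects a gross artifact trial", {
  set.seed(42)
  noise_sd <- 0.1
  shape <- sin(seq(0, 2 * pi, length.out = 50))
  dat <- array(0, c(50, 1, 50))
  for (i in 1:49) dat[i, 1, ] <- shape + rnorm(50, sd = noise_sd)
  dat[50, 1, ] <- 100 * (shape + rnorm(50, sd = noise_sd))
  ep <- epoch_set(dat, rep("standard", 50), seq_len(50) / 100, 100, "S1")
  ev <- robust_average(ep)
  clean_mean <- colMeans(matrix(dat[1:49, 1, ], 49))
  sem <- noise_sd / sqrt(49)
  expect_lt(max(abs(as.vector(ev$waveforms["standard", 1, ]) - clean_mean)),
            2 * noise_sd)
  # the arithmetic mean is badly contaminated by comparison
  contaminated <- colMeans(matrix(dat[, 1, ], 50))
  expect_gt(max(abs(contaminated - clean_mean)), 10 * noise_sd)
  expect_true(all(ev$weights$standard >= 0 & ev$weights$standard <= 1))
  # the artifact trial is strongly down-weighted
  expect_lt(mean(ev$weights$standard[50, 1, ]), 0.1)
})

test_that("compute_mmn recovers analytic amplitudes", {
  n_t <- 151
  time <- seq(-0.1, 0.5, length.out = n_t)
  waves <- array(0, c(2, 1, n_t), dimnames = list(c("standard", "duration"),
                                                  "A1_L", NULL))
  ev <- structure(list(waveforms = waves, conditions = c("standard", "duration"),
                       time = time, sfreq = 250, source_labels = "A1_L"),
                  class = "evoked_set")
  # identical averages -> exactly zero
  r0 <- compute_mmn(ev)
  expect_identical(r0$mmn_amplitude, 0)

  # rectangular -1 deflection over exactly 100-200 ms -> amplitude -1
  ev$waveforms["duration", 1, time >= 0.1 & time <= 0.2] <- -1
  r1 <- compute_mmn(ev)
  expect_equal(r1$mmn_amplitude, -1)
  expect_equal(unname(r1$per_dimension["duration"]), -1)

  # stored amplitude is recomputable from the stored waveform and window
  idx <- which(time >= r1$mmn_window_s[1] & time <= r1$mmn_window_s[2])
  expect_equal(mean(r1$mmn_waveform["A1_L", idx]), r1$mmn_amplitude)

  # M100: peak magnitude of the standard response in 50-150 ms
  ev$waveforms["standard", 1, ] <- 1.5 * exp(-(time - 0.1)^2 / (2 * 0.02^2))
  r2 <- compute_mmn(ev)
  expect_equal(r2$m100_amplitude, 1.5, tolerance = 1e-6)

  ev$conditions <- "duration"
  expect_error(compute_mmn(ev), "standard")
})

test_that("MMN amplitude is invariant to per-trial constant offsets", {
  set.seed(3)
  fs <- 250
  t_axis <- seq(-0.1, 0.5, by = 1 / fs)
  dat <- array(rnorm(20 * 1 * length(t_axis)), c(20, 1, length(t_axis)))
  cond <- rep(c("standard", "duration"), 10)
  ep <- epoch_set(dat, cond, t_axis, fs, "A1_L")
  ep1 <- epoch_and_baseline(ep)
  r1 <- compute_mmn(robust_average(ep1))

  offs <- rnorm(20, sd = 5)
  dat2 <- dat + rep(offs, times = length(t_axis))
  ep2 <- epoch_and_baseline(epoch_set(dat2, cond, t_axis, fs, "A1_L"))
  r2 <- compute_mmn(robust_average(ep2))
  expect_equal(r2$mmn_amplitude, r1$mmn_amplitude, tolerance = 1e-9)
})

test_that("group statistics detect a planted group effect and reject degenerate input", {
  set.seed(11)
  make_result <- function(amp) {
    n_t <- 151
    time <- seq(-0.1, 0.5, length.out = n_t)
    w <- matrix(rnorm(n_t, sd = 0.05), 1, n_t)
    w[1, time >= 0.1 & time <= 0.2] <- w[1, time >= 0.1 & time <= 0.2] + amp
    structure(list(mmn_waveform = `rownames<-`(w, "A1_L"),
                   mmn_amplitude = amp + rnorm(1, sd = 0.05),
                   m100_amplitude = 1.5, roi = "A1_L",
                   source_labels = "A1_L", time = time),
              class = "mmn_result")
  }
  results <- c(lapply(rep(-1, 10), make_result),
               lapply(rep(-0.4, 10), make_result))
  groups <- rep(c("controls", "patients"), each = 10)
  gs <- group_evoked_stats(results, groups)
  expect_lt(gs$anova$p, 0.001)
  expect_equal(unname(gs$group_means["controls"]), -1, tolerance = 0.1)
  # FDR mask marks timepoints, and is monotone in the raw p-values
  tp <- gs$timepoint$patients
  expect_true(any(tp$mask))
  expect_true(all(tp$p_fdr >= tp$p - 1e-12))
  thr <- max(tp$p[tp$mask], -Inf)
  expect_true(all(tp$p[!tp$mask] >= thr))

  expect_error(group_evoked_stats(results[1:2], c("a", "b")), "2 subjects")
  const <- results
  for (i in 1:10) const[[i]]$mmn_amplitude <- -1
  expect_error(group_evoked_stats(const, groups, amplitudes = NULL), "variance")
})
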