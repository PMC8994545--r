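#' The five deviant dimensions of the Optimum-1 multi-deviant oddball design
#' @format Character vector of length 5.
#' @export
DEVIANT_DIMENSIONS <- c("duration", "intensity", "frequency", "laterality", "gap")

#' All tone types
#'
#' The standard plus the concrete deviant variants; each deviant differs from
#' the standard in exactly one acoustic dimension.
#' @format Character vector of length 9.
#' @export
TONE_TYPES <- c(
  "standard", "duration", "intensity_up", "intensity_down",
  "frequency_up", "frequency_down", "laterality_left", "laterality_right",
  "gap"
)

#' Acoustic specification of a tone
#'
#' Returns the full acoustic parameter set for one tone type of the Optimum-1
#' multi-deviant oddball paradigm. The standard is a 75-ms complex tone with
#' harmonics at 500, 1000 and 1500 Hz, 7-ms cosine on/off ramps, presented
#' binaurally. Each deviant alters exactly one dimension: duration (shortened
#' to 25 ms), intensity (+/- 6 dB), frequency (all harmonics scaled by
#' +/- 10 percent, i.e. fundamentals 550 or 450 Hz), laterality (monaural
#' left or right), or continuity (a 25-ms silent gap centred at the tone
#' midpoint).
#'
#' @param tone_type One of `"standard"`, `"duration"`, `"intensity_up"`,
#'   `"intensity_down"`, `"frequency_up"`, `"frequency_down"`,
#'   `"laterality_left"`, `"laterality_right"`, `"gap"`.
#' @return A list of class `tone_spec` with fields `tone_type`, `dimension`,
#'   `duration_ms`, `level_db_offset`, `fundamentals_hz`, `channel_routing`,
#'   `gap_ms`, `ramp_ms`.
#' @export
#' @examples
#' tone_spec("frequency_up")$fundamentals_hz  # 550 1100 1650
tone_spec <- function(tone_type) {
  tone_type <- match.arg(tone_type, TONE_TYPES)
  base <- list(
    tone_type = tone_type,
    dimension = tone_dimension(tone_type),
    duration_ms = 75,
    level_db_offset = 0,
    fundamentals_hz = c(500, 1000, 1500),
    channel_routing = "binaural",
    gap_ms = 0,
    ramp_ms = 7
  )
  switch(tone_type,
    standard = base,
    duration = { base$duration_ms <- 25; base },
    intensity_up = { base$level_db_offset <- 6; base },
    intensity_down = { base$level_db_offset <- -6; base },
    frequency_up = { base$fundamentals_hz <- base$fundamentals_hz * 1.1; base },
    frequency_down = { base$fundamentals_hz <- base$fundamentals_hz * 0.9; base },
    laterality_left = { base$channel_routing <- "left"; base },
    laterality_right = { base$channel_routing <- "right"; base },
    gap = { base$gap_ms <- 25; base }
  ) -> spec
  class(spec) <- "tone_spec"
  spec
}

#' Deviant dimension of a tone type
#'
#' Maps a tone type to its deviant dimension (`"standard"` for the standard).
#'
#' @param tone_type Character vector of tone types.
#' @return Character vector of dimensions.
#' @export
tone_dimension <- function(tone_type) {
  map <- c(
    standard = "standard", duration = "duration",
    intensity_up = "intensity", intensity_down = "intensity",
    frequency_up = "frequency", frequency_down = "frequency",
    laterality_left = "laterality", laterality_right = "laterality",
    gap = "gap"
  )
  unname(map[tone_type])
}

#' Generate an Optimum-1 oddball stimulus sequence
#'
#' Builds a pseudo-random multi-deviant sequence in which standards and
#' deviants strictly alternate after the block-initial standards. Deviant
#' dimensions are drawn in non-overlapping blocks of five, each a uniform
#' random permutation of the five dimensions, redrawn when its first element
#' repeats the previous block's last element, so that no two consecutive
#' deviants share a dimension and every run of five deviants covers all five
#' dimensions. Within a dimension with two variants (intensity, frequency,
#' laterality) the variant is drawn uniformly. Each block opens with fifteen
#' standards flagged `analyzed = FALSE`; with the defaults (3 blocks of 300
#' standard-deviant pairs) the analysed set contains 900 standards, 900
#' deviants and 180 deviants per dimension.
#'
#' @param n_blocks Number of blocks (default 3).
#' @param pairs_per_block Standard-deviant pairs per block; must be divisible
#'   by 5 (default 300).
#' @param seed Integer seed; generation is a pure function of
#'   `(n_blocks, pairs_per_block, seed)`.
#' @param soa_s Stimulus onset asynchrony in seconds (default 0.5).
#' @param n_initial_standards Block-initial standards excluded from analysis
#'   (default 15).
#' @param max_redraws Bound on rejection-sampling redraws per block-of-five
#'   before an error is raised (default 1000).
#' @return A `stimulus_sequence`: list with `events` (data.frame with columns
#'   `onset`, `duration`, `tone_type`, `dimension`, `block`, `analyzed`),
#'   `soa_s`, `n_blocks`.
#' @export
generate_sequence <- function(n_blocks = 3, pairs_per_block = 300, seed = 1,
                              soa_s = 0.5, n_initial_standards = 15,
                              max_redraws = 1000) {
  stopifnot(n_blocks >= 1, pairs_per_block >= 5)
  if (pairs_per_block %% 5 != 0) {
    stop("pairs_per_block must be divisible by 5 (blocks-of-five coverage constraint)")
  }
  events <- vector("list", n_blocks)
  block_len <- n_initial_standards + 2 * pairs_per_block
  prev_last_dim <- NA_character_
  for (b in seq_len(n_blocks)) {
    # deterministic per-block RNG stream derived from the master seed
    set.seed(seed * 1000L + b)
    dims <- character(0)
    for (g in seq_len(pairs_per_block / 5)) {
      prev <- if (length(dims)) dims[length(dims)] else prev_last_dim
      ok <- FALSE
      for (try in seq_len(max_redraws)) {
        perm <- sample(DEVIANT_DIMENSIONS)
        if (is.na(prev) || perm[1] != prev) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("sequence generation failed: could not satisfy the ",
             "'no consecutive same-dimension deviants' constraint after ",
             max_redraws, " redraws in block ", b)
      }
      dims <- c(dims, perm)
    }
    prev_last_dim <- dims[length(dims)]
    # draw the concrete variant within two-variant dimensions
    types <- vapply(dims, function(d) {
      switch(d,
        duration = "duration",
        gap = "gap",
        intensity = sample(c("intensity_up", "intensity_down"), 1),
        frequency = sample(c("frequency_up", "frequency_down"), 1),
        laterality = sample(c("laterality_left", "laterality_right"), 1)
      )
    }, character(1))
    tone_type <- c(
      rep("standard", n_initial_standards),
      as.vector(rbind(rep("standard", pairs_per_block), types))
    )
    onset <- ((b - 1) * block_len + seq_len(block_len) - 1) * soa_s
    analyzed <- c(rep(FALSE, n_initial_standards),
                  rep(TRUE, 2 * pairs_per_block))
    events[[b]] <- data.frame(
      onset = onset,
      duration = vapply(tone_type, function(tt) tone_spec(tt)$duration_ms, numeric(1)) / 1000,
      tone_type = tone_type,
      dimension = tone_dimension(tone_type),
      block = b,
      analyzed = analyzed,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  out <- list(events = do.call(rbind, events), soa_s = soa_s, n_blocks = n_blocks)
  class(out) <- "stimulus_sequence"
  out
}

#' Validate an oddball stimulus sequence
#'
#' Report-only check of every structural invariant of the Optimum-1 design:
#' onset spacing, standard/deviant alternation, absence of consecutive
#' same-dimension deviants, coverage of all five dimensions in every
#' non-overlapping block of five deviants, equal per-dimension counts within
#' each block, and exclusion of block-initial standards from analysis.
#'
#' @param seq A `stimulus_sequence`.
#' @param n_initial_standards Expected number of excluded standards per block.
#' @return data.frame with columns `constraint`, `pass`,
#'   `first_violation_index` (NA when passing; event-row index otherwise).
#' @export
validate_sequence <- function(seq, n_initial_standards = 15) {
  ev <- seq$events
  report <- list()
  add <- function(name, pass, idx = NA_integer_) {
    report[[length(report) + 1]] <<- data.frame(
      constraint = name, pass = pass, first_violation_index = idx,
      stringsAsFactors = FALSE)
  }

  # onset spacing within block
  idx <- NA_integer_
  for (b in unique(ev$block)) {
    rows <- which(ev$block == b)
    d <- diff(ev$onset[rows])
    bad <- which(abs(d - seq$soa_s) > 1e-9 | d <= 0)
    if (length(bad)) { idx <- rows[bad[1] + 1]; break }
  }
  add("onsets increasing and spaced by SOA within block", is.na(idx), idx)

  # alternation after block-initial standards
  idx <- NA_integer_
  for (b in unique(ev$block)) {
    rows <- which(ev$block == b)
    post <- rows[-seq_len(min(n_initial_standards, length(rows)))]
    if (!length(post)) next
    is_dev <- ev$dimension[post] != "standard"
    expect_dev <- rep(c(FALSE, TRUE), length.out = length(post))
    bad <- which(is_dev != expect_dev)
    if (length(bad)) { idx <- post[bad[1]]; break }
  }
  add("standard and deviant strictly alternate after block-initial standards",
      is.na(idx), idx)

  # no consecutive same-dimension deviants (deviant subsequence, whole session)
  dev_rows <- which(ev$dimension != "standard")
  dd <- ev$dimension[dev_rows]
  rep_pos <- which(dd[-1] == dd[-length(dd)])
  add("no consecutive same-dimension deviants",
      length(rep_pos) == 0,
      if (length(rep_pos)) dev_rows[rep_pos[1] + 1] else NA_integer_)

  # every non-overlapping run of 5 deviants within a block covers all dims
  idx <- NA_integer_
  for (b in unique(ev$block)) {
    rows <- which(ev$block == b & ev$dimension != "standard")
    nfull <- floor(length(rows) / 5)
    for (g in seq_len(nfull)) {
      win <- rows[(5 * (g - 1) + 1):(5 * g)]
      if (!setequal(ev$dimension[win], DEVIANT_DIMENSIONS)) {
        idx <- win[1]; break
      }
    }
    if (!is.na(idx)) break
  }
  add("each non-overlapping run of 5 deviants covers all 5 dimensions",
      is.na(idx), idx)

  # equal per-dimension counts within each block
  idx <- NA_integer_
  for (b in unique(ev$block)) {
    rows <- which(ev$block == b & ev$dimension != "standard")
    if (!length(rows)) next
    counts <- table(ev$dimension[rows])
    if (length(unique(as.integer(counts))) != 1 ||
        !setequal(names(counts), DEVIANT_DIMENSIONS)) {
      idx <- rows[1]; break
    }
  }
  add("equal deviant-dimension counts within each block", is.na(idx), idx)

  # block-initial standards not analysed
  idx <- NA_integer_
  for (b in unique(ev$block)) {
    rows <- which(ev$block == b)
    head_rows <- rows[seq_len(min(n_initial_standards, length(rows)))]
    bad <- which(ev$analyzed[head_rows] |
                   ev$dimension[head_rows] != "standard")
    rest <- rows[-seq_len(min(n_initial_standards, length(rows)))]
    bad2 <- which(!ev$analyzed[rest])
    if (length(bad)) { idx <- head_rows[bad[1]]; break }
    if (length(bad2)) { idx <- rest[bad2[1]]; break }
  }
  add("block-initial standards excluded from analysis (and only those)",
      is.na(idx), idx)

  do.call(rbind, report)
}

#' Synthesize a tone waveform
#'
#' Renders a `tone_spec` as a stereo waveform: the sum of equal-amplitude
#' harmonics, scaled by the dB level offset, with raised-cosine on/off ramps.
#' The gap deviant zeroes a silent interval centred at the tone midpoint;
#' laterality deviants route the signal to a single channel.
#'
#' @param tone A `tone_spec` (or tone-type string).
#' @param sample_rate_hz Sampling rate; must be at least four times the
#'   highest harmonic.
#' @param base_amplitude Peak amplitude of the 0-dB standard (default 0.3,
#'   headroom for the +6 dB deviant in 16-bit output).
#' @return Numeric matrix, samples x 2 (left, right).
#' @export
synthesize_tone <- function(tone, sample_rate_hz = 44100, base_amplitude = 0.3) {
  if (is.character(tone)) tone <- tone_spec(tone)
  stopifnot(inherits(tone, "tone_spec"))
  f_max <- max(tone$fundamentals_hz)
  if (sample_rate_hz < 4 * f_max) {
    stop("sample_rate_hz must be at least 4x the highest harmonic (",
         4 * f_max, " Hz)")
  }
  if (tone$gap_ms > 0 && tone$gap_ms >= tone$duration_ms) {
    stop("gap_ms must be smaller than duration_ms")
  }
  n <- round(tone$duration_ms / 1000 * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  x <- rowSums(sapply(tone$fundamentals_hz, function(f) sin(2 * pi * f * t))) /
    length(tone$fundamentals_hz)
  # raised-cosine on/off ramps
  nr <- round(tone$ramp_ms / 1000 * sample_rate_hz)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  if (tone$gap_ms > 0) {
    ng <- round(tone$gap_ms / 1000 * sample_rate_hz)
    g0 <- floor((n - ng) / 2)
    x[(g0 + 1):(g0 + ng)] <- 0
  }
  x <- x * base_amplitude * 10^(tone$level_db_offset / 20)
  left <- if (tone$channel_routing %in% c("binaural", "left")) x else numeric(n)
  right <- if (tone$channel_routing %in% c("binaural", "right")) x else numeric(n)
  cbind(left = left, right = right)
}

#' Write a stimulus sequence to a TSV event file
#'
#' One row per event with columns `onset` (seconds, 6-decimal fixed point),
#' `duration` (seconds), `tone_type`, `block`, `analyzed`. Round-trips
#' losslessly through [read_events()].
#'
#' @param seq A `stimulus_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(seq, path) {
  ev <- seq$events
  out <- data.frame(
    onset = sprintf("%.6f", ev$onset),
    duration = sprintf("%.6f", ev$duration),
    tone_type = ev$tone_type,
    block = ev$block,
    analyzed = ev$analyzed,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus sequence from a TSV event file
#'
#' Inverse of [write_events()]; acoustic fields are reconstituted from the
#' tone type via [tone_spec()].
#'
#' @param path Event file written by [write_events()].
#' @return A `stimulus_sequence`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(ev) == 0) {
    out <- list(events = data.frame(onset = numeric(0), duration = numeric(0),
                                    tone_type = character(0),
                                    dimension = character(0),
                                    block = integer(0), analyzed = logical(0)),
                soa_s = NA_real_, n_blocks = 0L)
    class(out) <- "stimulus_sequence"
    return(out)
  }
  events <- data.frame(
    onset = as.numeric(ev$onset),
    duration = as.numeric(ev$duration),
    tone_type = ev$tone_type,
    dimension = tone_dimension(ev$tone_type),
    block = as.integer(ev$block),
    analyzed = as.logical(ev$analyzed),
    stringsAsFactors = FALSE
  )
  soa <- if (nrow(events) > 1) events$onset[2] - events$onset[1] else NA_real_
  out <- list(events = events, soa_s = soa,
              n_blocks = length(unique(events$block)))
  class(out) <- "stimulus_sequence"
  out
}

#' Write a stereo waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer for the synthesized tones (16-bit PCM, 2
#' channels).
#'
#' @param wave Samples x 2 numeric matrix in \[-1, 1\].
#' @param path Output path.
#' @param sample_rate_hz Sampling rate.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate_hz = 44100) {
  stopifnot(is.matrix(wave), ncol(wave) == 2)
  pcm <- as.integer(round(pmax(pmin(t(wave), 1), -1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(2L, con, size = 2, endian = "little")          # stereo
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Analysed tone counts of a sequence
#'
#' Convenience tabulation: analysed standards, analysed deviants, per-dimension
#' deviant counts, and excluded block-initial standards.
#'
#' @param seq A `stimulus_sequence`.
#' @return Named list of counts.
#' @export
sequence_counts <- function(seq) {
  ev <- seq$events
  a <- ev[ev$analyzed, ]
  list(
    standards = sum(a$dimension == "standard"),
    deviants = sum(a$dimension != "standard"),
    per_dimension = table(factor(a$dimension[a$dimension != "standard"],
                                 levels = DEVIANT_DIMENSIONS)),
    excluded_standards = sum(!ev$analyzed)
  )
}
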