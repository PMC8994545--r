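# ---- IO utilities -----------------------------------------------------------

#' Write an epoch set as long-format TSV
#'
#' Columns `trial`, `condition`, `source`, `sample`, `value` (scientific
#' notation, 9 decimal digits, so every value round-trips within 1e-9);
#' sampling rate and time origin are stored in `#`-prefixed header
#' lines so the file round-trips losslessly through
#' [read_timeseries_tsv()].
#'
#' @param ep An `epoch_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(ep, path) {
  stopifnot(inherits(ep, "epoch_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sfreq=%.9g", ep$sfreq),
               sprintf("# t0=%.9g", ep$time[1]),
               sprintf("# sources=%s", paste(ep$source_labels, collapse = ","))),
             con)
  d <- dim(ep$data)
  long <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    condition = rep(ep$condition, times = d[2] * d[3]),
    source = rep(rep(ep$source_labels, each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = sprintf("%.9e", as.vector(ep$data)),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an epoch set from long-format TSV
#'
#' Inverse of [write_timeseries_tsv()]. Malformed files raise a parse error
#' reporting the first offending line.
#'
#' @param path File written by [write_timeseries_tsv()].
#' @return An `epoch_set`.
#' @export
read_timeseries_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- sub(paste0("^# *", key, "="), "", grep(paste0("^# *", key, "="),
                                                hdr, value = TRUE))
    if (!length(m)) stop("missing header field '", key, "' in ", path)
    m[1]
  }
  sfreq <- as.numeric(get_field("sfreq"))
  t0 <- as.numeric(get_field("t0"))
  sources <- strsplit(get_field("sources"), ",")[[1]]
  body_start <- which(!grepl("^#", lines))[1]
  tab <- tryCatch(
    utils::read.table(text = lines[body_start:length(lines)], sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, " near line ",
                             body_start, ": ", conditionMessage(e))
  )
  need <- c("trial", "condition", "source", "sample", "value")
  if (!all(need %in% names(tab))) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  n_trial <- max(tab$trial); n_t <- max(tab$sample)
  if (nrow(tab) != n_trial * length(sources) * n_t) {
    stop("parse error in ", path, ": expected ",
         n_trial * length(sources) * n_t, " rows, found ", nrow(tab))
  }
  data <- array(NA_real_, c(n_trial, length(sources), n_t))
  data[cbind(tab$trial, match(tab$source, sources), tab$sample)] <- tab$value
  condition <- character(n_trial)
  condition[tab$trial] <- tab$condition
  time <- t0 + (seq_len(n_t) - 1) / sfreq
  epoch_set(data, condition, time, sfreq, sources)
}

#' Write a JSON report
#'
#' @param x List to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

# ---- pipeline configuration -------------------------------------------------

#' Build a pipeline configuration
#'
#' One configuration object drives the whole simulate - evoked -
#' connectivity - structure-function chain. Thresholds default to the study
#' settings: voxelwise p < 0.001, network probability 0.05, test level 0.05,
#' FDR q 0.05, 100 shuffle iterations.
#'
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory for persisted artifacts (`NULL` keeps
#'   everything in memory).
#' @param simulation A [simulation_config()] (its seed is overridden by
#'   `seed`).
#' @param stages Named logical vector toggling `simulate`, `evoked`,
#'   `connectivity`, `structure_function`.
#' @param measure Connectivity measure (default `"partial_plv"`).
#' @param window_s Connectivity analysis window.
#' @param n_iterations Shuffle iterations for the permutation null.
#' @param p_threshold,prob_threshold,alpha,q Statistical thresholds.
#' @param bands Band definition list.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            simulation = simulation_config(seed = seed),
                            stages = c(simulate = TRUE, evoked = TRUE,
                                       connectivity = TRUE,
                                       structure_function = TRUE),
                            measure = "partial_plv", window_s = c(0, 0.5),
                            n_iterations = 100, p_threshold = 0.001,
                            prob_threshold = 0.05, alpha = 0.05, q = 0.05,
                            bands = DEFAULT_BANDS) {
  simulation$seed <- seed
  cfg <- list(seed = seed, out_dir = out_dir, simulation = simulation,
              stages = stages, measure = measure, window_s = window_s,
              n_iterations = n_iterations, p_threshold = p_threshold,
              prob_threshold = prob_threshold, alpha = alpha, q = q,
              bands = bands)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' The atrophy-focus and coupling-table fields are flattened to plain lists
#' so the file is a faithful single-document round trip.
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` / a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$simulation <- unclass(ser$simulation)
  ser$simulation$coupling_table <- as.list(ser$simulation$coupling_table)
  # yaml drops names of atomic vectors; serialize named fields as maps
  for (f in c("groups", "mmn_attenuation", "band_freqs", "age_mean",
              "age_sd")) {
    ser$simulation[[f]] <- as.list(ser$simulation[[f]])
  }
  ser$stages <- as.list(ser$stages)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  sim$coupling_table <- as.data.frame(sim$coupling_table,
                                      stringsAsFactors = FALSE)
  for (f in c("groups", "mmn_attenuation", "band_freqs", "age_mean", "age_sd")) {
    sim[[f]] <- unlist(sim[[f]])
  }
  for (f in c("grid_shape", "epoch_window_s")) sim[[f]] <- unlist(sim[[f]])
  sim$atrophy_foci <- lapply(sim$atrophy_foci, function(g) {
    lapply(g, function(focus) {
      focus$center <- unlist(focus$center)
      focus
    })
  })
  class(sim) <- "simulation_config"
  cfg <- raw
  cfg$simulation <- sim
  cfg$stages <- unlist(cfg$stages)
  cfg$window_s <- unlist(cfg$window_s)
  cfg$bands <- lapply(cfg$bands, unlist)
  class(cfg) <- "pipeline_config"
  cfg
}

# Stable content hash of a configuration (for the run report); volatile
# fields (output paths) are excluded so reruns elsewhere hash identically.
.config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

# ---- orchestration ----------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — cohort simulation, evoked/MMN
#' quantification with group statistics, partialized connectivity with
#' trial-shuffled nulls and group comparisons, and the structure-function
#' overlap analysis — and returns a run report. Any stage error aborts with
#' the stage name after flushing the partial report. With `out_dir` set,
#' intermediate artifacts (subject MMN JSON, connectivity TSV, NIfTI maps,
#' report JSON) are persisted.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `run_report` with per-stage summaries, seeds, the
#'   configuration hash and package version.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  report <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                 version = as.character(utils::packageVersion("mmnpipe")),
                 stages_run = character(0), stages_skipped = character(0))
  flush <- function() {
    if (!is.null(cfg$out_dir)) {
      write_json_report(report, file.path(cfg$out_dir, "run_report.json"))
    }
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) {
      report$stages_skipped <<- c(report$stages_skipped, name)
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) {
      report$error <<- list(stage = name, message = conditionMessage(e))
      flush()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages_run <<- c(report$stages_run, name)
    out
  }

  cohort <- run_stage("simulate", function() {
    co <- simulate_cohort(cfg$simulation)
    report$simulate <<- list(
      n_subjects = length(co$subjects),
      groups = as.list(table(co$ground_truth$subject_table$group)),
      n_trials = dim(co$subjects[[1]]$epochs$data)[1],
      grid_shape = cfg$simulation$grid_shape
    )
    co
  })
  if (is.null(cohort)) {
    flush()
    class(report) <- "run_report"
    return(report)
  }
  groups <- cohort$ground_truth$subject_table$group
  control_label <- names(cfg$simulation$groups)[1]

  mmn <- run_stage("evoked", function() {
    results <- lapply(cohort$subjects, function(s) subject_mmn(s$epochs))
    stats_out <- group_evoked_stats(results, groups,
                                    control_label = control_label, q = cfg$q)
    if (!is.null(cfg$out_dir)) {
      amp <- data.frame(id = cohort$ground_truth$subject_table$id,
                        group = groups,
                        mmn_amplitude = vapply(results, `[[`, numeric(1),
                                               "mmn_amplitude"),
                        m100_amplitude = vapply(results, `[[`, numeric(1),
                                                "m100_amplitude"))
      utils::write.table(amp, file.path(cfg$out_dir, "mmn_amplitudes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$evoked <<- list(
      anova_F = stats_out$anova$F, anova_p = stats_out$anova$p,
      group_means = as.list(stats_out$group_means)
    )
    list(results = results, stats = stats_out)
  })

  run_stage("connectivity", function() {
    per_subject <- vector("list", length(cohort$subjects))
    nulls <- vector("list", length(cohort$subjects))
    for (i in seq_along(cohort$subjects)) {
      induced <- subtract_evoked(cohort$subjects[[i]]$epochs)
      spec <- multitaper_spectra(induced, cfg$window_s)
      per_subject[[i]] <- band_average(
        partial_connectivity(spec, cfg$measure), cfg$bands)
      nulls[[i]] <- trial_shuffle_null(spec, cfg$n_iterations,
                                       seed = cfg$seed + 13L * i,
                                       measure = cfg$measure,
                                       bands = cfg$bands)
    }
    ctrl_idx <- which(groups == control_label)
    comparisons <- list()
    for (g in setdiff(unique(groups), control_label)) {
      gi <- which(groups == g)
      nd <- null_group_difference(nulls[ctrl_idx], nulls[gi])
      comparisons[[g]] <- group_comparison(
        stack_connectivity(per_subject[ctrl_idx]),
        stack_connectivity(per_subject[gi]),
        nd, alpha = cfg$alpha)
    }
    if (!is.null(cfg$out_dir)) {
      for (g in names(comparisons)) {
        ob <- comparisons[[g]]$observed_diff
        tab <- data.frame(band = rep(rownames(ob), ncol(ob)),
                          connection = rep(colnames(ob), each = nrow(ob)),
                          diff = as.vector(ob),
                          flagged = as.vector(comparisons[[g]]$flags))
        utils::write.table(tab, file.path(cfg$out_dir,
                                          paste0("connectivity_", g, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    report$connectivity <<- lapply(comparisons, function(cmp) {
      list(welch = cmp$welch, n_flags = as.list(rowSums(cmp$flags)))
    })
    comparisons
  })

  run_stage("structure_function", function() {
    if (is.null(mmn)) stop("structure-function stage requires the evoked stage")
    amplitudes <- vapply(mmn$results, `[[`, numeric(1), "mmn_amplitude")
    covariates <- cohort$ground_truth$subject_table[, c("age", "tiv")]
    volumes <- lapply(cohort$subjects, `[[`, "volume")
    glm <- fit_voxelwise_glm(volumes, amplitudes, covariates,
                             design_variant = "all_subjects")
    md <- overlap_stats(glm, cohort$ground_truth$md_map, cfg$p_threshold,
                        cfg$prob_threshold)
    ctrl_net <- overlap_stats(glm, cohort$ground_truth$control_map,
                              cfg$p_threshold, cfg$prob_threshold)
    atro <- fit_atrophy_glm(volumes, groups, covariates, control_label)
    atro_t <- threshold_t_map(atro, cfg$p_threshold)
    struct_ratio_md <- if (sum(atro_t$grid) > 0) {
      structural_control_ratio(atro_t, cohort$ground_truth$md_map)
    } else NA_real_
    if (!is.null(cfg$out_dir)) {
      write_voxel_map(glm$t, file.path(cfg$out_dir, "structfunc_t.nii.gz"))
      write_voxel_map(cohort$ground_truth$md_map,
                      file.path(cfg$out_dir, "md_network.nii.gz"))
    }
    report$structure_function <<- list(
      md_overlap = md$overlap_proportion,
      md_activation_ratio = md$normalized_activation_ratio,
      control_overlap = ctrl_net$overlap_proportion,
      control_activation_ratio = ctrl_net$normalized_activation_ratio,
      md_structural_control_ratio = struct_ratio_md,
      n_surviving = md$n_surviving, df = glm$df
    )
    NULL
  })

  flush()
  class(report) <- "run_report"
  report
}
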