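# ---- mass-univariate GLM ----------------------------------------------------

#' Voxelwise regression of gray-matter volume on MMN amplitude
#'
#' Least-squares fit, per voxel, of volume against the MMN regressor with age
#' and total intracranial volume (TIV) as covariates of no interest. By
#' default the regressor is the MMN magnitude (the negated signed amplitude),
#' so that "reduced MMN related to reduced volume" appears as a positive t
#' for the volume-amplitude association. Design variants: `all_subjects`
#' (single group), `patients_only` (controls excluded), `group_adjusted_2`
#' (controls/patients indicator) and `group_adjusted_5` (full group
#' indicators), the grouped designs being fixed-effect mass-univariate
#' analogues of the grouped models.
#'
#' @param volumes List of per-subject `voxel_map`s on a shared grid.
#' @param amplitudes Signed MMN amplitudes, one per subject.
#' @param covariates data.frame with columns `age` (years) and `tiv` (ml).
#' @param design_variant One of `"all_subjects"`, `"patients_only"`,
#'   `"group_adjusted_2"`, `"group_adjusted_5"`.
#' @param groups Group labels (required for the grouped/patients-only
#'   variants).
#' @param control_label Label of the control group (default `"controls"`).
#' @param use_magnitude Regress the MMN magnitude, `-amplitude`
#'   (default TRUE).
#' @return Object of class `glm_result`: `beta`, `t`, `p` voxel maps for the
#'   amplitude regressor, `df` (residual degrees of freedom), `design`
#'   (description), `mask` (analysis mask after zero-variance exclusion),
#'   `n_zero_variance`.
#' @export
fit_voxelwise_glm <- function(volumes, amplitudes, covariates,
                              design_variant = c("all_subjects", "patients_only",
                                                 "group_adjusted_2",
                                                 "group_adjusted_5"),
                              groups = NULL, control_label = "controls",
                              use_magnitude = TRUE) {
  design_variant <- match.arg(design_variant)
  n <- length(volumes)
  stopifnot(length(amplitudes) == n, nrow(covariates) == n)
  if (design_variant != "all_subjects" && is.null(groups)) {
    stop("groups required for design variant '", design_variant, "'")
  }
  grid_dim <- dim(volumes[[1]]$grid)
  mask <- volumes[[1]]$mask
  for (v in volumes) {
    if (!identical(dim(v$grid), grid_dim)) stop("volumes must share a grid")
  }

  keep <- rep(TRUE, n)
  if (design_variant == "patients_only") keep <- groups != control_label
  x_amp <- (if (use_magnitude) -amplitudes else amplitudes)[keep]
  X <- cbind(intercept = 1, mmn = x_amp,
             age = covariates$age[keep], tiv = covariates$tiv[keep])
  if (design_variant == "group_adjusted_2") {
    X <- cbind(X, patient = as.numeric(groups[keep] != control_label))
  } else if (design_variant == "group_adjusted_5") {
    g <- factor(groups[keep])
    g <- stats::relevel(g, ref = intersect(control_label, levels(g))[1])
    G <- stats::model.matrix(~g)[, -1, drop = FALSE]
    colnames(G) <- levels(g)[-1]
    X <- cbind(X, G)
  }
  p <- ncol(X)
  if (nrow(X) < p + 2) stop("need at least ", p + 2, " subjects for ", p,
                            " regressors")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  Y <- vapply(volumes[keep], function(v) v$grid[mask], numeric(sum(mask)))
  Y <- t(Y)  # subjects x voxels
  v_var <- apply(Y, 2, stats::var)
  nz <- v_var > 0
  n_zero <- sum(!nz)
  if (n_zero > 0) {
    message(n_zero, " zero-variance voxel(s) excluded from the mask")
    mask_idx <- which(mask)
    mask[mask_idx[!nz]] <- FALSE
    Y <- Y[, nz, drop = FALSE]
  }

  XtX_inv <- chol2inv(chol(crossprod(X)))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  B <- XtX_inv %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtX_inv["mmn", "mmn"])
  t_vals <- B["mmn", ] / se
  p_vals <- 2 * stats::pt(-abs(t_vals), df)

  to_map <- function(vals, semantics) {
    g <- array(0, grid_dim)
    g[mask] <- vals
    voxel_map(g, mask, voxel_mm = volumes[[1]]$voxel_mm, semantics = semantics)
  }
  structure(list(beta = to_map(B["mmn", ], "volume"),
                 t = to_map(t_vals, "t_score"),
                 p = {
                   g <- array(1, grid_dim); g[mask] <- p_vals
                   voxel_map(g, mask, voxel_mm = volumes[[1]]$voxel_mm,
                             semantics = "probability")
                 },
                 df = df,
                 design = list(variant = design_variant,
                               columns = colnames(X),
                               use_magnitude = use_magnitude,
                               n_subjects = nrow(X)),
                 mask = mask, n_zero_variance = n_zero),
            class = "glm_result")
}

#' Group-atrophy GLM (volume vs patient status)
#'
#' Mass-univariate fit of volume on a patients-vs-controls indicator with age
#' and TIV covariates; the returned t map is signed so that atrophy (lower
#' volume in patients) is positive. Used for the structural control ratio.
#'
#' @param volumes List of `voxel_map`s.
#' @param groups Group labels.
#' @param covariates data.frame with `age` and `tiv`.
#' @param control_label Control group label.
#' @return A `glm_result` whose `t`/`p` maps refer to the atrophy contrast.
#' @export
fit_atrophy_glm <- function(volumes, groups, covariates,
                            control_label = "controls") {
  n <- length(volumes)
  stopifnot(length(groups) == n, nrow(covariates) == n)
  grid_dim <- dim(volumes[[1]]$grid)
  mask <- volumes[[1]]$mask
  # patient indicator signed so that atrophy -> positive coefficient
  X <- cbind(intercept = 1,
             atrophy = -as.numeric(groups != control_label),
             age = covariates$age, tiv = covariates$tiv)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient atrophy design")
  Y <- t(vapply(volumes, function(v) v$grid[mask], numeric(sum(mask))))
  v_var <- apply(Y, 2, stats::var)
  nz <- v_var > 0
  if (any(!nz)) {
    mask_idx <- which(mask)
    mask[mask_idx[!nz]] <- FALSE
    Y <- Y[, nz, drop = FALSE]
  }
  XtX_inv <- chol2inv(chol(crossprod(X)))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  B <- XtX_inv %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(X) - p
  sigma2 <- colSums(res^2) / df
  t_vals <- B["atrophy", ] / sqrt(sigma2 * XtX_inv["atrophy", "atrophy"])
  p_vals <- 2 * stats::pt(-abs(t_vals), df)
  to_map <- function(vals, semantics, fill = 0) {
    g <- array(fill, grid_dim)
    g[mask] <- vals
    voxel_map(g, mask, voxel_mm = volumes[[1]]$voxel_mm, semantics = semantics)
  }
  structure(list(beta = to_map(B["atrophy", ], "volume"),
                 t = to_map(t_vals, "t_score"),
                 p = to_map(p_vals, "probability", fill = 1),
                 df = df,
                 design = list(variant = "atrophy", columns = colnames(X),
                               n_subjects = n),
                 mask = mask, n_zero_variance = sum(!nz)),
            class = "glm_result")
}

# ---- thresholding and overlap ----------------------------------------------

#' Binarize a structure-function map at an uncorrected p threshold
#'
#' 1 where `p < p_threshold` and `t > 0` inside the mask, 0 elsewhere.
#'
#' @param glm A `glm_result`.
#' @param p_threshold Uncorrected voxelwise p (default 0.001).
#' @return Binary `voxel_map`.
#' @export
threshold_map <- function(glm, p_threshold = 0.001) {
  stopifnot(inherits(glm, "glm_result"))
  b <- array(0, dim(glm$t$grid))
  sel <- glm$mask & glm$p$grid < p_threshold & glm$t$grid > 0
  b[sel] <- 1
  voxel_map(b, glm$mask, voxel_mm = glm$t$voxel_mm, semantics = "binary")
}

#' Thresholded t-score map
#'
#' The t map with sub-threshold voxels zeroed (same surviving set as
#' [threshold_map()]); input to the normalized activation ratio.
#'
#' @inheritParams threshold_map
#' @return `voxel_map` with semantics `t_score`.
#' @export
threshold_t_map <- function(glm, p_threshold = 0.001) {
  stopifnot(inherits(glm, "glm_result"))
  g <- array(0, dim(glm$t$grid))
  sel <- glm$mask & glm$p$grid < p_threshold & glm$t$grid > 0
  g[sel] <- glm$t$grid[sel]
  voxel_map(g, glm$mask, voxel_mm = glm$t$voxel_mm, semantics = "t_score")
}

#' Overlap proportion of a thresholded map with a network
#'
#' Fraction of surviving structure-function voxels that fall inside the
#' probabilistic network map thresholded at `prob_threshold`.
#'
#' @param sf_binary Binary `voxel_map` of surviving voxels.
#' @param network_prob Probabilistic `voxel_map` on the same grid.
#' @param prob_threshold Probability threshold (default 0.05).
#' @return Fraction in \[0, 1\].
#' @export
overlap_proportion <- function(sf_binary, network_prob, prob_threshold = 0.05) {
  stopifnot(inherits(sf_binary, "voxel_map"), inherits(network_prob, "voxel_map"))
  if (!identical(dim(sf_binary$grid), dim(network_prob$grid))) {
    stop("maps must share a grid")
  }
  sf <- sf_binary$grid > 0
  n_sf <- sum(sf)
  if (n_sf == 0) stop("empty structure-function map: overlap undefined")
  sum(sf & network_prob$grid > prob_threshold) / n_sf
}

#' Normalized activation ratio
#'
#' Size- and range-normalized weighted overlap between a thresholded t map
#' and a probabilistic network map:
#' `(sum_v t_v p_v * mask_size) / (sum_v t_v * sum_v p_v)`, sums over mask
#' voxels. Equal to 1 when both maps are constant over the mask; 0 when the
#' t mass lies entirely where the network probability is 0. Invariant to
#' positive rescaling of either map.
#'
#' @param t_map_thresholded `voxel_map` of thresholded t scores (zeros off
#'   the surviving set).
#' @param network_prob Unthresholded probabilistic `voxel_map`.
#' @param mask Logical array; default the t map's mask.
#' @return Nonnegative ratio.
#' @export
normalized_activation_ratio <- function(t_map_thresholded, network_prob,
                                        mask = t_map_thresholded$mask) {
  stopifnot(inherits(t_map_thresholded, "voxel_map"),
            inherits(network_prob, "voxel_map"))
  if (!identical(dim(t_map_thresholded$grid), dim(network_prob$grid))) {
    stop("maps must share a grid")
  }
  tv <- t_map_thresholded$grid[mask]
  pv <- network_prob$grid[mask]
  sum_t <- sum(tv); sum_p <- sum(pv)
  if (sum_t == 0) stop("empty thresholded t map: ratio undefined")
  if (sum_p == 0) stop("zero-probability network map: ratio undefined")
  sum(tv * pv) * sum(mask) / (sum_t * sum_p)
}

#' Structural control ratio
#'
#' The normalized activation ratio computed from a structural (atrophy) t map
#' instead of the structure-function map: the specificity control showing
#' that network selectivity of the structure-function ratio is not a
#' nonspecific atrophy effect.
#'
#' @param atrophy_t_map Thresholded atrophy t `voxel_map` (from
#'   [fit_atrophy_glm()] + [threshold_t_map()]).
#' @param network_prob Unthresholded probabilistic `voxel_map`.
#' @param mask Logical array; default the atrophy map's mask.
#' @return Nonnegative ratio.
#' @export
structural_control_ratio <- function(atrophy_t_map, network_prob,
                                     mask = atrophy_t_map$mask) {
  normalized_activation_ratio(atrophy_t_map, network_prob, mask)
}

#' Overlap statistics of a GLM against a network map
#'
#' Bundles thresholding, the overlap proportion and the normalized activation
#' ratio for one network map.
#'
#' @param glm A `glm_result`.
#' @param network_prob Probabilistic `voxel_map`.
#' @param p_threshold Voxelwise p threshold (default 0.001).
#' @param prob_threshold Network probability threshold (default 0.05).
#' @return List of class `overlap_stats`: `overlap_proportion`,
#'   `normalized_activation_ratio`, `p_threshold`, `prob_threshold`,
#'   `n_surviving`.
#' @export
overlap_stats <- function(glm, network_prob, p_threshold = 0.001,
                          prob_threshold = 0.05) {
  sf_bin <- threshold_map(glm, p_threshold)
  sf_t <- threshold_t_map(glm, p_threshold)
  structure(list(
    overlap_proportion = overlap_proportion(sf_bin, network_prob,
                                            prob_threshold),
    normalized_activation_ratio = normalized_activation_ratio(sf_t,
                                                              network_prob),
    p_threshold = p_threshold, prob_threshold = prob_threshold,
    n_surviving = sum(sf_bin$grid)
  ), class = "overlap_stats")
}
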