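#' Polygenic scores as predictors of drug response
#'
#' Applies externally trained per-variant weights to a dosage matrix,
#' standardizes the score within the analysed cohort, and relates it to
#' the absolute and log-relative response phenotypes. On simulated data
#' where the drug acts multiplicatively on the raw biomarker scale, a
#' baseline-increasing PRS yields a negative absolute-scale response
#' effect (higher starting levels drop more in absolute terms) while the
#' log-scale effect is null — and conditioning the absolute response on
#' the baseline flips the sign of the PRS effect, the same mechanism as
#' the per-variant baseline-adjustment bias.
#'
#' @name prs_analysis
NULL

#' Compute and standardize a polygenic score
#'
#' Weighted dosage sum, then within-cohort standardization to mean 0,
#' SD 1.
#'
#' @param dosages participants x variants dosage matrix.
#' @param weights either a numeric vector named by variant id, or a
#'   data.frame (variant_id, weight). Every weight must match a dosage
#'   column.
#' @param standardize standardize within cohort (default TRUE).
#' @return named numeric score vector (participant ids from rownames).
#' @export
compute_prs <- function(dosages, weights, standardize = TRUE) {
  if (is.data.frame(weights)) {
    stopifnot(all(c("variant_id", "weight") %in% names(weights)))
    w <- stats::setNames(weights$weight, weights$variant_id)
  } else w <- weights
  missing_v <- setdiff(names(w), colnames(dosages))
  if (length(missing_v) > 0)
    stop("weights refer to variant(s) absent from the dosages: ",
         paste(utils::head(missing_v, 5), collapse = ", "), call. = FALSE)
  score <- as.numeric(dosages[, names(w), drop = FALSE] %*% w)
  names(score) <- rownames(dosages)
  if (standardize) {
    s <- stats::sd(score)
    if (s == 0) stop("score has zero variance; cannot standardize",
                     call. = FALSE)
    score <- (score - mean(score)) / s
  }
  score
}

#' Read a minimal PRS scoring file
#'
#' Delimited text with columns variant_id, effect_allele, weight.
#'
#' @param path scoring file.
#' @return data.table of weights.
#' @export
read_prs_weights <- function(path) {
  w <- data.table::fread(path)
  need <- c("variant_id", "effect_allele", "weight")
  if (!all(need %in% names(w)))
    stop("scoring file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  w
}

#' PRS-response association
#'
#' OLS of the response on the standardized PRS plus covariates; reports
#' the native-unit effect per SD of PRS and the SD-standardized effect,
#' with a 95% confidence interval. A negative absolute-scale effect means
#' a higher PRS increases treatment efficacy (a larger drop).
#'
#' @param prs named score vector from \code{\link{compute_prs}}.
#' @param cohort cohort table (participant_id, baseline, post, ...).
#' @param scale "abs" or "log".
#' @param covariates optional covariate data.frame aligned to the cohort.
#' @param adjust_baseline include the baseline level (the biased model).
#' @param min_n minimum analysable rows (default 30).
#' @return one-row data.table: scale, model, n, beta (native units per SD
#'   PRS), se, ci_lo, ci_hi, p, beta_std (SD outcome per SD PRS).
#' @export
prs_response_association <- function(prs, cohort, scale = c("abs", "log"),
                                     covariates = NULL,
                                     adjust_baseline = FALSE, min_n = 30L) {
  scale <- match.arg(scale)
  idx <- match(cohort$participant_id, names(prs))
  if (anyNA(idx))
    stop("cohort participants missing from the PRS vector", call. = FALSE)
  y <- response_phenotype(cohort, scale)
  r <- associate_variant(prs[idx], y, covariates,
                         adjust_baseline = adjust_baseline,
                         baseline = cohort$baseline,
                         variant_id = "PRS", min_n = min_n)
  sd_y <- stats::sd(y, na.rm = TRUE)
  data.table::data.table(
    scale = scale, model = r$model, n = r$n,
    beta = r$beta, se = r$se,
    ci_lo = r$beta - stats::qnorm(0.975) * r$se,
    ci_hi = r$beta + stats::qnorm(0.975) * r$se,
    p = r$p, beta_std = r$beta / sd_y)
}

#' Baseline levels adjusted for PRS
#'
#' Residual of the baseline on the PRS: with the genetic share removed,
#' the residual more closely reflects the environmental/lifestyle
#' component of the starting level.
#'
#' @param baseline numeric baseline vector.
#' @param prs aligned score vector.
#' @return residualized baseline.
#' @export
prs_adjusted_baseline <- function(baseline, prs) {
  stats::residuals(stats::lm(baseline ~ prs,
                             na.action = stats::na.exclude))
}

#' Variance explained by nested predictor sets
#'
#' In-sample R-squared per model over a sequence of nested predictor
#' sets, with increments; used to quantify what a PRS adds on top of
#' (PRS-adjusted) baseline levels.
#'
#' @param outcome numeric response.
#' @param predictor_sets named list of data.frames; each should extend
#'   the previous (a warning is raised and increments suppressed
#'   otherwise).
#' @return data.table: model, n_predictors, r_squared, increment.
#' @export
variance_explained <- function(outcome, predictor_sets) {
  stopifnot(is.list(predictor_sets), length(predictor_sets) >= 1)
  nested <- TRUE
  for (i in seq_along(predictor_sets)[-1])
    if (!all(names(predictor_sets[[i - 1]]) %in%
               names(predictor_sets[[i]]))) nested <- FALSE
  if (!nested)
    warning("predictor sets are not nested; increments suppressed",
            call. = FALSE)
  r2 <- vapply(predictor_sets, function(ps) {
    summary(stats::lm(outcome ~ ., data = as.data.frame(ps)))$r.squared
  }, numeric(1))
  out <- data.table::data.table(
    model = names(predictor_sets),
    n_predictors = vapply(predictor_sets, ncol, integer(1)),
    r_squared = r2,
    increment = c(NA_real_, diff(r2)))
  if (!nested) out$increment <- NA_real_
  out
}

#' Stratified mean-response grid
#'
#' Tiles of mean response by PRS quantile x PRS-adjusted-baseline
#' quantile (optionally further split by genotype), the structure of
#' stratified prediction heatmaps. Quantile bins are equal-count within
#' the cohort; ties are broken by stable participant order so the
#' binning is deterministic. Tiles below the size floor are masked
#' (values set to NA, n retained).
#'
#' @param cohort cohort table with baseline/post.
#' @param prs named score vector.
#' @param scale "abs" or "log".
#' @param n_bins quantile bins per axis (default 5, i.e. quintiles;
#'   must be >= 2).
#' @param genotype optional dosage vector (rounded to 0/1/2 strata).
#' @param min_tile_n mask tiles smaller than this (default 5).
#' @return data.table: prs_bin, baseline_bin (1 = lowest), optional
#'   genotype, n, mean_response, sd_response (masked tiles NA).
#' @export
stratified_response_grid <- function(cohort, prs, scale = c("abs", "log"),
                                     n_bins = 5L, genotype = NULL,
                                     min_tile_n = 5L) {
  scale <- match.arg(scale)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  idx <- match(cohort$participant_id, names(prs))
  score <- prs[idx]
  adj_base <- prs_adjusted_baseline(cohort$baseline, score)
  y <- response_phenotype(cohort, scale)
  eqcut <- function(x) {
    # equal-count bins; stable order breaks ties deterministically
    r <- rank(x, ties.method = "first")
    as.integer(ceiling(r / (length(x) / n_bins)))
  }
  tab <- data.table::data.table(
    prs_bin = eqcut(score), baseline_bin = eqcut(adj_base), y = y)
  by_cols <- c("prs_bin", "baseline_bin")
  if (!is.null(genotype)) {
    tab$genotype <- round(genotype[idx])
    by_cols <- c(by_cols, "genotype")
  }
  grid <- tab[!is.na(y),
              list(n = .N, mean_response = mean(y),
                   sd_response = stats::sd(y)),
              by = by_cols]
  mask <- grid$n < min_tile_n
  grid$mean_response[mask] <- NA_real_
  grid$sd_response[mask] <- NA_real_
  data.table::setorderv(grid, by_cols)
  grid
}
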