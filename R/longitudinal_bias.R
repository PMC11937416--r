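#' Baseline-adjustment bias in change-score regression
#'
#' Under the longitudinal biomarker model
#' \deqn{Y_t = \beta_0 G_0 + \beta_E E_t + \gamma_E G_E E_t + \beta_D D_t + \gamma_D G_D D_t + \epsilon_t}
#' the change score \eqn{\Delta Y = Y_{t_1} - Y_{t_0} = \beta_D + \gamma_D G_D + \delta_{01}}
#' is free of the baseline genetic effect \eqn{\beta_0}: regressing it on
#' genotype estimates the pharmacogenetic effect \eqn{\gamma_D} without
#' bias. Conditioning the change score on the baseline level re-introduces
#' the baseline genetics: the adjusted slope acquires a spurious component
#' approximately \eqn{C \beta_0} with
#' \eqn{C = 1 - (\beta_E^2 + \gamma_E^2)\,corr(E_t, E_0)}, under
#' standardized model components (environment standard normal, trait
#' variance 1 at baseline). These functions give the closed form and a
#' Monte-Carlo verifier on data from \code{\link{simulate_biomarker_panel}}.
#'
#' @name longitudinal_bias
NULL

#' Expected spurious slope added by baseline adjustment
#'
#' @param beta0 baseline genetic effect per allele (trait SD units).
#' @param betaE environmental main effect.
#' @param gammaE gene-environment interaction effect.
#' @param corrE correlation of the environment between the two time
#'   points, in \[-1, 1\].
#' @return \eqn{(1 - (\beta_E^2 + \gamma_E^2) corr_E)\,\beta_0}.
#' @export
bias_coefficient <- function(beta0, betaE, gammaE, corrE) {
  if (any(corrE < -1 | corrE > 1))
    stop("`corrE` must lie in [-1, 1]", call. = FALSE)
  (1 - (betaE^2 + gammaE^2) * corrE) * beta0
}

#' Decomposition of the change score
#'
#' Splits \eqn{\Delta Y} into the drug main effect, the pharmacogenetic
#' term and the residual \eqn{\delta_{01}}, whose variance under
#' standardized components is
#' \eqn{2\sigma_\epsilon^2 + (\beta_E^2 + \gamma_E^2)\,2(1 - corr_E)}.
#'
#' @param params a \code{\link{longitudinal_model_params}} object.
#' @return list with \code{drug_term} (betaD), \code{genetic_term_per_allele}
#'   (gammaD), \code{residual_var} (var of delta01) and \code{residual_sd}.
#' @export
delta_decomposition <- function(params) {
  stopifnot(inherits(params, "longitudinal_model_params"))
  v <- 2 * params$sigma_eps^2 +
    (params$betaE^2 + params$gammaE^2) * 2 * (1 - params$corrE)
  list(drug_term = params$betaD,
       genetic_term_per_allele = params$gammaD,
       residual_var = v,
       residual_sd = sqrt(v))
}

#' Monte-Carlo verification of the baseline-adjustment bias formula
#'
#' Simulates drug-naive longitudinal data under \code{params}, fits the
#' change score on genotype with and without baseline adjustment, and
#' compares the mean adjusted-slope excess over the pharmacogenetic effect
#' (zero in controls) with the closed-form \code{\link{bias_coefficient}}.
#'
#' @param params a \code{\link{longitudinal_model_params}} object.
#' @param n participants per replicate.
#' @param replicates number of Monte-Carlo replicates (>= 100 for the
#'   agreement flag to be meaningful).
#' @param seed integer seed.
#' @return one-row data.table: theoretical bias, empirical adjusted and
#'   unadjusted bias with Monte-Carlo SEs, and agreement flags
#'   (|empirical - theoretical| < 3 SE).
#' @export
verify_bias <- function(params, n = 5000, replicates = 200, seed = 1L) {
  stopifnot(inherits(params, "longitudinal_model_params"),
            replicates >= 2, n >= 10)
  theo <- bias_coefficient(params$beta0, params$betaE, params$gammaE,
                           params$corrE)
  rng <- rng_stream(seed)
  adj <- unadj <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_change_scores(params, n, seed = rng())
    adj[r] <- stats::coef(stats::lm(sim$delta ~ sim$g + sim$y0))[["sim$g"]]
    unadj[r] <- stats::coef(stats::lm(sim$delta ~ sim$g))[["sim$g"]]
  }
  se_adj <- stats::sd(adj) / sqrt(replicates)
  se_unadj <- stats::sd(unadj) / sqrt(replicates)
  data.table::data.table(
    beta0 = params$beta0, betaE = params$betaE, gammaE = params$gammaE,
    corrE = params$corrE,
    theoretical_bias = theo,
    empirical_bias_adjusted = mean(adj),
    mc_se_adjusted = se_adj,
    empirical_bias_unadjusted = mean(unadj),
    mc_se_unadjusted = se_unadj,
    agrees_adjusted = abs(mean(adj) - theo) < 3 * se_adj,
    agrees_unadjusted = abs(mean(unadj)) < 3 * se_unadj)
}

#' Verify the bias formula over a parameter grid
#'
#' @param grid data.frame with columns beta0, betaE, gammaE, corrE (and
#'   optionally maf); sigma_eps is solved per row to close the unit
#'   variance budget.
#' @param n,replicates,seed as in \code{\link{verify_bias}}.
#' @return data.table, one row per grid point, as \code{verify_bias}.
#' @export
verify_bias_grid <- function(grid, n = 5000, replicates = 200, seed = 1L) {
  stopifnot(is.data.frame(grid),
            all(c("beta0", "betaE", "gammaE", "corrE") %in% names(grid)))
  rng <- rng_stream(seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    maf <- if ("maf" %in% names(grid)) grid$maf[i] else 0.3
    p <- longitudinal_model_params(
      beta0 = grid$beta0[i], betaE = grid$betaE[i], gammaE = grid$gammaE[i],
      gammaD = 0, betaD = 0, corrE = grid$corrE[i], maf = maf)
    verify_bias(p, n = n, replicates = replicates, seed = rng())
  })
  data.table::rbindlist(rows)
}
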