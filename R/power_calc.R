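#' GWAS power analysis via the non-centrality parameter
#'
#' Power to detect an association at a two-sided significance level
#' \code{alpha} when the association z-statistic is normal with
#' non-centrality \eqn{\sqrt{\lambda}}:
#' \deqn{power(\alpha, \lambda) = \Phi(\sqrt{\lambda} - c) + \Phi(-\sqrt{\lambda} - c)}
#' where \eqn{c = \Phi^{-1}(1 - \alpha/2)}. The NCP is scaled from a
#' discovery result to a target sample size and allele frequency as
#' \deqn{\lambda = \frac{N}{n_{obs}} \cdot \frac{\beta_{obs}^2}{se_{obs}^2}
#'   \cdot \frac{MAF(1-MAF)}{MAF_{obs}(1-MAF_{obs})}}
#' so that power transfers across ancestries that differ in allele
#' frequency at the signal.
#'
#' @name power_calc
NULL

#' Critical value of the two-sided z-test
#'
#' @param alpha two-sided significance level in (0, 1).
#' @return the upper-tail standard-normal quantile at \code{alpha/2};
#'   e.g. 5.45 at genome-wide significance 5e-8.
#' @export
#' @examples
#' critical_value(5e-8)  # 5.45
#' critical_value(0.05)  # 1.96
critical_value <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha > 1))
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  stats::qnorm(alpha / 2, lower.tail = FALSE)
}

#' Power of the two-sided z-test at a given non-centrality parameter
#'
#' @param alpha two-sided significance level.
#' @param lam non-centrality parameter (squared expected z), >= 0.
#' @return detection probability in \code{[alpha, 1]}.
#' @export
power_ncp <- function(alpha, lam) {
  if (any(lam < 0)) stop("`lam` must be non-negative", call. = FALSE)
  cc <- critical_value(alpha)
  stats::pnorm(sqrt(lam) - cc) + stats::pnorm(-sqrt(lam) - cc)
}

#' Recover a standard error from a reported effect size and p-value
#'
#' Published association tables often print beta and p but not se; under
#' the Wald z-test se = |beta| / z where z is the normal quantile of the
#' two-sided p-value. \code{stats::qnorm} is called on the upper tail so
#' extreme p-values (e.g. 1e-300) do not underflow.
#'
#' @param beta reported effect size (non-zero; sign is irrelevant).
#' @param p two-sided p-value in (0, 1).
#' @return the implied standard error.
#' @export
se_from_summary <- function(beta, p) {
  if (any(p <= 0) || any(p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (any(beta == 0)) stop("`beta` must be non-zero", call. = FALSE)
  abs(beta) / stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Discovery summary inputs for the power chain
#'
#' @param alpha two-sided significance level (default genome-wide 5e-8).
#' @param n_obs discovery sample size.
#' @param beta_obs discovery effect size.
#' @param se_obs discovery standard error; derived from \code{p_obs} when
#'   missing.
#' @param p_obs discovery p-value, used only when \code{se_obs} is missing.
#' @param maf_obs discovery minor allele frequency in (0, 0.5].
#' @param maf_target target-population minor allele frequency in (0, 0.5].
#' @param power_target desired power in (0, 1), default 0.8.
#' @param n_grid_step grid increment for the sample-size search, default 500.
#' @param n_grid_origin offset added to every grid point (default 0, i.e.
#'   multiples of the step; 1 gives grids of the form 501, 1001, ...).
#' @return an object of class \code{power_inputs}.
#' @export
power_inputs <- function(alpha = 5e-8, n_obs, beta_obs, se_obs = NULL,
                         p_obs = NULL, maf_obs, maf_target,
                         power_target = 0.8, n_grid_step = 500L,
                         n_grid_origin = 0L) {
  if (is.null(se_obs)) {
    if (is.null(p_obs))
      stop("provide either `se_obs` or `p_obs`", call. = FALSE)
    se_obs <- se_from_summary(beta_obs, p_obs)
  }
  stopifnot(alpha > 0, alpha < 1, n_obs > 0, se_obs > 0,
            power_target > 0, power_target < 1, n_grid_step >= 1)
  for (m in c(maf_obs, maf_target))
    if (m <= 0 || m > 0.5)
      stop("minor allele frequencies must lie in (0, 0.5]", call. = FALSE)
  structure(list(alpha = alpha, n_obs = n_obs, beta_obs = beta_obs,
                 se_obs = se_obs, maf_obs = maf_obs, maf_target = maf_target,
                 power_target = power_target, n_grid_step = as.integer(n_grid_step),
                 n_grid_origin = as.integer(n_grid_origin)),
            class = "power_inputs")
}

#' Non-centrality parameter at a target sample size
#'
#' @param n target sample size (> 0); vectorised.
#' @param inputs a \code{\link{power_inputs}} object.
#' @return the NCP lambda, linear in \code{n}.
#' @export
ncp <- function(n, inputs) {
  stopifnot(inherits(inputs, "power_inputs"))
  if (any(n <= 0)) stop("`n` must be positive", call. = FALSE)
  n / inputs$n_obs * (inputs$beta_obs / inputs$se_obs)^2 *
    (inputs$maf_target * (1 - inputs$maf_target)) /
    (inputs$maf_obs * (1 - inputs$maf_obs))
}

#' Minimal sample size achieving the target power
#'
#' Searches sample sizes on the grid \code{origin + k * step} (k = 1, 2, ...)
#' for the smallest value whose power meets \code{power_target}; also
#' reports the exact (un-gridded) root, which the gridded answer always
#' weakly exceeds by less than one step. Power is strictly increasing in N,
#' so the search terminates.
#'
#' @param inputs a \code{\link{power_inputs}} object.
#' @return a list with \code{n_required} (gridded), \code{n_exact}
#'   (continuous root), \code{power_at_n} and the inputs echoed back.
#' @export
required_n <- function(inputs) {
  stopifnot(inherits(inputs, "power_inputs"))
  # invert: power is monotone in lambda, lambda linear in N
  lam_root <- stats::uniroot(
    function(l) power_ncp(inputs$alpha, l) - inputs$power_target,
    lower = 0, upper = 1e6, tol = 1e-12)$root
  n_exact <- lam_root / ncp(1, inputs)
  step <- inputs$n_grid_step
  origin <- inputs$n_grid_origin
  k <- max(1L, ceiling((n_exact - origin) / step))
  n_req <- origin + k * step
  # guard against floating-point edge at the boundary
  while (power_ncp(inputs$alpha, ncp(n_req, inputs)) < inputs$power_target)
    n_req <- n_req + step
  while (n_req - step > origin &&
         power_ncp(inputs$alpha, ncp(n_req - step, inputs)) >= inputs$power_target)
    n_req <- n_req - step
  list(n_required = n_req, n_exact = n_exact,
       power_at_n = power_ncp(inputs$alpha, ncp(n_req, inputs)),
       inputs = inputs)
}

#' Required sample size across ancestries
#'
#' Convenience wrapper: one \code{required_n} call per row of an
#' (ancestry, MAF) table, as when transferring a discovery signal to
#' populations with different allele frequencies.
#'
#' @param inputs a \code{\link{power_inputs}} object (its
#'   \code{maf_target} is ignored).
#' @param maf_table data.frame with columns \code{ancestry} and \code{maf}.
#' @return data.table with ancestry, maf, n_required, n_exact.
#' @export
required_n_by_ancestry <- function(inputs, maf_table) {
  stopifnot(is.data.frame(maf_table),
            all(c("ancestry", "maf") %in% names(maf_table)))
  res <- lapply(seq_len(nrow(maf_table)), function(i) {
    inp <- inputs
    inp$maf_target <- maf_table$maf[i]
    r <- required_n(inp)
    data.table::data.table(ancestry = maf_table$ancestry[i],
                           maf = maf_table$maf[i],
                           n_required = r$n_required,
                           n_exact = r$n_exact)
  })
  data.table::rbindlist(res)
}
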