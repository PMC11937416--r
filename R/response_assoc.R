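#' Genetic association testing of drug-response phenotypes
#'
#' Per-variant ordinary least squares of the absolute (post - base) or
#' log-relative (log(post) - log(base)) biomarker difference on genotype
#' dosage plus covariates. The difference is deliberately NOT adjusted
#' for baseline levels in the correct model: conditioning a change score
#' on baseline re-introduces the baseline genetics and biases the
#' pharmacogenetic estimate (see \link{longitudinal_bias}). The
#' baseline-adjusted model is available as the explicitly biased variant
#' for comparison. The same machinery runs on drug-naive controls (two
#' spaced measures) as a negative-control scan, and on per-gene rare
#' allele burdens after inverse-normal transformation.
#'
#' @name response_assoc
NULL

#' Response phenotype on the requested scale
#'
#' @param cohort cohort table with columns baseline and post.
#' @param scale "abs" for post - base, "log" for log(post/base).
#' @return numeric vector; under "log", rows with a non-positive value
#'   are \code{NA} and their indices are attached as
#'   \code{attr(, "dropped")}.
#' @export
response_phenotype <- function(cohort, scale = c("abs", "log")) {
  scale <- match.arg(scale)
  if (scale == "abs") {
    out <- cohort$post - cohort$baseline
    attr(out, "dropped") <- integer(0)
  } else {
    ok <- cohort$baseline > 0 & cohort$post > 0
    out <- rep(NA_real_, nrow(cohort))
    out[ok] <- log(cohort$post[ok]) - log(cohort$baseline[ok])
    attr(out, "dropped") <- which(!ok)
  }
  out
}

# Build a full-rank covariate design matrix: drops constant columns with a
# warning, errors naming collinear columns.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1,
                                                                  drop = FALSE]
  const <- apply(X, 2, function(x) stats::var(x) == 0)
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) > 0 && qr(cbind(1, X))$rank < ncol(X) + 1) {
    qrX <- qr(cbind(1, X))
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop("collinear covariate column(s): ",
         paste(colnames(X)[dropped], collapse = ", "), call. = FALSE)
  }
  X
}

#' Residualize an outcome on covariates
#'
#' Joint fitting of covariates alongside the genotype is the default in
#' \code{\link{associate_variant}}; residualization is offered for
#' plotting parity (e.g. sex- and age-adjusted standardized baselines in
#' genotype-stratified figures).
#'
#' @param outcome numeric vector.
#' @param covariates data.frame of covariates.
#' @param standardize scale the residuals to SD 1.
#' @return residualized (optionally standardized) outcome.
#' @export
adjust_covariates <- function(outcome, covariates, standardize = FALSE) {
  X <- covariate_matrix(covariates, length(outcome))
  res <- if (ncol(X) == 0) outcome - mean(outcome, na.rm = TRUE)
  else stats::residuals(stats::lm(outcome ~ X, na.action = stats::na.exclude))
  if (standardize) res <- res / stats::sd(res, na.rm = TRUE)
  res
}

#' Per-variant association test
#'
#' OLS of the outcome on dosage + covariates (+ baseline when
#' \code{adjust_baseline}); Wald two-sided p-value from the normal
#' approximation (GWAS convention), or the exact t-distribution when
#' \code{exact_t} (recommended for n < 200).
#'
#' @param dosage numeric dosage vector (0..2, fractional allowed).
#' @param outcome numeric response vector.
#' @param covariates optional data.frame of covariates.
#' @param adjust_baseline logical; include the baseline level as a
#'   covariate (the biased model).
#' @param baseline numeric baseline vector, required when
#'   \code{adjust_baseline}.
#' @param variant_id label for the output row.
#' @param min_n minimum complete rows (default 30).
#' @param exact_t use Student-t rather than normal p-values.
#' @return one-row data.table: variant_id, eaf, n, beta, se, p, model,
#'   plus scale = NA (filled by callers that know it); or NULL with a
#'   message when the variant is monomorphic.
#' @export
associate_variant <- function(dosage, outcome, covariates = NULL,
                              adjust_baseline = FALSE, baseline = NULL,
                              variant_id = "variant", min_n = 30L,
                              exact_t = FALSE) {
  if (adjust_baseline && is.null(baseline))
    stop("`baseline` is required when `adjust_baseline = TRUE`",
         call. = FALSE)
  X <- covariate_matrix(covariates, length(outcome))
  if (adjust_baseline) X <- cbind(X, baseline = baseline)
  ok <- stats::complete.cases(dosage, outcome,
                              if (ncol(X) > 0) X else rep(0, length(outcome)))
  if (sum(ok) < min_n)
    stop(sprintf("only %d complete rows (< min_n = %d)", sum(ok), min_n),
         call. = FALSE)
  g <- dosage[ok]; y <- outcome[ok]
  if (stats::var(g) == 0) {
    message("variant ", variant_id, " is monomorphic; skipped")
    return(NULL)
  }
  df <- data.frame(y = y, g = g)
  if (ncol(X) > 0) df <- cbind(df, as.data.frame(X[ok, , drop = FALSE]))
  fit <- stats::lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  beta <- cf["g", "Estimate"]; se <- cf["g", "Std. Error"]
  p <- if (exact_t) 2 * stats::pt(abs(beta / se), df = fit$df.residual,
                                  lower.tail = FALSE)
  else 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  data.table::data.table(
    variant_id = variant_id, eaf = mean(g) / 2, n = sum(ok),
    beta = beta, se = se, p = max(p, .Machine$double.xmin),
    model = if (adjust_baseline) "baseline_adjusted" else "unadjusted")
}

#' Association scan over a dosage matrix
#'
#' @param dosages participants x variants dosage matrix.
#' @param outcome,covariates,adjust_baseline,baseline,min_n,exact_t as in
#'   \code{\link{associate_variant}}.
#' @param scale label ("abs"/"log") stamped on the output rows.
#' @return data.table of per-variant results (monomorphic variants are
#'   skipped with a message).
#' @export
associate_scan <- function(dosages, outcome, covariates = NULL,
                           adjust_baseline = FALSE, baseline = NULL,
                           scale = "abs", min_n = 30L, exact_t = FALSE) {
  res <- lapply(colnames(dosages), function(v)
    associate_variant(dosages[, v], outcome, covariates,
                      adjust_baseline, baseline, variant_id = v,
                      min_n = min_n, exact_t = exact_t))
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  if (nrow(out) > 0) out$scale <- scale
  out
}

#' Build a drug-naive control cohort from two spaced measures
#'
#' Selects control participants whose two measures are spaced between
#' \code{spacing_days[1]} and \code{spacing_days[2]} days (default 6
#' months to 3 years, matching the allowed interval between baseline and
#' post-treatment measures) and maps first/second onto baseline/post so
#' the association machinery is path-independent.
#'
#' @param measurements measurement table with two rows per control
#'   (participant_id, date, value).
#' @param spacing_days allowed spacing range in days.
#' @return cohort-shaped data.table (participant_id, baseline, post,
#'   delta_abs, delta_log, time_to_post_days).
#' @export
build_control_cohort <- function(measurements, spacing_days = c(183, 1095)) {
  ms <- data.table::as.data.table(measurements)
  ms$date <- as.Date(ms$date)
  data.table::setorder(ms, participant_id, date)
  first <- ms[, .SD[1], by = "participant_id"]
  second <- ms[, .SD[.N], by = "participant_id"]
  spacing <- as.numeric(second$date - first$date)
  keep <- spacing >= spacing_days[1] & spacing <= spacing_days[2]
  b <- first$value[keep]; p <- second$value[keep]
  dl <- rep(NA_real_, length(b))
  pos <- b > 0 & p > 0
  dl[pos] <- log(p[pos]) - log(b[pos])
  data.table::data.table(
    participant_id = first$participant_id[keep],
    baseline = b, post = p, delta_abs = p - b, delta_log = dl,
    time_to_post_days = spacing[keep])
}

#' Longitudinal-change scan in drug-naive controls
#'
#' The negative control for treatment specificity: identical machinery
#' with the first/second measure replacing baseline/post. Under the
#' correct (unadjusted) model, variants with purely pharmacogenetic
#' effects show no signal here; under baseline adjustment, variants with
#' baseline effects spuriously associate.
#'
#' @param control_cohort output of \code{\link{build_control_cohort}}.
#' @param dosages dosage matrix with rownames matching participant ids.
#' @param covariates,adjust_baseline,scale,min_n,exact_t as in
#'   \code{\link{associate_scan}}.
#' @return data.table of per-variant results.
#' @export
control_change_scan <- function(control_cohort, dosages, covariates = NULL,
                                adjust_baseline = FALSE, scale = "abs",
                                min_n = 30L, exact_t = FALSE) {
  idx <- match(control_cohort$participant_id, rownames(dosages))
  if (anyNA(idx))
    stop("control participants missing from the dosage matrix: ",
         paste(utils::head(control_cohort$participant_id[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  y <- if (scale == "abs") control_cohort$delta_abs
  else control_cohort$delta_log
  associate_scan(dosages[idx, , drop = FALSE], y, covariates,
                 adjust_baseline, baseline = control_cohort$baseline,
                 scale = scale, min_n = min_n, exact_t = exact_t)
}

#' Inverse-normal (inverse quantile) transformation
#'
#' Ranks (ties to the average rank) mapped through the standard-normal
#' quantile of (rank - 0.5)/n; used for rare-variant outcomes to temper
#' false positives from non-normal tails.
#'
#' @param x numeric vector (n >= 2, not all equal).
#' @return transformed vector with mean ~0 and SD ~1; rank-invariant
#'   under monotone transforms of the input.
#' @export
inverse_normal_transform <- function(x) {
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  if (length(unique(x[!is.na(x)])) < 2)
    stop("all values equal: ranks undefined", call. = FALSE)
  r <- rank(x, ties.method = "average", na.last = "keep")
  stats::qnorm((r - 0.5) / sum(!is.na(x)))
}

#' Additive rare-variant burden test
#'
#' Per-participant burden = sum of qualifying minor-allele dosages
#' (variants with MAF below \code{maf_threshold}), regressed on the
#' inverse-normal-transformed outcome with covariates, per gene.
#'
#' @param dosages participants x variants dosage matrix.
#' @param outcome numeric response (transformed internally when
#'   \code{transform = TRUE}).
#' @param gene_map data.frame (variant_id, gene) mapping variants to
#'   genes.
#' @param covariates optional covariate data.frame.
#' @param maf_threshold qualifying-variant MAF ceiling (default 0.01).
#' @param transform apply \code{\link{inverse_normal_transform}} first.
#' @param min_n minimum complete rows.
#' @return data.table, one row per gene with >= 1 qualifying variant and
#'   >= 1 carrier: gene, n_variants, n_carriers, beta, se, p.
#' @export
burden_additive <- function(dosages, outcome, gene_map, covariates = NULL,
                            maf_threshold = 0.01, transform = TRUE,
                            min_n = 30L) {
  stopifnot(all(c("variant_id", "gene") %in% names(gene_map)))
  y <- if (transform) inverse_normal_transform(outcome) else outcome
  maf <- pmin(colMeans(dosages, na.rm = TRUE) / 2,
              1 - colMeans(dosages, na.rm = TRUE) / 2)
  rows <- lapply(unique(gene_map$gene), function(gn) {
    vars <- intersect(gene_map$variant_id[gene_map$gene == gn],
                      colnames(dosages)[maf < maf_threshold])
    if (length(vars) == 0) return(NULL)
    burden <- rowSums(dosages[, vars, drop = FALSE])
    carriers <- sum(burden > 0, na.rm = TRUE)
    if (carriers == 0) {
      message("gene ", gn, ": no carriers; skipped")
      return(NULL)
    }
    r <- associate_variant(burden, y, covariates, variant_id = gn,
                           min_n = min_n)
    if (is.null(r)) return(NULL)
    data.table::data.table(gene = gn, n_variants = length(vars),
                           n_carriers = carriers, n = r$n,
                           beta = r$beta, se = r$se, p = r$p)
  })
  data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

#' Genotype-stratified summary with slope
#'
#' Per-genotype means, SDs and counts of a (covariate-adjusted) outcome
#' plus the regression slope b on dosage with its significance tier —
#' the numbers behind genotype-stratified panel figures. Genotype groups
#' smaller than \code{min_group_n} are omitted from the group table
#' (noted), mirroring the omission of rare homozygote strata.
#'
#' @param g dosage vector (rounded to 0/1/2 for grouping).
#' @param outcome numeric outcome.
#' @param covariates optional covariate data.frame (e.g. sex, age),
#'   residualized out before summarising and included in the slope fit.
#' @param baseline,adjust_baseline baseline adjustment of the slope (the
#'   biased variant) when requested.
#' @param min_group_n smallest reported genotype group (default 5).
#' @param standardize standardize the adjusted outcome before summarising.
#' @return list: groups (genotype, n, mean, sd), omitted_groups, slope
#'   (b), se, p, tier ("ns", "nominal" p<=0.05, "strong" p<1e-3,
#'   "genome-wide" p<5e-8).
#' @export
genotype_stratified_summary <- function(g, outcome, covariates = NULL,
                                        baseline = NULL,
                                        adjust_baseline = FALSE,
                                        min_group_n = 5L,
                                        standardize = TRUE) {
  geno <- round(g)
  if (length(unique(geno[!is.na(geno)])) < 2)
    stop("monomorphic genotype: nothing to stratify", call. = FALSE)
  adj <- if (!is.null(covariates))
    adjust_covariates(outcome, covariates, standardize = standardize)
  else if (standardize) as.numeric(scale(outcome)) else outcome
  tab <- data.table::data.table(genotype = geno, y = adj)
  grp <- tab[!is.na(genotype) & !is.na(y),
             list(n = .N, mean = mean(y), sd = stats::sd(y)),
             by = "genotype"]
  data.table::setorder(grp, genotype)
  omitted <- grp$genotype[grp$n < min_group_n]
  grp <- grp[grp$n >= min_group_n, ]
  if (nrow(grp) < 2)
    stop("fewer than two genotype groups meet the size floor",
         call. = FALSE)
  fit <- associate_variant(g, adj, covariates = covariates,
                           adjust_baseline = adjust_baseline,
                           baseline = baseline, min_n = 2L, exact_t = TRUE)
  tier <- if (fit$p < 5e-8) "genome-wide" else if (fit$p < 1e-3) "strong"
  else if (fit$p <= 0.05) "nominal" else "ns"
  list(groups = grp, omitted_groups = omitted,
       slope = fit$beta, se = fit$se, p = fit$p, tier = tier)
}

#' Write association results as GWAS summary statistics
#'
#' Delimited text with the conventional column set SNP, CHR, POS, EA, OA,
#' EAF, N, BETA, SE, P, MODEL, SCALE; variant metadata columns absent
#' from the results are filled with NA.
#'
#' @param results data.table from \code{\link{associate_scan}}.
#' @param path output file.
#' @param variant_meta optional data.frame (variant_id, chr, pos, ea, oa).
#' @param header_lines optional comment lines (e.g. seed / config hash)
#'   written before the table, prefixed with "#".
#' @return invisibly, the path.
#' @export
write_sumstats <- function(results, path, variant_meta = NULL,
                           header_lines = NULL) {
  out <- data.table::data.table(
    SNP = results$variant_id, CHR = NA, POS = NA, EA = NA, OA = NA,
    EAF = results$eaf, N = results$n, BETA = results$beta,
    SE = results$se, P = results$p, MODEL = results$model,
    SCALE = results$scale)
  if (!is.null(variant_meta)) {
    m <- match(out$SNP, variant_meta$variant_id)
    for (src_dst in list(c("chr", "CHR"), c("pos", "POS"),
                         c("ea", "EA"), c("oa", "OA")))
      if (src_dst[1] %in% names(variant_meta))
        out[[src_dst[2]]] <- variant_meta[[src_dst[1]]][m]
  }
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), path)
  data.table::fwrite(out, path, sep = "\t",
                     append = !is.null(header_lines), col.names = TRUE)
  invisible(path)
}

#' Bonferroni significance thresholds
#'
#' @param n_tests number of tests (e.g. genes in a burden scan, or
#'   variants followed up for replication).
#' @param alpha family-wise error rate (default 0.05).
#' @return per-test threshold alpha / n_tests.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha <= 1)
  alpha / n_tests
}
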