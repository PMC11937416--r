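test_that("response phenotypes follow the exact elementwise formulas", {
  co <- data.table::data.table(baseline = c(4, 3, 2, 4), post = c(2, 3, 0, 8))
  expect_equal(response_phenotype(co, "abs"), c(-2, 0, -2, 4),
               ignore_attr = TRUE)
  lg <- response_phenotype(co, "log")
  expect_equal(lg[1], log(0.5), tolerance = 1e-12)
  expect_equal(lg[2], 0)
  expect_true(is.na(lg[3]))          # post = 0 rejected under log
  expect_equal(attr(lg, "dropped"), 3L)
  expect_equal(lg[4], log(2), tolerance = 1e-12)
})

test_that("per-variant OLS equals the closed-form matrix oracle", {
  # 6-row worked fixture
  g6 <- c(0, 1, 2, 0, 1, 2)
  y6 <- c(0.2, -0.4, -1.1, 0.5, -0.2, -0.9)
  r6 <- associate_variant(g6, y6, min_n = 2L)
  o6 <- ols_oracle(g6, y6)
  expect_equal(r6$beta, o6$beta, tolerance = 1e-10)
  expect_equal(r6$se, o6$se, tolerance = 1e-10)
  expect_equal(r6$eaf, mean(g6) / 2)
  # 50-row instance with covariates and baseline adjustment
  set.seed(42)
  g <- rbinom(50, 2, 0.3); base <- rnorm(50, 4); y <- rnorm(50)
  covs <- data.frame(sex = rbinom(50, 1, 0.5), age = rnorm(50, 60, 8))
  r <- associate_variant(g, y, covs, adjust_baseline = TRUE,
                         baseline = base, min_n = 30L)
  o <- ols_oracle(g, y, cbind(covs$sex, covs$age, base))
  expect_equal(r$beta, o$beta, tolerance = 1e-10)
  expect_equal(r$se, o$se, tolerance = 1e-10)
  expect_equal(r$model, "baseline_adjusted")
})

test_that("monomorphic and underpowered inputs are handled explicitly", {
  y <- rnorm(40)
  expect_message(r <- associate_variant(rep(2, 40), y, min_n = 30L),
                 "monomorphic")
  expect_null(r)
  expect_error(associate_variant(rbinom(10, 2, 0.5), rnorm(10), min_n = 30L),
               "complete rows")
})

test_that("constant covariates drop with a warning; collinear ones error", {
  set.seed(7)
  g <- rbinom(100, 2, 0.4); y <- rnorm(100)
  expect_warning(r <- associate_variant(g, y, data.frame(k = rep(1, 100)),
                                        min_n = 30L), "constant")
  r0 <- associate_variant(g, y, min_n = 30L)
  expect_equal(r$beta, r0$beta, tolerance = 1e-12)
  x <- rnorm(100)
  expect_error(associate_variant(g, y, data.frame(a = x, b = 2 * x),
                                 min_n = 30L), "collinear")
})

test_that("joint fit equals residualize-then-fit on orthogonal covariates", {
  set.seed(11)
  g <- rbinom(200, 2, 0.3)
  x <- rnorm(200)
  x_orth <- residuals(lm(x ~ g))  # orthogonalized against the genotype
  y <- 0.3 * g + 0.5 * x_orth + rnorm(200)
  joint <- associate_variant(g, y, data.frame(x = x_orth), min_n = 30L)
  y_res <- adjust_covariates(y, data.frame(x = x_orth))
  two_step <- associate_variant(g, y_res, min_n = 30L)
  expect_equal(joint$beta, two_step$beta, tolerance = 1e-10)
})

test_that("type-I error of the unadjusted test is calibrated", {
  # full generative null: gammaD = 0 and beta0 = 0
  p <- longitudinal_model_params(beta0 = 0, betaE = 0.6, corrE = 0.5,
                                 maf = 0.3)
  rng <- pgxehr:::rng_stream(101)
  rej <- 0L
  n_reps <- 1000L
  for (r in seq_len(n_reps)) {
    sim <- pgxehr:::simulate_change_scores(p, 400, seed = rng())
    res <- associate_variant(sim$g, sim$delta, min_n = 30L)
    if (!is.null(res) && res$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_reps - 0.05), 0.02)
})

test_that("delta_abs associations are shift invariant; delta_log scale invariant", {
  set.seed(5)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  base <- rnorm(n, 4, 0.5); post <- base - 0.8 + 0.2 * g + rnorm(n, 0, 0.3)
  co <- data.table::data.table(participant_id = as.character(1:n),
                               baseline = base, post = post)
  co_shift <- data.table::copy(co)
  co_shift$baseline <- co$baseline + 7; co_shift$post <- co$post + 7
  a1 <- associate_variant(g, response_phenotype(co, "abs"), min_n = 30L)
  a2 <- associate_variant(g, response_phenotype(co_shift, "abs"), min_n = 30L)
  expect_equal(a1$beta, a2$beta, tolerance = 1e-12)
  expect_equal(a1$p, a2$p, tolerance = 1e-12)
  co_scale <- data.table::copy(co)
  co_scale$baseline <- co$baseline * 3.2; co_scale$post <- co$post * 3.2
  l1 <- associate_variant(g, response_phenotype(co, "log"), min_n = 30L)
  l2 <- associate_variant(g, response_phenotype(co_scale, "log"), min_n = 30L)
  expect_equal(l1$beta, l2$beta, tolerance = 1e-10)
})

test_that("inverse-normal transform has the rank-map properties", {
  out <- inverse_normal_transform(c(1, 2, 3))
  q <- qnorm(5 / 6)
  expect_equal(out, c(-q, 0, q), tolerance = 1e-12)
  x <- rexp(50)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(log(x)),
               tolerance = 1e-12)  # monotone-transform invariance
  set.seed(9)
  z <- inverse_normal_transform(rnorm(1e4))
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_lt(unname(ks$statistic), 0.02)
  expect_lt(abs(mean(z)), 0.01)
  expect_equal(sd(z), 1, tolerance = 0.01)
  expect_error(inverse_normal_transform(rep(1, 5)), "all values equal")
  expect_error(inverse_normal_transform(1), "two observations")
})

test_that("burden test reduces to the single-variant result and recovers effects", {
  set.seed(21)
  n <- 5000
  rare <- rbinom(n, 2, 0.004)
  common <- rbinom(n, 2, 0.3)
  dos <- cbind(rv1 = rare, cv1 = common)
  y <- rnorm(n)
  gm <- data.frame(variant_id = c("rv1", "cv1"), gene = c("GENE1", "GENE1"))
  # the common variant fails the MAF < 0.01 mask, so the gene's burden is rv1
  b <- burden_additive(dos, y, gm, transform = FALSE, min_n = 30L)
  sv <- associate_variant(rare, y, min_n = 30L)
  expect_equal(b$beta, sv$beta, tolerance = 1e-12)
  expect_equal(b$n_variants, 1L)
  # injected burden effect on the INT scale is recovered within the CI
  set.seed(22)
  dos2 <- sapply(1:5, function(i) rbinom(n, 2, 0.004))
  colnames(dos2) <- paste0("v", 1:5)
  burden_true <- rowSums(dos2)
  y2 <- 0.5 * burden_true + rnorm(n)
  gm2 <- data.frame(variant_id = colnames(dos2), gene = "GENE2")
  b2 <- burden_additive(dos2, y2, gm2, transform = TRUE, min_n = 30L)
  # INT compresses the scale; recovery is checked on the untransformed fit
  b2_raw <- burden_additive(dos2, y2, gm2, transform = FALSE, min_n = 30L)
  expect_lt(abs(b2_raw$beta - 0.5), 1.96 * b2_raw$se)
  expect_lt(b2$p, 1e-6)
  expect_gt(b2$n_carriers, 0)
})

test_that("burden p-values are uniform under permutation", {
  set.seed(23)
  n <- 2000; n_genes <- 40
  dos <- sapply(seq_len(3 * n_genes), function(i) rbinom(n, 2, 0.005))
  colnames(dos) <- paste0("v", seq_len(ncol(dos)))
  gm <- data.frame(variant_id = colnames(dos),
                   gene = rep(paste0("G", seq_len(n_genes)), each = 3))
  y <- sample(rnorm(n))  # outcome permuted: no structure
  b <- burden_additive(dos, y, gm, min_n = 30L)
  expect_gte(nrow(b), n_genes - 2)
  rej <- mean(b$p < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(b)) + 0.01)
})

test_that("control scan is null at PGx-only variants, inflated when adjusted", {
  # pharmacogenetic-only variant: no signal in drug-naive change
  p_pgx <- longitudinal_model_params(beta0 = 0, betaE = 0.6, gammaD = 0.3,
                                     corrE = 0.5, maf = 0.3)
  rng <- pgxehr:::rng_stream(55)
  rej_unadj <- rej_base_adj <- 0L
  p_base <- longitudinal_model_params(beta0 = 0.3, betaE = 0.6, corrE = 0.5,
                                      maf = 0.3)
  for (r in 1:200) {
    sim <- pgxehr:::simulate_change_scores(p_pgx, 500, seed = rng())
    res <- associate_variant(sim$g, sim$delta, min_n = 30L)
    if (res$p < 0.05) rej_unadj <- rej_unadj + 1L
    simb <- pgxehr:::simulate_change_scores(p_base, 500, seed = rng())
    resb <- associate_variant(simb$g, simb$delta, adjust_baseline = TRUE,
                              baseline = simb$y0, min_n = 30L)
    if (resb$p < 0.05) rej_base_adj <- rej_base_adj + 1L
  }
  expect_lt(abs(rej_unadj / 200 - 0.05), 0.05)  # calibrated negative control
  expect_gt(rej_base_adj / 200, 0.5)            # baseline adjustment inflates
})

test_that("control cohort machinery enforces the spacing window", {
  ms <- data.table::data.table(
    participant_id = rep(c("A", "B", "C"), each = 2),
    date = as.Date("2012-01-01") + c(0, 300, 0, 100, 0, 1200),
    value = c(4, 3.5, 4, 3, 5, 4))
  cc <- build_control_cohort(ms)
  expect_equal(cc$participant_id, "A")  # B spaced 100 d, C spaced 1200 d
  expect_equal(cc$delta_abs, -0.5)
  p <- longitudinal_model_params(beta0 = 0.3, betaE = 0.6, corrE = 0.5,
                                 maf = 0.3)
  design <- cohort_design(n_treated = 0, n_controls = 800, seed = 3)
  dos <- simulate_genotypes(800, c(p$maf, 0.2), seed = 3)
  panel <- simulate_biomarker_panel(dos, p, design, seed = 3)
  cc2 <- build_control_cohort(panel$measurements)
  scan <- control_change_scan(cc2, dos)
  expect_equal(nrow(scan), 2L)
  expect_true(all(scan$model == "unadjusted"))
  scan_adj <- control_change_scan(cc2, dos, adjust_baseline = TRUE)
  # baseline-effect variant: adjustment manufactures signal in controls
  expect_lt(scan_adj$p[scan_adj$variant_id == "var001"],
            scan$p[scan$variant_id == "var001"])
})

test_that("genotype-stratified summaries reproduce the panel patterns", {
  # baseline-only variant: baseline slope significant, change slopes null
  p_base <- longitudinal_model_params(beta0 = 0.3, betaE = 0.6, corrE = 0.5,
                                      maf = 0.3)
  sim <- pgxehr:::simulate_change_scores(p_base, 4000, seed = 74)
  s_base <- genotype_stratified_summary(sim$g, sim$y0)
  expect_lt(s_base$p, 1e-3)
  s_chg <- genotype_stratified_summary(sim$g, sim$delta)
  expect_gt(s_chg$p, 0.05)
  expect_equal(s_chg$tier, "ns")
  # pharmacogenetic-only variant: treated change slope significant,
  # control slope null, baseline adjustment leaves the treated slope alone
  p_pgx <- longitudinal_model_params(beta0 = 0, betaE = 0.6, gammaD = 0.25,
                                     corrE = 0.5, maf = 0.3)
  tr <- pgxehr:::simulate_change_scores(p_pgx, 4000, seed = 72, d1 = 1)
  ct <- pgxehr:::simulate_change_scores(p_pgx, 4000, seed = 73, d1 = 0)
  s_tr <- genotype_stratified_summary(tr$g, tr$delta)
  s_ct <- genotype_stratified_summary(ct$g, ct$delta)
  s_tr_adj <- genotype_stratified_summary(tr$g, tr$delta, baseline = tr$y0,
                                          adjust_baseline = TRUE)
  expect_lt(s_tr$p, 1e-3)
  expect_gt(s_ct$p, 0.05)
  expect_lt(abs(s_tr_adj$slope - s_tr$slope), 3 * s_tr$se)
  # groups below the size floor are omitted with a note
  g_rare <- c(rep(0, 50), rep(1, 20), rep(2, 3))
  y <- rnorm(73)
  s_rare <- genotype_stratified_summary(g_rare, y, min_group_n = 5L)
  expect_equal(s_rare$omitted_groups, 2)
  expect_equal(nrow(s_rare$groups), 2L)
  expect_error(genotype_stratified_summary(rep(1, 50), rnorm(50)),
               "monomorphic")
})

test_that("summary statistics writer emits the conventional columns", {
  set.seed(3)
  g <- matrix(rbinom(200, 2, 0.3), ncol = 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  res <- associate_scan(g, rnorm(100), scale = "abs", min_n = 30L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(res, path,
                 variant_meta = data.frame(variant_id = c("rs1", "rs2"),
                                           chr = c(1, 2), pos = c(100, 200),
                                           ea = c("A", "C"), oa = c("G", "T")),
                 header_lines = "seed=1")
  lines <- readLines(path)
  expect_match(lines[1], "^# seed=1")
  tab <- data.table::fread(path, skip = 1)
  expect_equal(names(tab), c("SNP", "CHR", "POS", "EA", "OA", "EAF", "N",
                             "BETA", "SE", "P", "MODEL", "SCALE"))
  expect_equal(tab$SNP, c("rs1", "rs2"))
  expect_equal(tab$CHR, c(1, 2))
})

test_that("Bonferroni thresholds are plain division", {
  expect_equal(bonferroni_threshold(18983), 0.05 / 18983)
  expect_equal(bonferroni_threshold(10), 0.005)
  expect_error(bonferroni_threshold(0), "n_tests")
})
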