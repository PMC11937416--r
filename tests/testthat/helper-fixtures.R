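# In-code fixtures shared across the suite.

# 12-participant QC fixture with one engineered failure per cascade step.
# Hand trace (stringent config, min_drug_group_size = 1, min baseline 2,
# add-on policy "fibrate"): start day 0 = 2010-06-01 for everyone.
# Compliant template: primary simvastatin 40mg on days 0/50/100/150/200/250,
# unrelated GP record day -800, baseline measure day -30 (4.0), post
# measure day 180 (3.0). Completeness over [0, 180): 3 bins of 61 days
# (the 58-day remainder >= 30.5 counts), all covered -> 1.0.
#   QC01 step (i):   baseline measure removed
#   QC02 step (ii):  unrelated record at day -300 only (< 2 years)
#   QC03 step (iii): no related prescription after the post measure
#   QC04 step (iv):  combination product (simvastatin/ezetimibe) day 100
#   QC05 step (v):   scripts on days 0 and 300 only -> completeness 1/3
#   QC06 step (vi):  baseline value 1.5 < 2
#   QC07 same-class: rosuvastatin (same_class_other) on day -100
#   QC08..QC12:      fully compliant
# Removals: (1,1,1,1,1,1,1) then 0s; final cohort = 5.
make_qc_fixture <- function() {
  start <- as.Date("2010-06-01")
  rx_row <- function(id, day, class = "primary", name = "simvastatin",
                     desc = "simvastatin 40mg tablets") {
    data.table::data.table(participant_id = id, date = start + day,
                           drug_code = "S01", drug_class = class,
                           drug_name = name, description = desc)
  }
  standard_rx <- function(id, days = c(0, 50, 100, 150, 200, 250)) {
    rbind(do.call(rbind, lapply(days, function(d) rx_row(id, d))),
          rx_row(id, -800, class = "unrelated", name = "consultation",
                 desc = "GP consultation"))
  }
  ms_row <- function(id, day, value) {
    data.table::data.table(participant_id = id, date = start + day,
                           biomarker_code = "LDL", value = value,
                           unit = "mmol/L")
  }
  standard_ms <- function(id, base = 4.0, post = 3.0) {
    rbind(ms_row(id, -30, base), ms_row(id, 180, post))
  }
  ids <- sprintf("QC%02d", 1:12)
  rx <- list(); ms <- list()
  for (id in ids) { rx[[id]] <- standard_rx(id); ms[[id]] <- standard_ms(id) }
  ms[["QC01"]] <- ms_row("QC01", 180, 3.0)                      # (i)
  rx[["QC02"]] <- rbind(do.call(rbind, lapply(c(0, 50, 100, 150, 200, 250),
                                              function(d) rx_row("QC02", d))),
                        rx_row("QC02", -300, class = "unrelated",
                               name = "consultation",
                               desc = "GP consultation"))       # (ii)
  rx[["QC03"]] <- rbind(do.call(rbind, lapply(c(0, 50, 100, 150),
                                              function(d) rx_row("QC03", d))),
                        rx_row("QC03", -800, class = "unrelated",
                               name = "consultation",
                               desc = "GP consultation"))       # (iii)
  rx[["QC04"]] <- rbind(standard_rx("QC04"),
                        rx_row("QC04", 100, class = "combination",
                               name = "simvastatin/ezetimibe",
                               desc = "simvastatin/ezetimibe 40mg"))  # (iv)
  rx[["QC05"]] <- rbind(do.call(rbind, lapply(c(0, 300),
                                              function(d) rx_row("QC05", d))),
                        rx_row("QC05", -800, class = "unrelated",
                               name = "consultation",
                               desc = "GP consultation"))       # (v)
  ms[["QC06"]] <- rbind(ms_row("QC06", -30, 1.5), ms_row("QC06", 180, 1.2))  # (vi)
  rx[["QC07"]] <- rbind(standard_rx("QC07"),
                        rx_row("QC07", -100, class = "same_class_other",
                               name = "rosuvastatin",
                               desc = "rosuvastatin 10mg tablets"))  # same-class
  list(prescriptions = data.table::rbindlist(rx),
       measurements = data.table::rbindlist(ms),
       start = start)
}

qc_fixture_config <- function(scenario = "stringent") {
  filter_config(scenario, min_baseline_level = 2,
                min_drug_group_size = 1, addon_policy = "fibrate")
}

# Closed-form OLS oracle: beta/se for the coefficient of the second design
# column (the genotype), written directly from (X'X)^-1 X'y algebra.
ols_oracle <- function(g, y, covs = NULL) {
  X <- cbind(1, g)
  if (!is.null(covs)) X <- cbind(X, as.matrix(covs))
  XtX_inv <- solve(t(X) %*% X)
  bh <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% bh
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = unname(bh[2, 1]), se = unname(sqrt(s2 * XtX_inv[2, 2])))
}

# Root-solve oracle for the z-score implied by a two-sided p-value, done on
# the log tail so extreme p-values stay representable.
z_from_p_oracle <- function(p) {
  stats::uniroot(function(z) stats::pnorm(z, lower.tail = FALSE,
                                          log.p = TRUE) - log(p / 2),
                 c(0.1, 50), tol = 1e-12)$root
}
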