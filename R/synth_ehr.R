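#' Synthetic longitudinal EHR generator
#'
#' Generates genotypes, prescription histories and sparse biomarker
#' measurements with the statistical structure the downstream analyses
#' assume, so cohort extraction, association testing and the
#' baseline-adjustment bias theory can all be exercised without access to
#' controlled biobank data. Biomarker values follow the longitudinal model
#' \deqn{Y_t = \beta_0 G_0 + \beta_E E_t + \gamma_E G_E E_t + \beta_D D_t + \gamma_D G_D D_t + \epsilon_t}
#' with a single variant playing all three genetic roles
#' (G0 = GE = GD), a standard-normal environment with inter-visit
#' correlation \code{corrE}, and the trait variance normalized to 1 at
#' baseline by solving the residual SD from the variance budget.
#'
#' @name synth_ehr
NULL

# Deterministic stream of sub-seeds (< 2^31) derived from one master seed,
# so nested simulations never share or disturb the global RNG sequence.
rng_stream <- function(seed) {
  seed <- as.double(seed)
  i <- 0
  function() {
    i <<- i + 1
    as.integer((seed * 48271 + i * 104729) %% 2147483629 + 1)
  }
}

#' Parameters of the longitudinal biomarker model
#'
#' The variance budget at baseline is
#' \eqn{\beta_0^2\,2\,maf(1-maf) + \beta_E^2 + \gamma_E^2 + \sigma_\epsilon^2
#'  = total\_var} (default 1). When \code{sigma_eps} is omitted it is
#' solved from the budget; when given, the budget must close within 1e-9.
#'
#' @param beta0 baseline genetic effect per allele (trait SD units).
#' @param betaE environmental main effect.
#' @param gammaE gene-environment interaction effect.
#' @param betaD drug main effect (trait units; applies when D switches
#'   from 0 to 1).
#' @param gammaD pharmacogenetic effect per allele.
#' @param corrE correlation of the environment between the two time
#'   points, in \[-1, 1\].
#' @param maf causal-variant minor allele frequency in (0, 0.5].
#' @param sigma_eps residual measurement-noise SD; solved from the budget
#'   when \code{NULL}.
#' @param total_var trait variance at baseline (default 1).
#' @return an object of class \code{longitudinal_model_params}; the
#'   implied change-score residual SD (\code{delta01_sd}) is attached.
#' @export
longitudinal_model_params <- function(beta0 = 0, betaE = 0.6, gammaE = 0,
                                      betaD = 0, gammaD = 0, corrE = 0.5,
                                      maf = 0.3, sigma_eps = NULL,
                                      total_var = 1) {
  if (maf <= 0 || maf > 0.5)
    stop("`maf` must lie in (0, 0.5]", call. = FALSE)
  if (corrE < -1 || corrE > 1)
    stop("`corrE` must lie in [-1, 1]", call. = FALSE)
  explained <- beta0^2 * 2 * maf * (1 - maf) + betaE^2 + gammaE^2
  if (is.null(sigma_eps)) {
    resid <- total_var - explained
    if (resid < 0)
      stop(sprintf(paste0("variance budget violated: genetic + environmental",
                          " components explain %.4f > total_var = %.4f"),
                   explained, total_var), call. = FALSE)
    sigma_eps <- sqrt(resid)
  } else {
    if (sigma_eps < 0) stop("`sigma_eps` must be >= 0", call. = FALSE)
    gap <- explained + sigma_eps^2 - total_var
    if (abs(gap) > 1e-9)
      stop(sprintf("variance budget violated: residual %.3e (must be 0 +/- 1e-9)",
                   gap), call. = FALSE)
  }
  out <- structure(list(beta0 = beta0, betaE = betaE, gammaE = gammaE,
                        betaD = betaD, gammaD = gammaD, corrE = corrE,
                        maf = maf, sigma_eps = sigma_eps,
                        total_var = total_var),
                   class = "longitudinal_model_params")
  out$delta01_sd <- sqrt(2 * sigma_eps^2 + (betaE^2 + gammaE^2) * 2 * (1 - corrE))
  out
}

#' Cohort and visit-schedule design for the synthetic EHR
#'
#' @param n_treated,n_controls participant counts.
#' @param prescription_interval_days mean gap between repeat prescriptions.
#' @param skip_probability per-interval chance a prescription is missing.
#' @param dose_change_probability chance the dose changes mid-follow-up.
#' @param addon_probability chance an allowed add-on class is co-prescribed.
#' @param baseline_offset_range baseline measure offset (days, relative to
#'   first prescription), drawn uniformly; default \[-100, 0\].
#' @param post_offset_meanlog,post_offset_sdlog log-normal post-treatment
#'   measure offset; defaults give a median near 200 days.
#' @param followup_days length of the prescription follow-up to simulate.
#' @param control_spacing_days range (days) between the two control
#'   measures; default \[183, 1095\] (6 months to 3 years).
#' @param seed integer seed.
#' @return an object of class \code{cohort_design}.
#' @export
cohort_design <- function(n_treated = 1000, n_controls = 1000,
                          prescription_interval_days = 30,
                          skip_probability = 0,
                          dose_change_probability = 0,
                          addon_probability = 0,
                          baseline_offset_range = c(-100, 0),
                          post_offset_meanlog = log(200),
                          post_offset_sdlog = 0.3,
                          followup_days = 365,
                          control_spacing_days = c(183, 1095),
                          seed = 1L) {
  stopifnot(n_treated >= 0, n_controls >= 0,
            prescription_interval_days > 0, followup_days > 0)
  for (p in c(skip_probability, dose_change_probability, addon_probability))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(length(baseline_offset_range) == 2,
            baseline_offset_range[1] <= baseline_offset_range[2],
            length(control_spacing_days) == 2,
            control_spacing_days[1] <= control_spacing_days[2])
  structure(list(n_treated = n_treated, n_controls = n_controls,
                 prescription_interval_days = prescription_interval_days,
                 skip_probability = skip_probability,
                 dose_change_probability = dose_change_probability,
                 addon_probability = addon_probability,
                 baseline_offset_range = baseline_offset_range,
                 post_offset_meanlog = post_offset_meanlog,
                 post_offset_sdlog = post_offset_sdlog,
                 followup_days = followup_days,
                 control_spacing_days = control_spacing_days,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a genotype dosage matrix
#'
#' Hardy-Weinberg genotypes: each dosage is binomial(2, maf),
#' independently per variant.
#'
#' @param n participant count (> 0).
#' @param mafs vector of minor allele frequencies, each in (0, 0.5].
#' @param seed integer seed.
#' @return integer matrix (n x length(mafs)) with values 0/1/2; row names
#'   are participant ids \code{P000001, ...}, column names variant ids.
#' @export
simulate_genotypes <- function(n, mafs, seed = 1L) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("each maf must lie in (0, 0.5]", call. = FALSE)
  set.seed(seed)
  g <- vapply(mafs, function(m) stats::rbinom(n, 2L, m), integer(n))
  g <- matrix(g, nrow = n)
  dimnames(g) <- list(sprintf("P%06d", seq_len(n)),
                      sprintf("var%03d", seq_along(mafs)))
  g
}

# Core draw of the two-visit biomarker model for one genotype vector.
# Returns latent environments and the two trait values; D is the drug
# indicator at visit 1 (0 for controls, 1 for treated).
draw_two_visits <- function(g, params, d1) {
  n <- length(g)
  e0 <- stats::rnorm(n)
  e1 <- params$corrE * e0 + sqrt(1 - params$corrE^2) * stats::rnorm(n)
  y0 <- params$beta0 * g + params$betaE * e0 + params$gammaE * g * e0 +
    stats::rnorm(n, 0, params$sigma_eps)
  y1 <- params$beta0 * g + params$betaE * e1 + params$gammaE * g * e1 +
    params$betaD * d1 + params$gammaD * g * d1 +
    stats::rnorm(n, 0, params$sigma_eps)
  list(e0 = e0, e1 = e1, y0 = y0, y1 = y1)
}

# Minimal change-score simulation used by the bias verifier: one variant,
# drug-naive by default (d1 = 0).
simulate_change_scores <- function(params, n, seed = 1L, d1 = 0) {
  set.seed(seed)
  g <- stats::rbinom(n, 2L, params$maf)
  v <- draw_two_visits(g, params, d1)
  data.table::data.table(g = g, y0 = v$y0, y1 = v$y1, delta = v$y1 - v$y0)
}

#' Simulate the two-visit biomarker panel
#'
#' Treated participants get a baseline measure (drug status 0) and a
#' post-treatment measure (drug status 1); controls get two drug-free
#' measures. Schemas are identical for both groups so downstream code is
#' path-independent. Values can be shifted to a positive clinical scale
#' via \code{value_mean}/\code{value_sd} (e.g. LDL-C in mmol/L) so the
#' log-relative response is well defined.
#'
#' @param dosages dosage matrix from \code{\link{simulate_genotypes}};
#'   its first column is the causal variant. Rows must cover
#'   \code{design$n_treated + design$n_controls} participants.
#' @param params a \code{\link{longitudinal_model_params}} object.
#' @param design a \code{\link{cohort_design}} object.
#' @param seed integer seed.
#' @param biomarker_code,unit labels for the measurement rows.
#' @param value_mean,value_sd affine map from model (SD) units to reported
#'   clinical units; default identity.
#' @param link "identity" reports the affine-mapped trait directly;
#'   "log" treats the model as acting on the log biomarker and reports
#'   \code{exp(value_mean + value_sd * Y)} — i.e. drug and genetic
#'   effects become multiplicative on the raw scale (a drug main effect
#'   \code{betaD} then multiplies raw levels by \code{exp(value_sd * betaD)}).
#' @param origin_date first-prescription dates are drawn inside the year
#'   starting here (ISO-8601 string).
#' @return list with \code{measurements} (participant_id, date,
#'   biomarker_code, value, unit), \code{participants} (id, group, sex,
#'   age_at_start, start_date plus latent truth g, e0, e1) and the inputs
#'   echoed. Treated baseline/post offsets and control spacing follow the
#'   design's visit-schedule distributions.
#' @export
simulate_biomarker_panel <- function(dosages, params, design, seed = 1L,
                                     biomarker_code = "LDL", unit = "mmol/L",
                                     value_mean = 0, value_sd = 1,
                                     link = c("identity", "log"),
                                     origin_date = "2010-01-01") {
  link <- match.arg(link)
  stopifnot(inherits(params, "longitudinal_model_params"),
            inherits(design, "cohort_design"))
  n <- design$n_treated + design$n_controls
  if (nrow(dosages) < n)
    stop("dosage matrix has fewer rows than the design requires", call. = FALSE)
  set.seed(seed)
  ids <- rownames(dosages)[seq_len(n)]
  group <- rep(c("treated", "control"),
               c(design$n_treated, design$n_controls))
  g <- dosages[seq_len(n), 1]
  v <- draw_two_visits(g, params, d1 = as.numeric(group == "treated"))
  start <- as.Date(origin_date) + sample.int(365L, n, replace = TRUE) - 1L
  off0 <- off1 <- numeric(n)
  tr <- group == "treated"
  off0[tr] <- round(stats::runif(sum(tr), design$baseline_offset_range[1],
                                 design$baseline_offset_range[2]))
  off1[tr] <- round(stats::rlnorm(sum(tr), design$post_offset_meanlog,
                                  design$post_offset_sdlog))
  off0[!tr] <- 0
  off1[!tr] <- round(stats::runif(sum(!tr), design$control_spacing_days[1],
                                  design$control_spacing_days[2]))
  val <- function(y) {
    lin <- value_mean + value_sd * y
    if (link == "log") exp(lin) else lin
  }
  meas <- data.table::data.table(
    participant_id = rep(ids, 2L),
    date = c(start + off0, start + off1),
    biomarker_code = biomarker_code,
    value = c(val(v$y0), val(v$y1)),
    unit = unit,
    visit = rep(c("first", "second"), each = n))
  data.table::setorder(meas, participant_id, date)
  participants <- data.table::data.table(
    participant_id = ids, group = group,
    sex = sample(c(0L, 1L), n, replace = TRUE),
    age_at_start = round(stats::runif(n, 40, 75)),
    start_date = start, g = g, e0 = v$e0, e1 = v$e1)
  list(measurements = meas, participants = participants,
       params = params, design = design)
}

#' Default synthetic drug catalogue
#'
#' A statin-like medication class: two primary drugs, one same-class
#' alternative, one combination product and one allowed add-on class,
#' mirroring the roles the QC cascade distinguishes.
#' @return data.table with columns drug_name, drug_code, drug_class, doses.
#' @export
default_drug_catalogue <- function() {
  data.table::data.table(
    drug_name = c("simvastatin", "atorvastatin", "rosuvastatin",
                  "simvastatin/ezetimibe", "fenofibrate"),
    drug_code = c("S01", "S02", "S03", "SC1", "F01"),
    drug_class = c("primary", "primary", "same_class_other",
                   "combination", "allowed_addon:fibrate"),
    doses = c("20,40,80", "10,20,40", "5,10,20", "20,40", "160"))
}

#' Simulate prescription histories for treated participants
#'
#' Repeat prescriptions of one primary drug at the design's interval
#' (skipped with \code{skip_probability}), optional mid-follow-up dose
#' changes and add-on class scripts, plus one unrelated clinical record
#' at least two years before the start so the prior-record QC step holds
#' by default.
#'
#' @param treated_ids character vector of participant ids.
#' @param start_dates Date vector aligned to \code{treated_ids} (first
#'   prescription dates).
#' @param design a \code{\link{cohort_design}} object.
#' @param catalogue drug catalogue as \code{\link{default_drug_catalogue}}.
#' @param seed integer seed.
#' @return data.table of prescription records: participant_id, date,
#'   drug_code, drug_class, drug_name, description (with a parseable
#'   "<dose>mg" token), dose_mg.
#' @export
simulate_prescriptions <- function(treated_ids, start_dates, design,
                                   catalogue = default_drug_catalogue(),
                                   seed = 1L) {
  if (nrow(catalogue) == 0) stop("drug catalogue is empty", call. = FALSE)
  stopifnot(length(treated_ids) == length(start_dates),
            inherits(design, "cohort_design"))
  set.seed(seed)
  primaries <- catalogue[catalogue$drug_class == "primary", ]
  addons <- catalogue[startsWith(catalogue$drug_class, "allowed_addon"), ]
  rows <- vector("list", length(treated_ids))
  for (i in seq_along(treated_ids)) {
    id <- treated_ids[i]
    start <- start_dates[i]
    drug <- primaries[sample.int(nrow(primaries), 1L), ]
    doses <- as.numeric(strsplit(drug$doses, ",")[[1]])
    dose <- sample(doses, 1L)
    offsets <- seq(0, design$followup_days,
                   by = design$prescription_interval_days)
    keep <- c(TRUE, stats::runif(length(offsets) - 1) >= design$skip_probability)
    offsets <- offsets[keep]
    dose_vec <- rep(dose, length(offsets))
    if (length(doses) > 1 && length(offsets) > 1 &&
        stats::runif(1) < design$dose_change_probability) {
      at <- sample(2:length(offsets), 1L)
      dose_vec[at:length(offsets)] <- sample(setdiff(doses, dose), 1L)
    }
    rec <- data.table::data.table(
      participant_id = id, date = start + offsets,
      drug_code = drug$drug_code, drug_class = "primary",
      drug_name = drug$drug_name,
      description = sprintf("%s %gmg tablets", drug$drug_name, dose_vec),
      dose_mg = dose_vec)
    if (nrow(addons) > 0 && stats::runif(1) < design$addon_probability) {
      ad <- addons[sample.int(nrow(addons), 1L), ]
      ad_dose <- as.numeric(strsplit(ad$doses, ",")[[1]])[1]
      # consistently in baseline and post windows, as the lenient policy needs
      ad_off <- c(-30, round(design$followup_days / 2))
      rec <- rbind(rec, data.table::data.table(
        participant_id = id, date = start + ad_off,
        drug_code = ad$drug_code, drug_class = ad$drug_class,
        drug_name = ad$drug_name,
        description = sprintf("%s %gmg tablets", ad$drug_name, ad_dose),
        dose_mg = ad_dose))
    }
    # unrelated clinical record >= 2 years earlier (prior-record QC step)
    rec <- rbind(rec, data.table::data.table(
      participant_id = id, date = start - 730L - sample.int(365L, 1L),
      drug_code = "GP00", drug_class = "unrelated",
      drug_name = "consultation", description = "GP consultation",
      dose_mg = NA_real_))
    rows[[i]] <- rec
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, participant_id, date)
  out
}

#' Simulate a complete synthetic EHR bundle
#'
#' Convenience wrapper tying genotypes, the biomarker panel and
#' prescriptions together; the unit of input every downstream stage
#' consumes.
#'
#' @param params a \code{\link{longitudinal_model_params}} object.
#' @param design a \code{\link{cohort_design}} object.
#' @param n_variants total simulated variants; the first is the causal one
#'   with \code{params$maf}, the rest are null with frequencies drawn
#'   uniformly on (0.05, 0.5).
#' @param seed integer seed (defaults to the design's).
#' @param ... passed to \code{\link{simulate_biomarker_panel}}.
#' @return list: dosages, mafs, measurements, participants, prescriptions.
#' @export
simulate_ehr <- function(params, design, n_variants = 1L,
                         seed = design$seed, ...) {
  rng <- rng_stream(seed)
  set.seed(rng())
  mafs <- c(params$maf,
            if (n_variants > 1) stats::runif(n_variants - 1, 0.05, 0.5))
  n <- design$n_treated + design$n_controls
  dosages <- simulate_genotypes(n, mafs, seed = rng())
  panel <- simulate_biomarker_panel(dosages, params, design, seed = rng(), ...)
  tr <- panel$participants[panel$participants$group == "treated", ]
  scripts <- if (nrow(tr) > 0)
    simulate_prescriptions(tr$participant_id, tr$start_date, design,
                           seed = rng())
  else data.table::data.table()
  list(dosages = dosages, mafs = mafs,
       measurements = panel$measurements,
       participants = panel$participants,
       prescriptions = scripts,
       params = params, design = design)
}

#' Write the synthetic EHR bundle as delimited text
#'
#' Three standard tables (prescriptions, measurements, participants) as
#' tab-separated files with ISO-8601 dates, plus the dosage matrix.
#'
#' @param bundle output of \code{\link{simulate_ehr}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_ehr_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(prescriptions = file.path(dir, "prescriptions.tsv"),
             measurements = file.path(dir, "measurements.tsv"),
             participants = file.path(dir, "participants.tsv"),
             dosages = file.path(dir, "dosages.tsv"))
  data.table::fwrite(bundle$prescriptions, paths["prescriptions"], sep = "\t")
  data.table::fwrite(bundle$measurements, paths["measurements"], sep = "\t")
  data.table::fwrite(bundle$participants, paths["participants"], sep = "\t")
  dos <- data.table::as.data.table(bundle$dosages, keep.rownames = "participant_id")
  data.table::fwrite(dos, paths["dosages"], sep = "\t")
  invisible(paths)
}
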