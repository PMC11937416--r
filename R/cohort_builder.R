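#' Drug-response cohort extraction from longitudinal EHR tables
#'
#' Turns raw prescription and biomarker-measurement tables into a
#' drug-response cohort (one row per participant with baseline and
#' post-treatment values) through an ordered quality-control cascade, and
#' emits a per-step exclusion ledger. Two filtering scenarios are
#' supported: a stringent one (narrow windows, monotherapy only, no dose
#' changes, completeness >= 60%) and a lenient one (wide windows, add-on
#' therapy allowed with covariate flags, dose changes averaged,
#' completeness >= 30%).
#'
#' @name cohort_builder
NULL

#' Filtering configuration for cohort extraction
#'
#' Defaults encode the two scenarios: baseline window \[-100, +7\] days
#' around the first prescription (stringent) or \[-365, +7\] (lenient);
#' post-treatment window starting 100 days after start (delayed-effect
#' drugs such as statins/metformin; use 60 for antihypertensives) and
#' ending at 365 (stringent) or 730 (lenient) days; completeness
#' threshold 0.60/0.30; dose changes excluded only under stringent.
#'
#' @param scenario "stringent" or "lenient".
#' @param baseline_window length-2 numeric, days relative to first
#'   prescription.
#' @param post_window length-2 numeric, days relative to first
#'   prescription.
#' @param aggregation "average_all" (default) or "closest_single".
#' @param completeness_threshold minimum prescription completeness in
#'   \[0, 1\].
#' @param min_baseline_level minimum baseline biomarker value (e.g.
#'   LDL-C >= 2 mmol/L); \code{-Inf} disables.
#' @param allow_dose_change logical; under \code{FALSE} a dose change in
#'   the post window is a treatment change.
#' @param addon_policy character vector of allowed add-on class names
#'   (the "<name>" of \code{allowed_addon:<name>} labels); only consulted
#'   under the lenient scenario.
#' @param min_drug_group_size drugs taken by fewer participants are
#'   dropped (default 20).
#' @param prior_record_years required years of unrelated record history
#'   before the medication start (default 2).
#' @param plausible_range length-2 numeric; measurement values outside it
#'   are row-level rejects.
#' @param bin_days completeness bin width (default 61, i.e. two months).
#' @return an object of class \code{filter_config}.
#' @export
filter_config <- function(scenario = c("stringent", "lenient"),
                          baseline_window = NULL,
                          post_window = NULL,
                          aggregation = c("average_all", "closest_single"),
                          completeness_threshold = NULL,
                          min_baseline_level = -Inf,
                          allow_dose_change = NULL,
                          addon_policy = character(),
                          min_drug_group_size = 20L,
                          prior_record_years = 2,
                          plausible_range = c(-Inf, Inf),
                          bin_days = 61L) {
  scenario <- match.arg(scenario)
  aggregation <- match.arg(aggregation)
  stringent <- scenario == "stringent"
  if (is.null(baseline_window))
    baseline_window <- if (stringent) c(-100, 7) else c(-365, 7)
  if (is.null(post_window))
    post_window <- if (stringent) c(100, 365) else c(100, 730)
  if (is.null(completeness_threshold))
    completeness_threshold <- if (stringent) 0.60 else 0.30
  if (is.null(allow_dose_change)) allow_dose_change <- !stringent
  stopifnot(length(baseline_window) == 2,
            baseline_window[1] <= baseline_window[2],
            length(post_window) == 2, post_window[1] <= post_window[2],
            completeness_threshold >= 0, completeness_threshold <= 1,
            min_drug_group_size >= 1,
            length(plausible_range) == 2,
            plausible_range[1] <= plausible_range[2])
  structure(list(scenario = scenario, baseline_window = baseline_window,
                 post_window = post_window, aggregation = aggregation,
                 completeness_threshold = completeness_threshold,
                 min_baseline_level = min_baseline_level,
                 allow_dose_change = allow_dose_change,
                 addon_policy = addon_policy,
                 min_drug_group_size = as.integer(min_drug_group_size),
                 prior_record_years = prior_record_years,
                 plausible_range = plausible_range,
                 bin_days = as.integer(bin_days)),
            class = "filter_config")
}

#' Date of the first primary-medication prescription
#'
#' @param prescriptions prescription table (needs participant_id, date,
#'   drug_class).
#' @param participant a participant id.
#' @return the earliest primary-record date, or \code{NA} (of class Date)
#'   when the participant has no primary record.
#' @export
first_prescription <- function(prescriptions, participant) {
  d <- prescriptions$date[prescriptions$participant_id == participant &
                            prescriptions$drug_class == "primary"]
  if (length(d) == 0) return(as.Date(NA))
  min(as.Date(d))
}

#' Prescription completeness over the follow-up
#'
#' The interval from treatment start to the post-treatment measure is
#' partitioned into consecutive bins of \code{bin_days} (default 61, a
#' two-month cadence); the final partial bin is included iff it is at
#' least half a bin long. Completeness is the fraction of bins containing
#' at least one primary prescription — the adherence proxy under the
#' assumption that skipped prescriptions reflect inconsistent intake.
#'
#' @param primary_dates Date vector of primary prescription dates.
#' @param start treatment start date.
#' @param post_measure date of the post-treatment measure (> start).
#' @param bin_days bin width in days.
#' @return fraction in \[0, 1\].
#' @export
prescription_completeness <- function(primary_dates, start, post_measure,
                                      bin_days = 61L) {
  start <- as.Date(start); post_measure <- as.Date(post_measure)
  if (post_measure <= start)
    stop("`post_measure` must be after `start`", call. = FALSE)
  len <- as.numeric(post_measure - start)
  n_bins <- floor(len / bin_days)
  if (len - n_bins * bin_days >= bin_days / 2) n_bins <- n_bins + 1
  if (n_bins == 0) return(1)  # follow-up shorter than half a bin
  off <- as.numeric(as.Date(primary_dates) - start)
  off <- off[off >= 0 & off < len]
  if (length(off) == 0) return(0)
  covered <- unique(pmin(floor(off / bin_days), n_bins - 1))
  length(covered) / n_bins
}

#' Select the baseline or post-treatment measure within a window
#'
#' @param measures data.frame/data.table with columns date and value.
#' @param start treatment start date (offsets are relative to it).
#' @param window length-2 numeric, day offsets defining the closed window.
#' @param aggregation "closest_single" (measure minimising |offset|, ties
#'   to the earlier date) or "average_all" (unweighted mean; the reported
#'   offset is that of the closest contributing measure).
#' @return list(value, time_to_measure_days, date, n_measures_used), or
#'   \code{NULL} when no measure falls in the window.
#' @export
select_window_measures <- function(measures, start, window,
                                   aggregation = c("closest_single",
                                                   "average_all")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(window) == 2, window[1] <= window[2])
  start <- as.Date(start)
  off <- as.numeric(as.Date(measures$date) - start)
  inw <- which(off >= window[1] & off <= window[2])
  if (length(inw) == 0) return(NULL)
  off_in <- off[inw]
  # closest measure; at equal |offset| the earlier date wins
  ord <- order(abs(off_in), off_in)
  closest <- inw[ord[1]]
  if (aggregation == "closest_single") {
    list(value = measures$value[closest],
         time_to_measure_days = off[closest],
         date = as.Date(measures$date[closest]),
         n_measures_used = 1L)
  } else {
    list(value = mean(measures$value[inw]),
         time_to_measure_days = off[closest],
         date = as.Date(measures$date[closest]),
         n_measures_used = length(inw))
  }
}

#' Extract a dose in mg from a drug description string
#'
#' Takes the first "<number>mg" token (case-insensitive, optional space
#' before the unit), e.g. "Simvastatin 40mg tablets" -> 40,
#' "Metformin 500 mg" -> 500. Absence is a value (\code{NA}), not an
#' error; median imputation is a separate explicit step
#' (\code{\link{impute_dose}}).
#'
#' @param description character vector of drug descriptions.
#' @return numeric vector of mg values, \code{NA} where no token matches.
#' @export
parse_dose <- function(description) {
  m <- regmatches(description,
                  regexpr("([0-9]+(\\.[0-9]+)?)[ ]?mg", description,
                          ignore.case = TRUE))
  out <- rep(NA_real_, length(description))
  hit <- regexpr("([0-9]+(\\.[0-9]+)?)[ ]?mg", description,
                 ignore.case = TRUE) > 0
  out[hit] <- as.numeric(sub("[ ]?mg", "", m, ignore.case = TRUE))
  out
}

#' Impute missing doses by the per-drug median
#'
#' @param dose_mg numeric vector with NAs.
#' @param drug_name character vector aligned to \code{dose_mg}.
#' @return list(dose_mg = imputed vector, imputed = logical flag vector).
#' @export
impute_dose <- function(dose_mg, drug_name) {
  imputed <- is.na(dose_mg)
  med <- tapply(dose_mg, drug_name, stats::median, na.rm = TRUE)
  dose_mg[imputed] <- med[drug_name[imputed]]
  list(dose_mg = dose_mg, imputed = imputed)
}

#' Detect a treatment change during the follow-up
#'
#' A treatment change is: a same-class non-allowed medication prescribed
#' in the post-treatment window; a combination product at any time between
#' start and post measure (combination products always exclude); or a dose
#' change of the primary drug when \code{allow_dose_change} is FALSE.
#'
#' @param scripts prescription rows of one participant.
#' @param start treatment start date.
#' @param post_measure date of the post-treatment measure.
#' @param config a \code{\link{filter_config}}.
#' @return list(change = logical, reason = character).
#' @export
detect_treatment_change <- function(scripts, start, post_measure, config) {
  start <- as.Date(start); post_measure <- as.Date(post_measure)
  stopifnot(start < post_measure)
  d <- as.Date(scripts$date)
  span <- d >= start & d <= post_measure
  if (any(span & scripts$drug_class == "combination"))
    return(list(change = TRUE, reason = "combination_product"))
  if (any(d > start & span & scripts$drug_class == "same_class_other"))
    return(list(change = TRUE, reason = "same_class_medication_post"))
  if (!config$allow_dose_change) {
    doses <- scripts$dose_mg[span & scripts$drug_class == "primary"]
    doses <- doses[!is.na(doses)]
    if (length(unique(doses)) > 1)
      return(list(change = TRUE, reason = "dose_change"))
  }
  list(change = FALSE, reason = NA_character_)
}

#' Apply the add-on (concomitant medication) policy
#'
#' Stringent: only monotherapies — any related add-on record drops the
#' participant. Lenient: an allowed add-on class consistently present in
#' both the baseline and post-treatment windows is kept and flagged as a
#' covariate; an add-on appearing only in the post window drops the
#' participant; baseline-only use is kept with a prior-use flag.
#'
#' @param scripts prescription rows of one participant.
#' @param start treatment start date.
#' @param config a \code{\link{filter_config}} (windows and
#'   \code{addon_policy} are taken from it).
#' @return list(keep = logical, reason, flags = named integer vector of
#'   add-on covariate flags, one per policy class: 1 if consistently
#'   taken, else 0; prior-only use sets \code{<name>_prior}).
#' @export
apply_addon_policy <- function(scripts, start, config) {
  start <- as.Date(start)
  is_addon <- startsWith(scripts$drug_class, "allowed_addon:")
  classes <- unique(sub("^allowed_addon:", "", scripts$drug_class[is_addon]))
  unknown <- setdiff(classes, config$addon_policy)
  if (length(unknown) > 0)
    stop(sprintf("add-on class(es) not covered by the policy: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  flags <- stats::setNames(integer(2 * length(config$addon_policy)),
                           c(config$addon_policy,
                             paste0(config$addon_policy, "_prior")))
  if (!any(is_addon))
    return(list(keep = TRUE, reason = NA_character_, flags = flags))
  if (config$scenario == "stringent")
    return(list(keep = FALSE, reason = "addon_medication_stringent",
                flags = flags))
  d <- as.Date(scripts$date)
  off <- as.numeric(d - start)
  for (cl in classes) {
    sel <- is_addon & sub("^allowed_addon:", "", scripts$drug_class) == cl
    in_base <- any(sel & off >= config$baseline_window[1] &
                     off <= config$baseline_window[2])
    in_post <- any(sel & off >= config$post_window[1] &
                     off <= config$post_window[2])
    if (in_post && !in_base)
      return(list(keep = FALSE, reason = "addon_only_post_window",
                  flags = flags))
    if (in_base && in_post) flags[cl] <- 1L
    else if (any(sel & off < 0)) flags[paste0(cl, "_prior")] <- 1L
  }
  list(keep = TRUE, reason = NA_character_, flags = flags)
}

#' NGSP/IFCC HbA1c unit conversion (master equation)
#'
#' NGSP(%) = 0.09148 * IFCC(mmol/mol) + 2.152; applied before
#' plausible-range filtering when harmonizing mixed-unit HbA1c tables.
#'
#' @param x values to convert.
#' @return converted values.
#' @export
hba1c_ifcc_to_ngsp <- function(x) 0.09148 * x + 2.152

#' @rdname hba1c_ifcc_to_ngsp
#' @export
hba1c_ngsp_to_ifcc <- function(x) (x - 2.152) / 0.09148

# Assemble an exclusion-log table and check conservation.
make_exclusion_log <- function(initial_n, steps) {
  log <- data.table::data.table(
    step = names(steps),
    n_removed = as.integer(unlist(steps)))
  log$n_remaining <- initial_n - cumsum(log$n_removed)
  stopifnot(all(log$n_removed >= 0),
            all(diff(c(initial_n, log$n_remaining)) <= 0))
  structure(log, initial_n = initial_n, class = c("exclusion_log",
                                                  class(log)))
}

#' Human-readable exclusion report
#'
#' @param log an exclusion_log from \code{\link{build_cohort}}.
#' @return character vector of report lines.
#' @export
exclusion_report <- function(log) {
  c(sprintf("Participants entering QC: %d", attr(log, "initial_n")),
    sprintf("  %-28s removed %5d, remaining %5d",
            log$step, log$n_removed, log$n_remaining),
    sprintf("Final cohort size: %d", log$n_remaining[nrow(log)]))
}

#' Build a drug-response cohort through the QC cascade
#'
#' Applies, in order: (i) available baseline and post-treatment measures;
#' (ii) an unrelated primary-care record at least
#' \code{prior_record_years} before the medication start (guards against
#' mistaking a provider switch for a first prescription); (iii) a
#' related-class prescription after the post-treatment measure (continued
#' treatment); (iv) treatment change between start and post measure;
#' (v) prescription completeness >= threshold; (vi) minimum baseline
#' level; then same-class medication within a year of start, the add-on
#' policy, and the minimum per-drug group size. The exclusion ledger
#' reconciles exactly: initial n minus the removals sums to the final
#' cohort size.
#'
#' @param prescriptions prescription table (participant_id, date,
#'   drug_code, drug_class, drug_name, description and/or dose_mg).
#' @param measurements measurement table (participant_id, date,
#'   biomarker_code, value, unit).
#' @param config a \code{\link{filter_config}}.
#' @param participants optional covariate table (participant_id, sex,
#'   age_at_start, ...) joined onto the cohort.
#' @return list with \code{cohort} (data.table: participant_id, start_date,
#'   baseline, post, delta_abs, delta_log, time_to_post_days,
#'   completeness, drug_name, dose_mg, add-on flags, covariates),
#'   \code{exclusion_log}, \code{row_rejects} (malformed/out-of-range
#'   measurement rows) and \code{skipped} (participants without a primary
#'   prescription).
#' @export
build_cohort <- function(prescriptions, measurements, config,
                         participants = NULL) {
  stopifnot(inherits(config, "filter_config"))
  rx <- data.table::as.data.table(prescriptions)
  ms <- data.table::as.data.table(measurements)
  required_rx <- c("participant_id", "date", "drug_class", "drug_name")
  missing_cols <- setdiff(required_rx, names(rx))
  if (length(missing_cols) > 0)
    stop("prescription table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"dose_mg" %in% names(rx))
    rx$dose_mg <- if ("description" %in% names(rx))
      parse_dose(rx$description) else NA_real_

  # row-level rejects: unparseable dates and implausible values
  rx$date <- as.Date(as.character(rx$date), format = "%Y-%m-%d")
  ms$date <- as.Date(as.character(ms$date), format = "%Y-%m-%d")
  bad_rx <- rx[is.na(rx$date), ]
  rx <- rx[!is.na(rx$date), ]
  bad_date <- is.na(ms$date)
  bad_val <- !is.na(ms$date) &
    (!is.finite(ms$value) | ms$value < config$plausible_range[1] |
       ms$value > config$plausible_range[2])
  row_rejects <- ms[bad_date | bad_val, ]
  if (nrow(row_rejects) > 0)
    row_rejects$reject_reason <- ifelse(bad_date[bad_date | bad_val],
                                        "unparseable_date",
                                        "outside_plausible_range")
  ms <- ms[!(bad_date | bad_val), ]

  ids <- sort(unique(rx$participant_id))
  starts <- vapply(ids, function(id) {
    as.numeric(first_prescription(rx, id))
  }, numeric(1))
  skipped <- ids[is.na(starts)]
  ids <- ids[!is.na(starts)]
  starts <- as.Date(starts[!is.na(starts)], origin = "1970-01-01")
  initial_n <- length(ids)

  steps <- c(no_baseline_or_post_measure = 0L, no_prior_record = 0L,
             no_prescription_after_post = 0L, treatment_change = 0L,
             low_completeness = 0L, baseline_below_minimum = 0L,
             same_class_within_year = 0L, addon_policy = 0L,
             small_drug_group = 0L)
  rows <- list()

  for (k in seq_along(ids)) {
    id <- ids[k]; start <- starts[k]
    p_rx <- rx[rx$participant_id == id, ]
    p_ms <- ms[ms$participant_id == id, ]

    base <- select_window_measures(p_ms, start, config$baseline_window,
                                   config$aggregation)
    post <- select_window_measures(p_ms, start, config$post_window,
                                   config$aggregation)
    if (is.null(base) || is.null(post)) {
      steps["no_baseline_or_post_measure"] <-
        steps["no_baseline_or_post_measure"] + 1L
      next
    }
    prior_cut <- start - round(365.25 * config$prior_record_years)
    if (!any(p_rx$drug_class != "primary" & p_rx$date <= prior_cut)) {
      steps["no_prior_record"] <- steps["no_prior_record"] + 1L
      next
    }
    related <- p_rx$drug_class != "unrelated"
    if (!any(related & p_rx$date > post$date)) {
      steps["no_prescription_after_post"] <-
        steps["no_prescription_after_post"] + 1L
      next
    }
    tc <- detect_treatment_change(p_rx, start, post$date, config)
    if (tc$change) {
      steps["treatment_change"] <- steps["treatment_change"] + 1L
      next
    }
    compl <- prescription_completeness(
      p_rx$date[p_rx$drug_class == "primary"], start, post$date,
      bin_days = config$bin_days)
    if (compl < config$completeness_threshold) {
      steps["low_completeness"] <- steps["low_completeness"] + 1L
      next
    }
    if (base$value < config$min_baseline_level) {
      steps["baseline_below_minimum"] <- steps["baseline_below_minimum"] + 1L
      next
    }
    # same-class (non-add-on, non-combination already handled) medication
    # within a year of initiation, outside the post-change check
    year_off <- as.numeric(p_rx$date - start)
    if (any(p_rx$drug_class == "same_class_other" &
              abs(year_off) <= 365 & p_rx$date <= start)) {
      steps["same_class_within_year"] <- steps["same_class_within_year"] + 1L
      next
    }
    ap <- apply_addon_policy(p_rx, start, config)
    if (!ap$keep) {
      steps["addon_policy"] <- steps["addon_policy"] + 1L
      next
    }
    prim <- p_rx[p_rx$drug_class == "primary", ]
    start_dose <- prim$dose_mg[which.min(prim$date)][1]
    post_doses <- prim$dose_mg[prim$date > start & prim$date <= post$date]
    dose_cov <- if (config$allow_dose_change && length(post_doses) > 0 &&
                      any(!is.na(post_doses)))
      mean(post_doses, na.rm = TRUE) else start_dose
    row <- data.table::data.table(
      participant_id = id, start_date = start,
      baseline = base$value, post = post$value,
      delta_abs = post$value - base$value,
      delta_log = if (base$value > 0 && post$value > 0)
        log(post$value) - log(base$value) else NA_real_,
      time_to_post_days = post$time_to_measure_days,
      time_to_baseline_days = base$time_to_measure_days,
      n_baseline_measures = base$n_measures_used,
      n_post_measures = post$n_measures_used,
      completeness = compl,
      drug_name = prim$drug_name[which.min(prim$date)][1],
      dose_mg = dose_cov)
    for (fl in names(ap$flags)) row[[paste0("addon_", fl)]] <- ap$flags[[fl]]
    rows[[length(rows) + 1L]] <- row
  }

  cohort <- if (length(rows) > 0) data.table::rbindlist(rows, fill = TRUE)
  else data.table::data.table()
  if (nrow(cohort) > 0) {
    grp <- table(cohort$drug_name)
    small <- names(grp)[grp < config$min_drug_group_size]
    steps["small_drug_group"] <- sum(cohort$drug_name %in% small)
    cohort <- cohort[!cohort$drug_name %in% small, ]
  }
  if (!is.null(participants) && nrow(cohort) > 0) {
    pt <- data.table::as.data.table(participants)
    keep_cols <- setdiff(names(pt), c("g", "e0", "e1", "group", "start_date"))
    cohort <- merge(cohort, pt[, keep_cols, with = FALSE],
                    by = "participant_id", all.x = TRUE, sort = TRUE)
  }
  log <- make_exclusion_log(initial_n, as.list(steps))
  stopifnot(initial_n - sum(log$n_removed) == nrow(cohort))
  list(cohort = cohort, exclusion_log = log, row_rejects = row_rejects,
       skipped = skipped)
}
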