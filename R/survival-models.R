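# Multivariable Cox comparison of epitope score vs antigen mismatches:
# three exposure models, country-stratified baseline, missing-as-category
# confounders, cross-categorized subgroup HRs, AIC, horizon discrimination.

#' @importFrom survival Surv strata coxph
NULL

DEFAULT_CONFOUNDERS <- c("recipient_age", "donor_age", "recipient_sex",
                         "donor_sex", "dialysis", "disease", "pra",
                         "marginal_donor", "induction", "immunosuppression",
                         "tx_period", "cit_hours")

# Categorical confounders get explicit "unknown" levels (missing data are a
# category, never dropped); numeric confounders enter linearly.
normalize_confounders <- function(data, confounders) {
  miss <- setdiff(confounders, names(data))
  if (length(miss)) stop("cohort lacks confounder column(s): ", paste(miss, collapse = ", "))
  for (cc in confounders) {
    v <- data[[cc]]
    if (is.numeric(v)) {
      if (anyNA(v)) stop("numeric confounder '", cc, "' has NAs; impute or recode first")
    } else {
      v <- as.character(v)
      v[is.na(v) | v == ""] <- "unknown"
      lev <- unique(c(setdiff(sort(unique(v)), "unknown"), intersect("unknown", v)))
      data[[cc]] <- factor(v, levels = lev)
    }
  }
  data
}

prepare_cox_data <- function(cohort, exposure, confounders, horizon,
                             time_col, event_col, strata_col) {
  need <- c(time_col, event_col, strata_col,
            if (exposure %in% c("pirche", "both")) "pirche_adj",
            if (exposure %in% c("hla", "both")) "hla_mm")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  d <- normalize_confounders(cohort, confounders)
  time <- d[[time_col]]
  event <- as.integer(d[[event_col]])
  if (any(!is.finite(time) | time <= 0)) stop("follow-up times must be > 0")
  if (!all(event %in% c(0L, 1L))) stop("event flag must be 0/1")
  # administrative censoring at the analysis horizon
  if (is.finite(horizon)) {
    event <- ifelse(time <= horizon, event, 0L)
    time <- pmin(time, horizon)
  }
  d$.time <- time
  d$.event <- event
  d$.strata <- factor(d[[strata_col]])
  # strata without events carry no information for a stratified fit
  ev_by <- tapply(d$.event, d$.strata, sum)
  dead <- names(ev_by)[is.na(ev_by) | ev_by == 0]
  if (length(dead)) {
    warning("dropping stratum/strata without events: ", paste(dead, collapse = ", "))
    d <- d[!d$.strata %in% dead, , drop = FALSE]
    d$.strata <- droplevels(d$.strata)
  }
  d
}

#' Fit a multivariable Cox model for graft survival
#'
#' Fits the proportional-hazards model for death-censored graft survival with
#' one or both compatibility exposures (adjusted epitope score `pirche_adj`
#' and/or antigen mismatch count `hla_mm`, both entered linearly so hazard
#' ratios are per unit), the confounder set entered alongside (categorical
#' confounders with explicit `"unknown"` levels, numeric confounders linear),
#' a baseline hazard stratified by country, and Efron handling of tied event
#' times (Breslow available). Follow-up is administratively censored at the
#' analysis horizon, 60 months for the 5-year analysis.
#'
#' @param cohort A cohort `data.frame` (see [simulate_cohort()] for the
#'   column layout).
#' @param exposure `"hla"`, `"pirche"`, or `"both"`.
#' @param confounders Character vector of confounder column names.
#' @param horizon_months Administrative censoring horizon (default 60).
#' @param time_col,event_col,strata_col Column names for follow-up time
#'   (months), the graft-loss indicator (death with function = censored,
#'   i.e. 0), and the stratification label.
#' @param ties `"efron"` or `"breslow"`.
#' @return An object of class `cox_fit`: list with `table` (one row per
#'   covariate: `term`, `hr`, `ci_lower`, `ci_upper`, `z`, `p`), `aic`, `n`,
#'   `events`, `exposure`, `horizon`, the fitted [survival::coxph()] object
#'   (`model`) and the prepared analysis data (`data`).
#' @export
fit_cox <- function(cohort, exposure = c("both", "hla", "pirche"),
                    confounders = intersect(DEFAULT_CONFOUNDERS, names(cohort)),
                    horizon_months = 60,
                    time_col = "time", event_col = "event",
                    strata_col = "country",
                    ties = c("efron", "breslow")) {
  exposure <- match.arg(exposure)
  ties <- match.arg(ties)
  d <- prepare_cox_data(cohort, exposure, confounders, horizon_months,
                        time_col, event_col, strata_col)
  exp_terms <- switch(exposure, hla = "hla_mm", pirche = "pirche_adj",
                      both = c("pirche_adj", "hla_mm"))
  rhs <- paste(c(exp_terms, confounders, "strata(.strata)"), collapse = " + ")
  f <- stats::as.formula(paste("Surv(.time, .event) ~", rhs),
                         env = environment())
  fit <- survival::coxph(f, data = d, ties = ties, model = TRUE)
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_lower = unname(s$conf.int[, "lower .95"]),
    ci_upper = unname(s$conf.int[, "upper .95"]),
    z = unname(s$coefficients[, "z"]),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, aic = stats::AIC(fit), n = s$n,
                 events = s$nevent, exposure = exposure,
                 horizon = horizon_months, ties = ties,
                 confounders = confounders, model = fit, data = d),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> exposure = %s, n = %d, events = %d, AIC = %.1f\n",
              x$exposure, x$n, x$events, x$aic))
  show <- x$table[x$table$term %in% c("pirche_adj", "hla_mm"), , drop = FALSE]
  if (nrow(show)) {
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %-11s HR %.3f (95%% CI %.3f-%.3f), z = %.1f, p = %.3g\n",
                  show$term[i], show$hr[i], show$ci_lower[i], show$ci_upper[i],
                  show$z[i], show$p[i]))
    }
  }
  invisible(x)
}

#' Extract the exposure row(s) of a Cox fit
#'
#' @param fit A `cox_fit`.
#' @return The `table` rows for `pirche_adj` / `hla_mm`.
#' @export
exposure_effects <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  fit$table[fit$table$term %in% c("pirche_adj", "hla_mm"), , drop = FALSE]
}

#' Cross-categorized subgroup hazard ratios
#'
#' Analyzes the effect of one compatibility measure within categories of the
#' other: the per-unit epitope-score HR inside each HLA-mismatch stratum, or
#' the per-mismatch HR inside each epitope-score category. Within a subgroup
#' the model contains both exposures (the stratifying exposure is dropped
#' automatically when it is constant there, as in single-mismatch-value
#' strata) plus the full confounder set and country stratification.
#'
#' @param cohort The cohort `data.frame`.
#' @param scheme `"hla7"` (7 mismatch strata, epitope HR reported),
#'   `"pirche7"` (7 raw-score categories, mismatch HR reported),
#'   `"hla_coarse"` (mismatches 0-3 vs 4-6, epitope HR), or
#'   `"pirche_coarse"` (score 0-12 vs >12, mismatch HR).
#' @param min_events Minimum events a subgroup must retain; below it the row
#'   is flagged `"insufficient events"` and no model is fitted.
#' @param ... Passed to [fit_cox()] (confounders, horizon, ties, columns).
#' @return A `data.frame` with one row per subgroup: `subgroup`, `n`,
#'   `events`, `term`, `hr`, `ci_lower`, `ci_upper`, `z`, `p`, `flag`
#'   (`NA`, `"insufficient events"`, or collected fit warnings).
#' @export
cross_subgroup_hrs <- function(cohort, scheme = c("hla7", "pirche7",
                                                  "hla_coarse", "pirche_coarse"),
                               min_events = 10, ...) {
  scheme <- match.arg(scheme)
  split_var <- switch(scheme,
    hla7 = , hla_coarse = "hla_mm",
    pirche7 = , pirche_coarse = "pirche_raw")
  report_term <- switch(scheme,
    hla7 = , hla_coarse = "pirche_adj",
    pirche7 = , pirche_coarse = "hla_mm")
  if (!split_var %in% names(cohort)) stop("cohort lacks column ", split_var)
  cats <- switch(scheme,
    hla7 = categorize(cohort$hla_mm, hla_categories()),
    hla_coarse = categorize(cohort$hla_mm, hla_coarse_categories()),
    pirche7 = categorize(cohort$pirche_raw, pirche_categories()),
    pirche_coarse = categorize(cohort$pirche_raw, pirche_coarse_categories()))
  out <- lapply(levels(cats), function(lv) {
    rows <- which(cats == lv)
    sub <- cohort[rows, , drop = FALSE]
    base <- data.frame(subgroup = lv, n = length(rows),
                       events = if (length(rows)) sum(sub$event) else 0L,
                       term = report_term, hr = NA_real_, ci_lower = NA_real_,
                       ci_upper = NA_real_, z = NA_real_, p = NA_real_,
                       flag = NA_character_, stringsAsFactors = FALSE)
    if (base$events < min_events) {
      base$flag <- "insufficient events"
      return(base)
    }
    stratifier_constant <- length(unique(sub[[switch(report_term,
      pirche_adj = "hla_mm", hla_mm = "pirche_adj")]])) == 1L
    exposure <- if (stratifier_constant) {
      if (report_term == "pirche_adj") "pirche" else "hla"
    } else "both"
    # sparse subgroups routinely produce monotone-likelihood warnings from
    # near-empty factor levels; record them on the row instead of emitting
    notes <- character(0)
    fit <- tryCatch(
      withCallingHandlers(
        fit_cox(sub, exposure = exposure, ...),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(fit, "error")) {
      base$flag <- conditionMessage(fit)
      return(base)
    }
    if (length(notes)) base$flag <- paste(unique(trimws(notes)), collapse = "; ")
    row <- fit$table[fit$table$term == report_term, , drop = FALSE]
    base$events <- fit$events
    base[c("hr", "ci_lower", "ci_upper", "z", "p")] <-
      row[c("hr", "ci_lower", "ci_upper", "z", "p")]
    base
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Rank Cox models by AIC
#'
#' @param ... `cox_fit` objects fitted on the identical cohort and horizon
#'   (checked via n/events/horizon).
#' @return A `data.frame` with `model` (exposure label), `aic`, `delta_aic`,
#'   `best`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "cox_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "cox_fit")))
  n <- vapply(fits, `[[`, numeric(1), "n")
  ev <- vapply(fits, `[[`, numeric(1), "events")
  hz <- vapply(fits, `[[`, numeric(1), "horizon")
  if (length(unique(n)) > 1L || length(unique(ev)) > 1L || length(unique(hz)) > 1L) {
    stop("models were not fitted on the same cohort and horizon")
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  labs <- vapply(fits, `[[`, character(1), "exposure")
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  out <- data.frame(model = labs, aic = aic, delta_aic = aic - min(aic),
                    best = aic == min(aic), stringsAsFactors = FALSE)
  out[order(out$aic), , drop = FALSE]
}

#' Discrimination of a fitted model at a time horizon
#'
#' Area under the ROC curve of the model's linear predictor against the
#' binary outcome "graft lost by the horizon". Subjects censored before the
#' horizon without an event carry no usable outcome and are excluded.
#'
#' @param fit A `cox_fit`.
#' @param horizon_months Horizon defining the binary outcome; defaults to the
#'   fit's own horizon.
#' @return List with `auc`, `n`, `cases`, `flag` (`NA`, or a message when the
#'   outcome is single-class and the AUC undefined).
#' @export
discrimination_auc <- function(fit, horizon_months = fit$horizon) {
  stopifnot(inherits(fit, "cox_fit"))
  d <- fit$data
  lp <- unname(fit$model$linear.predictors)
  lost <- d$.event == 1L & d$.time <= horizon_months
  usable <- lost | d$.time >= horizon_months
  y <- as.integer(lost[usable])
  lp <- lp[usable]
  if (length(unique(y)) < 2L) {
    return(list(auc = NA_real_, n = length(y), cases = sum(y),
                flag = "single-class outcome: AUC undefined"))
  }
  roc <- pROC::roc(response = y, predictor = lp, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)), n = length(y), cases = sum(y),
       flag = NA_character_)
}
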