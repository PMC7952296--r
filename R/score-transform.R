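# Log-adjustment of raw epitope loads onto the 0-6 HLA-mismatch scale,
# category schemes, and the score/mismatch rank correlation.

#' Fit the cohort-maximum log adjustment
#'
#' Epitope loads and HLA mismatches live on different scales (0 to the cohort
#' maximum, here up to a few hundred, versus 0-6), so their per-unit hazard
#' ratios are not comparable. The adjustment maps a raw score `s` to
#' `ln(s + 1) * 6 / max(ln(raw + 1))`, where the maximum is taken over the
#' cohort: the log captures the diminishing marginal effect of additional
#' epitopes, and the rescaling pins the cohort maximum at 6 and a raw score of
#' 0 at 0. The fitted context is stored so that new data (e.g. at allocation
#' time) can be adjusted onto the same scale without refitting.
#'
#' @param raw_scores Numeric vector of raw scores, all `>= 0`, at least one
#'   `> 0`.
#' @param scale_top Upper end of the target scale; 6, the HLA A+B+DRB1
#'   mismatch maximum.
#' @return An object of class `adjustment_context`: list with
#'   `cohort_max_log` and `scale_top`.
#' @export
#' @examples
#' ctx <- fit_adjustment(0:211)
#' adjust_scores(c(0, 1, 211), ctx)  # 0, 6*log(2)/log(212), 6
fit_adjustment <- function(raw_scores, scale_top = 6) {
  if (any(!is.finite(raw_scores) | raw_scores < 0)) {
    stop("raw scores must be finite and >= 0")
  }
  m <- max(log(raw_scores + 1))
  if (m <= 0) stop("all raw scores are 0; the adjustment is undefined")
  structure(list(cohort_max_log = m, scale_top = scale_top),
            class = "adjustment_context")
}

#' @export
print.adjustment_context <- function(x, ...) {
  cat(sprintf("<adjustment_context> max ln(raw+1) = %.6f, scale top = %g\n",
              x$cohort_max_log, x$scale_top))
  invisible(x)
}

#' Adjust raw epitope scores onto the 0-6 scale
#'
#' @param raw_scores Numeric vector of raw scores `>= 0`.
#' @param context An [fit_adjustment()] context; defaults to fitting on
#'   `raw_scores` itself (the cohort-maximum convention).
#' @return Numeric vector of adjusted scores in `[0, scale_top]` (values above
#'   `scale_top` can only arise when applying a stored context to new data
#'   exceeding the original cohort maximum). The context used is attached as
#'   attribute `"context"`.
#' @export
adjust_scores <- function(raw_scores, context = fit_adjustment(raw_scores)) {
  stopifnot(inherits(context, "adjustment_context"))
  if (any(!is.finite(raw_scores) | raw_scores < 0)) {
    stop("raw scores must be finite and >= 0")
  }
  out <- log(raw_scores + 1) * context$scale_top / context$cohort_max_log
  attr(out, "context") <- context
  out
}

#' Save / load an adjustment context
#'
#' Plain-text (YAML) persistence so a cohort-fitted scale can be reapplied to
#' new patients.
#'
#' @param context An `adjustment_context`.
#' @param path File path.
#' @export
write_adjustment <- function(context, path) {
  stopifnot(inherits(context, "adjustment_context"))
  yaml::write_yaml(list(cohort_max_log = context$cohort_max_log,
                        scale_top = context$scale_top), path, precision = 15)
  invisible(context)
}

#' @rdname write_adjustment
#' @export
read_adjustment <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(list(cohort_max_log = cfg$cohort_max_log, scale_top = cfg$scale_top),
            class = "adjustment_context")
}

#' Category schemes for scores and mismatches
#'
#' A category scheme partitions the non-negative value range into ordered,
#' gap-free intervals with inclusive upper bounds. The stock schemes are the
#' seven raw-score categories (0-1, 2-12, 13-25, 26-43, 44-68, 69-102, >102)
#' built to mirror the seven HLA mismatch groups, the seven mismatch
#' categories 0..6, and the coarse groupings used in subgroup analyses
#' (score 0-12 vs >12; score 0-12 / 13-68 / 69+; mismatches 0-3 vs 4-6).
#'
#' @param upper Numeric vector of strictly increasing inclusive upper bounds;
#'   the last may be `Inf`.
#' @param labels Character labels, one per interval.
#' @return An object of class `category_scheme`.
#' @export
category_scheme <- function(upper, labels) {
  stopifnot(length(upper) == length(labels), length(upper) >= 2L)
  if (any(diff(upper) <= 0)) stop("upper bounds must be strictly increasing")
  structure(list(upper = upper, labels = labels), class = "category_scheme")
}

#' @rdname category_scheme
#' @export
pirche_categories <- function() {
  category_scheme(c(1, 12, 25, 43, 68, 102, Inf),
                  c("0-1", "2-12", "13-25", "26-43", "44-68", "69-102", ">102"))
}

#' @rdname category_scheme
#' @export
hla_categories <- function() {
  category_scheme(0:6, as.character(0:6))
}

#' @rdname category_scheme
#' @export
pirche_coarse_categories <- function() {
  category_scheme(c(12, Inf), c("0-12", ">12"))
}

#' @rdname category_scheme
#' @export
pirche_three_way_categories <- function() {
  category_scheme(c(12, 68, Inf), c("0-12", "13-68", "69+"))
}

#' @rdname category_scheme
#' @export
hla_coarse_categories <- function() {
  category_scheme(c(3, 6), c("0-3", "4-6"))
}

#' Assign values to scheme categories
#'
#' Boundaries are inclusive upper bounds: with the stock score scheme, 12
#' falls in "2-12" and 13 in "13-25". Non-integer imputed means follow the
#' same `value <= upper` rule.
#'
#' @param values Non-negative numeric vector.
#' @param scheme A [category_scheme()].
#' @return Factor with the scheme's labels as ordered levels.
#' @export
categorize <- function(values, scheme = pirche_categories()) {
  stopifnot(inherits(scheme, "category_scheme"))
  if (any(values < 0, na.rm = TRUE)) stop("values must be >= 0")
  idx <- vapply(values, function(v) {
    if (is.na(v)) NA_integer_ else which(v <= scheme$upper)[1]
  }, integer(1))
  if (any(is.na(idx) & !is.na(values))) stop("value above the scheme's last bound")
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Derive similarly-sized category boundaries
#'
#' Helper for synthetic cohorts: given target group proportions (for example
#' the cohort's HLA mismatch distribution), returns raw-score boundaries whose
#' groups match those proportions as closely as the score's discreteness
#' allows.
#'
#' @param raw_scores Numeric vector of raw scores.
#' @param proportions Target group proportions (summing to 1).
#' @return A [category_scheme()] on the raw scale.
#' @export
derive_category_scheme <- function(raw_scores, proportions) {
  stopifnot(all(proportions > 0), abs(sum(proportions) - 1) < 1e-8)
  cuts <- stats::quantile(raw_scores, probs = cumsum(proportions),
                          type = 1, names = FALSE)
  upper <- unique(c(cuts[-length(cuts)], Inf))
  lower <- c(0, utils::head(upper, -1) + 1)
  labels <- ifelse(is.infinite(upper), paste0(">", lower - 1),
                   paste0(lower, "-", upper))
  category_scheme(upper, labels)
}

#' Spearman rank correlation between two measures
#'
#' Rank-based correlation with average ranks for ties and a two-sided
#' asymptotic p-value; used to quantify how strongly the epitope score tracks
#' the antigen mismatch count.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List with `rho`, `p_value`, `n`, and `flag` (`NA` or a message,
#'   set when either vector is constant and rho is undefined).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                flag = "constant input: rho undefined"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x), flag = NA_character_)
}
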