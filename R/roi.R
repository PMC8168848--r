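## Return-on-investment scoring ---------------------------------------------

#' Taxonomic-confidence weight table
#'
#' Weights encoding the certainty that a species needs taxonomic revision:
#' no revision 0, probably not 0.2, highly probable 0.8, definitely 1.0.
#' Weights must be monotone non-decreasing in confidence order.
#'
#' @param none,probably_not,highly_probable,definite weights in `[0, 1]`.
#' @return named numeric vector of class `tax_weights`.
#' @export
tax_weights <- function(none = 0, probably_not = 0.2,
                        highly_probable = 0.8, definite = 1.0) {
  w <- c(none = none, probably_not = probably_not,
         highly_probable = highly_probable, definite = definite)
  if (any(w < 0 | w > 1)) stop("tax weights must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(w)) stop("tax weights must be monotone non-decreasing ",
                           "in confidence order", call. = FALSE)
  structure(w, class = "tax_weights")
}

# Core arithmetic, vectorized. benefit/cost integer vectors, tax numeric.
.roi_compute <- function(benefit, cost, tax) benefit * tax / cost

#' ROI score for one assessed species
#'
#' `ROI = (c1 + c2 + c3 + c4) * tax / (r1 + r2 + r3 + r4)`: the summed
#' conservation-benefit flags, weighted by the confidence that revision is
#' needed, divided by the number of outstanding research steps. The species
#' must be in the ROI cohort (predicted outcome `increase`, tax weight > 0)
#' and must have at least one outstanding research step — at minimum,
#' analysis and manuscript preparation are always pending for an undescribed
#' species, so a zero cost is a data error rather than an infinite return.
#'
#' @param assessment one-row canonical assessment data.frame.
#' @param weights a [tax_weights()] table.
#' @param threshold priority threshold on ROI (default 1).
#' @param strict logical; if `TRUE` priority requires `roi > threshold`
#'   rather than the default `roi >= threshold`.
#' @return one-row data.frame: `species_id`, `benefit_sum`, `cost_sum`,
#'   `tax_weight`, `roi`, `is_priority`.
#' @export
roi_score <- function(assessment, weights = tax_weights(), threshold = 1,
                      strict = FALSE) {
  validate_assessments(assessment)
  if (nrow(assessment) != 1L) stop("roi_score expects a single record",
                                   call. = FALSE)
  scores <- score_cohort(assessment, weights = weights, threshold = threshold,
                         strict = strict)
  as.data.frame(scores)[, c("species_id", "benefit_sum", "cost_sum",
                            "tax_weight", "roi", "is_priority")]
}

#' Score an ROI cohort
#'
#' Computes the ROI statistic for every species in a cohort of resolved
#' assessments and ranks them. All records must satisfy the cohort
#' preconditions: outcome `increase`, tax weight > 0 and at least one
#' outstanding research step (use [filter_revision_cohort()] first). The
#' result is sorted by decreasing ROI, ties broken by `species_id` for
#' reproducibility.
#'
#' @inheritParams roi_score
#' @param assessments canonical resolved assessment data.frame.
#' @return object of class `roi_cohort`: a data.frame of scores with
#'   attributes `threshold`, `strict`, `weights` and `priority_count`.
#' @examples
#' a <- synthetic_supplement()
#' res <- resolve_conflicts(a$raw, a$conflict_labels)
#' cohort <- filter_revision_cohort(res$resolved)
#' scores <- score_cohort(cohort)
#' print(scores)
#' @export
score_cohort <- function(assessments, weights = tax_weights(), threshold = 1,
                         strict = FALSE) {
  validate_assessments(assessments, resolved = TRUE)
  stopifnot(inherits(weights, "tax_weights"))

  bad_outcome <- assessments$species_id[assessments$outcome != "increase"]
  if (length(bad_outcome) > 0)
    stop("species outside the ROI cohort (outcome != increase): ",
         paste(bad_outcome, collapse = ", "), call. = FALSE)

  tax <- unclass(weights)[assessments$confidence]
  zero_tax <- assessments$species_id[tax <= 0]
  if (length(zero_tax) > 0)
    stop("species with tax weight 0 cannot be scored: ",
         paste(zero_tax, collapse = ", "), call. = FALSE)

  benefit <- rowSums(assessments[, conservation_cols(), drop = FALSE])
  cost <- rowSums(assessments[, research_cols(), drop = FALSE])
  zero_cost <- assessments$species_id[cost == 0]
  if (length(zero_cost) > 0)
    stop("species with no outstanding research step (cost 0): ",
         paste(zero_cost, collapse = ", "), call. = FALSE)

  roi <- .roi_compute(benefit, cost, tax)
  is_priority <- if (strict) roi > threshold else roi >= threshold

  out <- data.frame(
    species_id = assessments$species_id,
    family = if ("family" %in% names(assessments)) assessments$family
             else NA_character_,
    higher_group = if ("higher_group" %in% names(assessments))
      assessments$higher_group else NA_character_,
    benefit_sum = as.integer(benefit),
    cost_sum = as.integer(cost),
    tax_weight = unname(tax),
    roi = roi,
    is_priority = is_priority,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$roi, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("roi_cohort", "data.frame"),
            threshold = threshold, strict = strict, weights = weights,
            priority_count = sum(is_priority))
}

#' Number of priority species in a scored cohort
#' @param x an `roi_cohort` object.
#' @return integer count of species meeting the priority rule.
#' @export
priority_count <- function(x) {
  stopifnot(inherits(x, "roi_cohort"))
  attr(x, "priority_count")
}

#' @export
print.roi_cohort <- function(x, n = 10L, ...) {
  thr <- attr(x, "threshold")
  op <- if (attr(x, "strict")) ">" else ">="
  cat(sprintf("ROI cohort: %d species, %d priority (ROI %s %g)\n",
              nrow(x), attr(x, "priority_count"), op, thr))
  utils::head(as.data.frame(x), n)
}

#' @export
summary.roi_cohort <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(
    n = nrow(df),
    priority_count = attr(object, "priority_count"),
    threshold = attr(object, "threshold"),
    strict = attr(object, "strict"),
    roi_quantiles = stats::quantile(df$roi, c(0, .25, .5, .75, 1)),
    by_group = if (all(is.na(df$higher_group))) NULL else
      table(df$higher_group, priority = df$is_priority)
  ), class = "summary.roi_cohort")
}

#' @export
print.summary.roi_cohort <- function(x, ...) {
  op <- if (x$strict) ">" else ">="
  cat(sprintf("%d species scored; %d priority (ROI %s %g)\n",
              x$n, x$priority_count, op, x$threshold))
  cat("ROI quantiles:\n")
  print(round(x$roi_quantiles, 3))
  if (!is.null(x$by_group)) { cat("\nBy higher group:\n"); print(x$by_group) }
  invisible(x)
}

#' @export
plot.roi_cohort <- function(x, top = 30L, ...) {
  df <- as.data.frame(x)
  df <- utils::head(df, top)
  df <- df[rev(seq_len(nrow(df))), ]
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(df$roi, names.arg = df$species_id, horiz = TRUE,
                    las = 1, cex.names = 0.6, xlab = "ROI",
                    col = ifelse(df$is_priority, "firebrick", "grey70"), ...)
  graphics::abline(v = attr(x, "threshold"), lty = 2)
  invisible(x)
}

#' Score a resolved assessment table end to end
#'
#' Convenience wrapper: applies the conservative cohort filter (confidence
#' `highly_probable` or better, outcome `increase`) and scores the result.
#' With `permissive = TRUE` the confidence floor drops to `probably_not`,
#' i.e. every species with a positive tax weight is admitted.
#'
#' @inheritParams score_cohort
#' @param records resolved canonical assessment data.frame.
#' @param permissive logical; admit all species with tax weight > 0.
#' @return an `roi_cohort` object.
#' @export
roi_prioritize <- function(records, weights = tax_weights(), threshold = 1,
                           strict = FALSE, permissive = FALSE) {
  floor <- if (permissive) "probably_not" else "highly_probable"
  cohort <- filter_revision_cohort(records, confidence_floor = floor,
                                   outcomes = "increase")
  score_cohort(cohort, weights = weights, threshold = threshold,
               strict = strict)
}
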