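## Headline summaries ---------------------------------------------------------

#' Round half-up
#'
#' Percentages are rendered half-up to one decimal place (base R `round()`
#' is round-half-even). Counts are stored exactly; rounding is applied only
#' at report rendering.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

revision_confidences <- function() c("highly_probable", "definite")

#' Census of taxonomic uncertainty
#'
#' Aggregates a resolved assessment table into the headline counts: species
#' assessed, species probably or definitely needing taxonomic revision, and
#' the split of predicted revision outcomes (increase / decrease /
#' species complex). Percentages are stored exact and rendered to one
#' decimal place by the print method.
#'
#' @param records resolved canonical assessment data.frame.
#' @param n_total_species size of the full species pool the assessments were
#'   drawn from (>= number of records).
#' @return object of class `census_summary`.
#' @export
census <- function(records, n_total_species) {
  validate_assessments(records, resolved = TRUE)
  n_assessed <- nrow(records)
  if (n_total_species < n_assessed)
    stop("n_total_species (", n_total_species,
         ") is smaller than the number of assessed species (", n_assessed,
         ")", call. = FALSE)
  rev_idx <- records$confidence %in% revision_confidences()
  n_revision <- sum(rev_idx)
  oc <- records$outcome[rev_idx]
  n_increase <- sum(oc == "increase")
  n_decrease <- sum(oc == "decrease")
  n_complex <- sum(oc == "species_complex")
  structure(list(
    n_total_species = as.integer(n_total_species),
    n_assessed = n_assessed,
    pct_assessed = pct(n_assessed, n_total_species),
    n_revision = n_revision,
    pct_revision_of_assessed = pct(n_revision, n_assessed),
    n_increase = n_increase,
    n_decrease = n_decrease,
    n_complex = n_complex,
    pct_increase_of_assessed = pct(n_increase, n_assessed),
    pct_increase_incl_complex = pct(n_increase + n_complex, n_assessed)
  ), class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  f <- function(v) format(round_half_up(v, 1), nsmall = 1)
  cat(sprintf("Assessed %d of %d species (%s%%)\n",
              x$n_assessed, x$n_total_species, f(x$pct_assessed)))
  cat(sprintf("Needing revision (highly probable/definite): %d (%s%% of assessed)\n",
              x$n_revision, f(x$pct_revision_of_assessed)))
  cat(sprintf("  increase %d | decrease %d | species complex %d\n",
              x$n_increase, x$n_decrease, x$n_complex))
  cat(sprintf("Unrecognized diversity: %s%% of assessed (%s%% incl. complexes)\n",
              f(x$pct_increase_of_assessed), f(x$pct_increase_incl_complex)))
  invisible(x)
}

#' Family-level summary of taxonomic need
#'
#' One row per family with assessed / increase counts, the percentage of
#' assessed species whose revision would increase diversity, and two flags:
#' `flag_high_revision` (>= 30\% increase — families needing high levels of
#' taxonomic revision) and `flag_low_coverage` (fewer than 75\% of the
#' family's species assessed). Flags are recomputed from the counts.
#'
#' @param records resolved canonical assessment data.frame with non-empty
#'   `family`.
#' @param family_totals optional named integer vector of the total number of
#'   species per family (assessed + unassessed); defaults to the assessed
#'   counts, in which case coverage flags are all `FALSE`.
#' @param high_revision_pct,low_coverage_pct flag thresholds (percent).
#' @return data.frame, one row per family, sorted by family name.
#' @export
family_summary <- function(records, family_totals = NULL,
                           high_revision_pct = 30, low_coverage_pct = 75) {
  validate_assessments(records, resolved = TRUE)
  if (any(is.na(records$family) | !nzchar(records$family)))
    stop("records with empty family", call. = FALSE)
  fams <- sort(unique(records$family))
  rev_idx <- records$confidence %in% revision_confidences()
  inc_idx <- rev_idx & records$outcome == "increase"
  n_assessed <- vapply(fams, function(f) sum(records$family == f), integer(1))
  n_increase <- vapply(fams, function(f)
    sum(inc_idx & records$family == f), integer(1))
  n_species <- if (is.null(family_totals)) n_assessed else {
    missing <- setdiff(fams, names(family_totals))
    if (length(missing) > 0)
      stop("family_totals missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    as.integer(family_totals[fams])
  }
  if (any(n_species < n_assessed))
    stop("family_totals smaller than assessed counts", call. = FALSE)
  pct_increase <- ifelse(n_assessed > 0, 100 * n_increase / n_assessed, NA)
  out <- data.frame(
    family = fams,
    n_species = n_species,
    n_assessed = n_assessed,
    n_increase = n_increase,
    pct_increase = pct_increase,
    flag_high_revision = pct_increase >= high_revision_pct,
    flag_low_coverage = 100 * n_assessed / n_species < low_coverage_pct,
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Research-needs profile of the increase cohort
#'
#' Counts the 16 combinations of the four outstanding research steps
#' (fieldwork, genetics/genomics, morphology, analysis & manuscript) across
#' the increase cohort, split by higher group, and quantifies the
#' description backlog: species whose field sampling and genetic data are
#' already complete (both flags 0) but with at least one remaining step.
#' A record with all four steps complete contradicts "needs revision" and is
#' an error.
#'
#' @param records increase-cohort assessment data.frame (every record must
#'   have outcome `increase`).
#' @return object of class `research_profile`: list with `combinations`
#'   (data.frame of pattern counts by higher group), `n`, `backlog_count`,
#'   `backlog_pct`, and `data_ready` counts per higher group (pattern
#'   `0,0,0,1`: only analysis and manuscript preparation remaining).
#' @export
research_profile <- function(records) {
  validate_assessments(records, resolved = TRUE)
  if (any(records$outcome != "increase"))
    stop("research_profile expects the increase cohort only", call. = FALSE)
  r <- as.matrix(records[, research_cols()])
  zero <- rowSums(r) == 0
  if (any(zero))
    stop("species needing revision but with no outstanding research step: ",
         paste(records$species_id[zero], collapse = ", "), call. = FALSE)
  pattern <- apply(r, 1, paste, collapse = "")
  grp <- records$higher_group
  combos <- as.data.frame(table(pattern = pattern, higher_group = grp),
                          stringsAsFactors = FALSE)
  names(combos)[names(combos) == "Freq"] <- "count"
  backlog_idx <- r[, "r_fieldwork"] == 0 & r[, "r_genetics"] == 0 &
    (r[, "r_morphology"] == 1 | r[, "r_analysis"] == 1)
  ready_idx <- pattern == "0001"
  structure(list(
    n = nrow(records),
    combinations = combos,
    backlog_count = sum(backlog_idx),
    backlog_pct = pct(sum(backlog_idx), nrow(records)),
    data_ready = vapply(split(ready_idx, grp), sum, integer(1)),
    cohort_by_group = vapply(split(seq_len(nrow(records)), grp), length,
                             integer(1))
  ), class = "research_profile")
}

#' @export
print.research_profile <- function(x, ...) {
  cat(sprintf("Increase cohort: %d species\n", x$n))
  cat(sprintf("Backlog (field + genetic data complete, work remaining): %d (%s%%)\n",
              x$backlog_count, format(round_half_up(x$backlog_pct, 1),
                                      nsmall = 1)))
  for (g in names(x$cohort_by_group))
    cat(sprintf("  %s: %d species, %d data-ready (analysis/manuscript only)\n",
                g, x$cohort_by_group[[g]],
                if (g %in% names(x$data_ready)) x$data_ready[[g]] else 0L))
  invisible(x)
}

#' Conservation summary of the increase cohort
#'
#' Counts candidate species predicted to be highly localized (extent of
#' occurrence below the 20,000 km2 IUCN Vulnerable-range threshold) and
#' species of conservation concern. "Concern" is operationalized as a
#' species-level threatening process or a high probability of a threatened
#' Red List category (`rule = "any_threat"`, the default) or as the latter
#' alone (`rule = "high_threat_only"`). Percentages use the increase cohort
#' as denominator; an empty cohort is an error.
#'
#' @param records increase-cohort assessment data.frame.
#' @param rule concern definition, see above.
#' @return object of class `conservation_summary`.
#' @export
conservation_summary <- function(records,
                                 rule = c("any_threat", "high_threat_only")) {
  rule <- match.arg(rule)
  validate_assessments(records, resolved = TRUE)
  if (nrow(records) == 0)
    stop("empty cohort: percentages undefined", call. = FALSE)
  n <- nrow(records)
  n_loc <- sum(records$c_highly_localized == 1)
  concern <- if (rule == "any_threat")
    records$c_threatening_process == 1 | records$c_high_threat_probability == 1
  else records$c_high_threat_probability == 1
  structure(list(
    n = n,
    rule = rule,
    n_highly_localized = n_loc,
    pct_highly_localized = pct(n_loc, n),
    n_concern = sum(concern),
    pct_concern = pct(sum(concern), n)
  ), class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  f <- function(v) format(round_half_up(v, 1), nsmall = 1)
  cat(sprintf("Increase cohort: %d species\n", x$n))
  cat(sprintf("Highly localized (< 20,000 km2 EOO): %d (%s%%)\n",
              x$n_highly_localized, f(x$pct_highly_localized)))
  cat(sprintf("Conservation concern [%s]: %d (%s%%)\n",
              x$rule, x$n_concern, f(x$pct_concern)))
  invisible(x)
}
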