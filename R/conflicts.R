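## Multi-assessor conflict resolution ---------------------------------------

#' Conflict category labels
#'
#' Discordant multi-assessor assessments fall into three categories:
#' \describe{
#'   \item{`morph_vs_genetic` (1)}{morphological variation suggests a
#'     candidate species but unpublished genetic data indicate within-species
#'     variation; resolved as \emph{not} requiring revision.}
#'   \item{`isolated_no_genetic` (2)}{morphology suggests a geographically
#'     isolated short-range endemic candidate with no genetic data for the
#'     location; resolved as \emph{highly probable} revision.}
#'   \item{`already_described` (3)}{an assessor was unaware the candidate has
#'     already been formally described; resolved as not requiring revision.}
#' }
#'
#' @return character vector of the three canonical category labels, named by
#'   their numeric codes.
#' @export
conflict_categories <- function() {
  c(`1` = "morph_vs_genetic", `2` = "isolated_no_genetic",
    `3` = "already_described")
}

normalize_conflict_category <- function(x) {
  cats <- conflict_categories()
  out <- character(length(x))
  for (i in seq_along(x)) {
    xi <- as.character(x[[i]])
    if (xi %in% names(cats)) out[i] <- cats[[xi]]
    else if (normalize_label(xi) %in% cats) out[i] <- normalize_label(xi)
    else stop("unknown conflict category: ", xi, call. = FALSE)
  }
  out
}

# does a record assert that revision is needed?
asserts_revision <- function(rec) {
  rec$confidence %in% c("highly_probable", "definite") | rec$outcome != "none"
}

merge_flags_max <- function(block, cols) {
  vapply(cols, function(cl) as.integer(max(block[[cl]])), integer(1))
}

first_nonempty <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) > 0) x[[1]] else NA_character_
}

#' Resolve multi-assessor assessment conflicts
#'
#' Collapses a raw, possibly multi-row-per-species assessment table into one
#' resolved record per species. Concordant duplicates (same confidence and
#' outcome) are merged, with the eight binary flags combined by field-wise
#' maximum (any assessor flagging a need or benefit keeps it). Species whose
#' duplicate records disagree on confidence or outcome must carry a conflict
#' category in `conflict_labels`:
#' categories 1 (`morph_vs_genetic`) and 3 (`already_described`) resolve
#' conservatively to confidence `none`, outcome `none`, all flags 0;
#' category 2 (`isolated_no_genetic`) resolves to confidence
#' `highly_probable`, with the outcome and flags taken from the record(s)
#' asserting revision (flags by field-wise maximum).
#'
#' The operation is deterministic and idempotent: resolving an already
#' resolved table is the identity.
#'
#' @param records raw canonical assessment data.frame (see
#'   [read_assessments()]).
#' @param conflict_labels named vector mapping `species_id` to a conflict
#'   category (numeric code 1/2/3 or label); only needed for species with
#'   discordant duplicates.
#' @return list with components `resolved` (canonical data.frame, one row per
#'   species, sorted by `species_id`) and `conflicts` (data.frame log:
#'   `species_id`, `category`, `n_records`, `resolution_confidence`).
#' @export
resolve_conflicts <- function(records, conflict_labels = NULL) {
  validate_assessments(records)
  if (!is.null(conflict_labels) && length(conflict_labels) > 0) {
    stopifnot(!is.null(names(conflict_labels)))
    names(conflict_labels) <- normalize_species_id(names(conflict_labels))
    conflict_labels <- stats::setNames(
      normalize_conflict_category(conflict_labels), names(conflict_labels))
  }

  ids <- sort(unique(records$species_id))
  resolved <- vector("list", length(ids))
  log_rows <- list()
  unresolved <- character(0)

  for (k in seq_along(ids)) {
    id <- ids[k]
    block <- records[records$species_id == id, , drop = FALSE]
    if (nrow(block) == 1L) {
      resolved[[k]] <- block
      next
    }
    concordant <- length(unique(block$confidence)) == 1L &&
      length(unique(block$outcome)) == 1L
    if (concordant) {
      rec <- block[1, , drop = FALSE]
      rec[, binary_cols()] <- as.list(merge_flags_max(block, binary_cols()))
      rec$assessor_id <- NA_character_
      resolved[[k]] <- rec
      next
    }
    if (is.null(conflict_labels) || !id %in% names(conflict_labels)) {
      unresolved <- c(unresolved, id)
      next
    }
    category <- conflict_labels[[id]]
    rec <- block[1, , drop = FALSE]
    rec$assessor_id <- NA_character_
    rec$family <- first_nonempty(block$family)
    if (category %in% c("morph_vs_genetic", "already_described")) {
      rec$confidence <- "none"
      rec$outcome <- "none"
      rec[, binary_cols()] <- as.list(rep(0L, length(binary_cols())))
    } else { # isolated_no_genetic
      rec$confidence <- "highly_probable"
      asserters <- block[asserts_revision(block), , drop = FALSE]
      if (nrow(asserters) == 0L) asserters <- block
      oc <- asserters$outcome[asserters$outcome != "none"]
      rec$outcome <- if (length(oc) > 0) oc[[1]] else "none"
      rec[, binary_cols()] <- as.list(merge_flags_max(asserters, binary_cols()))
    }
    resolved[[k]] <- rec
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      species_id = id, category = category, n_records = nrow(block),
      resolution_confidence = rec$confidence, stringsAsFactors = FALSE)
  }

  if (length(unresolved) > 0)
    stop("discordant assessments without a conflict label for species: ",
         paste(unresolved, collapse = ", "), call. = FALSE)

  res <- do.call(rbind, resolved)
  rownames(res) <- NULL
  conflicts <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(species_id = character(0), category = character(0),
               n_records = integer(0), resolution_confidence = character(0),
               stringsAsFactors = FALSE)
  validate_assessments(res, resolved = TRUE)
  list(resolved = res, conflicts = conflicts)
}

#' Write a conflict-resolution log to CSV
#'
#' @param conflicts the `conflicts` component of [resolve_conflicts()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_conflict_log <- function(conflicts, path) {
  utils::write.csv(conflicts, path, row.names = FALSE)
  invisible(path)
}

#' Filter assessments to a revision cohort
#'
#' Retains resolved records at or above a taxonomic-confidence floor and,
#' optionally, with a predicted revision outcome in a given set. The default
#' floor keeps only the `highly_probable` and `definite` categories — the
#' deliberately conservative rule that limits overinflation of the estimated
#' taxonomic uncertainty. For ROI scoring restrict `outcomes` to
#' `"increase"`; for the uncertainty census pass `outcomes = NULL` (any).
#'
#' @param records resolved canonical assessment data.frame.
#' @param confidence_floor minimum confidence category retained.
#' @param outcomes character vector of outcomes retained, or `NULL` for all.
#' @return subset of `records`.
#' @export
filter_revision_cohort <- function(records,
                                   confidence_floor = "highly_probable",
                                   outcomes = "increase") {
  validate_assessments(records, resolved = TRUE)
  stopifnot(confidence_floor %in% confidence_levels())
  conf <- factor(records$confidence, levels = confidence_levels(),
                 ordered = TRUE)
  keep <- conf >= confidence_floor
  if (!is.null(outcomes)) {
    stopifnot(all(outcomes %in% outcome_levels()))
    keep <- keep & records$outcome %in% outcomes
  }
  records[keep, , drop = FALSE]
}
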