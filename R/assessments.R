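#' @keywords internal
"_PACKAGE"

## Canonical vocabulary ------------------------------------------------------

#' Canonical category levels used throughout the package
#'
#' Taxonomic confidence is ordered: `none < probably_not < highly_probable <
#' definite`. Revision outcome is unordered and mutually exclusive.
#'
#' @name vocabulary
#' @keywords internal
NULL

confidence_levels <- function() {
  c("none", "probably_not", "highly_probable", "definite")
}

outcome_levels <- function() {
  c("none", "increase", "decrease", "species_complex")
}

research_cols <- function() {
  c("r_fieldwork", "r_genetics", "r_morphology", "r_analysis")
}

conservation_cols <- function() {
  c("c_enables_assessment", "c_highly_localized",
    "c_threatening_process", "c_high_threat_probability")
}

binary_cols <- function() c(research_cols(), conservation_cols())

#' Canonical assessment-table schema
#'
#' Returns the canonical column names of an assessment table, one row per
#' species (or per species x assessor for raw, unresolved tables).
#'
#' @param optional logical; include optional columns (`family`,
#'   `higher_group`, `assessor_id` and the three free-text note fields).
#' @return character vector of column names.
#' @export
assessment_schema <- function(optional = TRUE) {
  required <- c("species_id", "confidence", "outcome", binary_cols())
  if (!optional) return(required)
  c("species_id", "family", "higher_group", "assessor_id",
    "confidence", "outcome", binary_cols(),
    "notes_taxonomy", "notes_research", "notes_conservation")
}

## Parsing helpers -----------------------------------------------------------

# Normalize a free-form label: trim, lower-case, collapse separators.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ /-]+", "_", x)
}

parse_confidence <- function(x) {
  lab <- normalize_label(x)
  lab[lab %in% c("no_revision", "no", "0")] <- "none"
  lab[lab %in% c("probably_not", "prob_not")] <- "probably_not"
  lab[lab %in% c("highly_probable", "high", "probable")] <- "highly_probable"
  lab[lab %in% c("definite", "definitely", "yes")] <- "definite"
  out <- factor(lab, levels = confidence_levels(), ordered = TRUE)
  bad <- which(!is.na(x) & nzchar(trimws(as.character(x))) & is.na(out))
  blank <- which(is.na(x) | !nzchar(trimws(as.character(x))))
  list(value = out, bad = bad, blank = blank)
}

parse_outcome <- function(x) {
  lab <- normalize_label(x)
  lab[lab %in% c("", "na", "none")] <- "none"
  lab[lab %in% c("complex", "species_complex", "sp_complex")] <- "species_complex"
  lab[lab == "synonymy"] <- "decrease"
  out <- factor(lab, levels = outcome_levels())
  # blank cells mean "no predicted direction", not an error
  out[is.na(x)] <- "none"
  bad <- which(is.na(out))
  list(value = out, bad = bad)
}

# Coerce a column to {0,1} integers. Blank handling is caller policy.
parse_binary <- function(x, col, blank_to_zero = FALSE) {
  raw <- trimws(as.character(x))
  blank <- is.na(x) | !nzchar(raw)
  val <- suppressWarnings(as.numeric(raw))
  ok <- !blank & !is.na(val) & val %in% c(0, 1)
  if (blank_to_zero) {
    val[blank] <- 0
    ok <- ok | blank
  }
  if (!all(ok)) {
    stop(sprintf("non-binary value in column '%s' at row(s) %s",
                 col, paste(which(!ok), collapse = ", ")), call. = FALSE)
  }
  list(value = as.integer(val), n_blank = sum(blank))
}

## Validation ----------------------------------------------------------------

#' Validate a canonical assessment table
#'
#' Checks column presence, category levels and binary domains. Called by
#' [read_assessments()] and by every function that consumes assessments.
#'
#' @param x data.frame in canonical form.
#' @param resolved logical; additionally require at most one row per species.
#' @return `x`, invisibly, with canonical column types enforced.
#' @export
validate_assessments <- function(x, resolved = FALSE) {
  stopifnot(is.data.frame(x))
  missing <- setdiff(assessment_schema(optional = FALSE), names(x))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(is.na(x$species_id) | !nzchar(trimws(x$species_id))))
    stop("empty species_id", call. = FALSE)
  if (!all(x$confidence %in% confidence_levels()))
    stop("invalid confidence value(s): ",
         paste(unique(setdiff(x$confidence, confidence_levels())), collapse = ", "),
         call. = FALSE)
  if (!all(x$outcome %in% outcome_levels()))
    stop("invalid outcome value(s)", call. = FALSE)
  for (col in binary_cols()) {
    v <- x[[col]]
    if (!all(v %in% c(0L, 1L)))
      stop(sprintf("column '%s' contains values outside {0,1} at row(s) %s",
                   col, paste(which(!v %in% c(0L, 1L)), collapse = ", ")),
           call. = FALSE)
    x[[col]] <- as.integer(v)
  }
  if (resolved && anyDuplicated(x$species_id))
    stop("duplicated species_id in resolved table: ",
         paste(unique(x$species_id[duplicated(x$species_id)]), collapse = ", "),
         call. = FALSE)
  invisible(x)
}

## Reading and writing -------------------------------------------------------

#' Read an expert-elicitation assessment table
#'
#' Reads a CSV of structured expert assessments, one row per species (or
#' per species x assessor), and canonicalizes it: confidence and outcome
#' labels are normalized, the eight research/conservation flags are coerced
#' to `{0,1}`, blank conservation cells default conservatively to 0 (with a
#' warning), and blank confidence cells are rejected. Source files whose
#' headers differ from the canonical schema are mapped via `column_map`.
#'
#' @param source path to a CSV file (UTF-8, header row).
#' @param column_map optional named character vector mapping canonical
#'   column names to the source file's headers, e.g.
#'   `c(species_id = "Species", r_genetics = "Genetics needed")`.
#' @return data.frame in canonical form (see [assessment_schema()]); species
#'   identifiers are whitespace-trimmed, internal whitespace collapsed, and
#'   lower-cased for matching purposes is *not* applied (identity is exact
#'   match after whitespace/case normalization, see [normalize_species_id()]).
#' @seealso [write_assessments()], [resolve_conflicts()]
#' @export
read_assessments <- function(source, column_map = NULL) {
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  raw <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  # apply header aliases
  if (!is.null(column_map)) {
    stopifnot(!is.null(names(column_map)))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop("column_map refers to absent source column '", src, "'",
             call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing <- setdiff(assessment_schema(optional = FALSE), names(raw))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  n <- nrow(raw)
  out <- data.frame(
    species_id = normalize_species_id(raw$species_id),
    family = if ("family" %in% names(raw)) trimws(raw$family) else NA_character_,
    higher_group = if ("higher_group" %in% names(raw))
      normalize_label(raw$higher_group) else rep("other", n),
    assessor_id = if ("assessor_id" %in% names(raw))
      trimws(raw$assessor_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  out$higher_group[!out$higher_group %in% c("lizard", "snake")] <- "other"

  conf <- parse_confidence(raw$confidence)
  if (length(conf$blank) > 0)
    stop("blank confidence at row(s) ", paste(conf$blank, collapse = ", "),
         call. = FALSE)
  if (length(conf$bad) > 0)
    stop("unrecognized confidence at row(s) ", paste(conf$bad, collapse = ", "),
         call. = FALSE)
  out$confidence <- as.character(conf$value)

  oc <- parse_outcome(raw$outcome)
  if (length(oc$bad) > 0)
    stop("unrecognized outcome at row(s) ", paste(oc$bad, collapse = ", "),
         call. = FALSE)
  out$outcome <- as.character(oc$value)

  for (col in research_cols())
    out[[col]] <- parse_binary(raw[[col]], col, blank_to_zero = FALSE)$value
  n_blank <- 0L
  for (col in conservation_cols()) {
    p <- parse_binary(raw[[col]], col, blank_to_zero = TRUE)
    out[[col]] <- p$value
    n_blank <- n_blank + p$n_blank
  }
  if (n_blank > 0)
    warning(n_blank, " blank conservation cell(s) scored conservatively as 0",
            call. = FALSE)

  for (col in c("notes_taxonomy", "notes_research", "notes_conservation"))
    out[[col]] <- if (col %in% names(raw)) raw[[col]] else NA_character_

  validate_assessments(out)
  out
}

#' Normalize a species identifier
#'
#' Identity is exact string match after trimming, collapsing internal
#' whitespace, and lower-casing; no fuzzy synonym matching is attempted.
#'
#' @param x character vector of species names/identifiers.
#' @return normalized character vector.
#' @export
normalize_species_id <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Write a canonical assessment table to CSV
#'
#' Inverse of [read_assessments()]: binary and category columns round-trip
#' bit-exactly.
#'
#' @param x canonical assessment data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(x, path) {
  validate_assessments(x)
  cols <- intersect(assessment_schema(optional = TRUE), names(x))
  utils::write.csv(x[, cols, drop = FALSE], path, row.names = FALSE, na = "")
  invisible(path)
}
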