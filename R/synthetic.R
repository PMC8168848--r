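## Synthetic assessment and range generator ----------------------------------

#' Configuration for the synthetic-data generator
#'
#' Defines the marginal rates, distributions and seed governing generated
#' assessment tables and range polygons. The defaults are calibrated to the
#' composition of the Australian squamate expert-elicitation study the
#' package emulates: 870/1,034 species assessed; 282/870 probably or
#' definitely needing revision; revision outcomes split
#' (increase, decrease, complex, undirected) = (216, 11, 43, 12)/282;
#' per-step research-need probabilities implying a ~26.4\% description
#' backlog; 52/216 highly localized and P(threat or high-threat) = 38/216
#' among increase species; 27/870 conflicted species in a 21:5:1 category
#' mix. Range areas are lognormal (km2), heavy-tailed with mass below the
#' 20,000 km2 "highly localized" threshold.
#'
#' @param n_species number of species to generate.
#' @param seed root seed; all randomness derives from it through named
#'   substreams, so identical seed + config give identical output.
#' @param p_assessed probability a species receives an expert assessment.
#' @param p_confidence 4-vector of probabilities over confidence categories
#'   (none, probably_not, highly_probable, definite); must sum to 1.
#' @param p_outcome_given_revision 4-vector over (increase, decrease,
#'   species_complex, none) for revision-needed species; must sum to 1.
#' @param p_research 4-vector of independent per-step need probabilities for
#'   revision-needed species; a guard forces `r_analysis = 1` when all four
#'   draws are 0, so every revision-needed species has at least one step.
#' @param p_conservation 3-vector of probabilities for `c_highly_localized`,
#'   `c_threatening_process`, `c_high_threat_probability`, drawn only for
#'   increase-outcome species (conservative default 0 otherwise);
#'   `c_enables_assessment` is set to 1 for every increase species.
#' @param p_conflict probability an assessed species receives a second,
#'   discordant assessment.
#' @param conflict_mix 3-vector of relative weights of conflict categories
#'   1:2:3 (default 21:5:1).
#' @param n_families number of families (round-robin assignment).
#' @param extent bounding box `c(xmin, ymin, xmax, ymax)` in meters
#'   (equal-area CRS) for range placement.
#' @param range_area_log_mean,range_area_log_sd lognormal parameters of
#'   range area in km2.
#' @param crs planar CRS of generated ranges.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_species = 1034,
    seed = 1,
    p_assessed = 870 / 1034,
    p_confidence = c(none = 400 / 870, probably_not = 188 / 870,
                     highly_probable = 200 / 870, definite = 82 / 870),
    p_outcome_given_revision = c(increase = 216 / 282, decrease = 11 / 282,
                                 species_complex = 43 / 282, none = 12 / 282),
    p_research = c(r_fieldwork = 0.48, r_genetics = 0.48,
                   r_morphology = 0.60, r_analysis = 0.95),
    p_conservation = c(c_highly_localized = 52 / 216,
                       c_threatening_process = 0.12,
                       c_high_threat_probability = 0.0635),
    p_conflict = 27 / 870,
    conflict_mix = c(21, 5, 1),
    n_families = 13,
    extent = c(-1900000, -4800000, 2000000, -1100000),
    range_area_log_mean = 10,
    range_area_log_sd = 1.5,
    crs = "EPSG:3577") {
  chk_prob <- function(p, nm) {
    if (any(p < 0 | p > 1)) stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  chk_simplex <- function(p, nm, k) {
    if (length(p) != k || abs(sum(p) - 1) > 1e-8)
      stop(nm, " must be a ", k, "-vector summing to 1", call. = FALSE)
    chk_prob(p, nm)
  }
  chk_prob(p_assessed, "p_assessed"); chk_prob(p_conflict, "p_conflict")
  chk_simplex(p_confidence, "p_confidence", 4)
  chk_simplex(p_outcome_given_revision, "p_outcome_given_revision", 4)
  chk_prob(p_research, "p_research"); chk_prob(p_conservation, "p_conservation")
  stopifnot(length(p_research) == 4, length(p_conservation) == 3,
            length(conflict_mix) == 3, all(conflict_mix >= 0),
            n_species >= 1, n_families >= 1, range_area_log_sd >= 0)
  structure(list(
    n_species = as.integer(n_species), seed = as.integer(seed),
    p_assessed = p_assessed, p_confidence = p_confidence,
    p_outcome_given_revision = p_outcome_given_revision,
    p_research = p_research, p_conservation = p_conservation,
    p_conflict = p_conflict, conflict_mix = conflict_mix,
    n_families = as.integer(n_families), extent = extent,
    range_area_log_mean = range_area_log_mean,
    range_area_log_sd = range_area_log_sd, crs = crs),
    class = "synthetic_config")
}

# Named substreams derived from the root seed: adding a component never
# perturbs the draws of the others. Offsets keep derived seeds < 2^31.
substream_seed <- function(config, name) {
  offsets <- c(assessed = 1L, confidence = 2L, outcome = 3L, research = 4L,
               conservation = 5L, conflict = 6L, geometry = 7L)
  if (!name %in% names(offsets)) stop("unknown substream: ", name)
  (abs(config$seed) + offsets[[name]] * 1000003L) %% .Machine$integer.max
}

with_substream <- function(config, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(config, name))
  expr
}

#' Generate a raw synthetic assessment table
#'
#' Draws one assessment per species from the configured marginal rates, then
#' injects multi-assessor conflicts: a conflicted species is emitted as two
#' discordant rows (assessors A and B) together with its conflict-category
#' label, such that resolving with [resolve_conflicts()] recovers the
#' originally drawn record for category 2 and a conservative
#' no-revision record for categories 1 and 3.
#'
#' @param config a [synthetic_config()].
#' @return list: `raw` (canonical data.frame, possibly two rows for
#'   conflicted species), `conflict_labels` (named category vector),
#'   `n_total_species`, and `resolved_preview` (the intended post-resolution
#'   table, for reference).
#' @export
generate_assessments <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_species
  ids <- sprintf("sp%04d", seq_len(n))
  families <- paste0("family_", sprintf("%02d", ((seq_len(n) - 1L) %%
                                                   config$n_families) + 1L))
  higher <- ifelse(((seq_len(n) - 1L) %% config$n_families) <
                     ceiling(config$n_families * 2 / 3), "lizard", "snake")

  assessed <- with_substream(config, "assessed",
                             stats::runif(n) < config$p_assessed)
  conf <- with_substream(config, "confidence",
                         sample(confidence_levels(), n, replace = TRUE,
                                prob = config$p_confidence))
  needs_rev <- conf %in% c("highly_probable", "definite")
  outc <- rep("none", n)
  outc[needs_rev] <- with_substream(config, "outcome",
    sample(c("increase", "decrease", "species_complex", "none"),
           sum(needs_rev), replace = TRUE,
           prob = config$p_outcome_given_revision))

  r <- matrix(0L, n, 4, dimnames = list(NULL, research_cols()))
  k <- sum(needs_rev)
  if (k > 0) {
    draws <- with_substream(config, "research",
      matrix(stats::runif(k * 4), k, 4))
    rk <- matrix(as.integer(t(t(draws) < config$p_research)), k, 4)
    allzero <- rowSums(rk) == 0
    rk[allzero, 4] <- 1L  # at minimum analysis & manuscript remain
    r[needs_rev, ] <- rk
  }

  cmat <- matrix(0L, n, 4, dimnames = list(NULL, conservation_cols()))
  inc <- outc == "increase"
  cmat[inc, "c_enables_assessment"] <- 1L
  ki <- sum(inc)
  if (ki > 0) {
    draws <- with_substream(config, "conservation",
      matrix(stats::runif(ki * 3), ki, 3))
    cmat[inc, 2:4] <- matrix(as.integer(t(t(draws) < config$p_conservation)),
                             ki, 3)
  }

  resolved <- data.frame(
    species_id = ids, family = families, higher_group = higher,
    assessor_id = "assessor_a", confidence = conf, outcome = outc,
    stringsAsFactors = FALSE)
  resolved <- cbind(resolved, as.data.frame(r), as.data.frame(cmat))
  resolved$notes_taxonomy <- NA_character_
  resolved$notes_research <- NA_character_
  resolved$notes_conservation <- NA_character_
  resolved <- resolved[assessed, , drop = FALSE]
  rownames(resolved) <- NULL

  # conflict injection on the assessed set
  m <- nrow(resolved)
  conflict_draw <- with_substream(config, "conflict", {
    is_conf <- stats::runif(m) < config$p_conflict
    cats <- sample(names(conflict_categories()), m, replace = TRUE,
                   prob = config$conflict_mix / sum(config$conflict_mix))
    list(is_conf = is_conf, cats = cats)
  })
  # category 2 must resolve to highly_probable + retained outcome: only
  # inject it on species already drawn as highly_probable; categories 1/3
  # resolve to "none": only inject on species drawn with confidence none.
  eligible2 <- conflict_draw$is_conf & resolved$confidence == "highly_probable"
  eligible13 <- conflict_draw$is_conf & resolved$confidence == "none"
  use2 <- eligible2 & conflict_draw$cats == "2"
  use13 <- eligible13 & conflict_draw$cats %in% c("1", "3")

  raw <- resolved
  labels <- character(0)
  extra <- list()
  for (i in which(use2)) {
    # assessor B saw no evidence of revision
    b <- resolved[i, , drop = FALSE]
    b$assessor_id <- "assessor_b"
    b$confidence <- "none"; b$outcome <- "none"
    b[, binary_cols()] <- as.list(rep(0L, 8))
    extra[[length(extra) + 1L]] <- b
    labels[resolved$species_id[i]] <- "isolated_no_genetic"
  }
  for (i in which(use13)) {
    # assessor B asserted a candidate from morphology (cat 1) or an already
    # described species (cat 3); panel resolution discards it
    b <- resolved[i, , drop = FALSE]
    b$assessor_id <- "assessor_b"
    b$confidence <- "highly_probable"; b$outcome <- "increase"
    b$r_analysis <- 1L; b$c_enables_assessment <- 1L
    extra[[length(extra) + 1L]] <- b
    labels[resolved$species_id[i]] <-
      conflict_categories()[[conflict_draw$cats[i]]]
  }
  if (length(extra) > 0) raw <- rbind(raw, do.call(rbind, extra))
  raw <- raw[order(raw$species_id, raw$assessor_id), , drop = FALSE]
  rownames(raw) <- NULL

  list(raw = raw, conflict_labels = labels,
       n_total_species = n, resolved_preview = resolved)
}

# regular k-gon of given area centred at (cx, cy)
circle_polygon <- function(cx, cy, area, k = 48) {
  r <- sqrt(2 * area / (k * sin(2 * pi / k)))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

#' Generate synthetic range polygons
#'
#' One convex blob (regular 48-gon of the target area, clipped to the
#' extent) per species, centered at a uniform random point. Target areas are
#' lognormal in km2; species flagged as highly localized are forced below
#' the 20,000 km2 extent-of-occurrence threshold by truncated resampling.
#' Blobs are deliberately simple — they exercise the overlay logic, not
#' realistic range shapes.
#'
#' @param config a [synthetic_config()].
#' @param species_ids character vector of species identifiers.
#' @param localized logical vector (same length) marking species whose area
#'   must fall below `localized_threshold_km2`.
#' @param localized_threshold_km2 the EOO threshold, default 20,000.
#' @return list of [range_map()] objects.
#' @export
generate_ranges <- function(config, species_ids,
                            localized = rep(FALSE, length(species_ids)),
                            localized_threshold_km2 = 20000) {
  stopifnot(inherits(config, "synthetic_config"),
            length(localized) == length(species_ids))
  ext <- config$extent
  w <- ext[3] - ext[1]; h <- ext[4] - ext[2]
  n <- length(species_ids)
  with_substream(config, "geometry", {
    areas_km2 <- stats::rlnorm(n, config$range_area_log_mean,
                               config$range_area_log_sd)
    for (i in which(localized)) {
      tries <- 0
      while (areas_km2[i] >= localized_threshold_km2 && tries < 1000) {
        areas_km2[i] <- stats::rlnorm(1, config$range_area_log_mean,
                                      config$range_area_log_sd)
        tries <- tries + 1
      }
      if (areas_km2[i] >= localized_threshold_km2)
        areas_km2[i] <- stats::runif(1, 0.5, 0.95) * localized_threshold_km2
    }
    radius <- sqrt(areas_km2 * 1e6 / pi)
    if (any(2 * radius > min(w, h)))
      stop("extent too small for requested range area(s)", call. = FALSE)
    cx <- stats::runif(n, ext[1], ext[3])
    cy <- stats::runif(n, ext[2], ext[4])
    lapply(seq_len(n), function(i) {
      ring <- circle_polygon(cx[i], cy[i], areas_km2[i] * 1e6)
      ring <- clip_ring_rect(ring, ext[1], ext[2], ext[3], ext[4])
      if (nrow(ring) < 3)
        ring <- circle_polygon(
          min(max(cx[i], ext[1] + radius[i]), ext[3] - radius[i]),
          min(max(cy[i], ext[2] + radius[i]), ext[4] - radius[i]),
          areas_km2[i] * 1e6)
      range_map(species_ids[i], ring, crs = config$crs)
    })
  })
}

#' Worked-example fixture for the weighted-mean grid cell
#'
#' Six species whose ranges all fall inside one 25 km grid cell, with ROI
#' scores (1, 1, 1, 1, 3, 4): the cell's richness is 6 and its weighted mean
#' score is 11/6 = 1.83, the textbook example of the richness-adjusted cell
#' score.
#'
#' @return list: `scores` (named vector), `ranges` (list of range maps),
#'   `grid` (4 x 4 grid of 25 km cells), `target_cell` (row, col).
#' @export
make_worked_example_fixture <- function() {
  grid <- build_grid(c(0, 0, 100000, 100000), cell_size = 25000)
  # target cell row 2, col 2: [25, 50) km square
  centers <- cbind(x = c(30, 35, 40, 45, 37, 42) * 1000,
                   y = c(30, 42, 35, 44, 38, 30) * 1000)
  ids <- sprintf("sp%d", 1:6)
  ranges <- lapply(1:6, function(i)
    range_map(ids[i], circle_polygon(centers[i, 1], centers[i, 2],
                                     area = 4e6)))  # 4 km2 blobs
  scores <- stats::setNames(c(1, 1, 1, 1, 3, 4), ids)
  list(scores = scores, ranges = ranges, grid = grid,
       target_cell = c(row = 2L, col = 2L))
}
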