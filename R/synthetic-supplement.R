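## Synthetic benchmark supplement --------------------------------------------

# Family composition of the synthetic pool (total, assessed, increase and
# the non-increase assessed split). Lizard families first, then snakes.
supplement_families <- function() {
  df <- data.frame(
    family = c("Scincidae", "Diplodactylidae", "Agamidae",
               "Carphodactylidae", "Gekkonidae", "Pygopodidae", "Varanidae",
               "Elapidae", "Typhlopidae", "Pythonidae", "Colubridae",
               "Homalopsidae", "Acrochordidae"),
    higher_group = c(rep("lizard", 7), rep("snake", 6)),
    n_total  = c(430, 155, 110, 35, 56, 45, 31, 90, 47, 15, 10, 8, 2),
    n_assessed = c(350, 140, 95, 30, 46, 40, 29, 75, 35, 14, 8, 6, 2),
    n_increase = c(60, 55, 20, 6, 9, 7, 10, 19, 21, 6, 2, 1, 0),
    n_complex  = c(25, 8, 5, 0, 0, 0, 0, 5, 0, 0, 0, 0, 0),
    n_decrease = c(6, 0, 0, 0, 2, 0, 0, 3, 0, 0, 0, 0, 0),
    n_nodir    = c(6, 0, 0, 0, 0, 3, 0, 0, 3, 0, 0, 0, 0),
    n_probnot  = c(81, 25, 22, 8, 11, 10, 6, 15, 4, 3, 2, 1, 0),
    stringsAsFactors = FALSE)
  df$n_none <- df$n_assessed - df$n_increase - df$n_complex - df$n_decrease -
    df$n_nodir - df$n_probnot
  stopifnot(sum(df$n_total) == 1034, sum(df$n_assessed) == 870,
            sum(df$n_increase) == 216, all(df$n_none >= 0))
  df
}

# The 216 increase-cohort flag patterns, in cohort order (167 lizards then
# 49 snakes). Columns: confidence, c1..c4, r1..r4. The composition realizes
# the benchmark aggregates: 24 species with ROI >= 1 (all lizards), 52
# highly localized, 38 of conservation concern, 57 backlog species (26.4%),
# and 9 data-ready snakes.
supplement_increase_patterns <- function() {
  pat <- function(k, conf, c4v, r4v)
    data.frame(confidence = rep(conf, k),
               c_enables_assessment = 1L,
               c_highly_localized = c4v[1], c_threatening_process = c4v[2],
               c_high_threat_probability = c4v[3],
               r_fieldwork = r4v[1], r_genetics = r4v[2],
               r_morphology = r4v[3], r_analysis = r4v[4],
               stringsAsFactors = FALSE)
  lizard <- rbind(
    pat(10, "definite",        c(1, 1, 1), c(1, 1, 1, 1)),  # ROI 1.0
    pat(10, "highly_probable", c(1, 1, 1), c(0, 0, 1, 1)),  # ROI 1.6
    pat(4,  "definite",        c(1, 1, 0), c(0, 0, 0, 1)),  # ROI 3.0
    pat(14, "highly_probable", c(1, 1, 0), c(1, 1, 1, 1)),  # ROI 0.6
    pat(14, "highly_probable", c(1, 0, 0), c(1, 1, 1, 1)),  # ROI 0.4
    pat(34, "highly_probable", c(0, 0, 0), c(0, 0, 1, 1)),  # ROI 0.4
    pat(44, "highly_probable", c(0, 0, 0), c(1, 1, 1, 1)),  # ROI 0.2
    pat(37, "definite",        c(0, 0, 0), c(1, 1, 1, 1)))  # ROI 0.25
  snake <- rbind(
    pat(31, "definite",        c(0, 0, 0), c(1, 1, 1, 1)),  # ROI 0.25
    pat(9,  "highly_probable", c(0, 0, 0), c(1, 1, 1, 1)),  # ROI 0.2
    pat(9,  "highly_probable", c(0, 0, 0), c(0, 0, 0, 1)))  # ROI 0.8, ready
  lizard$higher_group <- "lizard"
  snake$higher_group <- "snake"
  rbind(lizard, snake)
}

#' Synthetic stand-in for the published assessment supplement
#'
#' A deterministic, fully synthetic assessment table (no randomness, no
#' external data) whose composition realizes the benchmark aggregate
#' structure of the Australian squamate expert-elicitation study: 1,034
#' species of which 870 are assessed; 282 probably or definitely needing
#' revision, splitting 216 increase / 43 species complex / 11 decrease (12
#' with no predicted direction); 52 increase species flagged highly
#' localized and 38 of conservation concern; 24 priority species at
#' ROI >= 1; a 57/216 = 26.4\% description backlog; 49 snake increase
#' species of which 9 are data-ready; and 27 multi-assessor conflicts in
#' the 21:5:1 category mix. Family composition follows Australian squamate
#' families, with Diplodactylidae, Varanidae, Pythonidae and Typhlopidae the
#' four families at or above the 30\% high-revision flag.
#'
#' This is a synthetic benchmark for exercising and validating the pipeline
#' end to end — it is not the study's data; only its aggregate composition
#' is emulated. Species identifiers are synthetic (`sp0001`...).
#'
#' @return list: `raw` (canonical table including the 27 conflicted species
#'   as discordant assessor A/B row pairs), `conflict_labels` (named
#'   category vector), `n_total_species` (1034), and `family_totals` (named
#'   vector incl. unassessed species, for [family_summary()]).
#' @export
synthetic_supplement <- function() {
  fams <- supplement_families()
  inc <- supplement_increase_patterns()

  # lay out per-family blocks of resolved records
  rows <- list()
  li <- 1L  # cursor into lizard increase patterns (1..167)
  si <- 168L # cursor into snake increase patterns (168..216)
  for (f in seq_len(nrow(fams))) {
    fam <- fams[f, ]
    blk <- list()
    take_inc <- function(k) {
      if (fam$higher_group == "lizard") {
        idx <- li:(li + k - 1L); li <<- li + k
      } else {
        idx <- si:(si + k - 1L); si <<- si + k
      }
      p <- inc[idx, , drop = FALSE]
      data.frame(confidence = p$confidence, outcome = "increase",
                 p[, c(research_cols(), conservation_cols())],
                 stringsAsFactors = FALSE)
    }
    plain <- function(k, conf, outcome, r = c(1L, 1L, 1L, 1L)) {
      if (k == 0) return(NULL)
      data.frame(confidence = rep(conf, k), outcome = outcome,
                 r_fieldwork = r[1], r_genetics = r[2], r_morphology = r[3],
                 r_analysis = r[4], c_enables_assessment = 0L,
                 c_highly_localized = 0L, c_threatening_process = 0L,
                 c_high_threat_probability = 0L, stringsAsFactors = FALSE)
    }
    if (fam$n_increase > 0) blk$inc <- take_inc(fam$n_increase)
    blk$cpx <- plain(fam$n_complex, "highly_probable", "species_complex")
    blk$dec <- plain(fam$n_decrease, "highly_probable", "decrease",
                     r = c(0L, 0L, 1L, 1L))
    blk$nod <- plain(fam$n_nodir, "highly_probable", "none")
    blk$pnt <- plain(fam$n_probnot, "probably_not", "none",
                     r = c(0L, 0L, 0L, 0L))
    blk$non <- plain(fam$n_none, "none", "none", r = c(0L, 0L, 0L, 0L))
    blk <- do.call(rbind, blk)
    blk$family <- fam$family
    blk$higher_group <- fam$higher_group
    rows[[f]] <- blk
  }
  resolved <- do.call(rbind, rows)
  n_assessed <- nrow(resolved)
  resolved$species_id <- sprintf("sp%04d", seq_len(n_assessed))
  resolved$assessor_id <- "assessor_a"
  resolved$notes_taxonomy <- NA_character_
  resolved$notes_research <- NA_character_
  resolved$notes_conservation <- NA_character_
  resolved <- resolved[, assessment_schema(optional = TRUE)]
  rownames(resolved) <- NULL

  # 27 conflicted species, 21:5:1. Categories 1/3 on confidence-none
  # species; category 2 on highly-probable increase species.
  none_ids <- resolved$species_id[resolved$confidence == "none"]
  hp_inc_ids <- resolved$species_id[resolved$confidence == "highly_probable" &
                                      resolved$outcome == "increase"]
  cat1 <- none_ids[1:21]
  cat3 <- none_ids[22]
  cat2 <- hp_inc_ids[1:5]
  labels <- c(stats::setNames(rep("morph_vs_genetic", 21), cat1),
              stats::setNames("already_described", cat3),
              stats::setNames(rep("isolated_no_genetic", 5), cat2))

  extra <- list()
  for (id in c(cat1, cat3)) {
    b <- resolved[resolved$species_id == id, , drop = FALSE]
    b$assessor_id <- "assessor_b"
    b$confidence <- "highly_probable"; b$outcome <- "increase"
    b$r_analysis <- 1L; b$c_enables_assessment <- 1L
    extra[[length(extra) + 1L]] <- b
  }
  for (id in cat2) {
    b <- resolved[resolved$species_id == id, , drop = FALSE]
    b$assessor_id <- "assessor_b"
    b$confidence <- "none"; b$outcome <- "none"
    b[, binary_cols()] <- as.list(rep(0L, 8))
    extra[[length(extra) + 1L]] <- b
  }
  raw <- rbind(resolved, do.call(rbind, extra))
  raw <- raw[order(raw$species_id, raw$assessor_id), ]
  rownames(raw) <- NULL

  list(raw = raw,
       conflict_labels = labels,
       n_total_species = sum(fams$n_total),
       family_totals = stats::setNames(fams$n_total, fams$family))
}
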