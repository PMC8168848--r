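test_that("a canonical CSV parses to one record per row, round-tripping exactly", {
  df <- make_assessments(c("sp01", "sp02", "sp03"),
                         conf = c("definite", "highly_probable", "none"),
                         outcome = c("increase", "species_complex", "none"),
                         flags = c("11111111", "11000100", "00000000"))
  path <- write_assessment_csv(df)
  got <- read_assessments(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$species_id, df$species_id)
  expect_equal(got$confidence, df$confidence)
  expect_equal(got$outcome, df$outcome)
  for (col in c("r_fieldwork", "r_genetics", "r_morphology", "r_analysis",
                "c_enables_assessment", "c_highly_localized",
                "c_threatening_process", "c_high_threat_probability"))
    expect_identical(got[[col]], df[[col]])

  # write_assessments(read_assessments(f)) round-trips bit-exactly
  path2 <- tempfile(fileext = ".csv")
  write_assessments(got, path2)
  again <- read_assessments(path2)
  expect_identical(got, again)
})

test_that("column aliases map source headers onto the canonical schema", {
  df <- make_assessments("sp01")
  names(df)[names(df) == "species_id"] <- "Species name"
  names(df)[names(df) == "r_genetics"] <- "Genetics needed"
  path <- write_assessment_csv(df)
  expect_error(read_assessments(path), "species_id")
  got <- read_assessments(path, column_map = c(species_id = "Species name",
                                               r_genetics = "Genetics needed"))
  expect_equal(got$species_id, "sp01")
  expect_error(read_assessments(path, column_map = c(species_id = "nope")),
               "absent source column")
})

test_that("blank conservation cells default to 0 with a warning; blank confidence is an error", {
  df <- make_assessments(c("sp01", "sp02"))
  df$c_highly_localized <- c("", "1")
  path <- write_assessment_csv(df)
  expect_warning(got <- read_assessments(path), "scored conservatively as 0")
  expect_identical(got$c_highly_localized, c(0L, 1L))

  df2 <- make_assessments(c("sp01", "sp02"))
  df2$confidence <- c("definite", "")
  expect_error(read_assessments(write_assessment_csv(df2)),
               "blank confidence at row\\(s\\) 2")
})

test_that("out-of-domain binary values are rejected with the row index", {
  df <- make_assessments(c("sp01", "sp02"))
  df$r_genetics <- c("0", "2")
  expect_error(read_assessments(write_assessment_csv(df)),
               "non-binary value in column 'r_genetics' at row\\(s\\) 2")
})

test_that("species identity normalization collapses case and whitespace only", {
  expect_equal(normalize_species_id("  Ctenotus  Robustus "),
               "ctenotus robustus")
  expect_false(normalize_species_id("ctenotus robustus") ==
                 normalize_species_id("ctenotus robusta"))
})

test_that("concordant duplicates collapse to one record with field-wise max flags", {
  df <- rbind(make_assessments("sp01", flags = "11000000"),
              make_assessments("sp01", flags = "00110001",
                               assessor = "assessor_b"))
  res <- resolve_conflicts(df)
  expect_equal(nrow(res$resolved), 1)
  expect_equal(nrow(res$conflicts), 0)
  expect_identical(unlist(res$resolved[1, c("r_fieldwork", "r_genetics",
                                            "r_morphology", "r_analysis")],
                          use.names = FALSE), c(1L, 1L, 1L, 1L))
  # identical duplicates resolve to either record
  dup <- rbind(make_assessments("sp02"), make_assessments("sp02"))
  res2 <- resolve_conflicts(dup)
  expect_equal(nrow(res2$resolved), 1)
  expect_equal(res2$resolved$confidence, "definite")
})

test_that("discordant assessments resolve by conflict category", {
  mk_pair <- function(id) rbind(
    make_assessments(id, conf = "highly_probable", outcome = "increase",
                     flags = "00110100"),
    make_assessments(id, conf = "none", outcome = "none",
                     flags = "00000000", assessor = "assessor_b"))

  # categories 1 and 3: coded as not requiring revision
  for (cat in c("morph_vs_genetic", "already_described")) {
    res <- resolve_conflicts(mk_pair("sp01"), c(sp01 = cat))
    expect_equal(res$resolved$confidence, "none")
    expect_equal(res$resolved$outcome, "none")
    expect_true(all(res$resolved[, c("r_morphology", "c_highly_localized")] == 0))
    expect_equal(res$conflicts$category, cat)
  }
  # category 2: high probability of revision, outcome and flags retained
  res2 <- resolve_conflicts(mk_pair("sp02"), c(sp02 = "isolated_no_genetic"))
  expect_equal(res2$resolved$confidence, "highly_probable")
  expect_equal(res2$resolved$outcome, "increase")
  expect_equal(res2$resolved$c_highly_localized, 1L)
  # numeric category codes are accepted
  res3 <- resolve_conflicts(mk_pair("sp03"), c(sp03 = 2))
  expect_equal(res3$resolved$confidence, "highly_probable")

  # discordant species without a label is an error naming the species
  expect_error(resolve_conflicts(mk_pair("sp09")), "sp09")
})

test_that("resolve_conflicts is deterministic and idempotent", {
  s <- synthetic_supplement()
  r1 <- resolve_conflicts(s$raw, s$conflict_labels)
  r2 <- resolve_conflicts(s$raw, s$conflict_labels)
  expect_identical(r1$resolved, r2$resolved)
  r3 <- resolve_conflicts(r1$resolved)
  expect_identical(r3$resolved, r1$resolved)
  expect_equal(nrow(r3$conflicts), 0)
})

test_that("cohort filter is a monotone subset operation", {
  df <- make_assessments(sprintf("sp%02d", 1:5),
                         conf = c("none", "probably_not", "highly_probable",
                                  "definite", "definite"),
                         outcome = "increase")
  expect_equal(nrow(filter_revision_cohort(df)), 3)
  # outcome mismatch excluded
  df$outcome[5] <- "species_complex"
  expect_equal(nrow(filter_revision_cohort(df, outcomes = "increase")), 2)
  expect_equal(nrow(filter_revision_cohort(df, outcomes = NULL)), 3)
  # cardinality monotone non-increasing as the floor rises
  floors <- c("none", "probably_not", "highly_probable", "definite")
  ns <- vapply(floors, function(fl)
    nrow(filter_revision_cohort(df, confidence_floor = fl, outcomes = NULL)),
    integer(1))
  expect_true(all(diff(ns) <= 0))
  # output is a subset of input
  out <- filter_revision_cohort(df, outcomes = NULL)
  expect_true(all(out$species_id %in% df$species_id))
})

test_that("every resolved record keeps all eight flags binary (generated tables)", {
  cfg <- synthetic_config(n_species = 400, seed = 42)
  g <- generate_assessments(cfg)
  res <- resolve_conflicts(g$raw, g$conflict_labels)
  flags <- as.matrix(res$resolved[, c("r_fieldwork", "r_genetics",
    "r_morphology", "r_analysis", "c_enables_assessment",
    "c_highly_localized", "c_threatening_process",
    "c_high_threat_probability")])
  expect_true(all(flags %in% c(0L, 1L)))
})
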