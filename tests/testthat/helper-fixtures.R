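# Build a canonical assessment data.frame from terse arguments.
# conf/outcome recycled; flags given as 8-character strings "rrrrcccc".
make_assessments <- function(ids, conf = "definite", outcome = "increase",
                             flags = "11110000", family = "Scincidae",
                             higher_group = "lizard",
                             assessor = "assessor_a") {
  n <- length(ids)
  fl <- matrix(0L, n, 8)
  if (n > 0)
    fl <- do.call(rbind, lapply(rep_len(flags, n), function(s)
      as.integer(strsplit(s, "")[[1]])))
  df <- data.frame(
    species_id = ids, family = rep_len(family, n),
    higher_group = rep_len(higher_group, n),
    assessor_id = rep_len(assessor, n),
    confidence = rep_len(conf, n), outcome = rep_len(outcome, n),
    stringsAsFactors = FALSE)
  flagcols <- c("r_fieldwork", "r_genetics", "r_morphology", "r_analysis",
                "c_enables_assessment", "c_highly_localized",
                "c_threatening_process", "c_high_threat_probability")
  for (j in 1:8) df[[flagcols[j]]] <- fl[, j]
  df$notes_taxonomy <- rep(NA_character_, n)
  df$notes_research <- rep(NA_character_, n)
  df$notes_conservation <- rep(NA_character_, n)
  df
}

# Write a minimal assessment CSV with the canonical header.
write_assessment_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Axis-aligned rectangular range: occupancy has an exact independent
# oracle (1-D interval overlap on each axis).
rect_range <- function(id, xmin, ymin, xmax, ymax, crs = "EPSG:3577") {
  ring <- cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
  range_map(id, ring, crs = crs)
}

# Exact occupancy oracle for rectangles: positive-length overlap on both
# axes with each half-open cell.
rect_cells_oracle <- function(xmin, ymin, xmax, ymax, grid) {
  ids <- integer(0)
  s <- grid$cell_size
  for (row in seq_len(grid$n_rows)) {
    for (col in seq_len(grid$n_cols)) {
      cx0 <- grid$x0 + (col - 1) * s; cx1 <- cx0 + s
      cy0 <- grid$y0 + (row - 1) * s; cy1 <- cy0 + s
      if (min(xmax, cx1) - max(xmin, cx0) > 0 &&
          min(ymax, cy1) - max(ymin, cy0) > 0)
        ids <- c(ids, (row - 1L) * grid$n_cols + col)
    }
  }
  sort(ids)
}
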