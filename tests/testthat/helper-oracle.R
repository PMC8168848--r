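# Independent triple-loop spatial oracle, computed with shapely through the
# system python: for every species x cell, intersect the polygon with the
# cell box and test for positive area; per-cell richness and mean scores
# follow by brute force. Returns matrices indexed [row, col], row 1 at the
# bottom, matching score_raster layout.
shapely_grid_oracle <- function(ranges, grid, scores = NULL) {
  payload <- list(
    grid = list(x0 = grid$x0, y0 = grid$y0, s = grid$cell_size,
                n_rows = grid$n_rows, n_cols = grid$n_cols),
    species = lapply(ranges, function(r) list(
      id = r$species_id,
      score = if (is.null(scores)) -1 else scores[[r$species_id]],
      rings = lapply(r$geometry, function(p)
        lapply(seq_len(nrow(p$outer)), function(i)
          c(p$outer[i, 1], p$outer[i, 2]))))))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  script <- '
import json, sys
from shapely.geometry import Polygon, box
payload = json.load(open(sys.argv[1]))
g = payload["grid"]
nr, nc, s, x0, y0 = g["n_rows"], g["n_cols"], g["s"], g["x0"], g["y0"]
rich = [0.0] * (nr * nc)   # column-major: index = (j * nr) + i
ssum = [0.0] * (nr * nc)
for sp in payload["species"]:
    polys = [Polygon(rings) for rings in sp["rings"]]
    for i in range(nr):
        for j in range(nc):
            cell = box(x0 + j*s, y0 + i*s, x0 + (j+1)*s, y0 + (i+1)*s)
            a = sum(p.intersection(cell).area for p in polys)
            if a > 1e-6:
                rich[j*nr + i] += 1
                ssum[j*nr + i] += sp["score"]
mean = [ (ssum[k]/rich[k] if rich[k] else None) for k in range(nr*nc) ]
json.dump({"richness": rich, "mean": mean}, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, fin, fout))
  stopifnot(status == 0)
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  flat <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_
                             else as.numeric(v), numeric(1))
  list(richness = matrix(flat(res$richness), nrow = grid$n_rows),
       mean = matrix(flat(res$mean), nrow = grid$n_rows))
}
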