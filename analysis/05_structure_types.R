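#!/usr/bin/env Rscript
# Step 5: cytogenetic structure types and frequency-polygon vectors for the
# quantitative populations. Writes results/structure_types.tsv and
# results/polygon_vectors.tsv.

suppressPackageStartupMessages(library(karyopop))
dir.create("results", showWarnings = FALSE)

fx <- load_fixtures()

rows <- lapply(fx$table3, function(t) {
  ty <- classify_structure(t)
  data.frame(population = t$population, type = ty$label,
             dominant_B = unname(ty$dominant["B"]),
             mixed_arms = paste(ty$mixed, collapse = ","))
})
types <- do.call(rbind, rows)
write.table(types, "results/structure_types.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(types, row.names = FALSE)

poly <- t(vapply(fx$table3, polygon_vectors, numeric(7)))
poly_df <- data.frame(population = rownames(poly), round(poly, 3))
write.table(poly_df, "results/polygon_vectors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\ntype 0 populations:", paste(types$population[types$type == "0"], collapse = " "), "\n")
cat("type B populations:", paste(types$population[types$type == "B"], collapse = " "), "\n")
cat("written: results/structure_types.tsv, results/polygon_vectors.tsv\n")
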