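#!/usr/bin/env Rscript
# Step 3: allele frequencies from the genotype table, the banding-sequence
# pool census, quantitative-panel polymorphism means, and Hardy-Weinberg
# tests for the polymorphic arms of the panel populations.
# Writes results/allele_frequencies.tsv, results/hw_tests.tsv and
# results/polymorphism_summary.txt.

suppressPackageStartupMessages(library(karyopop))
dir.create("results", showWarnings = FALSE)

fx <- load_fixtures()
samples <- fixture_samples(fx)

# allele frequencies recomputed from the genotype table (all 20 columns)
freq_tables <- lapply(samples, allele_frequencies)
long <- do.call(rbind, lapply(freq_tables, function(t) {
  do.call(rbind, lapply(names(t$arms), function(a) {
    data.frame(population = t$population, arm = a,
               sequence = names(t$arms[[a]]),
               frequency = round(unname(t$arms[[a]]), 4))
  }))
}))
write.table(long, "results/allele_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# pool census across every fixture table (genotype-derived + printed)
census <- pool_census(c(unname(freq_tables), unname(fx$table3)))
cat("Banding-sequence pool census:", census$pool_size, "sequences\n")
cat(" ", paste(census$sequences, collapse = " "), "\n\n")

# quantitative panel (populations with more than 10 specimens)
panel <- fx$indices[fx$indices$panel == 1, ]
pm <- quantitative_panel_means(panel)
cat(sprintf("Panel means over %d populations: %.1f%% heterozygous larvae, %.2f heterozygous inversions per larva\n\n",
            pm["n_populations"], pm["pct_het_larvae"], pm["het_inv_per_larva"]))

# Hardy-Weinberg tests: polymorphic arms of panel populations, counts
# rebuilt from the genotype-frequency columns
hw_rows <- list()
for (pp in intersect(panel$population, names(samples))) {
  s <- samples[[pp]]
  cnt <- s$counts
  for (arm in unique(cnt$arm)) {
    d <- cnt[cnt$arm == arm & cnt$count > 0, ]
    if (length(unique(c(d$seq1, d$seq2))) < 2) next
    counts <- setNames(round(d$count * s$n), paste(d$seq1, d$seq2, sep = "/"))
    h <- hw_chi_square(counts)
    hw_rows[[length(hw_rows) + 1]] <- data.frame(
      population = pp, arm = arm, n = s$n,
      chi_square = round(h$chi_square, 3), df = h$df,
      p_value = signif(h$p_value, 3), direction = h$direction)
  }
}
hw <- do.call(rbind, hw_rows)
hw <- hw[order(hw$p_value), ]
write.table(hw, "results/hw_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Hardy-Weinberg deviations (p < 0.05):\n")
print(hw[!is.na(hw$p_value) & hw$p_value < 0.05, ], row.names = FALSE)

sink("results/polymorphism_summary.txt")
cat("Pool census:", census$pool_size, "banding sequences\n")
cat("Per population:\n")
print(census$per_population)
cat(sprintf("\nPanel means: %.2f%% heterozygous larvae, %.4f heterozygous inversions per larva (n = %d populations)\n",
            pm["pct_het_larvae"], pm["het_inv_per_larva"], pm["n_populations"]))
sink()
cat("\nwritten: results/allele_frequencies.tsv, results/hw_tests.tsv, results/polymorphism_summary.txt\n")
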