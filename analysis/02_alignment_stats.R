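#!/usr/bin/env Rscript
# Site-pattern statistics on the aa_like alignment: constant / variable /
# parsimony-informative counts with the out-group and calibration taxa
# excluded (the convention of the study this mirrors), under both
# gap-handling modes, plus the full pairwise-difference matrix.

suppressPackageStartupMessages(library(plastochron))
SEED <- 42L

fx <- make_fixture("aa_like", seed = SEED)
A <- fx$alignment
excl <- c("OUT", "CAL1", "CAL2")

rows <- lapply(c("missing", "delete_columns"), function(gm) {
  sc <- classify_sites(A, gap_mode = gm, exclude_taxa = excl)
  data.frame(gap_mode = gm, columns = sc$column_count,
             constant = sc$n_constant, variable = sc$n_variable,
             parsimony_informative = sc$n_parsimony_informative,
             singleton = sc$n_singleton, excluded = sc$n_excluded)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/site_classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab)

D <- pairwise_difference_matrix(A)
write.table(D, "results/pairwise_differences.tsv", sep = "\t", quote = FALSE)
ing <- grep("^AA", rownames(A), value = TRUE)
Di <- D[ing, ing]
cat(sprintf("ingroup pairwise differences: min %d  mean %.0f  max %d\n",
            min(Di[upper.tri(Di)]), mean(Di[upper.tri(Di)]),
            max(Di[upper.tri(Di)])))
cat("deleting gapped columns drops", tab$excluded[2], "columns;",
    "the paper-style contrast between the two modes is tabulated above\n")
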