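#!/usr/bin/env Rscript
# Preprocess the simulated abundance data: regress out sex and age per
# analyte, drop analytes with missing values, then the two-stage robust
# Z-score normalization. Writes the processed matrix and a drop report.
#
# Two variants are produced: the method's full prescription (per-analyte
# robust Z against the control group) and the exchangeability-preserving
# variant without the control reference, which the calibration analysis
# (06) shows is the one under which group comparisons are unbiased at this
# sample size.

library(diracr)

abundance <- read_abundance("results/data/abundance.tsv")
metadata <- read_metadata("results/data/metadata.tsv")

full <- preprocess_abundance(abundance, metadata, control = "Control")
write_abundance(full$table, "results/processed_abundance_controlref.tsv")

noref <- preprocess_abundance(abundance, metadata, control = "Control",
                              control_reference = FALSE)
write_abundance(noref$table, "results/processed_abundance.tsv")

cat(sprintf("Preprocessing: %d analytes in, %d out (control-referenced), %d dropped\n",
            full$report$n_in, full$report$n_out, nrow(full$report$dropped)))
if (nrow(full$report$dropped)) {
  print(table(full$report$dropped$reason))
}
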