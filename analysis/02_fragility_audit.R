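#!/usr/bin/env Rscript

# Step 2: the fragility audit itself.
#
# Reads results/corpus.csv (from step 1), deduplicates, screens eligibility,
# computes every trial's Fragility Index under the exact test, aggregates
# median/IQR per treatment category, and applies the LTFU > FI robustness
# criterion per study and per category. Writes per-study and summary tables
# under results/audit/ and the two summary figures as PDFs.
#
# Usage: Rscript analysis/02_fragility_audit.R

suppressMessages(library(fragilityaudit))

if (!file.exists("results/corpus.csv")) {
  stop("results/corpus.csv not found - run analysis/01_simulate_corpus.R first")
}

audit <- run_batch("results/corpus.csv", "results/audit")

print(audit$summary)
cat(sprintf("\n%d/%d studies individually flagged (LTFU > FI)\n",
            sum(audit$scored$ltfu_exceeds_fi), nrow(audit$scored)))

ggplot2::ggsave("results/audit/fi_by_category.pdf",
                plot_fi_by_category(audit$summary), width = 7, height = 4.5)
ggplot2::ggsave("results/audit/fi_vs_ltfu.pdf",
                plot_fi_vs_ltfu(audit$summary), width = 7, height = 4.5)
cat("Tables and figures written under results/audit/\n")
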