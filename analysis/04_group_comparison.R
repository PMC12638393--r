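#!/usr/bin/env Rscript
# Two-group prognostic comparison. Part A re-tests the published per-site
# group summaries directly (no patient-level data needed); part B runs the
# full pipeline (KS normality gate, then Welch t or Mann-Whitney) on the
# simulated per-patient cohort from 03_simulate_cohort.R.

suppressPackageStartupMessages(library(csfpulse))
dir.create("results", showWarnings = FALSE)

cat("A. Welch tests on the published group summaries:\n")
pub <- published_summary_tests()
pub$p_value <- round(pub$p_value, 3)
print(pub[, c("site", "mean1", "sd1", "mean2", "sd2", "t", "df",
              "p_value", "significant")], row.names = FALSE, digits = 4)
write.csv(pub, "results/published_summary_tests.csv", row.names = FALSE)
cat("Only the aqueduct and C2-C3 rows fall at p <= 0.05, matching the\n",
    "published starred pattern (both print as p = 0.03).\n\n")

cat("B. Full pipeline on the simulated per-patient cohort:\n")
cohort <- read_cohort("results/cohort.csv")  # run 03 first
cmp <- compare_cohort(cohort, t_variant = "welch")
print(cmp[, c("variable", "test", "statistic", "p_value", "significant")],
      row.names = FALSE, digits = 3)
write.csv(cmp, "results/group_comparison.csv", row.names = FALSE)
cat("\nMorphometrics are compared with the rank test by design and, being\n",
    "drawn from a shared distribution, should rarely be flagged.\n")
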