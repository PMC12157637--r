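#!/usr/bin/env Rscript
# Link karyotype-specific modules to traits: GLS regression of
# probit-transformed TWAS p-values on each SGM's top-1% loading indicator,
# with residual covariance from the cohort's gene-gene correlation matrix,
# BH-adjusted across the (SGM, trait) grid. A side study demonstrates why
# the covariance term matters: under a block-correlated null (blocks of 10,
# rho 0.3, 2,000 genes, 1,000 replicates) GLS with the true covariance
# stays at the nominal level while OLS does not.

library(modlink)

cfg <- pipeline_config(input_dir = "results/data",
                       sigma = "results/data/sigma_true.tsv",
                       output_dir = "results/run", k = 20, seed = 1)
report <- run_pipeline(cfg, stages = "gls")

assoc <- read_table_tsv("results/run/associations.tsv")
st <- report$stages$gls
cat(sprintf("Module-trait grid: %d pairs over the SGMs, %d links at FDR < 0.1 (%d modules)\n",
            st$n_pairs, st$n_significant, st$n_modules_linked))
print(assoc[assoc$significant,
            c("lv", "trait", "beta", "se", "pvalue", "fdr")],
      row.names = FALSE)

cal <- gls_calibration_study(n_replicates = 1000, seed = 1)
cat(sprintf("\nCalibration under the block-correlated null (n = %d):\n",
            cal$n_replicates))
cat(sprintf("  GLS with true covariance: type-I error %.3f at alpha = 0.05\n",
            cal$gls_rejection))
cat(sprintf("  OLS on the same replicates: %.3f\n", cal$ols_rejection))
dir.create("results/evaluation", recursive = TRUE, showWarnings = FALSE)
write_table_tsv(data.frame(method = c("gls", "ols"),
                           type1_error = c(cal$gls_rejection,
                                           cal$ols_rejection),
                           n_replicates = cal$n_replicates),
                "results/evaluation/gls_calibration.tsv")
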