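#!/usr/bin/env Rscript
# Generate the reference synthetic cohort: 2,000 genes x (300 T21 + 100 D21)
# samples, 20 planted gene modules (16 covered by prior sets), karyotype
# shifts on modules 1-3, TWAS enrichment for two traits on modules 1-2, and
# one comorbidity driven by module 3. Writes the pipeline input bundle under
# results/data/.

library(modlink)

cfg <- simulation_config(seed = 1)
dataset <- generate_dataset(cfg)
write_dataset(dataset, "results/data", cfg)

t21 <- dataset$metadata$karyotype == "T21"
cat("Synthetic cohort written to results/data/\n")
cat(sprintf("  genes: %d, samples: %d (%d T21 / %d D21)\n",
            nrow(dataset$expression), ncol(dataset$expression),
            sum(t21), sum(!t21)))
cat(sprintf("  prior sets: %d (aligned modules: %d of %d)\n",
            length(dataset$gene_sets),
            round(cfg$frac_aligned * cfg$k_true), cfg$k_true))
cat(sprintf("  karyotype-shifted modules: %s (effect %.1f SD)\n",
            paste(cfg$sgm_indices, collapse = ", "), cfg$sgm_effect))
cat(sprintf("  planted trait pairs: %s\n",
            paste(vapply(cfg$trait_plants, function(tp)
              sprintf("%s~module%d", tp$trait_id, tp$module), ""),
              collapse = ", ")))
cat(sprintf("  planted comorbidity: %s (module %d, prevalence %.2f in T21)\n",
            cfg$comorbidity_plants[[1]]$comorbidity_id,
            cfg$comorbidity_plants[[1]]$module,
            mean(dataset$metadata$comorbidity_1[t21])))
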