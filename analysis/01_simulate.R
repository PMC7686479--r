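#!/usr/bin/env Rscript
# Generate the synthetic study: an LD-blocked genotype panel for 478
# subjects (253 women, 225 men), cis-eQTL weight models for 76 genes,
# GWAS summary statistics with 50 causal variants, and write everything
# under results/data/ as TSVs for the downstream steps.

suppressPackageStartupMessages(library(tprspls))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20260920L)

g <- simulate_genotypes(cfg)
eq <- simulate_eqtl_weights(g, cfg)
ss <- simulate_gwas_sumstats(g, n_causal = 50L,
                             seed = derive_seed(cfg$seed, 3L))

write_genotypes(g, "results/data/genotypes")
utils::write.table(eq$weights, "results/data/eqtl_weights.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ss, "results/data/gwas_sumstats.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d subjects x %d variants (%d LD blocks of %d)\n",
            cfg$n_subjects, cfg$n_variants,
            ceiling(cfg$n_variants / cfg$ld_block_size), cfg$ld_block_size))
cat(sprintf("eQTL models: %d genes x %d variants each; %d causal GWAS variants\n",
            cfg$n_genes, cfg$snps_per_gene, length(attr(ss, "causal_ids"))))
cat("wrote results/data/{genotypes_*,eqtl_weights,gwas_sumstats}.tsv\n")
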