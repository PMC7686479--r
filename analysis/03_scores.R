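#!/usr/bin/env Rscript
# Build both polygenic scores on the QC'd panel: the transcriptome-based
# score (T-PRS: harmonise eQTL weights, impute cortical expression, signed
# z-score sum over the gene set) and the conventional clumping-and-
# thresholding score from GWAS summary statistics at nine p thresholds.

suppressPackageStartupMessages(library(tprspls))

g <- read_genotypes("results/qc/genotypes_clean_dosages.tsv")
w <- utils::read.table("results/data/eqtl_weights.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
ss <- utils::read.table("results/data/gwas_sumstats.tsv", header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)

hw <- harmonize(g, w)
cat(sprintf("weights: %d kept, %d flipped to the alt allele, %d dropped\n",
            hw$report$n_kept, hw$report$n_flipped, hw$report$n_dropped))
expr <- impute_expression(g, hw$table)
cat(sprintf("imputed expression for %d of %d genes\n",
            ncol(expr), length(unique(w$gene_id))))

# Direction of each gene's prior association with depression. The real
# analysis takes this from a postmortem meta-analysis table; the synthetic
# study fixes an alternating sign pattern.
de <- data.frame(gene_id = colnames(expr),
                 direction = rep(c(1, -1), length.out = ncol(expr)))
tprs <- compute_tprs(expr, de)
cat(sprintf("T-PRS over %d genes: mean %.3f, sd %.3f\n",
            tprs$n_features_used, mean(tprs$scores), sd(tprs$scores)))

hs <- harmonize(g, ss)
clumps <- ld_clump(hs$table, g, r2_max = 0.1, window_kb = 250, p_index_max = 1)
cat(sprintf("clumping: %d index variants from %d input variants\n",
            length(clumps$index_variants), nrow(hs$table)))
prs <- suppressWarnings(compute_pgc_prs(g, hs$table, clumps))

dir.create("results/scores", showWarnings = FALSE, recursive = TRUE)
utils::write.table(
  data.frame(subject_id = names(tprs$scores), tprs = tprs$scores,
             n_genes = tprs$n_features_used),
  "results/scores/tprs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
prs_tab <- data.frame(
  subject_id = names(prs[[1]]$scores),
  sapply(prs, `[[`, "scores"), check.names = FALSE)
utils::write.table(prs_tab, "results/scores/pgc_prs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(threshold = sapply(prs, `[[`, "threshold"),
             n_variants = sapply(prs, `[[`, "n_features_used")),
  "results/scores/pgc_prs_features.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("wrote results/scores/{tprs,pgc_prs,pgc_prs_features}.tsv\n")
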