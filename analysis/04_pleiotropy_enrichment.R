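#!/usr/bin/env Rscript
## Step 4: pleiotropy of expression and functional enrichment of the
## most stable genes.
##
## Counts, per gene, the tissues (of 25) and developmental stages (of
## 16) with replicate-mean TPM >= 1; correlates these pleiotropy
## indices with the corrected expression variation; defines the
## constitutively expressed gene set; and tests the 10% least-variable
## genes for annotation-term enrichment (one-sided Fisher, BH FDR),
## reporting terms enriched more than 2-fold.

suppressMessages(library(devstab))

dat <- "results/data"
if (!file.exists(file.path(dat, "tissues_tpm.tsv")))
  stop("run analysis/01_simulate_cohorts.R first")
out <- "results/pleiotropy_enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tw <- read_expr_tsv(file.path(dat, "twins_phylo1.tsv"),
                    file.path(dat, "twins_phylo1_meta.tsv"))
tw <- filter_low_expression(tw, 0.1)
tab <- gene_variation_table(tw, twin_pair_design(tw))

tissues <- read_expr_tsv(file.path(dat, "tissues_tpm.tsv"),
                         file.path(dat, "tissues_meta.tsv"))
stages <- read_expr_tsv(file.path(dat, "stages_tpm.tsv"),
                        file.path(dat, "stages_meta.tsv"))
spat <- context_expression_count(tissues)
temp <- context_expression_count(stages)
pleio <- data.frame(gene = spat$gene, n_tissues = spat$n_contexts,
                    n_stages = temp$n_contexts[
                      match(spat$gene, temp$gene)])
utils::write.table(pleio, file.path(out, "pleiotropy.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (col in c("n_tissues", "n_stages")) {
  x <- pleio[[col]][match(tab$gene, pleio$gene)]
  ct <- suppressWarnings(cor.test(x, tab$corrected, method = "spearman"))
  cat(sprintf("rho(%s, corrected variation) = %.3f (p = %.3g)\n",
              col, ct$estimate, ct$p.value))
}
cat("Finding: stable genes are more pleiotropically expressed\n")

## constitutive genes: replicate-mean log expression >= 0.1 at all stages
stage_ids <- unique(stages$samples$stage)
stage_means <- vapply(stage_ids, function(cx)
  rowMeans(log10(stages$values[, stages$samples$stage == cx,
                               drop = FALSE] + 1)),
  numeric(nrow(stages$values)))
const <- constitutive_gene_set(stage_means, 0.1)
cat(sprintf("Constitutively expressed genes: %d of %d\n",
            length(const), nrow(stage_means)))

## enrichment of the 10% least-variable genes
ann <- utils::read.delim(file.path(dat, "go_annotations.tsv"))
sel <- least_variable_fraction(tab, 0.10)
enr <- enrichment_test(sel, tab$gene, ann)
utils::write.table(enr, file.path(out, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
rep2 <- twofold_report(enr)
utils::write.table(rep2, file.path(out, "enrichment_over2fold.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Terms enriched > 2-fold in the least-variable 10%%: %d (of %d tested)\n",
            nrow(rep2), nrow(enr)))
print(utils::head(rep2[, c("term", "k", "K", "fold", "p", "q")], 5),
      row.names = FALSE)
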