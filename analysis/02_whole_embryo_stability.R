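#!/usr/bin/env Rscript
## Step 2: whole-embryo developmental stability per stage.
##
## Reads the twin cohorts written by 01_simulate_cohorts.R, applies the
## low-expression filter (log10(TPM+1) >= 0.1 in every individual of a
## stage) and the technical-error filter (one-sided rank-sum against
## the quadruplicate contrasts, alpha = 0.01), computes the per-pair
## whole-embryo distance V and, per stage, its mean; then tests the
## stage differences with Kruskal-Wallis followed by Steel-Dwass
## all-pairs comparisons. Also reports the rank-based 1 - Spearman
## distance for comparison, and the intraspecies diversity between the
## two wild populations at the phylotypic stage.

suppressMessages(library(devstab))

dat <- "results/data"
if (!file.exists(file.path(dat, "twins_early.tsv")))
  stop("run analysis/01_simulate_cohorts.R first")
out <- "results/whole_embryo"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tech <- read_expr_tsv(file.path(dat, "technical.tsv"),
                      file.path(dat, "technical_meta.tsv"))
stages <- c("early", "phylo1", "phylo2", "hatch")
v_by_stage <- list(); d_by_stage <- list(); n_kept <- c()

for (st in stages) {
  tw <- read_expr_tsv(file.path(dat, sprintf("twins_%s.tsv", st)),
                      file.path(dat, sprintf("twins_%s_meta.tsv", st)))
  tw <- filter_low_expression(tw, 0.1)
  pairs <- twin_pair_design(tw)
  flt <- filter_by_technical_error(tw, pairs,
                                   subset_expr(tech, genes = gene_ids(tw)))
  keep <- flt$gene[flt$pass]
  n_kept[st] <- length(keep)
  twk <- subset_expr(tw, genes = keep)
  v_by_stage[[st]] <- stage_stability(twk, pairs)$V
  d_by_stage[[st]] <- vapply(seq_len(nrow(pairs)), function(r)
    spearman_distance(twk$values[, pairs$sample_i[r]],
                      twk$values[, pairs$sample_k[r]]), numeric(1))
}

cmp <- stage_comparison(v_by_stage)
per_pair <- do.call(rbind, lapply(stages, function(st)
  data.frame(stage = st, pair = names(v_by_stage[[st]]),
             V = unname(v_by_stage[[st]]),
             spearman_dist = unname(d_by_stage[[st]]))))
utils::write.table(per_pair, file.path(out, "per_pair_distances.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(stage = stages, n_genes_kept = n_kept,
             mean_V = cmp$mean_V[stages],
             mean_spearman_dist = vapply(d_by_stage, mean, numeric(1))),
  file.path(out, "stage_summary.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(stage_a = rep(stages, each = 4),
             stage_b = rep(stages, 4),
             steel_dwass_p = as.vector(cmp$steel_dwass$p)),
  file.path(out, "steel_dwass_p.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

pa <- read_expr_tsv(file.path(dat, "popA_phylo1.tsv"),
                    file.path(dat, "popA_phylo1_meta.tsv"))
pb <- read_expr_tsv(file.path(dat, "popB_phylo1.tsv"),
                    file.path(dat, "popB_phylo1_meta.tsv"))
joint <- filter_low_expression(bind_samples(pa, pb), 0.1)
pa <- subset_expr(pa, genes = gene_ids(joint))
pb <- subset_expr(pb, genes = gene_ids(joint))
div <- intraspecies_diversity(pa, pb)

cat("Whole-embryo stability (mean V per stage):\n")
print(round(cmp$mean_V, 5))
cat(sprintf("Kruskal-Wallis: H = %.2f, p = %.3g\n",
            cmp$kruskal$H, cmp$kruskal$p))
cat("Steel-Dwass family-wise p:\n")
print(signif(cmp$steel_dwass$p, 3))
cat(sprintf("Finding: the two phylotypic stages have the smallest mean V (%s)\n",
            paste(names(sort(cmp$mean_V))[1:2], collapse = ", ")))
cat(sprintf("Intraspecies diversity at phylo1 (mean V over %d cross pairs): %.5f\n",
            length(div$V), div$mean_V))
cat(sprintf("  vs twin mean V at phylo1: %.5f\n", cmp$mean_V[["phylo1"]]))
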