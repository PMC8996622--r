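#!/usr/bin/env Rscript
## Step 1: generate the synthetic study cohorts and write them to disk.
##
## The design mirrors the twin-embryo study: four developmental stages
## (flanks noisier than the two mid, phylotypic stages), 20 sex-matched
## inbred twin pairs per stage, one technical quadruplicate (pooled RNA
## split four ways), two wild populations with per-gene divergence at
## the phylotypic stage, tissue/stage profiles for pleiotropy, and a
## toy genome annotation (TSS, ATAC-like peaks, substitution sites,
## promoters with planted TATA boxes).

suppressMessages(library(devstab))

seed <- 20260928L %% 1000000L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_genes = 3000, n_pairs_per_stage = 20, seed = seed)

for (st in cfg$stages) {
  tw <- simulate_twin_matrix(cfg, st)
  write_expr_tsv(tw$matrix,
                 file.path(out, sprintf("twins_%s.tsv", st)),
                 file.path(out, sprintf("twins_%s_meta.tsv", st)))
}
tech <- simulate_technical_replicates(cfg)
write_expr_tsv(tech$matrix, file.path(out, "technical.tsv"),
               file.path(out, "technical_meta.tsv"))

pop <- simulate_population_matrices(cfg, "phylo1")
write_expr_tsv(pop$matrix_a, file.path(out, "popA_phylo1.tsv"),
               file.path(out, "popA_phylo1_meta.tsv"))
write_expr_tsv(pop$matrix_b, file.path(out, "popB_phylo1.tsv"),
               file.path(out, "popB_phylo1_meta.tsv"))

truth <- sim_truth(cfg)
utils::write.table(
  data.frame(gene = truth$gene, mu = truth$mu, s = truth$s,
             delta = truth$delta, g = truth$g),
  file.path(out, "truth_genes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(truth$go, file.path(out, "go_annotations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tis <- simulate_pleiotropy_profiles(cfg, n_contexts = 25,
                                    n_replicates = 4, label = "tissue")
write_expr_tsv(tis$matrix, file.path(out, "tissues_tpm.tsv"),
               file.path(out, "tissues_meta.tsv"))
stg <- simulate_pleiotropy_profiles(cfg, n_contexts = 16,
                                    n_replicates = 3, label = "stage")
write_expr_tsv(stg$matrix, file.path(out, "stages_tpm.tsv"),
               file.path(out, "stages_meta.tsv"))

ann <- simulate_genome_annotation(cfg)
write_genome_annotation(ann, file.path(out, "genome"))

orth <- simulate_ortholog_profiles(cfg, species = "relative")
utils::write.table(
  data.frame(gene = names(orth$profile_ref), expr = orth$profile_ref),
  file.path(out, "profile_reference.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(gene = names(orth$profile_other), expr = orth$profile_other),
  file.path(out, "profile_relative.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(orth$map, file.path(out, "ortholog_map.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Synthetic cohorts written to", out, "\n")
cat(sprintf("  genes: %d, twin pairs/stage: %d, stages: %s\n",
            cfg$n_genes, cfg$n_pairs_per_stage,
            paste(cfg$stages, collapse = ", ")))
cat(sprintf("  stage noise sd: %s (hourglass profile)\n",
            paste(cfg$stage_noise_sd, collapse = ", ")))
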