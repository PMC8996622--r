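#!/usr/bin/env Rscript
## Step 5: regulatory-region features vs gene expression stability.
##
## Reads the toy genome annotation (BED peaks, TSS table, minimal VCF
## of homozygous substitutions, promoter FASTA), assigns peaks to the
## gene with the closest TSS (retained only when more than half of the
## peak lies inside the distal +/-5 kb or proximal -100..+50 window),
## counts substitution events in open chromatin across the eight
## resequenced samples, scans promoters for the four TATA-box motifs
## (two-base shifts and both strands counted separately), and
## correlates each feature with the corrected expression variation.

suppressMessages(library(devstab))

dat <- "results/data"
gdir <- file.path(dat, "genome")
if (!file.exists(file.path(gdir, "tss.tsv")))
  stop("run analysis/01_simulate_cohorts.R first")
out <- "results/regulome"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tss <- read_tss_tsv(file.path(gdir, "tss.tsv"))
peaks <- read_peaks_bed(file.path(gdir, "peaks.bed"))
snps <- read_snps_vcf(file.path(gdir, "snps.vcf"))
prom <- read_promoters_fasta(file.path(gdir, "promoters.fa"))

asg <- assign_peaks(tss, peaks)
utils::write.table(asg, file.path(out, "peak_assignment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
snp_counts <- count_snps(asg, snps, tss)
tata <- scan_tata_set(prom)
feats <- regulatory_features(asg, snp_counts, tata, tss)
utils::write.table(feats, file.path(out, "regulatory_features.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Peaks: %d total, %d retained as regulatory regions\n",
            nrow(asg), sum(asg$retained)))
cat(sprintf("Substitution events in open chromatin: %d; TATA matches: %d\n",
            sum(feats$n_snps), sum(feats$n_tata)))

tw <- read_expr_tsv(file.path(dat, "twins_phylo1.tsv"),
                    file.path(dat, "twins_phylo1_meta.tsv"))
tw <- filter_low_expression(tw, 0.1)
tab <- gene_variation_table(tw, twin_pair_design(tw))
corr <- feature_stability_correlation(feats, tab)
utils::write.table(corr, file.path(out, "feature_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Feature vs corrected-variation correlations:\n")
print(corr, row.names = FALSE)
cat("Finding: regulatory features show no material correlation with\n")
cat("stability (they are generated independently of the noise\n")
cat("multipliers), matching the null expectation.\n")
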