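boundary_tss <- data.frame(gene = "gA", chrom = "chr1", pos = 10000L,
                           strand = "+", stringsAsFactors = FALSE)

test_that("peak retention uses the strict more-than-half overlap rule", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(14000L, 13500L),
                      end = c(16000L, 15500L),
                      name = c("half", "threequarter"))
  got <- assign_peaks(boundary_tss, peaks)
  ## distal window [5000, 15000): overlaps 1000/2000 and 1500/2000
  expect_identical(got$overlap, c(1000, 1500))
  expect_identical(got$retained, c(FALSE, TRUE))
  expect_identical(got$gene, c("gA", "gA"))
})

test_that("equidistant TSS ties go to the smaller gene id", {
  tss <- data.frame(gene = c("gB", "gA"), chrom = "chr1",
                    pos = c(1000L, 3000L), strand = "+")
  ## interval [1995, 2006): 995 bp from both TSS points
  peaks <- data.frame(chrom = "chr1", start = 1995L, end = 2006L,
                      name = "mid")
  got <- assign_peaks(tss, peaks)
  expect_identical(got$gene, "gA")
  ## a TSS inside the peak gives distance 0
  inpeak <- assign_peaks(tss, data.frame(chrom = "chr1", start = 990L,
                                         end = 1010L, name = "on"))
  expect_identical(inpeak$distance, 0)
  expect_identical(inpeak$gene, "gB")
})

test_that("proximal windows mirror about the TSS under strand flips", {
  ## promoter-scale windows only: peak inside [-100, +50) on + strand
  tssp <- data.frame(gene = "g", chrom = "c", pos = 10000L, strand = "+")
  tssm <- transform(tssp, strand = "-")
  peak_up <- data.frame(chrom = "c", start = 9900L, end = 9960L,
                        name = "up")
  gp <- assign_peaks(tssp, peak_up, distal_flank = 120)
  gm <- assign_peaks(tssm, peak_up, distal_flank = 120)
  expect_true(gp$retained)
  expect_true(gm$retained)
  ## with a tiny distal flank, only the proximal window decides:
  ## [-100, +50) on +, mirrored to (-50, +100] on -
  gp2 <- assign_peaks(tssp, data.frame(chrom = "c", start = 10060L,
                                       end = 10100L, name = "down"),
                      distal_flank = 10)
  gm2 <- assign_peaks(tssm, data.frame(chrom = "c", start = 10060L,
                                       end = 10100L, name = "down"),
                      distal_flank = 10)
  expect_false(gp2$retained)   # beyond +50 on the plus strand
  expect_true(gm2$retained)    # within the mirrored upstream window
})

test_that("assignment and retention match the quadratic oracle", {
  set.seed(33)
  for (rep in 1:3) {
    n_gene <- 12
    tss <- data.frame(gene = sprintf("g%02d", sample(n_gene)),
                      chrom = sample(c("c1", "c2"), n_gene, TRUE),
                      pos = sample(2000:40000, n_gene),
                      strand = sample(c("+", "-"), n_gene, TRUE))
    peaks <- data.frame(chrom = sample(c("c1", "c2"), 60, TRUE),
                        start = sample(1000:45000, 60))
    peaks$end <- peaks$start + sample(50:4000, 60, TRUE)
    peaks$name <- sprintf("p%02d", seq_len(60))
    got <- assign_peaks(tss, peaks)
    ora <- oracle_assign_peaks(tss, peaks)
    expect_identical(got$gene, ora$gene)
    expect_identical(got$retained, ora$retained)
  }
})

test_that("SNP events are counted per carrier inside half-open regions", {
  tss <- boundary_tss
  peaks <- data.frame(chrom = "chr1", start = 12000L, end = 13000L,
                      name = "pk")
  asg <- assign_peaks(tss, peaks)
  snps <- data.frame(chrom = "chr1", pos = c(12500L, 13000L, 900L),
                     stringsAsFactors = FALSE)
  flags <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, rep(FALSE, 7),
                    rep(TRUE, 8)), 3, 8, byrow = TRUE,
                  dimnames = list(NULL, paste0("S", 1:8)))
  snps <- cbind(snps, as.data.frame(flags))
  ## 12500 inside (3 carriers); 13000 at the end coordinate -> outside
  got <- count_snps(asg, snps, tss)
  expect_identical(unname(got["gA"]), 3L)
  expect_identical(unname(count_snps(asg, snps[0, ], tss)["gA"]), 0L)
  snps2 <- snps; snps2$chrom[3] <- "chrUn"
  expect_warning(count_snps(asg, snps2, tss), "chrUn")
})

test_that("TATA scanning counts shifts and strands separately", {
  expect_identical(scan_tata("TATATATATATA"), 6L)
  expect_identical(scan_tata("TATATATATATA", both_strands = FALSE), 3L)
  expect_identical(scan_tata("TATAAAAA"), 1L)
  expect_identical(scan_tata(strrep("C", 150)), 0L)
  expect_error(scan_tata("TATAQATA"), "A/C/G/T/N")
  ## vectorized version agrees with the scalar one
  seqs <- c(a = "TATATATATATA", b = strrep("C", 20), c = "CCTATAAATACC")
  expect_identical(unname(scan_tata_set(seqs)), c(6L, 0L, 1L))
})

test_that("TATA scan equals the sliding-window oracle on random DNA", {
  set.seed(44)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    expect_identical(scan_tata(s), as.integer(oracle_scan_tata(s)))
    expect_identical(scan_tata(s, both_strands = FALSE),
                     as.integer(oracle_scan_tata(s, both_strands = FALSE)))
  }
})

test_that("feature correlations flag constant columns and self-identity", {
  set.seed(9)
  tab <- data.frame(gene = sprintf("g%02d", 1:40), corrected = rnorm(40))
  feats <- data.frame(gene = tab$gene,
                      self = tab$corrected,
                      flat = rep(2, 40),
                      noise = rnorm(40))
  got <- feature_stability_correlation(feats, tab)
  expect_equal(got$rho[got$feature == "self"], 1)
  expect_false(got$defined[got$feature == "flat"])
  expect_true(is.na(got$rho[got$feature == "flat"]))
  expect_error(feature_stability_correlation(feats[1:4, ], tab[1:4, ]),
               ">= 10")
})

test_that("regulatory feature table aggregates retained peaks only", {
  tss <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                    pos = c(10000L, 50000L), strand = "+")
  peaks <- data.frame(chrom = "chr1",
                      start = c(9000L, 14000L, 49000L),
                      end = c(9500L, 16000L, 49200L),
                      name = c("in1", "half", "in2"))
  asg <- assign_peaks(tss, peaks)
  feats <- regulatory_features(asg, tss = tss)
  expect_identical(feats$n_peaks, c(1L, 1L))
  expect_identical(feats$total_peak_length, c(500L, 200L))
})

test_that("genome annotation files round-trip through standard formats", {
  cfg <- sim_config(n_genes = 40, seed = 27)
  ann <- simulate_genome_annotation(cfg)
  dir <- tempfile()
  write_genome_annotation(ann, dir)
  tss <- read_tss_tsv(file.path(dir, "tss.tsv"))
  expect_identical(tss, ann$tss)
  peaks <- read_peaks_bed(file.path(dir, "peaks.bed"))
  expect_equal(peaks[, c("chrom", "start", "end")],
               ann$peaks[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  prom <- read_promoters_fasta(file.path(dir, "promoters.fa"))
  expect_identical(prom, ann$promoters)
  snps <- read_snps_vcf(file.path(dir, "snps.vcf"))
  expect_identical(snps$pos, as.integer(ann$snps$pos))
  flag_cols <- names(ann$snps)[vapply(ann$snps, is.logical, logical(1))]
  expect_identical(as.matrix(snps[, flag_cols]),
                   as.matrix(ann$snps[, flag_cols]))
  ## the full pipeline on files reproduces the planted truth
  asg <- assign_peaks(tss, peaks)
  counts <- count_snps(asg, snps, tss)
  expect_identical(unname(counts),
                   unname(ann$truth$snp_counts[names(counts)]))
  expect_identical(unname(scan_tata_set(prom)),
                   unname(ann$truth$tata_both))
})
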