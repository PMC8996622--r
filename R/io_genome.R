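## File-format boundary for the toy-genome annotation: BED (0-based
## half-open) for peaks, FASTA for promoters, minimal VCF (1-based) for
## substitution sites, plain TSV for the TSS table.

#' Write / read the TSS table
#'
#' Tab-separated with columns `gene`, `chrom`, `pos`, `strand`; `pos`
#' is the 0-based TSS coordinate (sources exporting 1-based positions
#' must be shifted by one upstream of this interface).
#'
#' @param tss TSS data frame.
#' @param path File path.
#' @return `read_tss_tsv` returns the data frame; `write_tss_tsv`
#'   invisibly returns `tss`.
#' @export
write_tss_tsv <- function(tss, path) {
  utils::write.table(tss[, c("gene", "chrom", "pos", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tss)
}

#' @rdname write_tss_tsv
#' @export
read_tss_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "character"))
}

#' Write / read peak intervals as BED
#'
#' The in-memory representation (0-based half-open `start`/`end`)
#' matches the BED convention; conversion is handled by rtracklayer.
#'
#' @param peaks Data frame `chrom`, `start`, `end`, optional `name`.
#' @param path BED file path.
#' @return `read_peaks_bed` returns the peaks data frame;
#'   `write_peaks_bed` invisibly returns `peaks`.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  if (!is.null(peaks$name)) names(gr) <- peaks$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(peaks)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Write / read proximal promoter sequences as FASTA
#'
#' @param promoters Named character vector (gene id -> sequence).
#' @param path FASTA file path.
#' @return `read_promoters_fasta` returns a named character vector;
#'   `write_promoters_fasta` invisibly returns `promoters`.
#' @export
write_promoters_fasta <- function(promoters, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(promoters), path)
  invisible(promoters)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read homozygous-substitution sites as minimal VCF
#'
#' One record per site with CHROM/POS/ID/REF/ALT/QUAL and a GT field
#' per resequenced sample (`1/1` for samples carrying the homozygous
#' substitution, `0/0` otherwise). POS follows the VCF 1-based
#' convention; the in-memory `pos` column is 0-based.
#'
#' @param snps Data frame `chrom`, `pos` (0-based), `id`, `ref`, `alt`,
#'   `qual`, plus one logical column per sample.
#' @param path VCF file path.
#' @return `read_snps_vcf` returns the snps data frame;
#'   `write_snps_vcf` invisibly returns `snps`.
#' @export
write_snps_vcf <- function(snps, path) {
  flag_cols <- names(snps)[vapply(snps, is.logical, logical(1))]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", flag_cols), collapse = "\t"))
  gt <- apply(snps[, flag_cols, drop = FALSE], 1, function(f)
    paste(ifelse(f, "1/1", "0/0"), collapse = "\t"))
  body <- paste(snps$chrom, snps$pos + 1L, snps$id, snps$ref, snps$alt,
                snps$qual, ".", ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, if (nrow(snps)) body), path)
  invisible(snps)
}

#' @rdname write_snps_vcf
#' @export
read_snps_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM,
                    pos = as.integer(fix$POS) - 1L,
                    id = fix$ID, ref = fix$REF, alt = fix$ALT,
                    qual = as.numeric(fix$QUAL),
                    stringsAsFactors = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  for (sn in colnames(gt)) out[[sn]] <- gt[, sn] == "1/1"
  out
}

#' Write a toy genome annotation to a directory
#'
#' Emits `tss.tsv`, `peaks.bed`, `promoters.fa`, `snps.vcf` and the
#' generator truth tables (`truth_peaks.tsv`, `truth_gene_counts.tsv`).
#'
#' @param ann A `genome_annotation` from [simulate_genome_annotation()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_genome_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "genome_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tss.tsv", "peaks.bed", "promoters.fa",
                            "snps.vcf", "truth_peaks.tsv",
                            "truth_gene_counts.tsv"))
  write_tss_tsv(ann$tss, paths[1])
  write_peaks_bed(ann$peaks, paths[2])
  write_promoters_fasta(ann$promoters, paths[3])
  write_snps_vcf(ann$snps, paths[4])
  utils::write.table(ann$truth$peaks, paths[5], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gc0 <- data.frame(gene = names(ann$truth$snp_counts),
                    snp_events = as.integer(ann$truth$snp_counts),
                    tata_both = as.integer(ann$truth$tata_both),
                    tata_forward = as.integer(ann$truth$tata_forward))
  utils::write.table(gc0, paths[6], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
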