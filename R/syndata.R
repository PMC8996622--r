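#' Configuration for the synthetic twin-embryo study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe the study design the analysis assumes: four developmental
#' stages sampled as sex-matched inbred twin pairs, with an hourglass
#' noise profile (the two mid, "phylotypic" stages quietest), technical
#' quadruplicates with smaller noise, two diverged wild populations, and
#' a monotone decreasing mean-variance coupling on the log10(TPM+1)
#' scale.
#'
#' Per-gene noise is `stage_noise_sd[stage] * s_j * g(mu_j)` where `s_j`
#' is a lognormal gene multiplier (spread `gene_scale_heterogeneity`;
#' shared between within-population noise and between-population shifts,
#' which plants the stability-conservation correlation) and
#' `g(mu) = a + b * exp(-c * mu)` is the mean-variance coupling.
#'
#' @param n_genes Number of genes.
#' @param n_pairs_per_stage Twin pairs per stage (the study used 13-25).
#' @param stages Ordered stage labels, flanks first/last.
#' @param stage_noise_sd Per-stage biological noise scale (log10 scale),
#'   same length/order as `stages`.
#' @param tech_noise_sd Technical noise scale (log10 scale).
#' @param divergence_sd Scale of the per-gene between-population shift.
#' @param mean_variance_coupling Named numeric `c(a=, b=, c=)` of
#'   `g(mu) = a + b*exp(-c*mu)`.
#' @param gene_scale_heterogeneity `sdlog` of the lognormal per-gene
#'   multiplier `s_j` (mean 1).
#' @param go_n_terms,go_base_rate,go_planted_fold Size of the synthetic
#'   GO-slim vocabulary, per-term annotation rate, and the enrichment
#'   factor of the first term among the 10% of genes with the smallest
#'   multipliers `s_j` (the planted signal recovered by enrichment
#'   tests).
#' @param seed RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_pairs_per_stage = 20,
                       stages = c("early", "phylo1", "phylo2", "hatch"),
                       stage_noise_sd = c(0.20, 0.10, 0.10, 0.25),
                       tech_noise_sd = 0.05,
                       divergence_sd = 0.15,
                       mean_variance_coupling = c(a = 0.25, b = 1.5, c = 1.2),
                       gene_scale_heterogeneity = 0.4,
                       go_n_terms = 30,
                       go_base_rate = 0.04,
                       go_planted_fold = 5,
                       seed = 1) {
  if (!length(stages)) stop("`stages` must be non-empty")
  if (length(stage_noise_sd) != length(stages))
    stop("`stage_noise_sd` must match `stages`")
  sds <- c(stage_noise_sd, tech_noise_sd, divergence_sd,
           gene_scale_heterogeneity)
  if (any(sds < 0)) stop("all sd parameters must be >= 0")
  if (n_genes < 1 || n_pairs_per_stage < 1)
    stop("`n_genes` and `n_pairs_per_stage` must be positive")
  mvc <- mean_variance_coupling
  if (!all(c("a", "b", "c") %in% names(mvc)))
    stop("`mean_variance_coupling` needs elements a, b, c")
  structure(list(n_genes = as.integer(n_genes),
                 n_pairs_per_stage = as.integer(n_pairs_per_stage),
                 stages = as.character(stages),
                 stage_noise_sd = stats::setNames(stage_noise_sd, stages),
                 tech_noise_sd = tech_noise_sd,
                 divergence_sd = divergence_sd,
                 mean_variance_coupling = mvc,
                 gene_scale_heterogeneity = gene_scale_heterogeneity,
                 go_n_terms = as.integer(go_n_terms),
                 go_base_rate = go_base_rate,
                 go_planted_fold = go_planted_fold,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## deterministic sub-seed per generator so that truth is shared but
## noise draws are independent across operations/stages
op_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) + offset) %% 2147483629)
}

#' Mean-variance coupling g(mu)
#'
#' Decreasing convex function `a + b*exp(-c*mu)` linking mean log
#' expression to the noise scale; flattens at high expression. This is
#' the expression-level bias the running-median correction removes.
#'
#' @param config A `sim_config`.
#' @param mu Mean log10(TPM+1) expression.
#' @return Numeric vector `g(mu)`.
#' @export
coupling_g <- function(config, mu) {
  p <- config$mean_variance_coupling
  unname(p["a"] + p["b"] * exp(-p["c"] * mu))
}

#' Per-gene ground truth of a simulation
#'
#' Deterministic in `config` (truth is drawn from `config$seed` alone and
#' shared by every generator): baseline log expression `mu`, lognormal
#' noise multiplier `s` (mean 1), between-population shift `delta`
#' (`Normal(0, divergence_sd * s)` -- sharing `s` plants the
#' stability-conservation correlation), the coupling value `g`, and
#' synthetic GO-slim annotations with one term enriched
#' `go_planted_fold`-fold among the 10% of genes with the smallest `s`.
#'
#' @param config A `sim_config`.
#' @return List with `gene` ids, `mu`, `s`, `delta`, `g`,
#'   `stage_noise_sd`, `go` (data frame gene/term) and
#'   `go_planted_term`.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  set.seed(op_seed(config, 0))
  gene <- sprintf("g%05d", seq_len(n))
  mu <- 0.5 + stats::rgamma(n, shape = 2, rate = 1.6)
  sdl <- config$gene_scale_heterogeneity
  s <- stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  delta <- stats::rnorm(n, 0, config$divergence_sd * s)
  g <- coupling_g(config, mu)

  terms <- sprintf("GOS:%04d", seq_len(config$go_n_terms))
  low_s <- rank(s, ties.method = "first") <= ceiling(0.10 * n)
  rate <- matrix(config$go_base_rate, n, config$go_n_terms)
  rate[low_s, 1] <- min(1, config$go_base_rate * config$go_planted_fold)
  hit <- matrix(stats::runif(n * config$go_n_terms), n) < rate
  go <- data.frame(gene = gene[row(hit)[hit]],
                   term = terms[col(hit)[hit]],
                   stringsAsFactors = FALSE)
  go <- go[order(go$gene, go$term), , drop = FALSE]
  rownames(go) <- NULL

  list(gene = gene, mu = stats::setNames(mu, gene),
       s = stats::setNames(s, gene), delta = stats::setNames(delta, gene),
       g = stats::setNames(g, gene),
       stage_noise_sd = config$stage_noise_sd,
       go = go, go_planted_term = terms[1],
       low_multiplier_genes = gene[low_s])
}

#' Simulate the twin-pair expression matrix of one stage
#'
#' Each of `n_pairs_per_stage` sex-matched twin pairs contributes two
#' samples; sample `x_j = mu_j + eps`,
#' `eps ~ Normal(0, stage_noise_sd[stage] * s_j * g(mu_j))` on the
#' log10(TPM+1) scale, independently for the two twins. Setting the
#' stage noise to zero makes the twins of every pair identical.
#'
#' @param config A `sim_config`.
#' @param stage One of `config$stages`.
#' @return List with `matrix` (an `expr_matrix`, scale `log10p1`) and
#'   `truth` (the [sim_truth()] list plus `sd_gene`, the per-gene noise
#'   sd used at this stage).
#' @export
simulate_twin_matrix <- function(config, stage) {
  stopifnot(inherits(config, "sim_config"))
  idx <- match(stage, config$stages)
  if (is.na(idx))
    stop("invalid stage label '", stage, "'; expected one of: ",
         paste(config$stages, collapse = ", "))
  truth <- sim_truth(config)
  n <- config$n_genes
  np <- config$n_pairs_per_stage
  sd_gene <- config$stage_noise_sd[idx] * truth$s * truth$g

  set.seed(op_seed(config, 1000 + idx))
  eps <- matrix(stats::rnorm(n * 2 * np), n) * sd_gene
  v <- truth$mu + eps
  pair_id <- sprintf("%s_p%02d", stage, rep(seq_len(np), each = 2))
  samp <- sprintf("%s_t%d", pair_id, rep(1:2, np))
  dimnames(v) <- list(truth$gene, samp)
  meta <- data.frame(sample = samp, stage = stage, strain = "inbred",
                     sex = rep(c("F", "M"), length.out = np)[
                       rep(seq_len(np), each = 2)],
                     pair = pair_id, role = "embryo",
                     stringsAsFactors = FALSE)
  truth$sd_gene <- sd_gene
  list(matrix = expr_matrix(v, meta, scale = "log10p1"), truth = truth)
}

#' Simulate two diverged population cohorts at one stage
#'
#' Population A uses baseline `mu_j`; population B uses `mu_j + delta_j`
#' with the per-gene shift `delta_j` drawn once (in [sim_truth()]) and
#' shared by every individual of B. Within-population noise is the twin
#' noise of the same stage. With `divergence_sd = 0` the populations are
#' statistically exchangeable.
#'
#' @param config A `sim_config`.
#' @param stage One of `config$stages`.
#' @param n_per_population Individuals per population (default
#'   `n_pairs_per_stage`).
#' @return List with `matrix_a`, `matrix_b` (both `expr_matrix`) and
#'   `truth`.
#' @export
simulate_population_matrices <- function(config, stage,
                                         n_per_population =
                                           config$n_pairs_per_stage) {
  stopifnot(inherits(config, "sim_config"))
  idx <- match(stage, config$stages)
  if (is.na(idx))
    stop("invalid stage label '", stage, "'")
  truth <- sim_truth(config)
  n <- config$n_genes
  m <- as.integer(n_per_population)
  sd_gene <- config$stage_noise_sd[idx] * truth$s * truth$g

  set.seed(op_seed(config, 2000 + idx))
  make <- function(base, popname) {
    eps <- matrix(stats::rnorm(n * m), n) * sd_gene
    v <- base + eps
    samp <- sprintf("%s_%s_i%02d", popname, stage, seq_len(m))
    dimnames(v) <- list(truth$gene, samp)
    meta <- data.frame(sample = samp, stage = stage, strain = popname,
                       sex = rep(c("F", "M"), length.out = m),
                       pair = NA_character_, role = "embryo",
                       stringsAsFactors = FALSE)
    expr_matrix(v, meta, scale = "log10p1")
  }
  ma <- make(truth$mu, "popA")
  mb <- make(truth$mu + truth$delta, "popB")
  truth$sd_gene <- sd_gene
  list(matrix_a = ma, matrix_b = mb, truth = truth)
}

#' Simulate a technical quadruplicate
#'
#' Four samples share one latent profile (the baseline `mu`, emulating a
#' pooled-then-split RNA sample) and receive independent technical noise
#' `Normal(0, tech_noise_sd * s_j * g(mu_j))`. The technical noise
#' carries the same per-gene multiplier and mean-variance coupling as
#' the biological noise, so equating `tech_noise_sd` with a stage sd
#' yields an exact per-gene null for filter calibration.
#'
#' @param config A `sim_config`.
#' @param n_replicates Number of replicates (default 4; the downstream
#'   technical-error summary expects 4).
#' @return List with `matrix` (`expr_matrix`) and `truth`.
#' @export
simulate_technical_replicates <- function(config, n_replicates = 4) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  n <- config$n_genes
  r <- as.integer(n_replicates)
  sd_gene <- config$tech_noise_sd * truth$s * truth$g
  set.seed(op_seed(config, 3000))
  eps <- matrix(stats::rnorm(n * r), n) * sd_gene
  v <- truth$mu + eps
  samp <- sprintf("tech_r%d", seq_len(r))
  dimnames(v) <- list(truth$gene, samp)
  meta <- data.frame(sample = samp, stage = NA_character_,
                     strain = "inbred", sex = NA_character_,
                     pair = "techpool", role = "technical",
                     stringsAsFactors = FALSE)
  truth$sd_gene <- sd_gene
  list(matrix = expr_matrix(v, meta, scale = "log10p1"), truth = truth)
}

#' Simulate a read-count matrix for the depth-bias analysis
#'
#' Counts are multinomial draws at `depth` reads per sample with
#' gene proportions proportional to the baseline TPM `10^mu - 1`
#' (identical latent profile for every sample, so observed variation is
#' pure counting noise).
#'
#' @param config A `sim_config`.
#' @param n_samples Number of samples.
#' @param depth Total reads per sample.
#' @return Integer matrix genes x samples.
#' @export
simulate_count_matrix <- function(config, n_samples = 4, depth = 2e5) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  p <- pmax(10^truth$mu - 1, 0)
  p <- p / sum(p)
  set.seed(op_seed(config, 4000))
  v <- stats::rmultinom(n_samples, as.integer(depth), p)
  dimnames(v) <- list(truth$gene,
                      sprintf("cnt_s%d", seq_len(n_samples)))
  v
}

## per-motif total match count of a planted, C-padded TATA motif:
## forward hit (1) plus a reverse-strand hit when the motif is its own
## reverse complement (only TATATATA). The C padding blocks any match
## window that crosses a planted-motif boundary (no motif contains C/G).
.tata_motifs <- c("TATAAAAA", "TATAAATA", "TATATAAA", "TATATATA")
.tata_planted_both <- c(TATAAAAA = 1L, TATAAATA = 1L,
                        TATATAAA = 1L, TATATATA = 2L)

#' Simulate a toy genome annotation
#'
#' Builds, for every gene, a TSS on a multi-chromosome toy genome
#' (20 kb spacing, alternating strand), ATAC-like peak intervals placed
#' at recorded offsets inside the distal window, homozygous-substitution
#' sites with per-sample carrier flags (8 samples) planted inside those
#' peaks, and a 150-bp proximal promoter sequence with a recorded number
#' of planted TATA-box motifs. Two boundary-test peaks are planted for
#' the first two genes: one overlapping its window by exactly half its
#' length (to be excluded by the strict > half rule) and one by
#' three-quarters (to be retained).
#'
#' The promoter background alphabet is {A, C, G} and each planted motif
#' is padded with C, so the recorded motif counts are exact under the
#' counting rules (every two-base shift and both strands counted).
#'
#' @param config A `sim_config`.
#' @param promoter_length Proximal promoter length in bp (default 150,
#'   i.e. -100..+50 around the TSS, half-open).
#' @param distal_flank Distal window half-width used to place peaks.
#' @param n_snp_samples Number of resequenced samples carrying
#'   substitution flags.
#' @return List of class `genome_annotation` with elements `tss`
#'   (gene, chrom, pos [0-based], strand), `peaks` (chrom, start, end,
#'   name; 0-based half-open), `snps` (chrom, pos, id, ref, alt, qual +
#'   logical carrier columns), `promoters` (named character vector),
#'   `n_snp_samples`, and `truth` (per-peak intended gene/retention,
#'   per-gene planted SNP-event and TATA counts).
#' @export
simulate_genome_annotation <- function(config, promoter_length = 150,
                                       distal_flank = 5000,
                                       n_snp_samples = 8) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  n <- config$n_genes
  set.seed(op_seed(config, 5000))

  genes_per_chrom <- 200L
  chrom <- sprintf("chr%d", (seq_len(n) - 1L) %/% genes_per_chrom + 1L)
  pos <- 10000L + ((seq_len(n) - 1L) %% genes_per_chrom) * 20000L
  strand <- rep(c("+", "-"), length.out = n)
  tss <- data.frame(gene = truth$gene, chrom = chrom, pos = pos,
                    strand = strand, stringsAsFactors = FALSE)

  ## regular peaks, fully inside the distal window of their own gene
  has_peak <- stats::runif(n) < 0.7
  has_peak[1:2] <- FALSE   # reserved for the boundary-test peaks
  pk <- list(); pk_truth <- list()
  for (j in which(has_peak)) {
    k <- sample(1:3, 1)
    w <- sample(200:1000, k, replace = TRUE)
    o <- vapply(w, function(wi) sample(seq(-4000L, 4000L - wi), 1),
                integer(1))
    start <- pos[j] + o
    nm <- sprintf("peak_%s_%d", truth$gene[j], seq_len(k))
    pk[[length(pk) + 1]] <-
      data.frame(chrom = chrom[j], start = start, end = start + w,
                 name = nm, stringsAsFactors = FALSE)
    pk_truth[[length(pk_truth) + 1]] <-
      data.frame(name = nm, gene = truth$gene[j], retained = TRUE,
                 stringsAsFactors = FALSE)
  }
  ## boundary peaks: distal window is [pos - flank, pos + flank), so a
  ## 2000-bp peak starting at pos + flank - 1000 overlaps exactly half
  bpos <- pos[1]
  flank <- as.integer(distal_flank)
  pk[[length(pk) + 1]] <- data.frame(
    chrom = chrom[1:2],
    start = c(bpos + flank - 1000L, pos[2] + flank - 1500L),
    end = c(bpos + flank + 1000L, pos[2] + flank + 500L),
    name = c("peak_boundary_half", "peak_boundary_kept"),
    stringsAsFactors = FALSE)
  pk_truth[[length(pk_truth) + 1]] <- data.frame(
    name = c("peak_boundary_half", "peak_boundary_kept"),
    gene = truth$gene[1:2], retained = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  peaks <- do.call(rbind, pk)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peak_truth <- do.call(rbind, pk_truth)

  ## SNPs planted strictly inside regular (retained) peaks
  snp <- list()
  snp_counts <- stats::setNames(integer(n), truth$gene)
  reg <- peak_truth$name[peak_truth$retained &
                           !grepl("boundary", peak_truth$name)]
  pick <- reg[stats::runif(length(reg)) < 0.5]
  bases <- c("A", "C", "G", "T")
  for (nm in pick) {
    row <- peaks[peaks$name == nm, ]
    gene <- peak_truth$gene[peak_truth$name == nm]
    p1 <- row$start + sample.int(row$end - row$start, 1) - 1L
    carriers <- stats::rbinom(1, n_snp_samples, 0.35)
    if (carriers == 0) carriers <- 1L
    flags <- sample(rep(c(TRUE, FALSE),
                        c(carriers, n_snp_samples - carriers)))
    ref <- sample(bases, 1)
    snp[[length(snp) + 1]] <- cbind(
      data.frame(chrom = row$chrom, pos = p1,
                 id = sprintf("snp_%s", nm),
                 ref = ref, alt = sample(setdiff(bases, ref), 1),
                 qual = round(stats::runif(1, 40, 90), 1),
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(
        flags, sprintf("S%d", seq_len(n_snp_samples))))))
    snp_counts[gene] <- snp_counts[gene] + carriers
  }
  snps <- if (length(snp)) do.call(rbind, snp) else
    cbind(data.frame(chrom = character(), pos = integer(),
                     id = character(), ref = character(),
                     alt = character(), qual = numeric()),
          as.data.frame(matrix(logical(), 0, n_snp_samples,
                               dimnames = list(NULL,
                                 sprintf("S%d", seq_len(n_snp_samples))))))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  ## promoters with planted TATA motifs
  bg <- function(len) paste(sample(c("A", "C", "G"), len, TRUE,
                                   prob = c(0.3, 0.4, 0.3)),
                            collapse = "")
  n_motifs <- sample(0:2, n, replace = TRUE)
  tata_both <- integer(n); tata_fwd <- integer(n)
  promoters <- character(n)
  for (j in seq_len(n)) {
    k <- n_motifs[j]
    if (k == 0) { promoters[j] <- bg(promoter_length); next }
    mot <- sample(.tata_motifs, k, replace = TRUE)
    units <- paste0("C", mot, "C")          # 10 nt each
    free <- promoter_length - 10 * k
    cuts <- sort(sample(0:free, k))
    segs <- diff(c(0, cuts))
    seq <- ""
    for (u in seq_len(k))
      seq <- paste0(seq, bg(segs[u]), units[u])
    promoters[j] <- paste0(seq, bg(free - cuts[k]))
    tata_both[j] <- sum(.tata_planted_both[mot])
    tata_fwd[j] <- k
  }
  names(promoters) <- truth$gene

  structure(list(
    tss = tss, peaks = peaks, snps = snps, promoters = promoters,
    n_snp_samples = n_snp_samples,
    truth = list(peaks = peak_truth, snp_counts = snp_counts,
                 tata_both = stats::setNames(tata_both, truth$gene),
                 tata_forward = stats::setNames(tata_fwd, truth$gene))),
    class = "genome_annotation")
}

#' Simulate tissue/stage expression profiles for pleiotropy analysis
#'
#' Each gene is expressed (clearly above TPM 1) in a random subset of
#' contexts; the per-gene probability of expression decreases with the
#' gene's noise multiplier `s_j`, planting the negative association
#' between expression variability and pleiotropy. Each context carries
#' `n_replicates` replicate samples on the TPM scale.
#'
#' @param config A `sim_config`.
#' @param n_contexts Number of tissues (25) or stages (16).
#' @param n_replicates Replicates per context (4 tissues / 3 stages).
#' @param label Context label prefix (`"tissue"` or `"stage"`).
#' @return List with `matrix` (`expr_matrix`, TPM scale; the context of
#'   each sample is stored in the `stage` metadata column) and `truth`
#'   (logical genes x contexts expression mask).
#' @export
simulate_pleiotropy_profiles <- function(config, n_contexts = 25,
                                         n_replicates = 4,
                                         label = "tissue") {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  n <- config$n_genes
  set.seed(op_seed(config, 6000 + n_contexts))
  p_expr <- 0.9 - 0.75 * (rank(truth$s, ties.method = "first") - 1) /
    max(n - 1, 1)
  mask <- matrix(stats::runif(n * n_contexts), n) < p_expr
  ctx <- sprintf("%s%02d", label, seq_len(n_contexts))
  dimnames(mask) <- list(truth$gene, ctx)

  base <- 10^truth$mu                     # >= ~3 TPM when expressed
  cols <- list(); meta <- list()
  for (ci in seq_len(n_contexts)) {
    for (r in seq_len(n_replicates)) {
      tpm <- ifelse(mask[, ci],
                    base * exp(stats::rnorm(n, 0, 0.2)),
                    stats::runif(n, 0, 0.3))
      cols[[length(cols) + 1]] <- tpm
      meta[[length(meta) + 1]] <- data.frame(
        sample = sprintf("%s_r%d", ctx[ci], r), stage = ctx[ci],
        strain = "inbred", sex = NA_character_, pair = NA_character_,
        role = "tissue", stringsAsFactors = FALSE)
    }
  }
  v <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  dimnames(v) <- list(truth$gene, meta$sample)
  list(matrix = expr_matrix(v, meta, scale = "tpm"), truth = mask)
}

#' Simulate replicate-averaged ortholog profiles of another species
#'
#' Returns the inbred-average log expression profile (baseline plus
#' small averaging error) together with a diverged species profile whose
#' per-gene shift partly shares the gene multiplier `s_j`
#' (`attenuation` controls the shared fraction; smaller values mimic the
#' weaker macroevolutionary signal), and the 1:1 ortholog map.
#'
#' @param config A `sim_config`.
#' @param species Species label used in ortholog ids.
#' @param attenuation Fraction in (0, 1] of the shift scale tied to
#'   `s_j`; the remainder is gene-independent.
#' @param shift_scale Overall interspecies shift scale (log10 units).
#' @return List with `profile_ref` (named numeric, reference species),
#'   `profile_other` (named by the other species' gene ids), and `map`
#'   (data frame `gene_ref`, `gene_other`).
#' @export
simulate_ortholog_profiles <- function(config, species = "species",
                                       attenuation = 0.5,
                                       shift_scale = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  n <- config$n_genes
  set.seed(op_seed(config, 7000))
  shared <- stats::rnorm(n, 0, shift_scale * attenuation * truth$s)
  indep <- stats::rnorm(n, 0, shift_scale * (1 - attenuation))
  profile_ref <- truth$mu + stats::rnorm(n, 0, 0.01)
  profile_other <- truth$mu + shared + indep + stats::rnorm(n, 0, 0.01)
  ids_other <- sprintf("%s_%s", species, truth$gene)
  names(profile_other) <- ids_other
  list(profile_ref = profile_ref,
       profile_other = profile_other,
       map = data.frame(gene_ref = truth$gene, gene_other = ids_other,
                        stringsAsFactors = FALSE))
}
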