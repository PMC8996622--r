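test_that("config validation rejects bad parameters", {
  expect_error(sim_config(stage_noise_sd = c(0.1, 0.1)), "match")
  expect_error(sim_config(tech_noise_sd = -1), ">= 0")
  expect_error(sim_config(stages = character(),
                          stage_noise_sd = numeric()), "non-empty")
  expect_error(simulate_twin_matrix(sim_config(n_genes = 10), "larva"),
               "invalid stage")
})

test_that("identical config and seed give bit-identical output", {
  cfg <- sim_config(n_genes = 120, n_pairs_per_stage = 5, seed = 42)
  a <- simulate_twin_matrix(cfg, "early")
  b <- simulate_twin_matrix(cfg, "early")
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(simulate_genome_annotation(cfg),
                   simulate_genome_annotation(cfg))
  expect_identical(simulate_pleiotropy_profiles(cfg, 5, 2)$matrix$values,
                   simulate_pleiotropy_profiles(cfg, 5, 2)$matrix$values)
  ## different stage or seed changes the noise draws
  expect_false(identical(a$matrix$values,
                         simulate_twin_matrix(cfg, "hatch")$matrix$values))
  cfg2 <- sim_config(n_genes = 120, n_pairs_per_stage = 5, seed = 43)
  expect_false(identical(a$matrix$values,
                         simulate_twin_matrix(cfg2, "early")$matrix$values))
})

test_that("zero noise propagates to exactly zero variation", {
  cfg <- sim_config(n_genes = 80, n_pairs_per_stage = 6,
                    stage_noise_sd = c(0, 0, 0, 0), tech_noise_sd = 0,
                    divergence_sd = 0, seed = 5)
  tw <- simulate_twin_matrix(cfg, "phylo2")
  pairs <- twin_pair_design(tw$matrix)
  d <- abs_pair_differences(tw$matrix, pairs)
  expect_true(all(d == 0))
  expect_identical(stage_stability(tw$matrix, pairs)$mean_V, 0)
  tech <- simulate_technical_replicates(cfg)
  expect_equal(tech$matrix$values[, 1], tech$matrix$values[, 4])
  pop <- simulate_population_matrices(cfg, "phylo2")
  expect_identical(intraspecies_diversity(pop$matrix_a,
                                          pop$matrix_b)$mean_V, 0)
})

test_that("twin log-differences match the closed-form variance", {
  cfg <- sim_config(n_genes = 5000, n_pairs_per_stage = 20, seed = 11)
  for (stage in c("early", "phylo1")) {
    tw <- simulate_twin_matrix(cfg, stage)
    pairs <- twin_pair_design(tw$matrix)
    y <- tw$matrix$values[, pairs$sample_i] -
      tw$matrix$values[, pairs$sample_k]
    ## pooled variance over genes x pairs vs mean_j 2 * sd_gene_j^2
    expected <- mean(2 * tw$truth$sd_gene^2)
    expect_equal(mean(y^2), expected, tolerance = 0.05)
  }
})

test_that("population shift is drawn once per gene and shared", {
  cfg <- sim_config(n_genes = 50, n_pairs_per_stage = 4,
                    stage_noise_sd = c(0, 0, 0, 0), seed = 2)
  pop <- simulate_population_matrices(cfg, "early")
  ## every individual of population B carries the same per-gene shift
  expect_true(all(apply(pop$matrix_b$values, 1,
                        function(r) diff(range(r)) == 0)))
  shift <- pop$matrix_b$values[, 1] - pop$matrix_a$values[, 1]
  expect_equal(unname(shift), unname(pop$truth$delta))
})

test_that("zero divergence makes the populations exchangeable", {
  cfg <- sim_config(n_genes = 2000, n_pairs_per_stage = 15,
                    divergence_sd = 0, seed = 9)
  tw <- simulate_twin_matrix(cfg, "phylo1")
  pop <- simulate_population_matrices(cfg, "phylo1")
  v_twin <- stage_stability(tw$matrix, twin_pair_design(tw$matrix))
  v_cross <- intraspecies_diversity(pop$matrix_a, pop$matrix_b)
  expect_equal(v_cross$mean_V, v_twin$mean_V, tolerance = 0.1)
})

test_that("shared gene multipliers couple stability and divergence", {
  cfg <- sim_config(n_genes = 5000, n_pairs_per_stage = 20, seed = 21)
  tw <- simulate_twin_matrix(cfg, "phylo1")
  pop <- simulate_population_matrices(cfg, "phylo1")
  twin_var <- gene_variation(tw$matrix, twin_pair_design(tw$matrix))
  cross_var <- gene_variation(
    bind_samples(pop$matrix_a, pop$matrix_b),
    cross_pair_design(pop$matrix_a, pop$matrix_b))
  expect_gt(cor(twin_var, cross_var, method = "spearman"), 0)
})

test_that("technical quadruplicate supports the six-pair design", {
  cfg <- sim_config(n_genes = 40, seed = 1)
  tech <- simulate_technical_replicates(cfg)
  expect_identical(ncol(tech$matrix$values), 4L)
  expect_identical(nrow(technical_pair_design(tech$matrix)), 6L)
})

test_that("genome annotation truth matches its own construction", {
  cfg <- sim_config(n_genes = 250, seed = 14)
  ann <- simulate_genome_annotation(cfg)
  expect_identical(nrow(ann$tss), 250L)
  expect_true(all(ann$peaks$start < ann$peaks$end))
  ## planted boundary peaks: half overlap excluded, 3/4 overlap kept
  tp <- ann$truth$peaks
  expect_false(tp$retained[tp$name == "peak_boundary_half"])
  expect_true(tp$retained[tp$name == "peak_boundary_kept"])
  ## promoters: length 150, alphabet ACGT, planted counts consistent
  expect_true(all(nchar(ann$promoters) == 150))
  expect_false(any(grepl("[^ACGT]", ann$promoters)))
  zero <- names(ann$truth$tata_both)[ann$truth$tata_both == 0]
  expect_gt(length(zero), 0)
  expect_identical(unname(scan_tata_set(ann$promoters[zero])),
                   rep(0L, length(zero)))
})

test_that("truth dimensions are consistent across generators", {
  cfg <- sim_config(n_genes = 90, n_pairs_per_stage = 3, seed = 8)
  truth <- sim_truth(cfg)
  expect_length(truth$mu, 90)
  expect_length(truth$s, 90)
  expect_length(truth$delta, 90)
  expect_true(all(truth$go$gene %in% truth$gene))
  tw <- simulate_twin_matrix(cfg, "early")
  expect_identical(gene_ids(tw$matrix), truth$gene)
  pl <- simulate_pleiotropy_profiles(cfg, n_contexts = 7, n_replicates = 2)
  expect_identical(dim(pl$truth), c(90L, 7L))
  expect_identical(dim(pl$matrix$values), c(90L, 14L))
})
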