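test_that("gene variation is the mean absolute pair difference", {
  v <- cbind(s1 = c(g1 = 1.0, g2 = 2.0), s2 = c(1.2, 2.0),
             s3 = c(0.6, 2.0), s4 = c(1.0, 2.0))
  em <- make_em(v)
  pr <- data.frame(sample_i = c("s1", "s3"), sample_k = c("s2", "s4"))
  gv <- gene_variation(em, pr)
  expect_equal(unname(gv), c(mean(c(0.2, 0.4)), 0))
  expect_equal(gene_variation(em, pr[2:1, ]), gv)
  expect_error(gene_variation(em, pr[0, ]), "empty")
})

test_that("running median reproduces hand-derived windows", {
  ## constant raw variation -> corrected identically 0
  tabc <- data.frame(gene = paste0("g", 1:9), mean_expr = 1:9, raw = 0.4)
  expect_equal(running_median_correct(tabc, 5)$corrected, rep(0, 9))
  ## window 5 over sorted raws 1..5: medians are the values themselves
  tab5 <- data.frame(gene = paste0("g", 1:5), mean_expr = 1:5, raw = 1:5)
  expect_equal(running_median_correct(tab5, 5)$corrected, rep(0, 5))
  ## first and last gene have a single-gene window -> corrected 0
  set.seed(2)
  tabr <- data.frame(gene = sprintf("g%03d", 1:40),
                     mean_expr = runif(40), raw = runif(40))
  out <- running_median_correct(tabr, 7)
  edge <- order(tabr$mean_expr, tabr$gene)[c(1, 40)]
  expect_equal(out$corrected[edge], c(0, 0))
  expect_error(running_median_correct(tabr, 6), "odd")
  expect_warning(running_median_correct(tabr, 41), "exceeds")
})

test_that("running median equals the brute-force window oracle", {
  set.seed(13)
  for (n in c(37, 500)) {
    tab <- data.frame(gene = sprintf("g%04d", sample(n)),
                      mean_expr = sample(round(runif(n), 2)),  # with ties
                      raw = rnorm(n)^2)
    for (w in c(1, 5, 51)) {
      got <- suppressWarnings(running_median_correct(tab, w))
      expect_equal(got$corrected,
                   oracle_running_median(tab$gene, tab$mean_expr,
                                         tab$raw, w),
                   info = sprintf("n=%d w=%d", n, w))
      expect_identical(got$gene, tab$gene)  # original order restored
      expect_equal(got$raw - got$running_median, got$corrected)
    }
  }
})

test_that("intraspecies gene variation is corrected like twin variation", {
  cfg <- sim_config(n_genes = 700, n_pairs_per_stage = 8,
                    divergence_sd = 0, stage_noise_sd = c(0, 0, 0, 0),
                    seed = 23)
  pop <- simulate_population_matrices(cfg, "phylo1")
  tab <- intraspecies_gene_variation(pop$matrix_a, pop$matrix_b,
                                     window = 51)
  expect_true(all(tab$raw == 0))
  expect_identical(tab$cohort[1], "intraspecies")
  ## symmetric in population order
  tab2 <- intraspecies_gene_variation(pop$matrix_b, pop$matrix_a,
                                      window = 51)
  expect_equal(tab2$raw, tab$raw)
})

test_that("reciprocal best hits require mutual best status", {
  ab <- data.frame(qseqid = c("a1", "a1", "a2"),
                   sseqid = c("b1", "b2", "b1"),
                   evalue = c(1e-30, 1e-10, 1e-40),
                   bitscore = c(300, 100, 400))
  ba <- data.frame(qseqid = c("b1", "b2"),
                   sseqid = c("a2", "a1"),
                   evalue = c(1e-35, 1e-12),
                   bitscore = c(350, 120))
  got <- resolve_rbh(ab, ba)
  ## a1's best is b1 but b1's best is a2: only (a2, b1) survives...
  ## and b2 -> a1 is reciprocal with a1 -> ? a1's best is b1, not b2
  expect_identical(got$gene_a, "a2")
  expect_identical(got$gene_b, "b1")
  ## weak-hit flag flips the filter direction
  none <- resolve_rbh(ab, ba, evalue_cutoff = 1e-50)
  expect_identical(nrow(none), 0L)
})

test_that("RBH resolution matches the double-loop oracle", {
  set.seed(91)
  for (rep in 1:20) {
    ht <- random_hit_tables()
    expect_equal(resolve_rbh(ht$ab, ht$ba),
                 oracle_rbh(ht$ab, ht$ba),
                 ignore_attr = TRUE)
  }
})

test_that("interspecies variation handles identity and empty maps", {
  prof <- c(a = 1, b = 2, c = 3)
  map <- data.frame(gene_a = c("a", "b", "c"),
                    gene_b = c("sa", "sb", "sc"))
  other <- c(sa = 1, sb = 2, sc = 3)
  tab <- interspecies_gene_variation(prof, other, map, window = 3)
  expect_equal(tab$raw, c(0, 0, 0))
  empty <- interspecies_gene_variation(prof, other, map[0, ], window = 3)
  expect_identical(nrow(empty), 0L)
  ## missing orthologs are dropped with a message
  expect_message(
    dropped <- suppressWarnings(interspecies_gene_variation(
      prof, other[1:2], map, window = 3)),
    "dropped")
  expect_identical(nrow(dropped), 2L)
})

test_that("stability-conservation correlation hits the rank anchors", {
  set.seed(3)
  t1 <- data.frame(gene = sprintf("g%02d", 1:30), corrected = rnorm(30))
  t2 <- t1
  expect_equal(stability_conservation_correlation(t1, t2)$rho, 1)
  t3 <- t1; t3$corrected <- -t1$corrected
  expect_equal(stability_conservation_correlation(t1, t3)$rho, -1)
  expect_error(stability_conservation_correlation(t1[1:5, ], t2[1:5, ]),
               ">= 10")
})

test_that("expression quintiles split with the remainder rule", {
  tab <- data.frame(gene = sprintf("g%02d", 1:12), mean_expr = 12:1,
                    raw = 0, corrected = 0)
  q <- expression_quintile_split(tab)
  expect_identical(unname(vapply(q, nrow, integer(1))),
                   c(3L, 3L, 2L, 2L, 2L))
  ## Q1 holds the lowest-expression genes
  expect_identical(q$Q1$gene, c("g12", "g11", "g10"))
  expect_setequal(unlist(lapply(q, `[[`, "gene")), tab$gene)
  ten <- expression_quintile_split(tab[1:10, ])
  expect_identical(unname(vapply(ten, nrow, integer(1))), rep(2L, 5))
  expect_error(expression_quintile_split(tab[1:4, ]), "at least 5")
})

test_that("macroevolutionary coupling is weaker than microevolutionary", {
  cfg <- sim_config(n_genes = 4000, n_pairs_per_stage = 20, seed = 29)
  tw <- simulate_twin_matrix(cfg, "phylo1")
  twin_tab <- gene_variation_table(tw$matrix, twin_pair_design(tw$matrix))
  pop <- simulate_population_matrices(cfg, "phylo1")
  intra_tab <- intraspecies_gene_variation(pop$matrix_a, pop$matrix_b)
  orth <- simulate_ortholog_profiles(cfg, attenuation = 0.4)
  inter_tab <- interspecies_gene_variation(orth$profile_ref,
                                           orth$profile_other, orth$map)
  rho_micro <- stability_conservation_correlation(twin_tab, intra_tab)$rho
  rho_macro <- stability_conservation_correlation(twin_tab, inter_tab)$rho
  expect_gt(rho_micro, 0)
  expect_gt(rho_macro, 0)
  expect_lt(rho_macro, rho_micro)
})
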