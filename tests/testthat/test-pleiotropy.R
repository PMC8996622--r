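test_that("context expression counts use inclusive replicate means", {
  v <- cbind(t1_r1 = c(g1 = 0.5, g2 = 0, g3 = 4),
             t1_r2 = c(1.5, 0, 4),
             t2_r1 = c(0.9, 0, 4),
             t2_r2 = c(0.9, 0, 4))
  em <- make_em(v, scale = "tpm", stage = c("t1", "t1", "t2", "t2"),
                role = "tissue")
  got <- context_expression_count(em)
  ## g1: mean 1.0 in t1 (counted, boundary inclusive), 0.9 in t2
  expect_identical(got$n_contexts, c(1L, 0L, 2L))
  expect_error(context_expression_count(make_em(v)), "TPM")
})

test_that("developmental gene set follows the ontology closure", {
  edges <- data.frame(child = c("GO:A", "GO:B", "GO:C"),
                      parent = c("GO:0032502", "GO:A", "GO:X"))
  ann <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    term = c("GO:0032502", "GO:B", "GO:C", "GO:Z"))
  got <- developmental_gene_set(ann, edges)
  ## direct annotation and grandchild term included; unrelated excluded
  expect_identical(got, c("g1", "g2"))
  expect_error(developmental_gene_set(ann, edges, root = "GO:NOPE"),
               "absent")
})

test_that("constitutive genes must clear the threshold at every stage", {
  m <- rbind(g1 = c(0.1, 0.1, 0.1), g2 = c(5, 5, 0.09),
             g3 = c(0.2, 0.3, 0.4))
  colnames(m) <- paste0("st", 1:3)
  expect_identical(constitutive_gene_set(m), c("g1", "g3"))
  expect_error(constitutive_gene_set(m[, 0]), ">= 1 stage")
})

test_that("least-variable selection floors the count and breaks ties", {
  tab <- data.frame(gene = sprintf("g%03d", 1:100),
                    corrected = rep(0.5, 100))
  sel <- least_variable_fraction(tab, 0.10)
  expect_length(sel, 10)
  expect_identical(sel, sprintf("g%03d", 1:10))  # documented tie rule
  expect_length(least_variable_fraction(tab, 1), 100)
  expect_error(least_variable_fraction(tab, 0), "fraction")
  tab$corrected <- rev(seq_len(100))
  expect_setequal(least_variable_fraction(tab, 0.05),
                  sprintf("g%03d", 96:100))
})

test_that("enrichment reproduces the 10-of-100 worked example", {
  universe <- sprintf("g%03d", 1:100)
  selected <- universe[1:10]
  with_term <- c(universe[1:4], universe[11:16])  # 4 in, 6 out
  ann <- data.frame(gene = with_term, term = "T1")
  out <- enrichment_test(selected, universe, ann)
  expect_equal(out$fold, (4 / 10) / (6 / 90))   # = 6
  p_direct <- sum(dhyper(4:10, 10, 90, 10))
  expect_equal(out$p, p_direct)
  ## independent route: one-sided Fisher's exact test
  p_fisher <- fisher.test(matrix(c(4, 6, 6, 84), 2),
                          alternative = "greater")$p.value
  expect_equal(out$p, p_fisher)
  expect_identical(out$k, 4L)
  expect_identical(out$K, 10L)
})

test_that("Fisher tail equals exhaustive enumeration on small universes", {
  universe <- sprintf("g%02d", 1:12)
  ann <- data.frame(gene = universe[c(1, 2, 3, 7, 8)], term = "T")
  selected <- universe[1:4]
  out <- enrichment_test(selected, universe, ann)
  ## enumerate all C(12,4) selections; p = fraction with >= k hits
  k_obs <- out$k
  combos <- combn(12, 4)
  hits <- colSums(matrix(combos %in% c(1, 2, 3, 7, 8), nrow = 4))
  expect_equal(out$p, mean(hits >= k_obs))
})

test_that("q-values follow the Benjamini-Hochberg step-up rule", {
  universe <- sprintf("g%03d", 1:60)
  set.seed(4)
  ann <- data.frame(gene = sample(universe, 90, TRUE),
                    term = sample(c("T1", "T2", "T3"), 90, TRUE))
  out <- enrichment_test(universe[1:12], universe, ann)
  m <- nrow(out)
  o <- order(out$p)
  hand <- rev(cummin(rev(out$p[o] * m / seq_len(m))))
  hand <- pmin(hand, 1)
  expect_equal(out$q[o], hand)
  expect_true(all(out$q >= out$p))
  ## the textbook vector: (0.001, 0.002, 0.5) -> (0.003, 0.003, 0.5)
  expect_equal(p.adjust(c(0.001, 0.002, 0.5), "BH"),
               c(0.003, 0.003, 0.5))
})

test_that("twofold report excludes the exact boundary", {
  tab <- data.frame(term = c("A", "B", "C"), fold = c(2.0, 6.0, 1.2),
                    q = c(0.001, 0.5, 0.001))
  got <- twofold_report(tab)
  expect_identical(got$term, "B")
  expect_false(got$significant)
  expect_identical(nrow(twofold_report(tab[0, ])), 0L)
})

test_that("planted GO term surfaces in the least-variable fraction", {
  cfg <- sim_config(n_genes = 2000, n_pairs_per_stage = 20, seed = 55)
  tw <- simulate_twin_matrix(cfg, "phylo1")
  tab <- gene_variation_table(tw$matrix, twin_pair_design(tw$matrix))
  sel <- least_variable_fraction(tab, 0.10)
  out <- enrichment_test(sel, tab$gene, tw$truth$go)
  planted <- out[out$term == tw$truth$go_planted_term, ]
  expect_lte(planted$q, 0.01)
  expect_gt(planted$fold, 2)
})

test_that("pleiotropy is negatively associated with expression variability", {
  cfg <- sim_config(n_genes = 1500, n_pairs_per_stage = 15, seed = 62)
  tw <- simulate_twin_matrix(cfg, "phylo1")
  tab <- gene_variation_table(tw$matrix, twin_pair_design(tw$matrix))
  pl <- simulate_pleiotropy_profiles(cfg, n_contexts = 25,
                                     n_replicates = 4)
  counts <- context_expression_count(pl$matrix)
  rho <- cor(counts$n_contexts[match(tab$gene, counts$gene)],
             tab$corrected, method = "spearman")
  expect_lt(rho, 0)
})
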