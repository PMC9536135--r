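de_matrix <- function(a, b, gene = "GX", n_pad = 3, seed = 1) {
  # one gene of interest plus background rows so BH has something to adjust
  withr::with_seed(seed, {
    pad <- matrix(rnorm(n_pad * (length(a) + length(b)), mean = 5), n_pad)
    m <- rbind(c(a, b), pad)
    rownames(m) <- c(gene, sprintf("BG%02d", seq_len(n_pad)))
    colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
    m
  })
}

test_that("Welch t matches the textbook computation", {
  m <- de_matrix(c(1, 2, 3), c(4, 5, 6))
  labels <- rep(c("A", "B"), each = 3)
  de <- differential_expression(m, labels, "A")
  row <- de[de$gene == "GX", ]
  expect_equal(row$t, -3.674, tolerance = 1e-3)
  expect_equal(row$df, 4, tolerance = 1e-9)
  expect_equal(row$log_fc, -3)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
})

test_that("swapping group roles negates the effect and preserves p", {
  sim <- simulate_bulk(simulation_config(n_genes = 100, n_samples = 16,
                                         k_clusters = 2, program_size = 10,
                                         seed = 8, n_decoys = 3,
                                         sets_per_program = 2))
  de1 <- differential_expression(sim$expression, sim$truth$labels, 1)
  de2 <- differential_expression(sim$expression, sim$truth$labels, 2)
  de2 <- de2[match(de1$gene, de2$gene), ]
  expect_equal(de1$log_fc, -de2$log_fc, tolerance = 1e-12)
  expect_equal(de1$t, -de2$t, tolerance = 1e-12)
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
})

test_that("identical groups and degenerate variances are handled", {
  base <- matrix(rep(c(1, 2, 3, 4), each = 4), nrow = 4, byrow = TRUE)
  m <- cbind(base, base)
  rownames(m) <- sprintf("G%d", 1:4); colnames(m) <- sprintf("S%d", 1:8)
  labels <- rep(c("A", "B"), each = 4)
  de <- expect_silent(differential_expression(m, labels, "A"))
  expect_true(all(de$log_fc == 0))
  expect_true(all(de$t == 0))
  expect_true(all(de$p == 1))
  # zero variance with unequal means: p floored and flagged
  m2 <- m; m2[1, labels == "A"] <- 9
  expect_warning(de2 <- differential_expression(m2, labels, "A"), "floored")
  row <- de2[de2$gene == "G1", ]
  expect_true(row$degenerate)
  expect_equal(row$p, .Machine$double.xmin)
})

test_that("ORA reproduces closed-form hypergeometric values", {
  universe <- sprintf("U%02d", 1:20)
  term <- list(T1 = universe[1:5])
  res <- ora(universe[1:5], term, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # query = universe: every term certain, p = 1
  res2 <- ora(universe, term, universe)
  expect_equal(res2$p, 1)
  # zero overlap with a tiny term
  res3 <- ora(universe[6:8], list(T1 = universe[1:2]), universe)
  expect_lte(res3$p, 1)
  expect_equal(res3$overlap, 0)
})

test_that("ORA matches the pmf-summation oracle on random configurations", {
  withr::with_seed(55, {
    for (i in 1:100) {
      u <- sample(10:30, 1)
      universe <- sprintf("U%03d", seq_len(u))
      ts <- sample(1:u, 1); qs <- sample(1:u, 1)
      term <- sample(universe, ts)
      query <- sample(universe, qs)
      res <- ora(query, list(T1 = term), universe)
      expect_equal(res$p,
                   hyper_oracle(res$overlap, ts, qs, u), tolerance = 1e-12)
    }
  })
})

test_that("ORA validates inputs", {
  expect_error(ora("A", list(T1 = "A"), character(0)), "empty universe")
  expect_warning(ora(c("A", "ZZZ"), list(T1 = c("A", "B")), c("A", "B", "C")),
                 "outside the universe")
})

test_that("upstream regulator calls reflect concordance and enrichment", {
  universe <- sprintf("U%03d", 1:300)
  sig <- structure(list(name = "S2-1P", genes = universe[1:25], component = 1L,
                        direction = "positive", source_sets = "x",
                        membership_counts = setNames(rep(5L, 25), universe[1:25])),
                   class = "gene_signature")
  regs <- gene_set_collection(list(
    PERFECT = paste0(universe[1:25], "+"),
    DISJOINT = paste0(universe[200:220], "+"),
    UNSIGNED = universe[1:25]), label = "regulons")
  res <- upstream_regulators(sig, regs, universe)
  perfect <- res[res$regulator == "PERFECT", ]
  expect_equal(perfect$direction_score, sqrt(25))
  expect_equal(perfect$call, "activated")
  expect_lt(perfect$p, 1e-10)
  expect_equal(res$p[res$regulator == "DISJOINT"], 1)
  expect_equal(res$call[res$regulator == "UNSIGNED"], "undetermined")
  expect_true(is.na(res$direction_score[res$regulator == "UNSIGNED"]))
})

test_that("a planted regulator outranks decoy regulons", {
  sim <- simulate_bulk(simulation_config(n_genes = 600, n_samples = 20,
                                         k_clusters = 2, program_size = 40,
                                         seed = 44, n_decoys = 10,
                                         sets_per_program = 6))
  prof <- normalize_es(sim$expression, sim$collection, n_perm = 150, seed = 3)
  pc <- pca_decompose(prof)
  sigs <- synthesize_signatures(pc, sim$collection, dataset_code = "S")
  # find the signature matching cluster 1's planted program
  prog <- sim$truth$program_genes[[1]][[1]]$genes
  best <- sigs[[which.max(vapply(sigs, function(s)
    length(intersect(s$genes, prog)), numeric(1)))]]
  decoys <- withr::with_seed(5, {
    setNames(lapply(1:50, function(i) sample(rownames(sim$expression), 40)),
             sprintf("DECOYREG%02d", 1:50))
  })
  regs <- gene_set_collection(c(list(PLANTED = prog), decoys), label = "regulons")
  res <- upstream_regulators(best, regs, rownames(sim$expression))
  expect_equal(res$regulator[[1]], "PLANTED")
})
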