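pca_fixture <- function(seed = 1, n = 30) {
  # two correlated blocks of variables with opposite loading signs on PC1
  withr::with_seed(seed, {
    f <- rnorm(n)
    x <- cbind(A1 = f + rnorm(n, sd = 0.3), A2 = f + rnorm(n, sd = 0.3),
               B1 = -f + rnorm(n, sd = 0.3), B2 = -f + rnorm(n, sd = 0.3),
               C1 = rnorm(n))
    rownames(x) <- sprintf("S%02d", seq_len(n))
    x
  })
}

test_that("contributions are squared-loading percentages summing to 100", {
  x <- pca_fixture()
  pc <- pca_decompose(x, n_components = 3)
  expect_equal(unname(colSums(pc$contributions)), rep(100, 3), tolerance = 1e-9)
  expect_true(all(pc$contributions >= 0))
  # two perfectly correlated standardized variables split PC1 evenly
  y <- cbind(V1 = x[, "A1"], V2 = 2 * x[, "A1"] + 5)
  pc2 <- pca_decompose(y, n_components = 1)
  expect_equal(unname(pc2$contributions[, 1]), c(50, 50), tolerance = 1e-9)
})

test_that("loadings match a brute-force eigendecomposition of the correlation matrix", {
  x <- pca_fixture(seed = 9)
  pc <- pca_decompose(x, n_components = 3)
  ev <- eigen(cor(x), symmetric = TRUE)
  for (k in 1:3) {
    v <- ev$vectors[, k]
    v <- v * sign(v[which.max(abs(v))])  # same sign convention
    expect_equal(unname(pc$loadings[, k]), v, tolerance = 1e-8)
  }
  expect_equal(pc$explained_variance_ratio[1:3],
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-8)
})

test_that("contributions are invariant to sample and variable ordering", {
  x <- pca_fixture(seed = 4)
  pc <- pca_decompose(x)
  perm_s <- sample(nrow(x)); perm_v <- sample(ncol(x))
  pc2 <- pca_decompose(x[perm_s, perm_v])
  expect_equal(pc2$contributions[colnames(x), ], pc$contributions,
               tolerance = 1e-10)
})

test_that("constant variables are dropped with a warning before scaling", {
  x <- pca_fixture()
  x <- cbind(x, FLAT = 7)
  expect_warning(pc <- pca_decompose(x), "constant")
  expect_false("FLAT" %in% rownames(pc$loadings))
})

test_that("signature names encode dataset, collection, component and direction", {
  x <- pca_fixture(seed = 2)
  colnames(x) <- paste0("SET", 1:5)
  sets <- lapply(1:5, function(i) sprintf("GENE%02d", i + 0:5))
  names(sets) <- colnames(x)
  col <- gene_set_collection(sets, label = "canonical")
  pc <- pca_decompose(x)
  sig <- suppressWarnings(
    synthesize_signature(pc, col, component = 1, direction = "negative",
                         dataset_code = "T", top_n = 2, min_overlap = 1))
  expect_equal(sig$name, "T2-1N")
  expect_equal(sig$direction, "negative")
})

test_that("membership threshold is a hard >= min_overlap cut", {
  # gene X in exactly 5 of the sources, gene Y in exactly 4
  sets <- lapply(1:6, function(i) {
    g <- sprintf("FILL%02d_%d", 1:8, i)
    if (i <= 5) g <- c(g, "X")
    if (i <= 4) g <- c(g, "Y")
    g
  })
  names(sets) <- paste0("SET", 1:6)
  col <- gene_set_collection(sets, label = "custom")
  withr::with_seed(3, {
    f <- rnorm(40)
    x <- vapply(1:6, function(i) f + rnorm(40, sd = 0.2), numeric(40))
    colnames(x) <- names(sets); rownames(x) <- sprintf("S%02d", 1:40)
  })
  pc <- pca_decompose(x)
  sig <- suppressWarnings(
    synthesize_signature(pc, col, 1, "positive", "S", top_n = 6, min_overlap = 5))
  expect_true("X" %in% sig$genes)
  expect_false("Y" %in% sig$genes)
  expect_equal(unname(sig$membership_counts["X"]), 5L)
})

test_that("identical source sets collapse to that set's gene list", {
  genes <- sprintf("GENE%02d", 1:10)
  sets <- setNames(rep(list(genes), 4), paste0("SET", 1:4))
  col <- gene_set_collection(sets)
  withr::with_seed(5, {
    f <- rnorm(30)
    x <- vapply(1:4, function(i) f + rnorm(30, sd = 0.1), numeric(30))
    colnames(x) <- names(sets); rownames(x) <- sprintf("S%02d", 1:30)
  })
  pc <- pca_decompose(x)
  sig <- suppressWarnings(
    synthesize_signature(pc, col, 1, "positive", "S", top_n = 4, min_overlap = 4))
  expect_setequal(sig$genes, genes)
  expect_true(all(sig$membership_counts == 4))
})

test_that("the P and N signatures swap exactly under a sign flip", {
  sim <- simulate_bulk(simulation_config(n_genes = 300, n_samples = 20,
                                         k_clusters = 2, program_size = 20,
                                         seed = 17, n_decoys = 10,
                                         sets_per_program = 4))
  prof <- normalize_es(sim$expression, sim$collection, n_perm = 150, seed = 2)
  pc <- pca_decompose(prof)
  pos <- suppressWarnings(synthesize_signature(pc, sim$collection, 1, "positive",
                                               "S", min_overlap = 3))
  flipped <- pc
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  neg <- suppressWarnings(synthesize_signature(flipped, sim$collection, 1,
                                               "negative", "S", min_overlap = 3))
  expect_identical(neg$genes, pos$genes)
  expect_identical(neg$source_sets, pos$source_sets)
  expect_equal(neg$name, sub("P$", "N", pos$name))
})

test_that("an unreachable overlap threshold raises an advisory error", {
  x <- pca_fixture(seed = 2)
  colnames(x) <- paste0("SET", 1:5)
  sets <- setNames(lapply(1:5, function(i) sprintf("UNIQ%02d_%d", 1:5, i)),
                   colnames(x))
  col <- gene_set_collection(sets)
  pc <- pca_decompose(x)
  expect_error(suppressWarnings(
    synthesize_signature(pc, col, 1, "positive", "S", top_n = 5, min_overlap = 5)),
    "min_overlap")
})

test_that("signature scoring delegates to NES and is reproducible", {
  sim <- simulate_bulk(simulation_config(n_genes = 300, n_samples = 20,
                                         k_clusters = 2, program_size = 20,
                                         seed = 23, n_decoys = 10,
                                         sets_per_program = 4))
  prof <- normalize_es(sim$expression, sim$collection, n_perm = 150, seed = 2)
  pc <- pca_decompose(prof)
  # component 1 carries the planted two-cluster contrast; its P and N
  # signatures are the two clusters' programs
  sigs <- synthesize_signatures(pc, sim$collection, dataset_code = "S",
                                components = 1, min_overlap = 3)
  expect_length(sigs, 2)
  sm1 <- score_signature_matrix(sim$expression, sigs, n_perm = 150, seed = 6)
  sm2 <- score_signature_matrix(sim$expression, sigs, n_perm = 150, seed = 6)
  expect_identical(sm1$nes, sm2$nes)
  # each cluster scores its own program's signature highest (majority rule)
  lab <- sim$truth$labels
  for (cl in 1:2) {
    prog <- sim$truth$program_genes[[cl]][[1]]$genes
    own <- names(sigs)[which.max(vapply(sigs, function(s)
      length(intersect(s$genes, prog)), numeric(1)))]
    other <- setdiff(colnames(sm1$nes), own)
    in_cl <- names(lab)[lab == cl]
    wins <- vapply(in_cl, function(s)
      sm1$nes[s, own] > max(sm1$nes[s, other]), logical(1))
    expect_gt(mean(wins), 0.5)
  }
})

test_that("a random-gene signature scores near zero on average", {
  sim <- simulate_bulk(simulation_config(n_genes = 300, n_samples = 30,
                                         effect = 0, seed = 29, n_decoys = 4,
                                         sets_per_program = 2, program_size = 10))
  rand <- structure(list(name = "R0-1P",
                         genes = withr::with_seed(1, sample(rownames(sim$expression), 30)),
                         component = 1L, direction = "positive",
                         source_sets = character(0),
                         membership_counts = integer(0)),
                    class = "gene_signature")
  sm <- score_signature_matrix(sim$expression, list(rand), n_perm = 200, seed = 8)
  expect_lt(abs(mean(sm$nes[, "R0-1P"])), 0.2)
})
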