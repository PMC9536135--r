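cells_fixture <- function() {
  m <- matrix(c(1, 2, 3,
                2, 4, 0,
                3, 0, 6), nrow = 3, byrow = FALSE,
              dimnames = list(c("G1", "G2", "G3"), c("C1", "C2", "C3")))
  m
}

test_that("cell scores are set mean minus detected-gene mean", {
  m <- matrix(c(1, 2, 3, 0, 1, 2), nrow = 3,
              dimnames = list(c("G1", "G2", "G3"), c("C1", "C2")))
  cs <- cell_scores(m, list(top = "G3", pair = c("G1", "G2")))
  expect_equal(cs$scores["C1", "top"], 3 - 2)
  expect_equal(cs$scores["C1", "pair"], 1.5 - 2)
  expect_equal(cs$scores["C2", "pair"], 0.5 - 1)
})

test_that("the all-detected-genes set scores exactly zero in every cell", {
  sc <- simulate_single_cell(60, list(list(name = "p", genes = sprintf("P%02d", 1:10),
                                           effect = 1)),
                             dropout = 0.4, seed = 3)
  cs <- cell_scores(sc$expression, list(all = rownames(sc$expression)))
  detected <- rownames(sc$expression)[rowSums(sc$expression != 0) > 0]
  cs2 <- cell_scores(sc$expression, list(all_detected = detected))
  expect_true(all(cs$scores[, "all"] == cs2$scores[, "all_detected"]))
  expect_equal(max(abs(cs$scores[, "all"])), 0)
})

test_that("scores are invariant to adding a constant to a cell", {
  m <- cells_fixture()
  m[m == 0] <- 0.5  # keep the detected universe fixed
  cs1 <- cell_scores(m, list(s = c("G1", "G3")))
  m2 <- m; m2[, "C2"] <- m2[, "C2"] + 7
  cs2 <- cell_scores(m2, list(s = c("G1", "G3")))
  expect_equal(cs1$scores["C2", "s"], cs2$scores["C2", "s"])
})

test_that("undetected sets are flagged missing, empty sets rejected", {
  m <- cells_fixture()
  withr::local_options(pathstrat.log_level = "error")
  cs <- cell_scores(m, list(ok = "G1", gone = c("ZZ1", "ZZ2")))
  expect_true(all(is.na(cs$scores[, "gone"])))
  expect_error(cell_scores(m, list(bad = character(0))), "empty gene set")
})

test_that("null scores center near zero without planted effect", {
  sc <- simulate_single_cell(300, list(list(name = "null", genes = sprintf("P%02d", 1:25),
                                            effect = 0)),
                             dropout = 0, seed = 9)
  cs <- cell_scores(sc$expression, list(p = sc$truth$programs$null))
  se <- sd(cs$scores[, "p"]) / sqrt(nrow(cs$scores))
  expect_lt(abs(mean(cs$scores[, "p"])), 3 * se)
})

test_that("a planted program separates its cells with high AUC", {
  g <- sprintf("CYC%02d", 1:40)
  sc <- simulate_single_cell(400, list(list(name = "cycling", genes = g, effect = 2),
                                       list(name = "rest",
                                            genes = sprintf("R%02d", 1:40),
                                            effect = 0)),
                             dropout = 0.3, seed = 15)
  cs <- cell_scores(sc$expression, list(cycling = g))
  pos <- cs$scores[sc$truth$state == "cycling", "cycling"]
  neg <- cs$scores[sc$truth$state != "cycling", "cycling"]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gte(auc, 0.9)
})

test_that("correlation maps are symmetric with BH-dominated adjusted p", {
  g1 <- sprintf("A%02d", 1:30); g2 <- sprintf("B%02d", 1:30)
  sc <- suppressWarnings(
    simulate_single_cell(250, list(list(name = "up", genes = g1, effect = 2),
                                   list(name = "down", genes = g1, effect = -2),
                                   list(name = "other", genes = g2, effect = 1)),
                         dropout = 0.2, seed = 21))
  cs <- cell_scores(sc$expression, list(sig1 = g1, sig2 = g2,
                                        sig3 = sample(rownames(sc$expression), 30)))
  cm <- correlation_map(cs, n_groups = 2)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  idx <- upper.tri(cm$p_raw)
  expect_true(all(cm$p_adj[idx] >= cm$p_raw[idx]))
  expect_true(all(abs(cm$r[idx]) <= 1))
})

test_that("antithetic states correlate negatively and significantly", {
  g1 <- sprintf("A%02d", 1:30); g2 <- sprintf("B%02d", 1:30)
  sc <- simulate_single_cell(250,
                             list(list(name = "s1", genes = g1, effect = 2),
                                  list(name = "s2", genes = g2, effect = 2)),
                             dropout = 0.2, seed = 33)
  cs <- cell_scores(sc$expression, list(sig1 = g1, sig2 = g2))
  cm <- correlation_map(cs, n_groups = 2)
  expect_lt(cm$r["sig1", "sig2"], 0)
  expect_true(cm$sig_adj["sig1", "sig2"])
})

test_that("with exactly one pair, adjusted p equals raw p, matching cor.test", {
  scores <- withr::with_seed(4,
    matrix(rnorm(40), 20, 2,
           dimnames = list(sprintf("C%02d", 1:20), c("s1", "s2"))))
  cm <- correlation_map(scores, n_groups = 2)
  expect_equal(cm$p_adj["s1", "s2"], cm$p_raw["s1", "s2"])
  ct <- stats::cor.test(scores[, 1], scores[, 2])
  expect_equal(cm$r["s1", "s2"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p_raw["s1", "s2"], ct$p.value, tolerance = 1e-12)
})

test_that("the correlation map is invariant to cell ordering", {
  sc <- simulate_single_cell(120, list(list(name = "p", genes = sprintf("P%02d", 1:20),
                                            effect = 1.5)),
                             dropout = 0.1, seed = 41)
  cs <- cell_scores(sc$expression, list(p = sprintf("P%02d", 1:20),
                                        bg = sprintf("BG%05d", 1:40)))
  cm1 <- correlation_map(cs)
  perm <- withr::with_seed(6, sample(nrow(cs$scores)))
  cm2 <- correlation_map(cs$scores[perm, ])
  expect_equal(cm2$r, cm1$r, tolerance = 1e-12)
  expect_equal(cm2$p_raw, cm1$p_raw, tolerance = 1e-12)
})

test_that("zero-variance score vectors leave their pairs undefined", {
  scores <- cbind(flat = rep(1, 10),
                  ok1 = withr::with_seed(2, rnorm(10)),
                  ok2 = withr::with_seed(3, rnorm(10)))
  rownames(scores) <- sprintf("C%02d", 1:10)
  withr::local_options(pathstrat.log_level = "error")
  cm <- correlation_map(scores, n_groups = 2)
  expect_true(is.na(cm$r["flat", "ok1"]))
  expect_true(is.na(cm$p_raw["flat", "ok2"]))
  expect_false(is.na(cm$r["ok1", "ok2"]))
})
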