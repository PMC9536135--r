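# Independent brute-force oracles used to verify the implementation paths.

# Literal position-by-position running sum, kept free of the package's
# cumsum / hit-position shortcuts.
es_oracle <- function(genes, stat, set, weight) {
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  w <- abs(stat)^weight
  sumw <- sum(w[hit])
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + if (sumw > 0) w[i] / sumw else 1 / nh
    } else {
      cur <- cur - 1 / (N - nh)
    }
    run[i] <- cur
  }
  es <- if (max(run) + min(run) >= -1e-12) max(run) else min(run)
  attr(es, "tied") <- abs(max(run) + min(run)) < 1e-9
  es
}

# Exhaustive hypergeometric upper tail by pmf summation.
hyper_oracle <- function(overlap, term_size, query_size, universe_size) {
  j <- overlap:min(term_size, query_size)
  sum(choose(term_size, j) * choose(universe_size - term_size, query_size - j)) /
    choose(universe_size, query_size)
}

# Tiny labeled expression matrix used across io/enrichment tests.
toy_matrix <- function() {
  m <- matrix(c(2, 0, 1,
                0, 2, 1,
                5, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), c("S1", "S2", "S3")))
  m
}

random_survival_table <- function(n, hazard = 0.1, censor = 0.3, group = NULL) {
  t_ev <- rexp(n, hazard)
  cens <- runif(n) < censor
  tibble::tibble(sample = sprintf("P%03d", seq_len(n)),
                 time = ifelse(cens, runif(n, 0, t_ev), t_ev),
                 event = as.integer(!cens),
                 group = group %||% rep(1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
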