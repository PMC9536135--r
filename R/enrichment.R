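# Preranked GSEA against the cohort mean.
#
# The ranking statistic for sample s is expr(g, s) minus the cohort mean of
# gene g (the scored sample included in the mean). The enrichment score is
# the signed maximum deviation of the weighted Kolmogorov-Smirnov running
# sum; NES divides ES by the mean magnitude of same-sign gene-label
# permutation nulls.

#' Rank one sample's genes against the cohort mean
#'
#' The per-gene statistic is the sample's log2 expression minus the mean
#' over all samples (the scored sample included). Genes are ordered by
#' statistic, descending; ties break by ascending gene symbol so the order
#' is reproducible.
#'
#' @param matrix Expression matrix (genes x samples), see
#'   [as_expression_matrix()].
#' @param sample Column identifier of the sample to rank.
#' @return A `ranked_list`: list with `sample`, `genes` (best to worst) and
#'   `stat` (non-increasing).
#' @export
rank_vs_cohort_mean <- function(matrix, sample) {
  matrix <- as_expression_matrix(matrix)
  if (!sample %in% colnames(matrix)) stop("sample not in matrix: ", sample)
  stat <- matrix[, sample] - rowMeans(matrix)
  ord <- order(-stat, names(stat), method = "radix")
  structure(list(sample = sample, genes = names(stat)[ord],
                 stat = unname(stat[ord])),
            class = "ranked_list")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: genes in the set add `|stat|^weight` (normalized
#' over in-set genes), genes outside subtract `1/(N - N_hit)`. The ES is the
#' running sum's maximum-magnitude deviation from zero, signed; when the
#' positive peak and negative trough tie in magnitude the positive side
#' wins (the usual GSEA convention). With `weight = 0` every hit
#' counts equally (the classic KS statistic); `weight = 1` is the GSEA
#' default. If every in-set `|stat|` is zero the hits fall back to equal
#' weights.
#'
#' @param ranked A `ranked_list` from [rank_vs_cohort_mean()].
#' @param gene_set Character vector of gene symbols.
#' @param weight Non-negative exponent on `|stat|`.
#' @return List with `es`, `running_sum` (length N) and `hits` (positions);
#'   `es` is `NA` (and `unscored = TRUE`) when the set has no gene in the
#'   ranked list.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"), weight >= 0)
  genes <- ranked$genes
  N <- length(genes)
  hit <- genes %in% toupper(gene_set)
  m <- sum(hit)
  if (m == 0L) {
    return(list(es = NA_real_, running_sum = rep(NA_real_, N),
                hits = integer(0), unscored = TRUE))
  }
  w <- abs(ranked$stat)^weight
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { w[hit] <- 1; tot <- m }
  inc <- w / tot
  dec <- if (N > m) 1 / (N - m) else 0
  running <- cumsum(ifelse(hit, inc, -dec))
  mx <- max(running); mn <- min(running)
  es <- if (mx + mn >= -1e-12) mx else mn  # ties resolve positive
  list(es = es, running_sum = running, hits = which(hit), unscored = FALSE)
}

# ES from sorted hit positions only: O(m) instead of O(N). The running
# sum's positive peaks sit at hit positions and its troughs just before
# hits (or at the final position, where it returns to exactly 0), so the
# signed extremum is recoverable from the hit candidates alone — tested
# against the full running sum.
es_from_hits <- function(pos, w, N) {
  m <- length(pos)
  if (m == 0L) return(NA_real_)
  if (m == N) return(1)
  tot <- sum(w)
  if (tot == 0) { w <- rep(1, m); tot <- m }
  ch <- cumsum(w) / tot
  d <- (pos - seq_len(m)) / (N - m)
  up <- ch - d                        # value at each hit position
  down <- (c(0, ch[-m]) - d)[pos > 1] # value just before each hit
  mx <- max(up)
  mn <- if (length(down)) min(down, 0) else 0
  if (mx + mn >= -1e-12) mx else mn  # same tie rule as the full running sum
}

#' Permutation-normalized enrichment profile
#'
#' Scores every sample x gene set pair: each sample is ranked against the
#' cohort mean, the ES computed, and normalized against a gene-label
#' permutation null (random sets of the same size redrawn from the ranked
#' genes, `n_perm` times). `nes = es / mean(|null es of matching sign|)`;
#' the two-sided empirical p-value is `(1 + #{|null| >= |es|}) / (n_perm + 1)`.
#' Sets with no gene in the matrix are left `NA`. Deterministic given
#' `seed`.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param collection A `gene_set_collection`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param weight ES weight exponent (default 1).
#' @return An `enrichment_profile`: matrices `nes`, `es`, `p` (samples x
#'   sets) plus `n_perm`, `weight`, `seed`.
#' @export
normalize_es <- function(matrix, collection, n_perm = 1000, seed = 1, weight = 1) {
  matrix <- as_expression_matrix(matrix)
  stopifnot(inherits(collection, "gene_set_collection"), n_perm >= 100)
  samples <- colnames(matrix)
  set_names <- names(collection$sets)
  es <- nes <- p <- array(NA_real_, dim = c(length(samples), length(set_names)),
                          dimnames = list(samples, set_names))
  cohort_mean <- rowMeans(matrix)
  with_seed(seed, {
    for (s in samples) {
      stat <- matrix[, s] - cohort_mean
      ord <- order(-stat, names(stat), method = "radix")
      stat_s <- unname(stat[ord])
      pos_of <- setNames(seq_along(ord), names(stat)[ord])
      N <- length(stat_s)
      wvec <- abs(stat_s)^weight

      hit_pos <- lapply(collection$sets, function(g) {
        sort(unname(pos_of[g[g %in% names(pos_of)]]))
      })
      sizes <- lengths(hit_pos)
      obs <- vapply(hit_pos, function(hp) es_from_hits(hp, wvec[hp], N),
                    numeric(1))
      es[s, ] <- obs
      for (m in sort(unique(sizes[sizes > 0]))) {
        null_es <- vapply(seq_len(n_perm), function(i) {
          hp <- sort(sample.int(N, m))
          es_from_hits(hp, wvec[hp], N)
        }, numeric(1))
        pos_null <- null_es[null_es > 0]
        neg_null <- null_es[null_es < 0]
        for (j in which(sizes == m)) {
          e <- obs[[j]]
          denom <- if (e >= 0) mean(abs(pos_null)) else mean(abs(neg_null))
          if (!is.finite(denom) || denom == 0) {
            warning(sprintf("no matching-sign null for set '%s' in sample '%s'",
                            set_names[[j]], s))
            nes[s, j] <- NA_real_
          } else {
            nes[s, j] <- e / denom
          }
          p[s, j] <- (1 + sum(abs(null_es) >= abs(e))) / (n_perm + 1)
        }
      }
    }
  })
  unscored <- colSums(!is.na(es)) == 0
  if (any(unscored)) {
    ps_log("warn", "unscored gene set(s) with no overlap: ",
           paste(set_names[unscored], collapse = ", "))
  }
  structure(list(nes = nes, es = es, p = p, n_perm = as.integer(n_perm),
                 weight = weight, seed = as.integer(seed)),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("<enrichment_profile> %d samples x %d gene sets (n_perm = %d, weight = %g)\n",
              nrow(x$nes), ncol(x$nes), x$n_perm, x$weight))
  invisible(x)
}

#' Complete-NES submatrix of a profile
#'
#' Drops gene-set columns containing any missing NES and returns the plain
#' samples x sets matrix most downstream steps consume.
#'
#' @param profile An `enrichment_profile`.
#' @return Numeric matrix.
#' @export
profile_matrix <- function(profile) {
  stopifnot(inherits(profile, "enrichment_profile"))
  keep <- colSums(is.na(profile$nes)) == 0
  if (!all(keep)) {
    ps_log("info", "dropping ", sum(!keep), " gene set(s) with missing NES")
  }
  profile$nes[, keep, drop = FALSE]
}
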