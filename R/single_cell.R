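# Per-cell signature scoring and the signature-signature correlation map.

# Accept a gene_set_collection, a list of gene_signature objects, or a named
# list of character vectors.
as_set_list <- function(sets) {
  if (inherits(sets, "gene_set_collection")) return(sets$sets)
  if (inherits(sets, "gene_signature")) sets <- list(sets)
  if (all(vapply(sets, inherits, logical(1), "gene_signature"))) {
    out <- lapply(sets, `[[`, "genes")
    names(out) <- vapply(sets, `[[`, character(1), "name")
    return(out)
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  lapply(sets, toupper)
}

#' Per-cell signature scores
#'
#' The score of a gene set in a cell is the mean log expression of the
#' set's detected genes minus the mean log expression of all detected
#' genes, in that cell. "Detected" defaults to dataset-wide: genes with
#' nonzero expression in at least one cell; `detection = "cell"` instead
#' uses each cell's own nonzero genes. By construction the set of all
#' detected genes scores exactly 0 in every cell.
#'
#' @param matrix Expression matrix (genes x cells, log scale).
#' @param sets A `gene_set_collection`, list of `gene_signature`s, or named
#'   list of gene vectors; all nonempty.
#' @param detection `"dataset"` (default) or `"cell"`.
#' @return A `cell_score_matrix`: `scores` (cells x sets; sets with no
#'   detected gene are `NA`), `detected_genes`, `detection`.
#' @export
cell_scores <- function(matrix, sets, detection = c("dataset", "cell")) {
  detection <- match.arg(detection)
  matrix <- as_expression_matrix(matrix, what = "single_cell")
  sets <- as_set_list(sets)
  if (any(!lengths(sets))) stop("empty gene set(s): ",
                                paste(names(sets)[!lengths(sets)], collapse = ", "))
  detected <- rownames(matrix)[rowSums(matrix != 0) > 0]
  cells <- colnames(matrix)
  scores <- array(NA_real_, dim = c(length(cells), length(sets)),
                  dimnames = list(cells, names(sets)))
  if (detection == "dataset") {
    bg <- colMeans(matrix[detected, , drop = FALSE])
    for (j in seq_along(sets)) {
      g <- intersect(sets[[j]], detected)
      if (!length(g)) next
      scores[, j] <- colMeans(matrix[g, , drop = FALSE]) - bg
    }
  } else {
    det_cell <- matrix != 0
    bg <- colSums(matrix * det_cell) / pmax(colSums(det_cell), 1)
    for (j in seq_along(sets)) {
      g <- intersect(sets[[j]], rownames(matrix))
      if (!length(g)) next
      sub <- matrix[g, , drop = FALSE]; d <- det_cell[g, , drop = FALSE]
      n_det <- colSums(d)
      sc <- colSums(sub * d) / pmax(n_det, 1) - bg
      sc[n_det == 0] <- NA_real_
      scores[, j] <- sc
    }
  }
  missing_sets <- colnames(scores)[colSums(!is.na(scores)) == 0]
  if (length(missing_sets)) {
    ps_log("warn", "set(s) with no detected gene: ",
           paste(missing_sets, collapse = ", "))
  }
  structure(list(scores = scores, detected_genes = detected,
                 detection = detection),
            class = "cell_score_matrix")
}

#' @export
print.cell_score_matrix <- function(x, ...) {
  cat(sprintf("<cell_score_matrix> %d cells x %d sets (%d detected genes, %s detection)\n",
              nrow(x$scores), ncol(x$scores), length(x$detected_genes),
              x$detection))
  invisible(x)
}

#' Signature-signature correlation map across cells
#'
#' Pairwise Pearson correlations of per-cell scores with two-sided
#' p-values, Benjamini-Hochberg adjusted over all unordered pairs (the
#' "dual diagonal" display shows raw p below and adjusted p above the
#' diagonal). Signatures are grouped by average-linkage hierarchical
#' clustering of `1 - r`.
#'
#' @param scores A `cell_score_matrix` (or plain cells x signatures matrix).
#' @param alpha Significance level recorded for both raw and adjusted p.
#' @param n_groups Number of hierarchical groups to cut.
#' @return A `correlation_map`: symmetric `r`, `p_raw`, `p_adj` (diagonal
#'   `NA`), logical `sig_raw`/`sig_adj`, `groups`, `alpha`. Pairs involving
#'   a zero-variance or all-`NA` score vector are left `NA`.
#' @export
correlation_map <- function(scores, alpha = 0.05, n_groups = 3) {
  x <- if (inherits(scores, "cell_score_matrix")) scores$scores else as.matrix(scores)
  stopifnot(nrow(x) >= 3, ncol(x) >= 2)
  m <- ncol(x)
  ok <- apply(x, 2, function(v) sum(!is.na(v)) >= 3 && sd(v, na.rm = TRUE) > 0)
  if (!all(ok)) {
    ps_log("warn", "zero-variance or missing score vector(s): ",
           paste(colnames(x)[!ok], collapse = ", "))
  }
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[!ok, ] <- NA; r[, !ok] <- NA
  diag(r)[ok] <- 1
  p_raw <- array(NA_real_, dim = c(m, m), dimnames = dimnames(r))
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!ok[a] || !ok[b]) next
    cc <- stats::complete.cases(x[, a], x[, b])
    n <- sum(cc)
    if (n < 3) next
    rr <- r[a, b]
    tt <- rr * sqrt((n - 2) / max(1 - rr^2, .Machine$double.eps))
    p_raw[a, b] <- p_raw[b, a] <- 2 * pt(-abs(tt), df = n - 2)
  }
  up <- upper.tri(p_raw)
  p_adj <- p_raw
  p_adj[up] <- p.adjust(p_raw[up], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- hclust(stats::as.dist(d), method = "average")
  groups <- cutree(hc, k = min(n_groups, m))
  structure(list(r = r, p_raw = p_raw, p_adj = p_adj,
                 sig_raw = p_raw < alpha, sig_adj = p_adj < alpha,
                 groups = groups, alpha = alpha, hclust = hc),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d signatures, %d groups, alpha = %g\n",
              ncol(x$r), length(unique(x$groups)), x$alpha))
  invisible(x)
}
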