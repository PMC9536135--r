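# Differential expression between clusters, hypergeometric
# overrepresentation analysis, and a transparent upstream-regulator
# stand-in (overlap enrichment + sign concordance; it makes no claim of
# reproducing IPA's curated knowledge base or z-scores).

#' Differential expression of one cluster versus the rest
#'
#' Per-gene Welch two-sample t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) of the cluster's samples against
#' all others, Benjamini-Hochberg adjusted across genes. `log_fc` is the
#' mean log2 difference (cluster minus rest). Genes with zero variance in
#' both groups get `p = 1` when the means agree; with differing means the
#' p-value is set to the smallest representable double and flagged.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param labels Cluster labels (named by sample or positional).
#' @param cluster The cluster to contrast (>= 2 samples on both sides).
#' @return Tibble with `gene`, `log_fc`, `t`, `df`, `p`, `p_adj`,
#'   `degenerate`.
#' @export
differential_expression <- function(matrix, labels, cluster) {
  matrix <- as_expression_matrix(matrix)
  labels <- resolve_labels(labels, colnames(matrix))
  in_cl <- labels == cluster
  if (sum(in_cl) < 2 || sum(!in_cl) < 2) {
    stop("cluster and complement each need >= 2 samples")
  }
  x1 <- matrix[, in_cl, drop = FALSE]; x2 <- matrix[, !in_cl, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df = df)
  degenerate <- se2 == 0
  tstat[degenerate] <- 0
  df[degenerate] <- n1 + n2 - 2
  p[degenerate & m1 == m2] <- 1
  zero_var_diff <- degenerate & m1 != m2
  p[zero_var_diff] <- .Machine$double.xmin
  if (any(zero_var_diff)) {
    warning(sum(zero_var_diff),
            " gene(s) with zero variance but unequal means; p floored")
  }
  res <- tibble::tibble(gene = rownames(matrix), log_fc = unname(m1 - m2),
                        t = unname(tstat), df = unname(df), p = unname(p),
                        degenerate = unname(degenerate))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res[order(res$p, res$gene), c("gene", "log_fc", "t", "df", "p", "p_adj",
                                "degenerate")]
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test `P[X >= overlap]` of each term against the
#' query within the universe, Benjamini-Hochberg adjusted across terms.
#' Query genes outside the universe are dropped with a warning; term genes
#' outside the universe are ignored.
#'
#' @param query Character vector of gene symbols.
#' @param terms A `gene_set_collection` (or named list of gene vectors).
#' @param universe Character vector of background gene symbols.
#' @return Tibble with `term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p`, `p_adj`, ordered by `p`.
#' @export
ora <- function(query, terms, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  sets <- as_set_list(terms)
  u <- length(universe); q <- length(query)
  res <- purrr::map_dfr(names(sets), function(nm) {
    tg <- intersect(sets[[nm]], universe)
    ov <- length(intersect(tg, query))
    tibble::tibble(term = nm, overlap = ov, term_size = length(tg),
                   query_size = q, universe_size = u,
                   p = phyper(ov - 1, length(tg), u - length(tg), q,
                              lower.tail = FALSE))
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res[order(res$p, res$term), ]
}

# Regulons may carry per-target signs encoded as trailing "+"/"-" on the
# symbol (e.g. "TP53+"). Returns list(genes, signs) with signs NULL when
# the regulon is unsigned.
parse_signed_regulon <- function(genes) {
  has_sign <- grepl("[+-]$", genes)
  if (!all(has_sign)) return(list(genes = toupper(genes), signs = NULL))
  list(genes = toupper(sub("[+-]$", "", genes)),
       signs = ifelse(grepl("\\+$", genes), 1L, -1L))
}

#' Upstream-regulator calls for a gene signature
#'
#' For every regulon (a regulator's known target set, optionally signed),
#' tests overlap enrichment of its targets in the signature by [ora()].
#' When targets carry `+`/`-` signs, a direction score
#' `(concordant - discordant) / sqrt(overlapping targets)` measures
#' agreement between the target signs and the signature's direction;
#' regulators are called `activated` (score >= 2), `inhibited`
#' (score <= -2) when also `p_adj < 0.05`, otherwise `undetermined`.
#' Unsigned regulons are always `undetermined` in direction. This is a
#' documented stand-in for curated upstream-regulator tools, driven purely
#' by the user-supplied regulons.
#'
#' @param signature A `gene_signature` (or character vector; then treated
#'   as direction-positive).
#' @param regulons A `gene_set_collection`; target signs optional, encoded
#'   as trailing `+`/`-` on the symbol.
#' @param universe Background gene symbols.
#' @param score_min Direction-score threshold for a directional call.
#' @param alpha Adjusted-p threshold for a directional call.
#' @return Tibble with `regulator`, `overlap`, `p`, `p_adj`,
#'   `direction_score`, `call`, ordered by `p`.
#' @export
upstream_regulators <- function(signature, regulons, universe,
                                score_min = 2, alpha = 0.05) {
  if (inherits(signature, "gene_signature")) {
    sig_genes <- signature$genes
    sig_sign <- if (signature$direction == "positive") 1L else -1L
  } else {
    sig_genes <- toupper(signature)
    sig_sign <- 1L
  }
  parsed <- lapply(as_set_list(regulons), parse_signed_regulon)
  plain <- lapply(parsed, `[[`, "genes")
  enr <- ora(sig_genes, plain, universe)
  scores <- vapply(names(parsed), function(nm) {
    pr <- parsed[[nm]]
    if (is.null(pr$signs)) return(NA_real_)
    hit <- pr$genes %in% sig_genes
    if (!any(hit)) return(0)
    conc <- sum(pr$signs[hit] == sig_sign)
    disc <- sum(hit) - conc
    (conc - disc) / sqrt(sum(hit))
  }, numeric(1))
  enr$direction_score <- unname(scores[enr$term])
  enr$call <- dplyr::case_when(
    is.na(enr$direction_score) ~ "undetermined",
    enr$p_adj < alpha & enr$direction_score >= score_min ~ "activated",
    enr$p_adj < alpha & enr$direction_score <= -score_min ~ "inhibited",
    TRUE ~ "undetermined")
  names(enr)[names(enr) == "term"] <- "regulator"
  enr[, c("regulator", "overlap", "term_size", "p", "p_adj",
          "direction_score", "call")]
}
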