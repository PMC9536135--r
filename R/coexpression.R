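# Weighted coexpression modules: soft-threshold adjacency, topological
# overlap, average-linkage tree with a static cut, module eigengenes and
# kME-ranked hub genes. A deliberately compact, deterministic variant of
# the WGCNA workflow (static rather than dynamic tree cut, unsigned
# network).

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3 || diff(range(k)) < 1e-8) {
    return(list(r2 = 0, slope = 0))
  }
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- as.numeric(table(cuts)) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  list(r2 = summary(fit)$r.squared, slope = coef(fit)[[2]])
}

#' Detect coexpression modules
#'
#' Builds an unsigned weighted network: adjacency `|cor|^beta` with `beta`
#' auto-selected as the smallest power in 1..20 whose connectivity
#' distribution fits a scale-free law at R-squared >= 0.8 (otherwise the
#' best-fitting power, preferring negative slopes). Genes are clustered by
#' average linkage on `1 - TOM` (topological overlap) with a static cut at
#' height `cut_height`; branches smaller than `min_module_size` stay
#' unassigned (module 0). Modules are labeled 1, 2, ... by decreasing size.
#' Each module's eigengene is the first principal component of its
#' standardized expression, unit length, sign-fixed to correlate positively
#' with the module's mean expression.
#'
#' @param matrix Expression matrix (genes x samples, >= 8 samples).
#' @param power Soft-threshold exponent; `NULL` (default) auto-selects.
#' @param min_module_size Smallest retained module.
#' @param cut_height Static tree-cut height on the 1 - TOM dendrogram.
#' @return A `module_set`: `power`, `scale_free_r2`, `assignments` (gene ->
#'   module id, 0 = unassigned), `eigengenes` (samples x modules), `kme`
#'   (genes x modules), `tom` (gene x gene topological overlap).
#' @export
detect_modules <- function(matrix, power = NULL, min_module_size = 10,
                           cut_height = 0.99) {
  matrix <- as_expression_matrix(matrix)
  if (ncol(matrix) < 8) stop("need >= 8 samples")
  sds <- apply(matrix, 1, sd)
  if (any(sds == 0)) {
    warning("dropping constant gene(s): ",
            paste(head(rownames(matrix)[sds == 0], 5), collapse = ", "))
    matrix <- matrix[sds > 0, , drop = FALSE]
  }
  if (nrow(matrix) < 2 * min_module_size) stop("too few variable genes")
  x <- t(matrix)                               # samples x genes
  ac <- abs(cor(x))
  diag(ac) <- 0
  if (is.null(power)) {
    ks <- lapply(1:20, function(b) rowSums(ac^b))
    fits <- lapply(ks, scale_free_fit)
    r2 <- vapply(fits, function(f) f$r2 * (f$slope < 0), numeric(1))
    # powers that collapse mean connectivity below 1 give degenerate,
    # fragmenting networks regardless of their apparent scale-free fit
    eligible <- vapply(ks, mean, numeric(1)) >= 1
    if (!any(eligible)) eligible <- rep(TRUE, 20)
    hit <- which(eligible & r2 >= 0.8)
    power <- if (length(hit)) hit[[1]] else which(eligible)[which.max(r2[eligible])]
  }
  adj <- ac^power
  k <- rowSums(adj)
  l <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  sf <- scale_free_fit(k)

  hc <- hclust(stats::as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  assignments <- rep(0L, nrow(matrix))
  names(assignments) <- rownames(matrix)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) assignments[raw == as.integer(ord[[i]])] <- i
  }
  modules <- sort(unique(assignments[assignments > 0]))
  eig <- array(NA_real_, dim = c(ncol(matrix), length(modules)),
               dimnames = list(colnames(matrix), paste0("M", modules)))
  for (m in modules) {
    g <- names(assignments)[assignments == m]
    xm <- scale(t(matrix[g, , drop = FALSE]))
    pc <- prcomp(xm, center = FALSE, scale. = FALSE)$x[, 1]
    pc <- pc / sqrt(sum(pc^2))
    if (cor(pc, colMeans(matrix[g, , drop = FALSE])) < 0) pc <- -pc
    eig[, paste0("M", m)] <- pc
  }
  kme <- if (length(modules)) cor(t(matrix), eig) else
    array(0, dim = c(nrow(matrix), 0))
  structure(list(power = power, scale_free_r2 = sf$r2,
                 assignments = assignments, eigengenes = eig, kme = kme,
                 tom = tom),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- ncol(x$eigengenes)
  cat(sprintf("<module_set> %d modules over %d genes (power = %d, scale-free R2 = %.2f)\n",
              n_mod, length(x$assignments), x$power, x$scale_free_r2))
  if (n_mod) {
    tab <- table(x$assignments[x$assignments > 0])
    cat("  sizes:", paste(tab, collapse = ", "),
        "| unassigned:", sum(x$assignments == 0), "\n")
  }
  invisible(x)
}

#' Associate modules with sample clusters
#'
#' Correlates each module eigengene with each cluster's indicator vector
#' (point-biserial correlation); a module is assigned to the cluster with
#' the largest correlation. Two-sided p-values are BH-adjusted across
#' modules.
#'
#' @param modules A `module_set`.
#' @param labels Cluster labels, named by sample or in eigengene row order.
#' @return Tibble with `module`, `cluster`, `r`, `p`, `p_adj`.
#' @export
module_cluster_association <- function(modules, labels) {
  stopifnot(inherits(modules, "module_set"))
  eig <- modules$eigengenes
  if (!ncol(eig)) stop("no modules detected")
  labels <- resolve_labels(labels, rownames(eig))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  n <- nrow(eig)
  res <- purrr::map_dfr(colnames(eig), function(m) {
    rs <- vapply(clusters, function(cl) cor(eig[, m], as.numeric(labels == cl)),
                 numeric(1))
    best <- which.max(rs)
    r <- rs[[best]]
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble::tibble(module = m, cluster = clusters[[best]], r = r,
                   p = 2 * pt(-abs(tt), df = n - 2))
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}

#' Hub genes per module
#'
#' Ranks each module's member genes by their kME (correlation with the
#' module eigengene), keeps those at or above `kme_min`, and truncates to
#' the `top_k` strongest; ties break by gene symbol.
#'
#' @param modules A `module_set`.
#' @param top_k Hubs reported per module.
#' @param kme_min Minimum kME.
#' @return Tibble with `module`, `gene`, `kme`, `rank`; empty (zero-row)
#'   lists are allowed.
#' @export
hub_genes <- function(modules, top_k = 10, kme_min = 0.8) {
  stopifnot(inherits(modules, "module_set"))
  purrr::map_dfr(colnames(modules$eigengenes), function(m) {
    id <- as.integer(sub("^M", "", m))
    genes <- names(modules$assignments)[modules$assignments == id]
    km <- modules$kme[genes, m]
    keep <- genes[km >= kme_min]
    if (!length(keep)) return(tibble::tibble())
    # round away sub-1e-10 kME noise so exact-tie ranking is lexicographic
    ord <- keep[order(-round(km[keep], 10), keep, method = "radix")]
    ord <- head(ord, top_k)
    tibble::tibble(module = m, gene = ord, kme = unname(km[ord]),
                   rank = seq_along(ord))
  })
}
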