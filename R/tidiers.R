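# broom-style accessors: tidy() returns the per-unit table, glance() the
# one-row model summary.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn normalize_es Long tibble of sample x gene-set scores
#'   (`sample`, `gene_set`, `es`, `nes`, `p`).
#' @param x The fitted object.
#' @export
tidy.enrichment_profile <- function(x, ...) {
  tibble::as_tibble(as.table(x$nes), .name_repair = "minimal") |>
    stats::setNames(c("sample", "gene_set", "nes")) |>
    dplyr::mutate(es = as.vector(x$es), p = as.vector(x$p)) |>
    dplyr::select("sample", "gene_set", "es", "nes", "p")
}

#' @describeIn normalize_es One-row summary.
#' @export
glance.enrichment_profile <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$nes), n_gene_sets = ncol(x$nes),
                 n_perm = x$n_perm, weight = x$weight, seed = x$seed,
                 prop_missing = mean(is.na(x$nes)))
}

#' @describeIn pca_decompose Long tibble of loadings and contributions per
#'   gene set and component.
#' @param x The fitted object.
#' @export
tidy.pca_result <- function(x, ...) {
  comps <- seq_len(ncol(x$loadings))
  purrr::map_dfr(comps, function(k) {
    tibble::tibble(gene_set = rownames(x$loadings), component = k,
                   loading = x$loadings[, k],
                   contribution = x$contributions[, k],
                   direction = ifelse(x$loadings[, k] >= 0, "positive", "negative"))
  })
}

#' @describeIn pca_decompose One row per component with explained variance.
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(component = seq_len(ncol(x$scores)),
                 explained_variance_ratio =
                   x$explained_variance_ratio[seq_len(ncol(x$scores))])
}

#' @describeIn synthesize_signature Tibble of signature genes with
#'   source-set membership counts.
#' @param x The fitted object.
#' @param ... Unused, for generic consistency.
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble::tibble(signature = x$name, gene = x$genes,
                 membership_count = unname(x$membership_counts[x$genes]))
}

#' @describeIn consensus_cluster Tibble of sample labels at the chosen k.
#' @param x The fitted object.
#' @export
tidy.consensus_result <- function(x, ...) {
  tibble::tibble(sample = names(x$labels), cluster = unname(x$labels))
}

#' @describeIn consensus_cluster One-row summary (chosen k, PAC).
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, pac_min = min(x$pac),
                 n_resamples = x$n_resamples, subsample = x$subsample,
                 seed = x$seed)
}

#' @describeIn km_curve The step-function table.
#' @param x The fitted object.
#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @describeIn km_curve One-row summary (n, events, median).
#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(n = x$n, events = sum(x$steps$n_event), median = x$median)
}

#' @describeIn logrank_test Per-group observed/expected events.
#' @param x The fitted object.
#' @param ... Unused, for generic consistency.
#' @export
tidy.logrank_result <- function(x, ...) x$table

#' @describeIn logrank_test One-row test summary.
#' @export
glance.logrank_result <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df, p = x$p)
}

#' @describeIn lda_frequency One-row estimate with CI.
#' @param x The fitted object.
#' @export
glance.lda_result <- function(x, ...) {
  tibble::tibble(frequency = x$frequency, one_in = x$one_in,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 boundary = x$boundary)
}

#' @describeIn lda_frequency Per-dose negative-well fractions.
#' @export
tidy.lda_result <- function(x, ...) {
  dplyr::mutate(x$data, fraction_negative = .data$negatives / .data$wells)
}

#' @describeIn detect_modules Tibble of gene assignments with kME to the
#'   own module.
#' @param x The fitted object.
#' @export
tidy.module_set <- function(x, ...) {
  own_kme <- vapply(seq_along(x$assignments), function(i) {
    m <- x$assignments[[i]]
    if (m == 0 || !ncol(x$kme)) NA_real_ else x$kme[i, paste0("M", m)]
  }, numeric(1))
  tibble::tibble(gene = names(x$assignments),
                 module = unname(x$assignments), kme = own_kme)
}

#' @describeIn detect_modules One-row network summary.
#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(n_modules = ncol(x$eigengenes), power = x$power,
                 scale_free_r2 = x$scale_free_r2,
                 n_unassigned = sum(x$assignments == 0))
}

#' @describeIn correlation_map Long tibble of unordered signature pairs.
#' @param x The fitted object.
#' @export
tidy.correlation_map <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(signature1 = rownames(x$r)[idx[, 1]],
                 signature2 = colnames(x$r)[idx[, 2]],
                 r = x$r[idx], p_raw = x$p_raw[idx], p_adj = x$p_adj[idx])
}

#' @describeIn cell_scores Long tibble of cell x set scores.
#' @param x The fitted object.
#' @param ... Unused, for generic consistency.
#' @export
tidy.cell_score_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$scores), .name_repair = "minimal") |>
    stats::setNames(c("cell", "signature", "score"))
}

#' @describeIn rf_robustness Per-cluster OOB accuracy.
#' @param x The fitted object.
#' @param ... Unused, for generic consistency.
#' @export
tidy.robustness_report <- function(x, ...) {
  tibble::tibble(cluster = names(x$per_cluster_accuracy),
                 accuracy = unname(x$per_cluster_accuracy))
}

#' @describeIn rf_robustness One-row summary.
#' @export
glance.robustness_report <- function(x, ...) {
  tibble::tibble(oob_accuracy = x$oob_accuracy, n_trees = x$n_trees)
}
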