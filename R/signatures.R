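# PCA of the enrichment profile and signature synthesis.
#
# Samples are observations and gene sets variables; the PCA runs on
# standardized variables (correlation PCA) because NES magnitudes vary with
# set size. A variable's "contribution" to a component is its squared
# loading as a percentage of the component's total; its "direction" is the
# sign of its loading. A signature collects the genes shared by at least
# `min_overlap` of the `top_n` contributing sets in one direction.

#' PCA of an enrichment profile with per-variable contributions
#'
#' Gene sets with missing NES are dropped (logged), as are constant
#' variables (warning). Variables are centered and scaled to unit variance.
#' Component signs are fixed deterministically: the variable with the
#' largest absolute loading gets a positive loading.
#'
#' @param profile An `enrichment_profile` (or plain samples x sets matrix).
#' @param n_components Number of components to keep.
#' @return A `pca_result`: `scores` (samples x components), `loadings`
#'   (sets x components), `explained_variance_ratio`, and `contributions`
#'   (sets x components, percentages summing to 100 per component).
#' @export
pca_decompose <- function(profile, n_components = 2) {
  x <- if (inherits(profile, "enrichment_profile")) profile_matrix(profile) else as.matrix(profile)
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  n_components <- min(n_components, ncol(x), nrow(x) - 1L)
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  load <- fit$rotation[, seq_len(n_components), drop = FALSE]
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    anchor <- which.max(abs(load[, k]))
    if (load[anchor, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  contrib <- sweep(load^2, 2, colSums(load^2), "/") * 100
  structure(list(scores = scores, loadings = load,
                 explained_variance_ratio = fit$sdev^2 / sum(fit$sdev^2),
                 contributions = contrib),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  evr <- x$explained_variance_ratio[seq_len(ncol(x$scores))]
  cat(sprintf("<pca_result> %d samples, %d variables, %d components (var: %s)\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * evr), collapse = ", ")))
  invisible(x)
}

#' Synthesize a directional gene signature from top-contributing gene sets
#'
#' Among gene sets whose loading sign on the chosen component matches
#' `direction`, the `top_n` by contribution are selected (ties by
#' contribution, then name); the signature comprises the genes present in
#' at least `min_overlap` of them. The name follows the convention
#' `<datasetCode><collectionCode>-<component><P|N>` — e.g. `"T2-1N"` for a
#' TCGA-derived (`T`) canonical-collection (`2`) signature on component 1,
#' negative direction.
#'
#' @param pca A `pca_result` over the collection's sets.
#' @param collection The `gene_set_collection` the profile was scored with.
#' @param component Component index.
#' @param direction `"positive"` or `"negative"` (loading sign).
#' @param dataset_code Short dataset code (e.g. `"T"`).
#' @param top_n Number of contributing sets to pool (default 20).
#' @param min_overlap Minimum number of source sets a gene must appear in
#'   (default 5).
#' @return A `gene_signature`: `name`, `genes`, `component`, `direction`,
#'   `source_sets`, and per-gene `membership_counts`.
#' @export
synthesize_signature <- function(pca, collection, component = 1,
                                 direction = c("positive", "negative"),
                                 dataset_code = "S", top_n = 20,
                                 min_overlap = 5) {
  direction <- match.arg(direction)
  stopifnot(inherits(pca, "pca_result"), component <= ncol(pca$loadings))
  load <- pca$loadings[, component]
  contrib <- pca$contributions[, component]
  want <- if (direction == "positive") load > 0 else load < 0
  cand <- names(load)[want]
  missing_sets <- setdiff(cand, names(collection$sets))
  if (length(missing_sets)) {
    stop("collection lacks set(s): ", paste(missing_sets, collapse = ", "))
  }
  if (!length(cand)) stop("no gene set loads in the requested direction")
  cand <- cand[order(-contrib[cand], cand, method = "radix")]
  if (length(cand) < top_n) {
    warning(sprintf("only %d set(s) load %s on component %d (top_n = %d); using all",
                    length(cand), direction, component, top_n))
  }
  source_sets <- head(cand, top_n)
  counts <- table(unlist(collection$sets[source_sets]))
  genes <- sort(names(counts)[counts >= min_overlap])
  if (!length(genes)) {
    stop("empty signature: no gene appears in >= ", min_overlap,
         " of the top sets; lower min_overlap or raise top_n")
  }
  nm <- sprintf("%s%s-%d%s", dataset_code, collection_code(collection),
                component, if (direction == "positive") "P" else "N")
  structure(list(name = nm, genes = genes, component = component,
                 direction = direction, source_sets = source_sets,
                 membership_counts = setNames(as.integer(counts[genes]), genes)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes from %d source sets (PC%d, %s)\n",
              x$name, length(x$genes), length(x$source_sets), x$component,
              x$direction))
  invisible(x)
}

#' Synthesize the default set of signatures (components 1-2, both directions)
#'
#' @param pca A `pca_result`.
#' @param collection The scoring `gene_set_collection`.
#' @param dataset_code Dataset code for the names.
#' @param components Component indices (default `1:2`).
#' @param top_n,min_overlap Passed to [synthesize_signature()].
#' @return Named list of `gene_signature` objects; combinations yielding an
#'   empty signature are skipped with a log line.
#' @export
synthesize_signatures <- function(pca, collection, dataset_code = "S",
                                  components = 1:2, top_n = 20,
                                  min_overlap = 5) {
  out <- list()
  for (k in intersect(components, seq_len(ncol(pca$loadings)))) {
    for (dir in c("positive", "negative")) {
      sig <- tryCatch(
        suppressWarnings(synthesize_signature(pca, collection, k, dir,
                                              dataset_code, top_n, min_overlap)),
        error = function(e) {
          ps_log("info", sprintf("PC%d %s: %s", k, dir, conditionMessage(e)))
          NULL
        })
      if (!is.null(sig)) out[[sig$name]] <- sig
    }
  }
  out
}

#' Convert gene signatures to a gene-set collection
#'
#' @param signatures List of `gene_signature` objects.
#' @param label Collection label.
#' @return A `gene_set_collection` whose descriptions record provenance
#'   (component, direction, source-set count).
#' @export
signatures_to_collection <- function(signatures, label = "signatures") {
  stopifnot(length(signatures) >= 1)
  sets <- lapply(signatures, `[[`, "genes")
  names(sets) <- vapply(signatures, `[[`, character(1), "name")
  desc <- vapply(signatures, function(s) {
    sprintf("PC%d %s from %d source sets", s$component, s$direction,
            length(s$source_sets))
  }, character(1))
  gene_set_collection(sets, setNames(desc, names(sets)), label = label)
}

#' Score gene signatures on an expression matrix
#'
#' Treats each signature as a gene set and delegates to [normalize_es()];
#' the result is the samples x signatures NES matrix used to recluster a
#' cohort by signature enrichment.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param signatures List of `gene_signature` objects.
#' @param n_perm,seed,weight Passed to [normalize_es()].
#' @return An `enrichment_profile` (samples x signatures).
#' @export
score_signature_matrix <- function(matrix, signatures, n_perm = 1000,
                                   seed = 1, weight = 1) {
  normalize_es(matrix, signatures_to_collection(signatures),
               n_perm = n_perm, seed = seed, weight = weight)
}
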