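# Monti-style consensus clustering over the enrichment profile, an NMF
# alternative, and a random-forest robustness check of the final labels.

# k-means++ seeding (base kmeans only offers random starts)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - x[rep(centers[1], n), , drop = FALSE])^2)
  for (i in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[i + 1L] <- sample.int(n, 1L)
    } else {
      centers[i + 1L] <- sample.int(n, 1L, prob = d2)
    }
    di <- rowSums((x - x[rep(centers[i + 1L], n), , drop = FALSE])^2)
    d2 <- pmin(d2, di)
  }
  x[centers, , drop = FALSE]
}

kmeans_pp <- function(x, k) {
  cent <- kmeanspp_centers(x, k)
  cl <- tryCatch(kmeans(x, centers = cent, iter.max = 50)$cluster,
                 error = function(e) NULL)
  if (is.null(cl)) {
    # fewer distinct points than k (duplicated samples): nearest-center rule
    d2 <- vapply(seq_len(nrow(cent)), function(j)
      rowSums((x - cent[rep(j, nrow(x)), , drop = FALSE])^2), numeric(nrow(x)))
    cl <- max.col(-d2, ties.method = "first")
  }
  cl
}

#' Consensus clustering with automatic choice of k
#'
#' Monti resampling: samples are repeatedly subsampled without replacement,
#' each subsample is clustered by k-means (k-means++ initialization), and
#' co-clustering frequencies are accumulated, normalized by how often each
#' pair was co-sampled. The proportion of ambiguous clustering,
#' `PAC(k)` = fraction of off-diagonal consensus entries strictly inside
#' (0.1, 0.9), selects `k` (ties to the smaller k). Final labels come from
#' average-linkage hierarchical clustering of `1 - consensus` at the chosen
#' k.
#'
#' @param profile An `enrichment_profile` or samples x features matrix.
#' @param k_range Candidate cluster counts, within `[2, n_samples - 1]`.
#' @param n_resamples Subsampling iterations per k (>= 50).
#' @param subsample Fraction of samples drawn each iteration.
#' @param seed Integer seed.
#' @return A `consensus_result`: `k_range`, per-k `consensus` matrices,
#'   `pac`, `chosen_k`, `labels`, `n_resamples`, `seed`.
#' @export
consensus_cluster <- function(profile, k_range = 2:6, n_resamples = 250,
                              subsample = 0.8, seed = 1) {
  x <- if (inherits(profile, "enrichment_profile")) profile_matrix(profile) else as.matrix(profile)
  n <- nrow(x)
  stopifnot(all(k_range >= 2), all(k_range <= n - 1), n_resamples >= 50,
            subsample > 0, subsample <= 1)
  n_sub <- max(2L, floor(subsample * n))
  consensus <- list()
  pac <- setNames(numeric(length(k_range)), paste0("k", k_range))
  with_seed(seed, {
    for (ki in seq_along(k_range)) {
      k <- k_range[[ki]]
      hits <- tries <- matrix(0, n, n)
      for (r in seq_len(n_resamples)) {
        idx <- sample.int(n, n_sub)
        cl <- kmeans_pp(x[idx, , drop = FALSE], k)
        same <- outer(cl, cl, "==") * 1
        tries[idx, idx] <- tries[idx, idx] + 1
        hits[idx, idx] <- hits[idx, idx] + same
      }
      off <- tries; diag(off) <- 1
      if (any(off == 0)) {
        stop("some sample pairs were never co-sampled; increase n_resamples")
      }
      cons <- hits / pmax(tries, 1)
      diag(cons) <- 1
      dimnames(cons) <- list(rownames(x), rownames(x))
      consensus[[paste0("k", k)]] <- cons
      up <- cons[upper.tri(cons)]
      pac[[ki]] <- mean(up > 0.1 & up < 0.9)
    }
  })
  chosen_k <- k_range[[which.min(pac)]]
  cons_k <- consensus[[paste0("k", chosen_k)]]
  hc <- hclust(stats::as.dist(1 - cons_k), method = "average")
  labels <- cutree(hc, k = chosen_k)
  names(labels) <- rownames(x)
  structure(list(k_range = k_range, consensus = consensus, pac = pac,
                 chosen_k = chosen_k, labels = labels,
                 n_resamples = as.integer(n_resamples),
                 subsample = subsample, seed = as.integer(seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> chosen k = %d over k in {%s}\n",
              x$chosen_k, paste(x$k_range, collapse = ", ")))
  cat("  PAC:", paste(sprintf("%s=%.3f", names(x$pac), x$pac), collapse = "  "), "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' NMF clustering of an enrichment profile
#'
#' The profile is shifted to non-negative by subtracting its global minimum,
#' then factorized by multiplicative-update NMF minimizing Frobenius error
#' (best of `n_restarts` random initializations). Each sample is assigned to
#' the basis component with its largest coefficient.
#'
#' @param profile An `enrichment_profile` or samples x features matrix.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (best by reconstruction error).
#' @param max_iter Update iterations per restart.
#' @param tol Relative error-change convergence tolerance.
#' @return Named integer vector of cluster labels.
#' @export
nmf_cluster <- function(profile, k, seed = 1, n_restarts = 20,
                        max_iter = 500, tol = 1e-6) {
  x <- if (inherits(profile, "enrichment_profile")) profile_matrix(profile) else as.matrix(profile)
  stopifnot(k >= 2, k <= nrow(x))
  a <- x - min(x)
  n <- nrow(a); m <- ncol(a)
  eps <- 1e-10
  with_seed(seed, {
    best <- NULL; best_err <- Inf
    for (r in seq_len(n_restarts)) {
      w <- matrix(runif(n * k, 0.1, 1), n, k)
      h <- matrix(runif(k * m, 0.1, 1), k, m)
      err_old <- Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        h <- h * (crossprod(w, a) / (crossprod(w) %*% h + eps))
        w <- w * (a %*% t(h) / (w %*% tcrossprod(h) + eps))
        if (it %% 10L == 0L) {
          err <- sum((a - w %*% h)^2)
          if (is.finite(err_old) && abs(err_old - err) <= tol * max(err_old, eps)) {
            converged <- TRUE
            break
          }
          err_old <- err
        }
      }
      err <- sum((a - w %*% h)^2)
      if (err < best_err) { best_err <- err; best <- w; best_conv <- converged }
    }
    if (!best_conv) warning("NMF did not converge within max_iter; returning best iterate")
    labels <- max.col(best, ties.method = "first")
    names(labels) <- rownames(x)
    labels
  })
}

#' Random-forest robustness check of cluster labels
#'
#' Trains a random forest to predict the cluster labels from the profile
#' and reports out-of-bag accuracy, overall and per cluster. High OOB
#' accuracy indicates the clusters are separable in profile space.
#'
#' @param profile An `enrichment_profile` or samples x features matrix.
#' @param labels Cluster labels (one per sample, each cluster >= 2 members).
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return A `robustness_report`: `oob_accuracy`, `per_cluster_accuracy`,
#'   `n_trees`, `seed`.
#' @export
rf_robustness <- function(profile, labels, n_trees = 500, seed = 1) {
  x <- if (inherits(profile, "enrichment_profile")) profile_matrix(profile) else as.matrix(profile)
  stopifnot(length(labels) == nrow(x))
  if (any(table(labels) < 2)) stop("every cluster needs >= 2 members")
  y <- factor(labels)
  with_seed(seed, {
    fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
    pred <- fit$predicted  # OOB predictions
    oob <- mean(pred == y)
    per <- vapply(levels(y), function(l) mean(pred[y == l] == l), numeric(1))
    structure(list(oob_accuracy = oob,
                   per_cluster_accuracy = per,
                   n_trees = as.integer(n_trees), seed = as.integer(seed)),
              class = "robustness_report")
  })
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("<robustness_report> OOB accuracy %.3f (%d trees)\n",
              x$oob_accuracy, x$n_trees))
  invisible(x)
}
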