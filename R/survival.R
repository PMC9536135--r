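# Survival machinery: product-limit estimator, Mantel-Cox log-rank with
# hypergeometric variance, pairwise comparisons with multiplicity
# correction, and single-hit Poisson limiting-dilution frequency estimation.

# Labels may be a named vector (matched by sample id) or positional.
resolve_labels <- function(labels, samples) {
  if (!is.null(names(labels))) {
    miss <- setdiff(samples, names(labels))
    if (length(miss)) stop("labels missing for sample(s): ",
                           paste(head(miss, 5), collapse = ", "))
    unname(labels[samples])
  } else {
    if (length(labels) != length(samples)) {
      stop("unnamed labels must match the number of samples")
    }
    labels
  }
}

#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator. Subjects censored at time t leave the risk set
#' after the deaths at t. The median is the smallest event time with
#' `S(t) <= 0.5`, `NA` if the curve never reaches 0.5.
#'
#' @param table A [as_survival_table()] tibble (columns `sample`, `time`,
#'   `event`, optionally `group`).
#' @param group If given, restrict to rows with this `group` value.
#' @return A `km_curve`: tibble `steps` (time, n_risk, n_event, survival),
#'   plus `median`, `n`, `group`.
#' @export
km_curve <- function(table, group = NULL) {
  table <- as_survival_table(table)
  if (!is.null(group)) {
    if (!"group" %in% names(table)) stop("table has no 'group' column")
    table <- table[table$group == group, , drop = FALSE]
  }
  if (!nrow(table)) stop("empty group")
  ev_times <- sort(unique(table$time[table$event == 1]))
  s <- 1
  steps <- lapply(ev_times, function(t) {
    n_risk <- sum(table$time >= t)
    n_event <- sum(table$time == t & table$event == 1)
    s <<- s * (1 - n_event / n_risk)
    tibble::tibble(time = t, n_risk = n_risk, n_event = n_event, survival = s)
  })
  steps <- if (length(steps)) dplyr::bind_rows(steps) else
    tibble::tibble(time = numeric(0), n_risk = integer(0),
                   n_event = integer(0), survival = numeric(0))
  med <- steps$time[steps$survival <= 0.5]
  structure(list(steps = steps,
                 median = if (length(med)) med[[1]] else NA_real_,
                 n = nrow(table), group = group),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d%s, %d event times, median = %s\n",
              x$n, if (!is.null(x$group)) paste0(" (group ", x$group, ")") else "",
              nrow(x$steps),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Mantel-Cox log-rank test across groups
#'
#' At each distinct event time the observed deaths per group are compared
#' with their hypergeometric expectation given the risk sets; the summed
#' (O - E) vector is combined with its variance-covariance matrix into a
#' chi-square statistic with `groups - 1` degrees of freedom.
#'
#' @param table Survival tibble with a `group` column (or see `labels`).
#' @param labels Optional group labels overriding `table$group`.
#' @return A `logrank_result`: `chi_square`, `df`, `p`, per-group
#'   observed/expected tibble.
#' @export
logrank_test <- function(table, labels = NULL) {
  table <- as_survival_table(table)
  if (!is.null(labels)) table$group <- resolve_labels(labels, table$sample)
  if (!"group" %in% names(table)) stop("no group labels supplied")
  groups <- sort(unique(table$group))
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  if (!any(table$event == 1)) stop("no events in any group")
  ev_times <- sort(unique(table$time[table$event == 1]))
  o_minus_e <- setNames(numeric(k), groups)
  observed <- expected <- setNames(numeric(k), groups)
  v <- matrix(0, k, k, dimnames = list(groups, groups))
  for (t in ev_times) {
    at_risk <- table$time >= t
    n <- sum(at_risk)
    n_j <- vapply(groups, function(g) sum(at_risk & table$group == g), numeric(1))
    d_j <- vapply(groups, function(g)
      sum(table$time == t & table$event == 1 & table$group == g), numeric(1))
    d <- sum(d_j)
    e_j <- d * n_j / n
    observed <- observed + d_j
    expected <- expected + e_j
    o_minus_e <- o_minus_e + (d_j - e_j)
    if (n > 1) {
      scale <- d * (n - d) / (n - 1)
      v <- v + scale * (diag(n_j / n, k) - tcrossprod(n_j / n))
    }
  }
  sub <- seq_len(k - 1)
  vi <- tryCatch(solve(v[sub, sub, drop = FALSE]),
                 error = function(e) pseudo_inverse(v[sub, sub, drop = FALSE]))
  chi <- drop(t(o_minus_e[sub]) %*% vi %*% o_minus_e[sub])
  chi <- max(chi, 0)
  structure(list(chi_square = chi, df = k - 1L,
                 p = pchisq(chi, df = k - 1, lower.tail = FALSE),
                 groups = groups,
                 table = tibble::tibble(group = groups, n = as.integer(table(table$group)[groups]),
                                        observed = observed, expected = expected)),
            class = "logrank_result")
}

# SVD-based Moore-Penrose fallback for a singular variance matrix (e.g. a group with
# no events at any shared risk time)
pseudo_inverse <- function(x, tol = sqrt(.Machine$double.eps)) {
  s <- svd(x)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(array(0, dim(x)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p))
  invisible(x)
}

#' All pairwise log-rank tests with multiplicity correction
#'
#' Runs [logrank_test()] on every unordered pair of groups and adjusts the
#' p-values across pairs, Benjamini-Hochberg by default (a Bonferroni
#' option is provided since both readings of "Bonferroni-Hochberg
#' correction" occur in the literature).
#'
#' @param table Survival tibble with `group` (or `labels`).
#' @param labels Optional labels overriding `table$group`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Tibble with `group1`, `group2`, `chi_square`, `p`, `p_adj`.
#' @export
pairwise_logrank_adjusted <- function(table, labels = NULL,
                                      method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  table <- as_survival_table(table)
  if (!is.null(labels)) table$group <- resolve_labels(labels, table$sample)
  groups <- sort(unique(table$group))
  if (length(groups) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    sub <- table[table$group %in% pr, , drop = FALSE]
    lr <- logrank_test(sub)
    tibble::tibble(group1 = pr[[1]], group2 = pr[[2]],
                   chi_square = lr$chi_square, p = lr$p)
  })
  res$p_adj <- p.adjust(res$p, method = method)
  res
}

#' Limiting-dilution frequency under the single-hit Poisson model
#'
#' In a sphere-formation limiting-dilution assay, a well seeded with `d`
#' cells stays negative with probability `exp(-f d)` where `f` is the
#' frequency of sphere-initiating cells. `f` is estimated by
#' complementary-log-log binomial regression of well outcome on dose with
#' unit slope (offset `log(dose)`); the 95% CI is a normal interval on
#' `log(f)`. With a single dose this reduces to the closed form
#' `f = -log(negatives / wells) / dose`.
#'
#' @param doses Cells plated per well at each dose level.
#' @param wells Number of wells per dose level.
#' @param negatives Number of negative (sphere-free) wells per dose level.
#' @return An `lda_result`: `frequency` (per cell), `one_in`
#'   (`1/frequency`), `ci_low`, `ci_high`, `boundary` flag, input tibble.
#' @export
lda_frequency <- function(doses, wells, negatives) {
  stopifnot(length(doses) == length(wells), length(wells) == length(negatives),
            all(doses > 0), all(wells >= 1),
            all(negatives >= 0), all(negatives <= wells))
  pos <- wells - negatives
  if (all(negatives == wells) || all(negatives == 0)) {
    # every well negative (no hits) or every well positive: MLE on the boundary
    f <- if (all(negatives == 0)) Inf else 0
    return(structure(list(frequency = f, one_in = 1 / f,
                          ci_low = NA_real_, ci_high = NA_real_,
                          boundary = TRUE,
                          data = tibble::tibble(dose = doses, wells = wells,
                                                negatives = negatives)),
                     class = "lda_result"))
  }
  fit <- glm(cbind(pos, negatives) ~ 1 + offset(log(doses)),
             family = binomial(link = "cloglog"))
  est <- coef(fit)[[1]]
  se <- sqrt(summary(fit)$cov.scaled[1, 1])
  structure(list(frequency = exp(est), one_in = exp(-est),
                 ci_low = exp(est - qnorm(0.975) * se),
                 ci_high = exp(est + qnorm(0.975) * se),
                 boundary = FALSE,
                 data = tibble::tibble(dose = doses, wells = wells,
                                       negatives = negatives)),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  if (x$boundary) {
    cat("<lda_result> boundary fit (all wells negative or all positive); no CI\n")
  } else {
    cat(sprintf("<lda_result> frequency 1/%.1f (95%% CI 1/%.1f - 1/%.1f)\n",
                x$one_in, 1 / x$ci_high, 1 / x$ci_low))
  }
  invisible(x)
}
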