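# Seed hygiene: every generator is a pure function of its config. Each call
# runs under a local RNG state and restores the caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the bulk-cohort simulator
#'
#' The defaults describe the cohort the downstream analyses assume: a
#' moderately sized bulk cohort (60 samples, 2000 genes) carrying three
#' latent clusters, each driven by one 50-gene transcriptional program
#' shifted by 2 log2 units over unit-SD Gaussian noise, with
#' cluster-dependent exponential survival and 20% uniform right-censoring.
#'
#' Each program is represented in the gene-set collection by
#' `sets_per_program` overlapping gene sets, each covering a random
#' `set_coverage` fraction of the program — emulating the redundancy of
#' curated pathway collections, which is what makes consensus-of-top-sets
#' signature synthesis meaningful. `n_decoys` size-matched random sets are
#' added so enrichment specificity is testable.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param k_clusters Number of planted clusters (>= 1).
#' @param programs_per_cluster Programs per cluster; directions alternate
#'   up/down starting with up.
#' @param program_size Genes per program (>= 2).
#' @param effect Mean log2 shift of program genes in their cluster.
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0).
#' @param hazard_by_cluster Exponential event rates, one per cluster;
#'   default an even grid from 0.04 to 0.10.
#' @param censor_rate Probability a subject is right-censored, in `[0, 1)`.
#' @param n_decoys Number of decoy gene sets.
#' @param sets_per_program Overlapping gene sets generated per program.
#' @param set_coverage Fraction of a program each planted set covers.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_samples = 60, k_clusters = 3,
                              programs_per_cluster = 1, program_size = 50,
                              effect = 2, noise_sd = 1,
                              hazard_by_cluster = NULL, censor_rate = 0.2,
                              n_decoys = 30, sets_per_program = 8,
                              set_coverage = 0.8, seed = 1) {
  if (is.null(hazard_by_cluster)) {
    hazard_by_cluster <- if (k_clusters == 1) 0.07 else
      seq(0.04, 0.10, length.out = k_clusters)
  }
  cfg <- list(n_genes = n_genes, n_samples = n_samples, k_clusters = k_clusters,
              programs_per_cluster = programs_per_cluster,
              program_size = program_size, effect = effect, noise_sd = noise_sd,
              hazard_by_cluster = hazard_by_cluster, censor_rate = censor_rate,
              n_decoys = n_decoys, sets_per_program = sets_per_program,
              set_coverage = set_coverage, seed = as.integer(seed))
  stopifnot(cfg$k_clusters >= 1, cfg$program_size >= 2, cfg$noise_sd > 0,
            length(cfg$hazard_by_cluster) == cfg$k_clusters,
            all(cfg$hazard_by_cluster > 0),
            cfg$censor_rate >= 0, cfg$censor_rate < 1,
            cfg$set_coverage > 0, cfg$set_coverage <= 1)
  n_program_genes <- cfg$program_size * cfg$programs_per_cluster * cfg$k_clusters
  if (n_program_genes > cfg$n_genes) {
    stop(sprintf("program genes (%d) exceed n_genes (%d)",
                 n_program_genes, cfg$n_genes))
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a bulk cohort with planted cluster, program and survival structure
#'
#' Baseline log2 expression is Gaussian around per-gene means (drawn once);
#' each cluster's program genes are shifted by `+effect` (down-programs by
#' `-effect`) in that cluster's samples. Survival times are exponential with
#' the cluster's hazard, with independent uniform right-censoring. The
#' returned gene-set collection holds the planted program sets plus
#' size-matched decoys; `truth` records everything needed to score recovery.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `expression` (genes x samples matrix),
#'   `clinical` (survival tibble), `collection` (`gene_set_collection`) and
#'   `truth` (labels, planted set names, program genes and directions,
#'   survival parameters).
#' @export
simulate_bulk <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    samples <- sprintf("S%03d", seq_len(config$n_samples))
    labels <- sample(rep_len(seq_len(config$k_clusters), config$n_samples))
    names(labels) <- samples

    mu <- rnorm(config$n_genes, mean = 6, sd = 1.5)
    expr <- matrix(rnorm(config$n_genes * config$n_samples, mean = mu,
                         sd = config$noise_sd),
                   nrow = config$n_genes, dimnames = list(genes, samples))

    # disjoint program blocks at the top of the gene index
    program_genes <- vector("list", config$k_clusters)
    planted <- rep(list(character(0)), config$k_clusters)
    desc <- character(); sets <- list()
    idx <- 0L
    for (cl in seq_len(config$k_clusters)) {
      cl_programs <- list()
      for (p in seq_len(config$programs_per_cluster)) {
        block <- genes[idx + seq_len(config$program_size)]
        idx <- idx + config$program_size
        dir <- if (p %% 2L == 1L) 1 else -1
        expr[block, labels == cl] <- expr[block, labels == cl] + dir * config$effect
        cl_programs[[p]] <- list(genes = block, direction = dir)
        n_cover <- max(2L, ceiling(config$set_coverage * config$program_size))
        for (s in seq_len(config$sets_per_program)) {
          nm <- sprintf("C%dP%d_SET%02d", cl, p, s)
          sets[[nm]] <- sample(block, n_cover)
          desc[[nm]] <- sprintf("planted cluster=%d program=%d direction=%s",
                                cl, p, if (dir > 0) "up" else "down")
          planted[[cl]] <- c(planted[[cl]], nm)
        }
      }
      program_genes[[cl]] <- cl_programs
    }
    set_size <- max(2L, ceiling(config$set_coverage * config$program_size))
    for (d in seq_len(config$n_decoys)) {
      nm <- sprintf("DECOY%03d", d)
      sets[[nm]] <- sample(genes, set_size)
      desc[[nm]] <- "decoy"
    }
    collection <- gene_set_collection(sets, desc, label = "synthetic")

    event_time <- rexp(config$n_samples, rate = config$hazard_by_cluster[labels])
    censored <- runif(config$n_samples) < config$censor_rate
    time <- ifelse(censored, runif(config$n_samples, 0, event_time), event_time)
    clinical <- as_survival_table(tibble::tibble(
      sample = samples, time = time, event = as.integer(!censored),
      group = labels))

    list(expression = as_expression_matrix(expr),
         clinical = clinical,
         collection = collection,
         truth = list(labels = labels,
                      planted_sets = planted,
                      program_genes = program_genes,
                      survival_params = config$hazard_by_cluster,
                      config = config))
  })
}

#' Simulate a single-cell expression matrix with planted cell states
#'
#' Cells are split evenly among the supplied states; each state's program
#' genes are shifted by that state's `effect` in its cells, on top of
#' Gaussian log-expression around per-gene means. Random entries are zeroed
#' at rate `dropout` to mimic detection dropout.
#'
#' @param n_cells Number of cells.
#' @param states List of states, each `list(name=, genes=, effect=)`.
#' @param noise_sd Gaussian noise SD (> 0).
#' @param dropout Probability an entry is zeroed, in `[0, 1)`.
#' @param n_background Background genes added beyond the state programs.
#' @param seed Integer seed.
#' @return List with `expression` (genes x cells) and `truth` (state per
#'   cell, program gene lists, overlap warnings).
#' @export
simulate_single_cell <- function(n_cells, states, noise_sd = 1, dropout = 0,
                                 n_background = 500, seed = 1) {
  stopifnot(length(states) >= 1, noise_sd > 0, dropout >= 0, dropout < 1)
  state_names <- vapply(states, `[[`, character(1), "name")
  programs <- lapply(states, function(s) toupper(s$genes))
  if (any(!lengths(programs))) stop("state programs must be nonempty")
  overlap <- character(0)
  if (length(states) > 1) {
    all_g <- unlist(programs)
    overlap <- unique(all_g[duplicated(all_g)])
    if (length(overlap)) {
      warning("program genes shared across states: ",
              paste(head(overlap, 5), collapse = ", "))
    }
  }
  with_seed(seed, {
    genes <- unique(c(unlist(programs),
                      sprintf("BG%05d", seq_len(n_background))))
    cells <- sprintf("CELL%04d", seq_len(n_cells))
    state <- sample(rep_len(seq_along(states), n_cells))
    names(state) <- cells
    mu <- rnorm(length(genes), mean = 2, sd = 1)
    expr <- matrix(rnorm(length(genes) * n_cells, mean = mu, sd = noise_sd),
                   nrow = length(genes), dimnames = list(genes, cells))
    for (s in seq_along(states)) {
      expr[programs[[s]], state == s] <-
        expr[programs[[s]], state == s] + states[[s]]$effect
    }
    if (dropout > 0) {
      expr[matrix(runif(length(expr)) < dropout, nrow = nrow(expr))] <- 0
    }
    list(expression = as_expression_matrix(expr, what = "single_cell"),
         truth = list(state = setNames(state_names[state], cells),
                      programs = setNames(programs, state_names),
                      overlap = overlap, seed = seed))
  })
}

#' Draw a random gene-set collection from a gene pool
#'
#' Sets are uniform random subsets of the pool, named `SET0001`,
#' `SET0002`, ...; deterministic given the seed.
#'
#' @param pool Character vector of gene symbols.
#' @param n_sets Number of sets.
#' @param size Genes per set (<= pool length).
#' @param seed Integer seed.
#' @return A `gene_set_collection`.
#' @export
make_collection <- function(pool, n_sets, size, seed = 1) {
  pool <- toupper(pool)
  stopifnot(size <= length(pool), n_sets >= 1)
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(pool, size))
    names(sets) <- sprintf("SET%04d", seq_len(n_sets))
    gene_set_collection(sets, label = "random")
  })
}

#' Simulate expression with planted coexpression modules
#'
#' Each module is driven by a latent sample-level factor; member genes load
#' on it with correlation `sqrt(rho)` so the expected within-module gene-gene
#' correlation is `rho`. Background genes are independent noise.
#'
#' @param n_modules Number of modules.
#' @param module_size Genes per module.
#' @param n_background Unassigned background genes.
#' @param n_samples Number of samples.
#' @param rho Expected within-module correlation, in `(0, 1]`.
#' @param seed Integer seed.
#' @return List with `expression` (genes x samples) and `truth` (module id
#'   per gene; 0 = background).
#' @export
simulate_coexpression <- function(n_modules = 3, module_size = 30,
                                  n_background = 40, n_samples = 50,
                                  rho = 0.8, seed = 1) {
  stopifnot(rho > 0, rho <= 1, n_modules >= 1, module_size >= 2)
  with_seed(seed, {
    n_genes <- n_modules * module_size + n_background
    genes <- sprintf("G%05d", seq_len(n_genes))
    samples <- sprintf("S%03d", seq_len(n_samples))
    module <- c(rep(seq_len(n_modules), each = module_size),
                rep(0L, n_background))
    names(module) <- genes
    factors <- matrix(rnorm(n_modules * n_samples), nrow = n_modules)
    expr <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
                   dimnames = list(genes, samples))
    in_mod <- module > 0
    expr[in_mod, ] <- sqrt(rho) * factors[module[in_mod], , drop = FALSE] +
      sqrt(1 - rho) * expr[in_mod, , drop = FALSE]
    expr <- expr + 6  # shift to a log2-expression-like scale
    list(expression = as_expression_matrix(expr),
         truth = list(module = module, rho = rho, seed = seed))
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return A number <= 1.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}
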