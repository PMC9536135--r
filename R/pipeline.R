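# End-to-end orchestration: simulate -> enrich -> signatures -> cluster ->
# survival -> single_cell -> modules -> annotate, from one config, with a
# run manifest capturing seeds and output digests. Stage outputs are plain
# TSV/GMT/JSON so every stage is independently re-runnable and diffable.

# Deterministic per-stage sub-seed: stages are reorderable without seed
# collisions because each derives only from the global seed and its name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

default_pipeline_config <- function() {
  list(
    out_dir = tempfile("pathstrat_run_"),
    seed = 1,
    stages = c("simulate", "enrich", "signatures", "cluster", "survival",
               "single_cell", "modules", "annotate"),
    simulate = list(),
    enrich = list(n_perm = 500, weight = 1),
    signatures = list(dataset_code = "S", top_n = 20, min_overlap = 5,
                      components = c(1, 2)),
    cluster = list(k_min = 2, k_max = 5, n_resamples = 100, subsample = 0.8),
    single_cell = list(n_cells = 400, effect = 2, dropout = 0.3,
                       noise_sd = 1),
    modules = list(min_module_size = 10, max_de_genes = 500),
    annotate = list(alpha = 0.05)
  )
}

validate_pipeline_config <- function(config) {
  known <- names(default_pipeline_config())
  extra <- setdiff(names(config), c(known, "inputs"))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  cfg <- modifyList(default_pipeline_config(), config)
  bad <- setdiff(cfg$stages, default_pipeline_config()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) stop("seed must be a single number")
  if (!is.null(config$inputs)) {
    miss <- !vapply(unlist(config$inputs), file.exists, logical(1))
    if (any(miss)) stop("input file(s) not found: ",
                        paste(unlist(config$inputs)[miss], collapse = ", "))
  }
  cfg
}

#' Run the full pathway-stratification pipeline
#'
#' Executes the enabled stages in dependency order against either a
#' simulated cohort (default) or user-supplied inputs
#' (`config$inputs$expression` / `clinical` / `gmt` TSV and GMT paths). All
#' stage outputs are written under `config$out_dir`; a `manifest.json`
#' recording the config snapshot, per-stage seeds, package version and
#' output digests is written last. Every stochastic stage derives its seed
#' deterministically from the global seed and the stage name, so two runs
#' of the same config produce byte-identical stage outputs.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   See `default_pipeline_config` internals for the schema; unknown keys
#'   are rejected before any computation.
#' @return Invisibly, the run manifest (list).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(config = cfg, version = as.character(packageVersion("pathstrat")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  enabled <- function(s) s %in% cfg$stages
  note <- function(stage, files, seed = NULL) {
    manifest$stages[[stage]] <<- list(
      seed = seed, outputs = as.list(files),
      digests = as.list(tools::md5sum(files)),
      at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  # --- inputs -----------------------------------------------------------
  truth <- NULL
  if (enabled("simulate") && is.null(cfg$inputs)) {
    s_seed <- stage_seed(cfg$seed, "simulate")
    sim <- tryCatch(
      simulate_bulk(do.call(simulation_config,
                            modifyList(cfg$simulate, list(seed = s_seed)))),
      error = function(e) fail("simulate", e))
    expr <- sim$expression; clinical <- sim$clinical; collection <- sim$collection
    truth <- sim$truth
    write_matrix(expr, out("expression.tsv"))
    write_matrix(as.data.frame(clinical), out("clinical.tsv"))
    write_gmt(collection, out("gene_sets.gmt"))
    jsonlite::write_json(
      list(labels = as.list(truth$labels),
           planted_sets = truth$planted_sets,
           hazards = truth$survival_params),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
    note("simulate", out(c("expression.tsv", "clinical.tsv", "gene_sets.gmt",
                           "truth.json")), s_seed)
  } else {
    if (is.null(cfg$inputs)) stop("either enable the simulate stage or provide config$inputs")
    expr <- read_matrix(cfg$inputs$expression, "expression")
    clinical <- if (!is.null(cfg$inputs$clinical))
      read_matrix(cfg$inputs$clinical, "clinical") else NULL
    collection <- read_gmt(cfg$inputs$gmt)
  }

  # --- enrichment profile ----------------------------------------------
  profile <- NULL
  if (enabled("enrich")) {
    e_seed <- stage_seed(cfg$seed, "enrich")
    profile <- tryCatch(
      normalize_es(expr, collection, n_perm = cfg$enrich$n_perm,
                   seed = e_seed, weight = cfg$enrich$weight),
      error = function(e) fail("enrich", e))
    write_matrix(profile$nes, out("profile_nes.tsv"), id = "sample")
    jsonlite::write_json(list(n_perm = profile$n_perm, weight = profile$weight,
                              seed = profile$seed),
                         out("profile_meta.json"), auto_unbox = TRUE)
    note("enrich", out(c("profile_nes.tsv", "profile_meta.json")), e_seed)
  }

  # --- signatures -------------------------------------------------------
  sigs <- NULL
  if (enabled("signatures") && !is.null(profile)) {
    pca <- tryCatch(pca_decompose(profile, n_components = max(cfg$signatures$components)),
                    error = function(e) fail("signatures", e))
    sigs <- synthesize_signatures(pca, collection,
                                  dataset_code = cfg$signatures$dataset_code,
                                  components = cfg$signatures$components,
                                  top_n = cfg$signatures$top_n,
                                  min_overlap = cfg$signatures$min_overlap)
    if (length(sigs)) write_gmt(signatures_to_collection(sigs), out("signatures.gmt"))
    write_matrix(pca$contributions, out("contributions.tsv"), id = "gene_set")
    note("signatures",
         out(c(if (length(sigs)) "signatures.gmt", "contributions.tsv")))
  }

  # --- clustering -------------------------------------------------------
  cons <- NULL
  if (enabled("cluster") && !is.null(profile)) {
    c_seed <- stage_seed(cfg$seed, "cluster")
    k_max <- min(cfg$cluster$k_max, nrow(profile$nes) - 1)
    cons <- tryCatch(
      consensus_cluster(profile, k_range = cfg$cluster$k_min:k_max,
                        n_resamples = cfg$cluster$n_resamples,
                        subsample = cfg$cluster$subsample, seed = c_seed),
      error = function(e) fail("cluster", e))
    nmf_labels <- nmf_cluster(profile, k = cons$chosen_k, seed = c_seed)
    rf <- rf_robustness(profile, cons$labels, seed = c_seed)
    write_matrix(tibble::tibble(sample = names(cons$labels),
                                consensus = unname(cons$labels),
                                nmf = unname(nmf_labels)),
                 out("labels.tsv"))
    write_matrix(tibble::tibble(k = cons$k_range, pac = unname(cons$pac)),
                 out("pac.tsv"))
    jsonlite::write_json(list(chosen_k = cons$chosen_k,
                              oob_accuracy = rf$oob_accuracy,
                              per_cluster = as.list(rf$per_cluster_accuracy)),
                         out("cluster_meta.json"), auto_unbox = TRUE, digits = NA)
    note("cluster", out(c("labels.tsv", "pac.tsv", "cluster_meta.json")), c_seed)
  }

  # --- survival ---------------------------------------------------------
  if (enabled("survival") && !is.null(cons) && !is.null(clinical)) {
    surv <- tryCatch({
      lr <- pairwise_logrank_adjusted(clinical, labels = cons$labels)
      med <- purrr::map_dfr(sort(unique(cons$labels)), function(cl) {
        tab <- clinical; tab$group <- resolve_labels(cons$labels, tab$sample)
        km <- km_curve(tab, group = cl)
        tibble::tibble(cluster = cl, n = km$n, median = km$median)
      })
      list(lr = lr, med = med)
    }, error = function(e) fail("survival", e))
    write_matrix(surv$lr, out("survdiff.tsv"))
    write_matrix(surv$med, out("km_medians.tsv"))
    note("survival", out(c("survdiff.tsv", "km_medians.tsv")))
  }

  # --- single cell ------------------------------------------------------
  if (enabled("single_cell") && length(sigs %||% list()) >= 1) {
    sc_seed <- stage_seed(cfg$seed, "single_cell")
    scr <- tryCatch({
      progs <- if (!is.null(truth)) {
        list(list(name = "cycling", genes = truth$program_genes[[1]][[1]]$genes,
                  effect = cfg$single_cell$effect),
             list(name = "stem_like",
                  genes = truth$program_genes[[min(2, length(truth$program_genes))]][[1]]$genes,
                  effect = cfg$single_cell$effect))
      } else {
        lapply(utils::head(sigs, 2), function(s)
          list(name = s$name, genes = s$genes, effect = cfg$single_cell$effect))
      }
      sc <- simulate_single_cell(cfg$single_cell$n_cells, progs,
                                 noise_sd = cfg$single_cell$noise_sd,
                                 dropout = cfg$single_cell$dropout,
                                 seed = sc_seed)
      cs <- cell_scores(sc$expression, sigs)
      cm <- correlation_map(cs)
      list(sc = sc, cs = cs, cm = cm)
    }, error = function(e) fail("single_cell", e))
    write_matrix(scr$cs$scores, out("cell_scores.tsv"), id = "cell")
    write_matrix(scr$cm$r, out("correlation_r.tsv"), id = "signature")
    write_matrix(scr$cm$p_raw, out("correlation_p_raw.tsv"), id = "signature")
    write_matrix(scr$cm$p_adj, out("correlation_p_adj.tsv"), id = "signature")
    write_matrix(tibble::tibble(signature = names(scr$cm$groups),
                                group = unname(scr$cm$groups)),
                 out("correlation_groups.tsv"))
    note("single_cell",
         out(c("cell_scores.tsv", "correlation_r.tsv", "correlation_p_raw.tsv",
               "correlation_p_adj.tsv", "correlation_groups.tsv")), sc_seed)
  }

  # --- coexpression modules --------------------------------------------
  de_by_cluster <- NULL
  if ((enabled("modules") || enabled("annotate")) && !is.null(cons)) {
    de_by_cluster <- lapply(sort(unique(cons$labels)), function(cl) {
      differential_expression(expr, cons$labels, cl)
    })
    names(de_by_cluster) <- paste0("cluster", sort(unique(cons$labels)))
  }
  if (enabled("modules") && !is.null(de_by_cluster)) {
    mod <- tryCatch({
      de_genes <- unique(unlist(lapply(de_by_cluster, function(d)
        head(d$gene[d$p_adj < 0.05], cfg$modules$max_de_genes))))
      if (length(de_genes) < 2 * cfg$modules$min_module_size) {
        ps_log("warn", "too few DE genes for module detection; skipping")
        NULL
      } else {
        ms <- detect_modules(expr[de_genes, , drop = FALSE],
                             min_module_size = cfg$modules$min_module_size)
        assoc <- if (ncol(ms$eigengenes))
          module_cluster_association(ms, cons$labels) else NULL
        list(ms = ms, assoc = assoc, hubs = hub_genes(ms))
      }
    }, error = function(e) fail("modules", e))
    if (!is.null(mod)) {
      write_matrix(tibble::tibble(gene = names(mod$ms$assignments),
                                  module = unname(mod$ms$assignments)),
                   out("module_assignments.tsv"))
      write_matrix(mod$ms$eigengenes, out("module_eigengenes.tsv"), id = "sample")
      if (!is.null(mod$assoc)) write_matrix(mod$assoc, out("module_cluster.tsv"))
      if (nrow(mod$hubs)) write_matrix(mod$hubs, out("hub_genes.tsv"))
      note("modules", out(c("module_assignments.tsv", "module_eigengenes.tsv",
                            if (!is.null(mod$assoc)) "module_cluster.tsv",
                            if (nrow(mod$hubs)) "hub_genes.tsv")))
    }
  }

  # --- annotation -------------------------------------------------------
  if (enabled("annotate") && !is.null(de_by_cluster)) {
    ann <- tryCatch({
      purrr::map_dfr(names(de_by_cluster), function(cl) {
        d <- de_by_cluster[[cl]]
        up <- d$gene[d$p_adj < cfg$annotate$alpha & d$log_fc > 0]
        if (!length(up)) return(tibble::tibble())
        res <- ora(up, collection, rownames(expr))
        res$cluster <- cl
        res
      })
    }, error = function(e) fail("annotate", e))
    write_matrix(ann, out("ora.tsv"))
    note("annotate", out("ora.tsv"))
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  ps_log("info", "pipeline complete: ", length(manifest$stages), " stage(s) in ",
         cfg$out_dir)
  invisible(manifest)
}
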