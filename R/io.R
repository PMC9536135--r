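#' @importFrom rlang %||% .data
#' @importFrom stats cor cutree dist hclust kmeans na.omit p.adjust pchisq
#'   phyper prcomp pt qnorm rbinom rexp rnorm runif sd var glm binomial coef
#'   quantile setNames weighted.mean predict
#' @importFrom utils read.delim write.table head modifyList packageVersion
NULL

# ---- logging -----------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Emit a structured log line
#'
#' Line-oriented logging used throughout the package. The minimum level that
#' is printed is controlled by `options(pathstrat.log_level = "info")`.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... Message parts, pasted together.
#' @return Invisibly, the formatted line.
#' @export
ps_log <- function(level = "info", ...) {
  level <- match.arg(level, names(.log_levels))
  floor_lev <- getOption("pathstrat.log_level", "info")
  line <- sprintf("[%s] %s %s", toupper(level),
                  format(Sys.time(), "%H:%M:%S"), paste0(..., collapse = ""))
  if (.log_levels[[level]] >= .log_levels[[floor_lev]]) message(line)
  invisible(line)
}

# ---- gene set collections ----------------------------------------------------

#' Construct a gene set collection
#'
#' A collection is a named list of gene sets (character vectors of uppercase
#' gene symbols) plus per-set descriptions and a collection label. Labels
#' `"canonical"` and `"oncogenic"` map to the single-character collection
#' codes `"2"` and `"6"` used in signature names.
#'
#' @param sets Named list of character vectors (gene symbols).
#' @param descriptions Optional character vector of per-set descriptions.
#' @param label Collection label (e.g. `"canonical"`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, label = "custom") {
  stopifnot(is.list(sets))
  nm <- names(sets) %||% character(0)
  if (length(sets) && (!length(nm) || any(!nzchar(nm)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- toupper(as.character(g))
    if (!length(g)) stop("gene sets must be nonempty")
    unique(g)
  })
  if (is.null(descriptions)) descriptions <- setNames(rep("na", length(sets)), nm)
  structure(list(sets = sets,
                 descriptions = setNames(as.character(descriptions), nm),
                 label = label),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (label: %s, code: %s)\n",
              length(x$sets), x$label, collection_code(x)))
  sizes <- lengths(x$sets)
  if (length(sizes)) {
    cat(sprintf("  set sizes: %d-%d (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Single-character collection code
#'
#' `"canonical"` collections are coded `"2"` and `"oncogenic"` collections
#' `"6"` (after the MSigDB C2CP / C6 families they stand for); any other
#' label uses its first character, uppercased.
#'
#' @param collection A `gene_set_collection`.
#' @return A single character.
#' @export
collection_code <- function(collection) {
  lab <- tolower(collection$label %||% "x")
  switch(lab,
         canonical = "2",
         oncogenic = "6",
         toupper(substr(lab, 1L, 1L)))
}

#' Read a GMT gene set file
#'
#' Broad-dialect GMT: one set per line, tab-separated, fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are uppercased
#' on ingest; duplicates within a line are dropped with a warning. File order
#' is preserved.
#'
#' @param path Path to a GMT file.
#' @param label Collection label; defaults to the file name without extension.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, label = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    ps_log("warn", "empty GMT file: ", path)
    return(gene_set_collection(list(), label = label))
  }
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d in %s: expected >= 3 tab-separated fields", i, path))
    }
    genes <- toupper(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene symbol(s) in set '%s' (line %d); dropped", f[[1]], i))
      genes <- unique(genes)
    }
    nms[[i]] <- f[[1]]; desc[[i]] <- f[[2]]; sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set name(s) in GMT: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  gene_set_collection(setNames(sets, nms), setNames(desc, nms), label = label)
}

#' Write a gene set collection as GMT
#'
#' Canonical form: tab-separated, newline-terminated; round-trips byte-for-byte
#' with [read_gmt()] for files already in canonical form.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- expression matrices and clinical tables ---------------------------------

#' Validate an expression matrix
#'
#' Enforces the package's expression-matrix contract: numeric matrix, unique
#' uppercase gene row names, unique sample/cell column names, all values
#' finite, at least two columns. Values are assumed already log2-normalized;
#' no normalization is performed.
#'
#' @param x A numeric matrix (genes x samples or genes x cells).
#' @param what Label used in error messages.
#' @return The validated matrix (gene names uppercased).
#' @export
as_expression_matrix <- function(x, what = "expression") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " matrix must carry gene row names and sample column names")
  }
  rownames(x) <- toupper(rownames(x))
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (ncol(x) < 2L) stop(what, " matrix needs >= 2 columns")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(x)[bad[[1]]], colnames(x)[bad[[2]]]))
  }
  x
}

#' Validate a clinical survival table
#'
#' @param df Data frame with columns `sample`, `time`, `event` (0 censored,
#'   1 event) and optionally `group`.
#' @return A tibble of class `survival_table`.
#' @export
as_survival_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample identifier(s) in clinical table")
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time < 0)) {
    stop("survival times must be finite and >= 0")
  }
  if (!all(df$event %in% c(0, 1))) stop("event values must be 0 (censored) or 1 (event)")
  df$event <- as.integer(df$event)
  class(df) <- c("survival_table", class(df))
  df
}

#' Read a tab-separated matrix or clinical table
#'
#' TSV with a header row; the first column holds row identifiers. `kind =
#' "expression"` and `"single_cell"` return a validated numeric matrix;
#' `"clinical"` returns a [as_survival_table()] tibble (columns `sample`,
#' `time`, `event` required).
#'
#' @param path Path to a TSV file.
#' @param kind One of `"expression"`, `"clinical"`, `"single_cell"`.
#' @return Matrix or survival tibble, by `kind`.
#' @export
read_matrix <- function(path, kind = c("expression", "clinical", "single_cell")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (kind == "clinical") {
    if (!"sample" %in% names(df)) names(df)[1] <- "sample"
    return(as_survival_table(df))
  }
  ids <- as.character(df[[1]])
  num <- df[-1]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   num[[j]][bad[[1]]], ids[bad[[1]]], names(num)[[j]]))
    }
    num[[j]] <- v
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  as_expression_matrix(m, what = kind)
}

#' Write a matrix (or survival table) as TSV
#'
#' Inverse of [read_matrix()]: round-trips values at full precision and
#' preserves identifier order.
#'
#' @param x Matrix with row/col names, or a data frame.
#' @param path Output path.
#' @param id Name for the identifier column (matrices only).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path, id = "gene") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), format(x, digits = 17, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1] <- id
  } else {
    df <- as.data.frame(x)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
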