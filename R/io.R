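#' Read/write feature-by-sample tables as TSV
#'
#' Plain TSV with the feature id in the first column (`feature_id`) and
#' one column per sample; the transposed subject-level layers
#' (metadata, markers, immune, diet) are written with subjects as rows
#' by [write_cohort()].
#'
#' @param x matrix with row and column names.
#' @param path file path.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param integer_counts coerce the values to integer storage (count
#'   tables).
#' @export
read_feature_table <- function(path, integer_counts = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (integer_counts) storage.mode(m) <- "integer"
  m
}

#' Write the generated cohort layers to a directory
#'
#' Emits `metadata.tsv`, `markers.tsv`, `immune.tsv`, `diet.tsv`
#' (subjects as rows).
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (layer in c("markers", "immune", "diet")) {
    df <- data.frame(subject = rownames(cohort[[layer]]), cohort[[layer]],
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(layer, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read/write a gene-reaction-compound map as JSON
#'
#' Schema: `{"genes": {gene_id: [reaction_id, ...]}, "reactions":
#' {reaction_id: {"substrates": [...], "products": [...]}}}`.
#' @param map reaction map list.
#' @param path file path.
#' @export
write_reaction_map <- function(map, path) {
  check_reaction_map(map)
  jsonlite::write_json(map, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reaction_map
#' @export
read_reaction_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  map <- list(genes = as.list(raw$genes),
              reactions = lapply(raw$reactions, function(r) {
                list(substrates = unlist(r$substrates),
                     products = unlist(r$products))
              }))
  check_reaction_map(map)
  map
}

#' Write a module set as a two-column TSV plus JSON metadata
#' @param modules a [smd_modules()] result.
#' @param path TSV path; metadata goes to `<path>.json`.
#' @export
write_module_set <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  rows <- do.call(rbind, lapply(names(modules$modules), function(id) {
    data.frame(module = id, member = modules$modules[[id]])
  })) %||% data.frame(module = character(0), member = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- modules[c("method", "threshold", "r_is_squared", "linkage")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a fitted score model to JSON
#' @param model a [fit_score_model()] result.
#' @param path file path.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  jsonlite::write_json(lapply(unclass(model), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export an association network to GraphML (requires igraph)
#' @param network an [spearman_network()] result.
#' @param path output .graphml path.
#' @export
write_graphml <- function(network, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("igraph is required for GraphML export", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
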