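#' Construct a directed modality-interaction graph
#'
#' The graph determines which cross-attention modules the model instantiates:
#' each directed edge (source -> target) marks a known regulatory link and
#' yields one cross-attention in which the target's groups attend over the
#' source's groups. Self-loops are forbidden (an edge must connect two
#' distinct modalities); cycles and mutual edges are permitted, each edge
#' being an independent module.
#'
#' @param nodes Character vector of modality names.
#' @param edges List of length-2 character vectors `c(source, target)` (or a
#'   two-column matrix / data frame). Edge order is meaningful: it fixes the
#'   concatenation order of branches downstream and is serialized with the
#'   model.
#'
#' @return An object of class `modality_graph` with elements `nodes` and
#'   `edges` (list of `c(source, target)`).
#' @export
modality_graph <- function(nodes, edges = list()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort_("duplicate node names in graph")
  if (is.matrix(edges) || is.data.frame(edges)) {
    edges <- lapply(seq_len(nrow(edges)), function(i) as.character(edges[i, 1:2]))
  }
  edges <- lapply(edges, as.character)
  for (e in edges) {
    if (length(e) != 2L) abort_("each edge must be a (source, target) pair")
    if (e[1L] == e[2L]) {
      abort_("self-loop '", e[1L], "' -> '", e[2L],
             "' is not allowed: an interaction edge must connect two ",
             "distinct modalities (source != target)")
    }
    if (!all(e %in% nodes)) {
      abort_("edge endpoint(s) not in nodes: ",
             paste(setdiff(e, nodes), collapse = ", "))
    }
  }
  keys <- vapply(edges, paste, "", collapse = "->")
  if (anyDuplicated(keys)) {
    abort_("duplicate edge(s): ", paste(unique(keys[duplicated(keys)]),
                                        collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "modality_graph")
}

#' @export
print.modality_graph <- function(x, ...) {
  cat("<modality_graph> ", length(x$nodes), " nodes, ",
      length(x$edges), " edges\n", sep = "")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  for (e in x$edges) cat("  ", e[1L], " -> ", e[2L], "\n", sep = "")
  invisible(x)
}

#' Read a modality graph from a YAML or JSON config file
#'
#' The config must contain `nodes: [...]` and `edges: [[src, tgt], ...]`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `modality_graph`.
#' @export
read_modality_graph <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$nodes)) abort_("graph config must list 'nodes'")
  edges <- cfg$edges %||% list()
  edges <- lapply(edges, function(e) as.character(unlist(e)))
  modality_graph(unlist(cfg$nodes), edges)
}

#' Write a modality graph to a YAML config file
#' @param graph A `modality_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modality_graph <- function(graph, path) {
  yaml::write_yaml(list(nodes = as.list(graph$nodes),
                        edges = lapply(graph$edges, as.list)), path)
  invisible(path)
}

#' Modalities with zero in-degree
#'
#' Modalities that no edge targets enter the classifier as unimodal branches
#' (their encoder output is used directly).
#'
#' @param graph A `modality_graph`.
#' @return Character vector of node names with no incoming edge, in node
#'   (config) order.
#' @export
zero_indegree <- function(graph) {
  targets <- vapply(graph$edges, `[[`, "", 2L)
  graph$nodes[!graph$nodes %in% targets]
}

#' Group the graph's edges by target modality
#'
#' @param graph A `modality_graph`.
#' @return Named list: target -> character vector of sources, both in config
#'   (edge) order. Drives deterministic branch construction.
#' @export
edges_by_target <- function(graph) {
  out <- list()
  for (e in graph$edges) out[[e[2L]]] <- c(out[[e[2L]]], e[1L])
  out
}

#' Example modality-interaction graph for the bundled synthetic data
#'
#' A minimal three-modality chain (CNV -> mRNA -> protein) mirroring the
#' best-established regulatory links between those omics layers: copy-number
#' gains raise transcript abundance, and transcript abundance drives protein
#' abundance. This is a reconstruction of a plausible curated graph, not
#' ground truth for any particular cohort.
#'
#' @return A `modality_graph`.
#' @export
default_modality_graph <- function() {
  modality_graph(nodes = c("cnv", "mrna", "prot"),
                 edges = list(c("cnv", "mrna"), c("mrna", "prot")))
}
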