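# Serialization: GraphML (Cytoscape/graph-library compatible), FASTA
# genome export, native serialized objects, and the build report.
#
# GraphML node attributes follow the flattened per-isolate key scheme:
# name, sequence, ids (comma-separated), and one <isolate>_leftend /
# <isolate>_rightend long-integer pair per member isolate. Edges carry
# name and ids.

graphml_ns <- "http://graphml.graphdrawing.org/xmlns"

#' Export a genome graph as GraphML
#'
#' @param graph A `genome_graph`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "genome_graph"))
  doc <- xml2::xml_new_root("graphml", xmlns = graphml_ns)
  add_key <- function(id, dom, name, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        `attr.name` = name, `attr.type` = type)
  }
  add_key("g_isolates", "graph", "isolates", "string")
  for (nm in names(graph$metadata)) {
    add_key(paste0("meta_", nm), "graph", paste0("meta_", nm), "string")
  }
  add_key("n_name", "node", "name", "string")
  add_key("n_sequence", "node", "sequence", "string")
  add_key("n_ids", "node", "ids", "string")
  has_seq_len <- any(vapply(graph$nodes, function(nd) !is.null(nd$seq_len),
                            logical(1)))
  if (has_seq_len) add_key("n_seq_len", "node", "seq_len", "long")
  for (iso in graph$isolates) {
    add_key(paste0(iso, "_leftend"), "node", paste0(iso, "_leftend"), "long")
    add_key(paste0(iso, "_rightend"), "node", paste0(iso, "_rightend"), "long")
  }
  add_key("e_name", "edge", "name", "string")
  add_key("e_ids", "edge", "ids", "string")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  add_data <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_text(d) <- as.character(value)
  }
  add_data(g, "g_isolates", paste(graph$isolates, collapse = ","))
  for (nm in names(graph$metadata)) {
    add_data(g, paste0("meta_", nm), graph$metadata[[nm]])
  }
  fmt_coord <- function(x) sprintf("%d", as.integer(x))
  for (nd in graph$nodes) {
    xn <- xml2::xml_add_child(g, "node", id = nd$name)
    add_data(xn, "n_name", nd$name)
    add_data(xn, "n_sequence", nd$sequence)
    add_data(xn, "n_ids", paste(nd$ids, collapse = ","))
    if (!is.null(nd$seq_len)) add_data(xn, "n_seq_len", fmt_coord(nd$seq_len))
    for (iso in nd$ids) {
      add_data(xn, paste0(iso, "_leftend"), fmt_coord(nd$coords[[iso]][1]))
      add_data(xn, paste0(iso, "_rightend"), fmt_coord(nd$coords[[iso]][2]))
    }
  }
  for (e in graph$edges) {
    xe <- xml2::xml_add_child(g, "edge", source = e$source, target = e$target)
    add_data(xe, "e_name", e$name)
    add_data(xe, "e_ids", paste(sort(e$ids), collapse = ","))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a genome graph from GraphML
#'
#' Reverses [export_graphml()] exactly; files must carry the full node
#' attribute schema (a member isolate with a missing coordinate key is a
#' schema error naming the node).
#'
#' @param path GraphML file path.
#' @return A `genome_graph`.
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "./key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
  g <- xml2::xml_find_first(doc, "./graph")
  if (inherits(g, "xml_missing")) stop("no <graph> element in ", path, call. = FALSE)
  data_of <- function(el) {
    ds <- xml2::xml_find_all(el, "./data")
    stats::setNames(xml2::xml_text(ds),
                    key_name[xml2::xml_attr(ds, "key")])
  }
  gdata <- data_of(g)
  isolates <- if ("isolates" %in% names(gdata) && nzchar(gdata[["isolates"]])) {
    strsplit(gdata[["isolates"]], ",", fixed = TRUE)[[1]]
  } else character(0)
  meta_keys <- grep("^meta_", names(gdata), value = TRUE)
  metadata <- stats::setNames(as.list(unname(gdata[meta_keys])),
                              sub("^meta_", "", meta_keys))
  graph <- genome_graph(isolates, metadata)
  for (xn in xml2::xml_find_all(g, "./node")) {
    d <- data_of(xn)
    nm <- if ("name" %in% names(d)) d[["name"]] else xml2::xml_attr(xn, "id")
    if (!"sequence" %in% names(d)) {
      stop(sprintf("GraphML node '%s': missing sequence attribute", nm), call. = FALSE)
    }
    if (!"ids" %in% names(d)) {
      stop(sprintf("GraphML node '%s': missing ids attribute", nm), call. = FALSE)
    }
    ids <- strsplit(d[["ids"]], ",", fixed = TRUE)[[1]]
    coords <- list()
    for (iso in ids) {
      lk <- paste0(iso, "_leftend"); rk <- paste0(iso, "_rightend")
      if (!lk %in% names(d) || !rk %in% names(d)) {
        stop(sprintf("GraphML node '%s': missing %s/%s coordinate key", nm, lk, rk),
             call. = FALSE)
      }
      coords[[iso]] <- c(as.numeric(d[[lk]]), as.numeric(d[[rk]]))
    }
    nd <- sequence_node(nm, d[["sequence"]], ids, coords)
    if ("seq_len" %in% names(d)) nd$seq_len <- as.numeric(d[["seq_len"]])
    graph <- add_node(graph, nd)
  }
  for (xe in xml2::xml_find_all(g, "./edge")) {
    d <- data_of(xe)
    src <- xml2::xml_attr(xe, "source"); tgt <- xml2::xml_attr(xe, "target")
    ids <- if ("ids" %in% names(d)) strsplit(d[["ids"]], ",", fixed = TRUE)[[1]]
           else character(0)
    if (length(ids) == 0L) {
      stop(sprintf("GraphML edge %s -> %s: missing ids attribute", src, tgt),
           call. = FALSE)
    }
    graph <- add_edge(graph, src, tgt, ids)
  }
  graph
}

#' Save / load a genome graph as a native serialized object
#'
#' @param graph A `genome_graph`.
#' @param path File path (`.rds`).
#' @return `save_graph`: the path, invisibly. `load_graph`: the graph.
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "genome_graph"))
  saveRDS(graph, path)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "genome_graph")) stop("not a serialized genome_graph: ", path,
                                         call. = FALSE)
  g
}

#' Export one isolate's genome as FASTA
#'
#' Writes the reconstructed genome wrapped at 70 columns under the
#' header `><isolate>`.
#'
#' @param graph A `genome_graph`.
#' @param isolate Isolate name.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_fasta <- function(graph, isolate, path) {
  if (!isolate %in% graph$isolates) {
    stop(sprintf("unknown isolate '%s'", isolate), call. = FALSE)
  }
  seqs <- stats::setNames(reconstruct_sequence(graph, isolate), isolate)
  write_fasta(seqs, path, width = 70L)
  invisible(path)
}

#' Summary report of a genome graph
#'
#' Node and edge counts, average in/out degree, total node sequence
#' length, directed-graph density, and per-isolate genome lengths.
#'
#' @param graph A `genome_graph`.
#' @return A `graph_report` list.
#' @export
generate_report <- function(graph) {
  stopifnot(inherits(graph, "genome_graph"))
  n <- length(graph$nodes); m <- length(graph$edges)
  glens <- vapply(stats::setNames(graph$isolates, graph$isolates),
                  function(iso) genome_length(graph, iso), numeric(1))
  structure(list(
    n_nodes = n,
    n_edges = m,
    avg_in_degree = if (n > 0) m / n else 0,
    avg_out_degree = if (n > 0) m / n else 0,
    total_node_sequence_length =
      sum(vapply(graph$nodes, function(nd) nchar(nd$sequence), numeric(1))),
    density = if (n >= 2) m / (n * (n - 1)) else 0,
    genome_lengths = glens), class = "graph_report")
}

#' @export
format.graph_report <- function(x, ...) {
  lines <- c(
    "Genome graph report",
    sprintf("  Number of nodes: %d", x$n_nodes),
    sprintf("  Number of edges: %d", x$n_edges),
    sprintf("  Average in degree: %.4f", x$avg_in_degree),
    sprintf("  Average out degree: %.4f", x$avg_out_degree),
    sprintf("  Total sequence length of all nodes: %d",
            as.integer(x$total_node_sequence_length)),
    sprintf("  Density: %.6f", x$density),
    "  Genome lengths:")
  for (iso in names(x$genome_lengths)) {
    lines <- c(lines, sprintf("    %s: %d", iso, as.integer(x$genome_lengths[[iso]])))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.graph_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a graph report as plain text
#' @param report A `graph_report` (or a `genome_graph`, reported first).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "genome_graph")) report <- generate_report(report)
  stopifnot(inherits(report, "graph_report"))
  writeLines(format(report), path)
  invisible(path)
}
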