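# The genome-graph data model.
#
# A genome graph is a directed sequence graph in which every node holds a
# sub-sequence homologous between the member isolates, together with the
# 1-based inclusive genomic interval that sub-sequence occupies in each
# isolate.  Each isolate's genome is a labelled walk through the graph:
# concatenating node sequences along the walk (reverse-complementing nodes
# traversed in inverted orientation) reproduces the genome exactly.
#
# Inversions are encoded in the coordinates: a segment occupying
# forward-strand positions [s, e] of an isolate, present in the node in the
# opposite orientation, is stored as leftend = -e, rightend = -s.  The
# values are both negated and reversed, so abs(leftend) >= abs(rightend)
# is a machine-checkable inversion flag.

#' Create a sequence node
#'
#' @param name Unique node identifier (e.g. `"Aln_66_3"`).
#' @param sequence Uppercase nucleotide string (IUPAC codes allowed, no
#'   gap characters), length >= 1. Stored in the orientation of the first
#'   member isolate (graph isolate order), which always has positive
#'   coordinates.
#' @param ids Character vector of member isolate names (non-empty).
#' @param coords Named list, one entry per member of `ids`, each a
#'   length-2 numeric `c(leftend, rightend)`. Positive 1-based inclusive
#'   for forward occurrences; negative and reversed (`-end, -start`) for
#'   inverted occurrences.
#' @return A `sequence_node` object.
#' @export
sequence_node <- function(name, sequence, ids, coords) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("node name must be a non-empty string", call. = FALSE)
  }
  sequence <- clean_sequence(sequence, what = sprintf("node '%s' sequence", name))
  if (nchar(sequence) < 1L) {
    stop(sprintf("node '%s': sequence must have length >= 1", name), call. = FALSE)
  }
  ids <- as.character(ids)
  if (length(ids) < 1L || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop(sprintf("node '%s': ids must be a non-empty set of isolate names", name),
         call. = FALSE)
  }
  if (!is.list(coords) || !setequal(names(coords), ids) ||
      length(coords) != length(ids)) {
    stop(sprintf("node '%s': coords must have exactly one entry per member of ids", name),
         call. = FALSE)
  }
  len <- nchar(sequence)
  for (iso in ids) {
    cc <- as.numeric(coords[[iso]])
    if (length(cc) != 2L || any(is.na(cc)) || any(cc != trunc(cc)) || any(cc == 0)) {
      stop(sprintf("node '%s', isolate '%s': coords must be two non-zero integers",
                   name, iso), call. = FALSE)
    }
    l <- cc[1]; r <- cc[2]
    if (l > 0 && r > 0) {
      if (l > r) {
        stop(sprintf("node '%s', isolate '%s': forward occurrence requires leftend <= rightend",
                     name, iso), call. = FALSE)
      }
      if (r - l + 1 != len) {
        stop(sprintf(
          "node '%s', isolate '%s': interval span %d does not equal sequence length %d",
          name, iso, as.integer(r - l + 1), as.integer(len)), call. = FALSE)
      }
    } else if (l < 0 && r < 0) {
      if (abs(l) < abs(r)) {
        stop(sprintf("node '%s', isolate '%s': inverted occurrence requires |leftend| >= |rightend|",
                     name, iso), call. = FALSE)
      }
      if (abs(l) - abs(r) + 1 != len) {
        stop(sprintf(
          "node '%s', isolate '%s': inverted interval span %d does not equal sequence length %d",
          name, iso, as.integer(abs(l) - abs(r) + 1), as.integer(len)), call. = FALSE)
      }
    } else {
      stop(sprintf("node '%s', isolate '%s': leftend and rightend must share a sign",
                   name, iso), call. = FALSE)
    }
    coords[[iso]] <- c(leftend = l, rightend = r)
  }
  structure(list(name = name, sequence = sequence, ids = ids,
                 coords = coords[ids]),
            class = "sequence_node")
}

node_is_inverted <- function(node, isolate) node$coords[[isolate]][1] < 0

# Forward-strand (absolute) genomic interval of a node in one isolate.
node_interval <- function(node, isolate) {
  cc <- node$coords[[isolate]]
  sort(abs(cc))
}

#' Create an empty genome graph
#'
#' @param isolates Ordered character vector of isolate names.
#' @param metadata Named list of build metadata strings.
#' @return A `genome_graph` with no nodes or edges.
#' @export
genome_graph <- function(isolates = character(), metadata = list()) {
  isolates <- as.character(isolates)
  if (anyDuplicated(isolates)) stop("duplicate isolate names", call. = FALSE)
  structure(list(nodes = list(), edges = list(), isolates = isolates,
                 metadata = metadata),
            class = "genome_graph")
}

#' @export
print.genome_graph <- function(x, ...) {
  cat(sprintf("genome_graph: %d node(s), %d edge(s), %d isolate(s)\n",
              length(x$nodes), length(x$edges), length(x$isolates)))
  if (length(x$isolates)) {
    cat("  isolates:", paste(x$isolates, collapse = ", "), "\n")
  }
  invisible(x)
}

edge_key <- function(source, target) paste0(source, "\r", target)

#' Edge name following the node-pair naming scheme
#' @param source,target Node names.
#' @return `"<source> (-) <target>"`.
#' @export
edge_name <- function(source, target) paste0(source, " (-) ", target)

#' Add a node to a genome graph
#'
#' Validates the node against the graph: unique name, member isolates
#' known to the graph.
#'
#' @param graph A `genome_graph`.
#' @param node A `sequence_node` (or the arguments to build one, passed on
#'   to [sequence_node()]).
#' @return The updated graph.
#' @export
add_node <- function(graph, node) {
  stopifnot(inherits(graph, "genome_graph"))
  if (!inherits(node, "sequence_node")) {
    stop("node must be a sequence_node", call. = FALSE)
  }
  if (!is.null(graph$nodes[[node$name]])) {
    stop(sprintf("duplicate node name '%s'", node$name), call. = FALSE)
  }
  unknown <- setdiff(node$ids, graph$isolates)
  if (length(unknown) > 0L) {
    stop(sprintf("node '%s': ids not among graph isolates: %s",
                 node$name, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  graph$nodes[[node$name]] <- node
  graph
}

#' Add (or extend) a directed edge
#'
#' Edges are named `"<source> (-) <target>"` and carry the set of isolates
#' whose walks use them. Adding an edge that already exists unions the
#' isolate sets. Self-loops are rejected: the graph never represents
#' repeats by loops.
#'
#' @param graph A `genome_graph`.
#' @param source,target Names of existing nodes.
#' @param ids Isolates using the edge; must be members of both endpoints.
#' @return The updated graph.
#' @export
add_edge <- function(graph, source, target, ids) {
  stopifnot(inherits(graph, "genome_graph"))
  if (source == target) {
    stop(sprintf("self-loop rejected on node '%s'", source), call. = FALSE)
  }
  for (nm in c(source, target)) {
    if (is.null(graph$nodes[[nm]])) {
      stop(sprintf("edge endpoint '%s' is not a node in the graph", nm), call. = FALSE)
    }
  }
  ids <- as.character(ids)
  if (length(ids) < 1L) stop("edge ids must be non-empty", call. = FALSE)
  allowed <- intersect(graph$nodes[[source]]$ids, graph$nodes[[target]]$ids)
  bad <- setdiff(ids, allowed)
  if (length(bad) > 0L) {
    stop(sprintf("edge %s: ids not shared by both endpoints: %s",
                 edge_name(source, target), paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  key <- edge_key(source, target)
  old <- graph$edges[[key]]
  if (is.null(old)) {
    graph$edges[[key]] <- list(source = source, target = target,
                               name = edge_name(source, target),
                               ids = ids)
  } else {
    graph$edges[[key]]$ids <- union(old$ids, ids)
  }
  graph
}

# TRUE if an edge labelled `isolate` joins u and v in either direction.
has_walk_edge <- function(graph, u, v, isolate) {
  for (key in c(edge_key(u, v), edge_key(v, u))) {
    e <- graph$edges[[key]]
    if (!is.null(e) && isolate %in% e$ids) return(TRUE)
  }
  FALSE
}

#' Genome length of an isolate encoded in the graph
#' @param graph A `genome_graph`.
#' @param isolate Isolate name.
#' @return Total length tiled by the isolate's walk.
#' @export
genome_length <- function(graph, isolate) {
  idx <- walk_index(graph, isolate, validate = FALSE)
  if (nrow(idx) == 0L) return(0L)
  max(idx$hi)
}

# Per-isolate node index: one row per node containing the isolate, sorted
# by genomic position, with absolute interval [lo, hi] and orientation.
walk_index <- function(graph, isolate, validate = TRUE) {
  stopifnot(inherits(graph, "genome_graph"))
  if (!isolate %in% graph$isolates) {
    stop(sprintf("unknown isolate '%s'", isolate), call. = FALSE)
  }
  keep <- vapply(graph$nodes, function(nd) isolate %in% nd$ids, logical(1))
  nodes <- graph$nodes[keep]
  n <- length(nodes)
  if (n == 0L) {
    return(data.frame(node = character(), lo = numeric(), hi = numeric(),
                      inverted = logical(), stringsAsFactors = FALSE))
  }
  lo <- numeric(n); hi <- numeric(n); inv <- logical(n)
  for (i in seq_len(n)) {
    iv <- node_interval(nodes[[i]], isolate)
    lo[i] <- iv[1]; hi[i] <- iv[2]
    inv[i] <- node_is_inverted(nodes[[i]], isolate)
  }
  ord <- order(lo)
  idx <- data.frame(node = names(nodes)[ord], lo = lo[ord], hi = hi[ord],
                    inverted = inv[ord], stringsAsFactors = FALSE)
  if (validate) {
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        if (idx$lo[i + 1L] != idx$hi[i] + 1) {
          stop(sprintf(
            "isolate '%s': coordinate %s between nodes '%s' [%d,%d] and '%s' [%d,%d]",
            isolate,
            if (idx$lo[i + 1L] > idx$hi[i] + 1) "gap" else "overlap",
            idx$node[i], as.integer(idx$lo[i]), as.integer(idx$hi[i]),
            idx$node[i + 1L], as.integer(idx$lo[i + 1L]), as.integer(idx$hi[i + 1L])),
            call. = FALSE)
        }
        if (!has_walk_edge(graph, idx$node[i], idx$node[i + 1L], isolate)) {
          stop(sprintf("isolate '%s': missing edge between consecutive walk nodes '%s' and '%s'",
                       isolate, idx$node[i], idx$node[i + 1L]), call. = FALSE)
        }
      }
    }
  }
  idx
}

#' Walk of an isolate through the graph
#'
#' The nodes containing the isolate, in ascending genomic order, with the
#' orientation in which the walk traverses each node. Errors if the walk
#' is structurally broken (coordinate gap/overlap or missing edge).
#'
#' @param graph A `genome_graph`.
#' @param isolate Isolate name.
#' @return `data.frame` with columns `node` and `orientation`
#'   (`"forward"`/`"inverted"`).
#' @export
isolate_walk <- function(graph, isolate) {
  idx <- walk_index(graph, isolate, validate = TRUE)
  data.frame(node = idx$node,
             orientation = ifelse(idx$inverted, "inverted", "forward"),
             stringsAsFactors = FALSE)
}

#' Reconstruct an isolate's genome from its walk
#'
#' Concatenates node sequences along the isolate's walk,
#' reverse-complementing nodes traversed in inverted orientation.
#'
#' @param graph A `genome_graph`.
#' @param isolate Isolate name.
#' @return The genome sequence as a single string.
#' @export
reconstruct_sequence <- function(graph, isolate) {
  idx <- walk_index(graph, isolate, validate = TRUE)
  if (nrow(idx) == 0L) return("")
  pieces <- character(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    s <- graph$nodes[[idx$node[i]]]$sequence
    pieces[i] <- if (idx$inverted[i]) revcomp(s) else s
  }
  paste(pieces, collapse = "")
}

#' Validate all genome-graph invariants
#'
#' Checks node-level coordinate invariants, edge id containment, absence
#' of self-loops, and per-isolate walk integrity (tiling + edges).
#'
#' @param graph A `genome_graph`.
#' @return Invisibly `TRUE`; errors describing the first violated
#'   invariant otherwise.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "genome_graph"))
  for (nd in graph$nodes) {
    sequence_node(nd$name, nd$sequence, nd$ids, nd$coords)
    unknown <- setdiff(nd$ids, graph$isolates)
    if (length(unknown) > 0L) {
      stop(sprintf("node '%s': unknown isolates %s", nd$name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  for (e in graph$edges) {
    if (e$source == e$target) {
      stop(sprintf("self-loop on '%s'", e$source), call. = FALSE)
    }
    allowed <- intersect(graph$nodes[[e$source]]$ids, graph$nodes[[e$target]]$ids)
    if (length(setdiff(e$ids, allowed)) > 0L) {
      stop(sprintf("edge %s: ids exceed endpoint intersection", e$name), call. = FALSE)
    }
  }
  for (iso in graph$isolates) {
    idx <- walk_index(graph, iso, validate = TRUE)
    if (nrow(idx) > 0L && idx$lo[1] != 1) {
      stop(sprintf("isolate '%s': walk does not start at position 1 (first node '%s' starts at %d)",
                   iso, idx$node[1], as.integer(idx$lo[1])), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Nodes of a graph as a data frame
#'
#' One row per node with name, sequence, comma-separated ids, and one
#' `<isolate>_leftend` / `<isolate>_rightend` column pair per graph
#' isolate (NA when the isolate is absent from the node).
#'
#' @param graph A `genome_graph`.
#' @return A `data.frame`.
#' @export
node_table <- function(graph) {
  nodes <- graph$nodes
  df <- data.frame(name = vapply(nodes, `[[`, character(1), "name"),
                   sequence = vapply(nodes, `[[`, character(1), "sequence"),
                   ids = vapply(nodes, function(nd) paste(nd$ids, collapse = ","),
                                character(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  for (iso in graph$isolates) {
    df[[paste0(iso, "_leftend")]] <- vapply(nodes, function(nd) {
      if (iso %in% nd$ids) nd$coords[[iso]][1] else NA_real_
    }, numeric(1))
    df[[paste0(iso, "_rightend")]] <- vapply(nodes, function(nd) {
      if (iso %in% nd$ids) nd$coords[[iso]][2] else NA_real_
    }, numeric(1))
  }
  df
}

#' Edges of a graph as a data frame
#' @param graph A `genome_graph`.
#' @return A `data.frame` with columns source, target, name, ids.
#' @export
edge_table <- function(graph) {
  edges <- graph$edges
  data.frame(source = vapply(edges, `[[`, character(1), "source"),
             target = vapply(edges, `[[`, character(1), "target"),
             name = vapply(edges, `[[`, character(1), "name"),
             ids = vapply(edges, function(e) paste(sort(e$ids), collapse = ","),
                          character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
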