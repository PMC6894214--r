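# Downstream analyses on a built genome graph: sub-sequence and gene
# extraction, coordinate translation between isolates, conserved-region
# queries, and position-based (graph-footprint) gene homology.

# Locate the node covering genomic position `pos` of `isolate`; returns
# the walk_index row.
locate_node <- function(idx, pos, isolate) {
  i <- findInterval(pos, idx$lo)
  if (i < 1L || pos > idx$hi[i]) {
    stop(sprintf("position %d outside isolate '%s' genome [1,%d]",
                 as.integer(pos), isolate, as.integer(max(idx$hi))), call. = FALSE)
  }
  idx[i, , drop = FALSE]
}

#' Extract a sub-sequence of an isolate's genome from the graph
#'
#' Locates the nodes overlapping `[start, end]` in the isolate's walk and
#' slices them directly (reverse-complementing inverted occurrences),
#' without reconstructing the whole genome.
#'
#' @param graph A `genome_graph`.
#' @param isolate Isolate name.
#' @param start,end 1-based inclusive forward-strand coordinates.
#' @return The forward-strand sub-sequence.
#' @export
extract_subsequence <- function(graph, isolate, start, end) {
  idx <- walk_index(graph, isolate, validate = FALSE)
  if (nrow(idx) == 0L) stop(sprintf("isolate '%s' absent from graph", isolate),
                            call. = FALSE)
  L <- max(idx$hi)
  if (!(start >= 1 && start <= end && end <= L)) {
    stop(sprintf("interval [%s,%s] out of range for isolate '%s' (length %d)",
                 format(start), format(end), isolate, as.integer(L)), call. = FALSE)
  }
  hit <- which(idx$hi >= start & idx$lo <= end)
  pieces <- character(length(hit))
  for (p in seq_along(hit)) {
    i <- hit[p]
    a <- max(start, idx$lo[i]); b <- min(end, idx$hi[i])
    sq <- graph$nodes[[idx$node[i]]]$sequence
    if (!idx$inverted[i]) {
      pieces[p] <- substr(sq, a - idx$lo[i] + 1, b - idx$lo[i] + 1)
    } else {
      # node sequence is the reverse complement of the forward segment
      e <- idx$hi[i]
      pieces[p] <- revcomp(substr(sq, e - b + 1, e - a + 1))
    }
  }
  paste(pieces, collapse = "")
}

#' Extract the sequence of an annotated feature
#'
#' @param graph A `genome_graph`.
#' @param feature One feature record: a list or one-row data frame with
#'   fields `isolate`, `start`, `end`, `strand` (see [read_features()]).
#' @return The feature sequence; reverse-complemented for `-` strand
#'   features.
#' @export
extract_gene_sequence <- function(graph, feature) {
  feature <- as.list(feature)
  s <- extract_subsequence(graph, feature$isolate, feature$start, feature$end)
  if (identical(feature$strand, "-")) revcomp(s) else s
}

#' Extract the subgraph covering a feature
#'
#' The induced subgraph covering the feature: all nodes whose interval
#' for the feature's isolate intersects `[start, end]`, plus, for every
#' other isolate, the nodes falling inside the genomic span those
#' shared nodes anchor in it (so parallel variant and insertion nodes
#' of the other isolates are included). A `seq_len` attribute (node
#' sequence length) is attached to every node for export and
#' visualisation. A single-node subgraph whose ids hold every isolate
#' means the gene is identical across all of them.
#'
#' @param graph A `genome_graph`.
#' @param feature Feature record as in [extract_gene_sequence()].
#' @return A `genome_graph` (subgraph; walks restricted to the region).
#' @export
extract_gene_subgraph <- function(graph, feature) {
  feature <- as.list(feature)
  isolate <- feature$isolate
  idx <- walk_index(graph, isolate, validate = FALSE)
  if (nrow(idx) == 0L) stop(sprintf("isolate '%s' absent from graph", isolate),
                            call. = FALSE)
  L <- max(idx$hi)
  if (!(feature$start >= 1 && feature$start <= feature$end && feature$end <= L)) {
    stop(sprintf("feature [%s,%s] out of range for isolate '%s'",
                 format(feature$start), format(feature$end), isolate), call. = FALSE)
  }
  keep <- idx$node[idx$hi >= feature$start & idx$lo <= feature$end]
  # anchor span per other isolate: the region its walk covers between
  # the shared nodes, pulling in parallel variant/insertion nodes
  for (iso2 in setdiff(graph$isolates, isolate)) {
    spans <- unlist(lapply(keep, function(nm) {
      nd <- graph$nodes[[nm]]
      if (iso2 %in% nd$ids) node_interval(nd, iso2) else NULL
    }))
    if (is.null(spans)) next
    idx2 <- walk_index(graph, iso2, validate = FALSE)
    extra <- idx2$node[idx2$lo >= min(spans) & idx2$hi <= max(spans)]
    keep <- union(keep, extra)
  }
  sub <- genome_graph(graph$isolates, graph$metadata)
  for (nm in keep) {
    nd <- graph$nodes[[nm]]
    nd$seq_len <- nchar(nd$sequence)
    sub$nodes[[nm]] <- nd
  }
  for (e in graph$edges) {
    if (e$source %in% keep && e$target %in% keep) {
      sub$edges[[edge_key(e$source, e$target)]] <- e
    }
  }
  sub
}

#' Translate a genomic position between isolates
#'
#' Finds the node and within-node offset of `pos` in `from_isolate`; if
#' `to_isolate` is also a member of that node, returns its coordinate at
#' the homologous offset. The result is negative when the target
#' isolate's occurrence of the node is inverted (its forward-strand
#' position is the absolute value). Positions falling in nodes private
#' to other isolates (e.g. inside an insertion) return `NA`: coordinates
#' are never interpolated.
#'
#' @param graph A `genome_graph`.
#' @param pos 1-based position in `from_isolate`.
#' @param from_isolate,to_isolate Isolate names.
#' @return Signed position in `to_isolate`, or `NA` if the position has
#'   no homologous base there.
#' @export
translate_position <- function(graph, pos, from_isolate, to_isolate) {
  idx <- walk_index(graph, from_isolate, validate = FALSE)
  if (nrow(idx) == 0L) stop(sprintf("isolate '%s' absent from graph", from_isolate),
                            call. = FALSE)
  row <- locate_node(idx, pos, from_isolate)
  nd <- graph$nodes[[row$node]]
  if (!to_isolate %in% graph$isolates) {
    stop(sprintf("unknown isolate '%s'", to_isolate), call. = FALSE)
  }
  if (!to_isolate %in% nd$ids) return(NA_real_)
  # offset of the homologous base in node-sequence space
  o <- if (row$inverted) row$hi - pos else pos - row$lo
  cc <- nd$coords[[to_isolate]]
  if (cc[1] > 0) {
    unname(cc[1] + o)
  } else {
    e <- abs(cc[1])
    unname(-(e - o))
  }
}

#' Largest node common to all isolates
#'
#' The longest uninterrupted sequence shared by every isolate: among
#' nodes whose ids contain all graph isolates, the one with the longest
#' sequence (ties broken by the alphabetically smallest name).
#'
#' @param graph A non-empty `genome_graph`.
#' @return The winning `sequence_node`, or `NULL` when no node is
#'   universal.
#' @export
largest_conserved_node <- function(graph) {
  stopifnot(inherits(graph, "genome_graph"))
  if (length(graph$nodes) == 0L) stop("empty graph", call. = FALSE)
  univ <- Filter(function(nd) setequal(nd$ids, graph$isolates), graph$nodes)
  if (length(univ) == 0L) return(NULL)
  lens <- vapply(univ, function(nd) nchar(nd$sequence), numeric(1))
  nms <- vapply(univ, `[[`, character(1), "name")
  univ[[order(-lens, nms)[1]]]
}

#' Short isolate-specific nodes (candidate private SNPs)
#'
#' Nodes with sequence length strictly less than `max_len` belonging to
#' a single isolate, sorted by isolate then genomic coordinate. With the
#' default `max_len = 3` these are isolate-specific SNPs and micro-indels.
#'
#' @param graph A `genome_graph`.
#' @param max_len Strict upper bound on node length (default 3).
#' @param exclusive If `TRUE` (default) keep only single-isolate nodes;
#'   if `FALSE`, keep every node shorter than `max_len`.
#' @return List of `sequence_node`s.
#' @export
isolate_specific_nodes <- function(graph, max_len = 3, exclusive = TRUE) {
  stopifnot(max_len >= 1)
  keep <- Filter(function(nd) {
    nchar(nd$sequence) < max_len && (!exclusive || length(nd$ids) == 1L)
  }, graph$nodes)
  if (length(keep) == 0L) return(list())
  iso <- vapply(keep, function(nd) min(nd$ids), character(1))
  pos <- vapply(keep, function(nd) min(abs(nd$coords[[min(nd$ids)]])), numeric(1))
  unname(keep[order(iso, pos)])
}

# Footprint of a feature: per overlapped node, the within-node offset
# interval (0-based, node-sequence orientation) covered by the feature.
gene_footprint <- function(graph, isolate, start, end) {
  idx <- walk_index(graph, isolate, validate = FALSE)
  L <- max(idx$hi)
  if (!(start >= 1 && start <= end && end <= L)) {
    stop(sprintf("annotation [%s,%s] outside isolate '%s' genome [1,%d]",
                 format(start), format(end), isolate, as.integer(L)), call. = FALSE)
  }
  hit <- which(idx$hi >= start & idx$lo <= end)
  out <- list()
  for (i in hit) {
    a <- max(start, idx$lo[i]); b <- min(end, idx$hi[i])
    o <- if (idx$inverted[i]) c(idx$hi[i] - b, idx$hi[i] - a) else
      c(a - idx$lo[i], b - idx$lo[i])
    out[[idx$node[i]]] <- o
  }
  out
}

footprint_shared <- function(fa, fb) {
  shared <- 0
  for (nm in intersect(names(fa), names(fb))) {
    ov <- min(fa[[nm]][2], fb[[nm]][2]) - max(fa[[nm]][1], fb[[nm]][1]) + 1
    if (ov > 0) shared <- shared + ov
  }
  shared
}

#' Position-based gene homology matrix
#'
#' Maps gene identifiers between isolates by shared graph footprint
#' rather than sequence similarity: two genes match when the length of
#' graph sequence their footprints share is at least
#' `overlap_threshold` of the shorter gene. Matching per isolate pair is
#' one-to-one, greedy by descending shared length (ties by gene id), so
#' high-identity paralogues at distinct loci map to their positional
#' counterparts.
#'
#' @param graph A `genome_graph`.
#' @param annotations Named list, isolate -> feature data frame (columns
#'   `gene_id`, `start`, `end`, `strand`; see [read_features()]).
#' @param reference Reference isolate whose genes form the rows
#'   (default: first annotated isolate in graph order).
#' @param overlap_threshold Minimum shared fraction of the shorter
#'   footprint (default 0.5).
#' @return A `data.frame`, rows = reference gene ids, one column per
#'   annotated isolate holding the orthologous gene id or `NA`.
#' @export
homology_matrix <- function(graph, annotations, reference = NULL,
                            overlap_threshold = 0.5) {
  stopifnot(inherits(graph, "genome_graph"), is.list(annotations))
  isos <- graph$isolates[graph$isolates %in% names(annotations)]
  if (length(isos) == 0L) stop("no annotated isolate is present in the graph",
                               call. = FALSE)
  reference <- reference %||% isos[1]
  if (!reference %in% isos) {
    stop(sprintf("reference isolate '%s' has no annotations", reference),
         call. = FALSE)
  }
  fps <- lapply(stats::setNames(isos, isos), function(iso) {
    ann <- annotations[[iso]]
    fp <- lapply(seq_len(nrow(ann)), function(i) {
      gene_footprint(graph, iso, ann$start[i], ann$end[i])
    })
    stats::setNames(fp, ann$gene_id)
  })
  lens <- lapply(fps, function(fp) {
    vapply(fp, function(f) sum(vapply(f, function(o) o[2] - o[1] + 1, numeric(1))),
           numeric(1))
  })
  ref_genes <- names(fps[[reference]])
  out <- data.frame(row.names = ref_genes)
  for (iso in isos) {
    col <- stats::setNames(rep(NA_character_, length(ref_genes)), ref_genes)
    # all candidate pairs above threshold
    cand <- list()
    for (g in ref_genes) {
      for (h in names(fps[[iso]])) {
        sh <- footprint_shared(fps[[reference]][[g]], fps[[iso]][[h]])
        if (sh >= overlap_threshold * min(lens[[reference]][[g]], lens[[iso]][[h]])) {
          cand[[length(cand) + 1L]] <- list(g = g, h = h, shared = sh)
        }
      }
    }
    if (length(cand) > 0L) {
      sh <- vapply(cand, `[[`, numeric(1), "shared")
      gs <- vapply(cand, `[[`, character(1), "g")
      hs <- vapply(cand, `[[`, character(1), "h")
      used_h <- character(0)
      for (i in order(-sh, gs, hs)) {
        if (is.na(col[[gs[i]]]) && !hs[i] %in% used_h) {
          col[[gs[i]]] <- hs[i]
          used_h <- c(used_h, hs[i])
        }
      }
    }
    out[[iso]] <- unname(col)
  }
  out
}

#' Write a homology matrix as TSV
#' @param mat Result of [homology_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_homology_matrix <- function(mat, path) {
  utils::write.table(cbind(gene_id = rownames(mat), mat), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
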