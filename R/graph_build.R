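# Two-stage graph construction: a structural graph of co-linear blocks,
# then per-block realignment and collapse into shared-sequence nodes that
# are spliced back in place of the temporary block nodes.

#' Block decomposition of a genome set
#'
#' @param blocks List of [aligned_block()]s.
#' @param genome_lengths Named numeric vector, isolate -> genome length.
#' @param isolates Ordered isolate names (defaults to
#'   `names(genome_lengths)`).
#' @return A `block_decomposition`; errors if, for any isolate, the
#'   forward-strand row intervals across blocks fail to tile
#'   `[1, genome_length]` disjointly.
#' @export
block_decomposition <- function(blocks, genome_lengths,
                                isolates = names(genome_lengths)) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  ids <- vapply(blocks, `[[`, character(1), "block_id")
  if (anyDuplicated(ids)) stop("duplicate block ids", call. = FALSE)
  for (iso in isolates) {
    ivs <- list()
    for (b in blocks) {
      for (r in b$rows) {
        if (r$isolate == iso) ivs[[length(ivs) + 1L]] <- c(r$start, r$end, b$block_id)
      }
    }
    if (length(ivs) == 0L) {
      stop(sprintf("isolate '%s' appears in no block", iso), call. = FALSE)
    }
    starts <- vapply(ivs, function(v) as.numeric(v[1]), numeric(1))
    ends <- vapply(ivs, function(v) as.numeric(v[2]), numeric(1))
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    bl <- vapply(ivs, function(v) v[3], character(1))[ord]
    if (starts[1] != 1) {
      stop(sprintf("isolate '%s': blocks do not cover position 1", iso), call. = FALSE)
    }
    if (length(starts) > 1L) {
      for (i in seq_len(length(starts) - 1L)) {
        if (starts[i + 1L] <= ends[i]) {
          stop(sprintf("isolate '%s': blocks %s and %s overlap", iso,
                       bl[i], bl[i + 1L]), call. = FALSE)
        }
        if (starts[i + 1L] != ends[i] + 1) {
          stop(sprintf("isolate '%s': coverage gap [%d,%d] between blocks %s and %s",
                       iso, as.integer(ends[i] + 1), as.integer(starts[i + 1L] - 1),
                       bl[i], bl[i + 1L]), call. = FALSE)
        }
      }
    }
    if (ends[length(ends)] != genome_lengths[[iso]]) {
      stop(sprintf("isolate '%s': blocks end at %d, genome length is %d",
                   iso, as.integer(ends[length(ends)]),
                   as.integer(genome_lengths[[iso]])), call. = FALSE)
    }
  }
  structure(list(blocks = blocks,
                 genome_lengths = genome_lengths[isolates],
                 isolates = as.character(isolates)),
            class = "block_decomposition")
}

# Flip a whole block: reverse columns, complement characters, swap
# strand flags. Used to normalise blocks so the first graph isolate
# present is always on the '+' strand.
flip_block <- function(block) {
  rows <- lapply(block$rows, function(r) {
    r$gapped_seq <- revcomp(r$gapped_seq)
    r$strand <- if (r$strand == "+") "-" else "+"
    r
  })
  aligned_block(block$block_id, rows)
}

normalize_block_orientation <- function(block, isolates) {
  present <- block_isolates(block)
  first <- isolates[isolates %in% present][1]
  r <- block$rows[[match(first, present)]]
  if (r$strand == "-") flip_block(block) else block
}

#' Parse an XMFA co-linear block decomposition
#'
#' Reads the XMFA dialect emitted by whole-genome aligners
#' (progressiveMauve style): `> seqnum:start-end strand comment` record
#' headers within each alignment block, blocks terminated by `=` lines.
#' Coordinates are forward-strand 1-based inclusive; a `-` strand row's
#' alignment text is the reverse complement of the forward-strand
#' segment. Sequence numbers are mapped to isolate names by the order of
#' `genomes`. Regions of a genome covered by no block are synthesised
#' into single-isolate blocks so that every genome is fully tiled.
#'
#' @param path XMFA file path.
#' @param genomes Named character vector of genome sequences in the
#'   order the aligner numbered them (see [read_genomes()]).
#' @return A [block_decomposition()].
#' @export
parse_xmfa <- function(path, genomes) {
  if (!file.exists(path)) stop("XMFA file not found: ", path, call. = FALSE)
  genomes <- vapply(genomes, clean_sequence, character(1), what = "genome")
  isolates <- names(genomes)
  lines <- readLines(path)
  blocks <- list()
  cur_rows <- list()
  cur_meta <- NULL
  cur_seq <- character()
  flush_row <- function() {
    if (is.null(cur_meta)) return()
    seqtext <- toupper(paste(cur_seq, collapse = ""))
    cur_rows[[length(cur_rows) + 1L]] <<- c(cur_meta, list(gapped_seq = seqtext))
    cur_meta <<- NULL; cur_seq <<- character()
  }
  flush_block <- function() {
    flush_row()
    if (length(cur_rows) > 0L) {
      k <- length(blocks) + 1L
      blocks[[k]] <<- aligned_block(paste0("Aln_", k), cur_rows)
      cur_rows <<- list()
    }
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || grepl("^#", ln)) next
    if (grepl("^=", ln)) { flush_block(); next }
    if (grepl("^>", ln)) {
      flush_row()
      m <- regmatches(ln, regexec("^>\\s*(\\d+):(\\d+)-(\\d+)\\s+([+-])", ln))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("malformed XMFA header: '%s'", ln), call. = FALSE)
      }
      idx <- as.integer(m[2]); s <- as.numeric(m[3]); e <- as.numeric(m[4])
      if (idx < 1L || idx > length(isolates)) {
        stop(sprintf("XMFA sequence index %d out of range (have %d genomes)",
                     idx, length(isolates)), call. = FALSE)
      }
      if (s > e) {
        stop(sprintf("XMFA header start > end: '%s'", ln), call. = FALSE)
      }
      cur_meta <- list(isolate = isolates[idx], start = s, end = e, strand = m[5])
    } else {
      if (is.null(cur_meta)) {
        stop(sprintf("XMFA sequence data before any header: '%s'", ln), call. = FALSE)
      }
      cur_seq <- c(cur_seq, gsub("\\s", "", ln))
    }
  }
  flush_block()
  if (length(blocks) == 0L) stop("XMFA file contains no alignment blocks", call. = FALSE)
  # verify row content against the genomes
  for (b in blocks) {
    for (r in b$rows) {
      slice <- substr(genomes[[r$isolate]], r$start, r$end)
      expect <- if (r$strand == "-") revcomp(slice) else slice
      if (ungap(r$gapped_seq) != expect) {
        stop(sprintf(
          "XMFA block %s, isolate '%s': row does not match genome segment [%d,%d] (%s strand)",
          b$block_id, r$isolate, as.integer(r$start), as.integer(r$end), r$strand),
          call. = FALSE)
      }
    }
  }
  blocks <- synthesize_gap_blocks(blocks, genomes)
  block_decomposition(blocks, stats::setNames(nchar(genomes), isolates),
                      isolates = isolates)
}

# Close per-isolate coverage gaps with single-isolate blocks so the
# decomposition tiles every genome.
synthesize_gap_blocks <- function(blocks, genomes) {
  k <- length(blocks)
  for (iso in names(genomes)) {
    covered <- matrix(numeric(0), ncol = 2)
    for (b in blocks) {
      for (r in b$rows) {
        if (r$isolate == iso) covered <- rbind(covered, c(r$start, r$end))
      }
    }
    L <- nchar(genomes[[iso]])
    if (nrow(covered) > 0L) {
      covered <- covered[order(covered[, 1]), , drop = FALSE]
      for (i in seq_len(nrow(covered) - 1L)) {
        if (covered[i + 1L, 1] <= covered[i, 2]) {
          stop(sprintf("isolate '%s': overlapping XMFA blocks at position %d",
                       iso, as.integer(covered[i + 1L, 1])), call. = FALSE)
        }
      }
    }
    gaps <- list()
    pos <- 1
    for (i in seq_len(nrow(covered))) {
      if (covered[i, 1] > pos) gaps[[length(gaps) + 1L]] <- c(pos, covered[i, 1] - 1)
      pos <- covered[i, 2] + 1
    }
    if (pos <= L) gaps[[length(gaps) + 1L]] <- c(pos, L)
    for (g in gaps) {
      k <- k + 1L
      blocks[[k]] <- aligned_block(paste0("Aln_", k), list(
        list(isolate = iso, gapped_seq = substr(genomes[[iso]], g[1], g[2]),
             start = g[1], end = g[2], strand = "+")))
    }
  }
  blocks
}

# Coordinates a block row contributes to a node: the node consumed
# `consumed` row bases before it and `len` bases within it (both in block
# orientation). '-' strand rows get negative, reversed values.
row_node_coords <- function(row, consumed, len) {
  if (row$strand == "+") {
    l <- row$start + consumed
    c(leftend = l, rightend = l + len - 1)
  } else {
    e <- row$end - consumed
    c(leftend = -e, rightend = -(e - len + 1))
  }
}

#' Build the structural graph of co-linear blocks
#'
#' One temporary node per block (named by its block id), holding the
#' block-orientation sequence of the first graph isolate present; edges
#' join blocks consecutive in each isolate's genomic order.
#'
#' @param decomp A [block_decomposition()].
#' @return A `genome_graph` of temporary block nodes.
#' @export
build_structure_graph <- function(decomp) {
  stopifnot(inherits(decomp, "block_decomposition"))
  isolates <- decomp$isolates
  graph <- genome_graph(isolates)
  for (b in decomp$blocks) {
    b <- normalize_block_orientation(b, isolates)
    present <- block_isolates(b)
    first <- isolates[isolates %in% present][1]
    seq0 <- ungap(b$rows[[match(first, present)]]$gapped_seq)
    coords <- list()
    for (r in b$rows) {
      coords[[r$isolate]] <- row_node_coords(r, 0, r$end - r$start + 1)
    }
    # temporary block nodes are imperfect alignments: spans of the
    # non-representative isolates need not equal the stored sequence
    # length, so bypass the strict node validator
    nd <- structure(list(name = b$block_id, sequence = seq0,
                         ids = present, coords = coords[present]),
                    class = "sequence_node")
    graph$nodes[[b$block_id]] <- nd
  }
  # edges: consecutive blocks in each isolate's genomic order
  for (iso in isolates) {
    idx <- walk_index(graph, iso, validate = FALSE)
    if (nrow(idx) > 1L) {
      for (i in seq_len(nrow(idx) - 1L)) {
        graph <- add_edge(graph, idx$node[i], idx$node[i + 1L], iso)
      }
    }
  }
  graph
}

#' Collapse a block alignment into a subgraph of shared-sequence nodes
#'
#' Column-partition collapse: in each alignment column, rows holding a
#' gap are absent and the remaining rows are grouped by identical
#' character. Maximal runs of consecutive columns with the same grouping
#' emit one node per group (the group's common ungapped run). Nodes are
#' named `<block_id>_<n>` sequentially in column order (within a column,
#' the group containing the alphabetically smallest isolate first), and
#' edges connect each row's consecutive nodes. Per-isolate coordinates
#' come from the row's genomic offsets; `-` strand rows receive negative
#' reversed values.
#'
#' @param block An [aligned_block()] carrying genomic offsets in its rows.
#' @param isolates Optional isolate order for the subgraph (defaults to
#'   row order).
#' @return A `genome_graph` in which every row's path spells its
#'   ungapped sequence.
#' @export
collapse_block <- function(block, isolates = NULL) {
  stopifnot(inherits(block, "aligned_block"))
  rows <- block$rows
  present <- block_isolates(block)
  if (is.null(isolates)) isolates <- present
  mat <- block_char_matrix(rows)
  k <- nrow(mat); L <- ncol(mat)
  # column signature: the partition of non-gap rows by character identity,
  # canonicalised by first-occurrence labels
  sigs <- character(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    lab <- match(col, unique(col[col != "-"]))
    lab[col == "-"] <- 0L
    sigs[j] <- paste(lab, collapse = ",")
  }
  runs <- rle(sigs)
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1L
  graph <- genome_graph(isolates[isolates %in% present])
  consumed <- stats::setNames(numeric(k), present)
  node_of_row <- vector("list", k)   # per row: ordered node names
  n_nodes <- 0L
  for (ri in seq_along(runs$lengths)) {
    j1 <- run_starts[ri]; j2 <- run_ends[ri]
    col <- mat[, j1]
    nongap <- which(col != "-")
    groups <- split(nongap, col[nongap])
    # order groups by their alphabetically smallest member isolate
    mins <- vapply(groups, function(g) min(present[g]), character(1))
    groups <- groups[order(mins)]
    run_len <- j2 - j1 + 1L
    for (g in groups) {
      n_nodes <- n_nodes + 1L
      nm <- paste0(block$block_id, "_", n_nodes)
      seq_g <- paste(mat[g[1], j1:j2], collapse = "")
      coords <- list()
      for (r in g) {
        coords[[present[r]]] <- row_node_coords(rows[[r]], consumed[[present[r]]], run_len)
      }
      graph <- add_node(graph, sequence_node(nm, seq_g, present[g], coords))
      for (r in g) node_of_row[[r]] <- c(node_of_row[[r]], nm)
    }
    for (r in nongap) consumed[[present[r]]] <- consumed[[present[r]]] + run_len
  }
  for (r in seq_len(k)) {
    path <- node_of_row[[r]]
    if (length(path) > 1L) {
      for (i in seq_len(length(path) - 1L)) {
        graph <- add_edge(graph, path[i], path[i + 1L], present[r])
      }
    }
  }
  graph
}

# First and last node of `isolate`'s genomic-order path within subgraph.
sub_endpoints <- function(sub, isolate) {
  idx <- walk_index(sub, isolate, validate = FALSE)
  c(first = idx$node[1], last = idx$node[nrow(idx)])
}

#' Splice a collapsed subgraph in place of a temporary block node
#'
#' The temporary node is removed; for each isolate, edges into it are
#' rewired to that isolate's genomically first node of the subgraph and
#' edges out of it to the isolate's last node.
#'
#' @param graph A `genome_graph` containing `temp_node_name`.
#' @param temp_node_name Name of the temporary block node to replace.
#' @param sub The collapsed subgraph; its isolate set and per-isolate
#'   coordinate spans must equal the temporary node's.
#' @return The updated graph.
#' @export
splice_subgraph <- function(graph, temp_node_name, sub) {
  stopifnot(inherits(graph, "genome_graph"), inherits(sub, "genome_graph"))
  temp <- graph$nodes[[temp_node_name]]
  if (is.null(temp)) {
    stop(sprintf("no node named '%s' in graph", temp_node_name), call. = FALSE)
  }
  sub_isos <- unique(unlist(lapply(sub$nodes, `[[`, "ids")))
  if (!setequal(sub_isos, temp$ids)) {
    stop(sprintf("splice of '%s': subgraph isolate set does not match node ids",
                 temp_node_name), call. = FALSE)
  }
  for (iso in temp$ids) {
    span_t <- node_interval(temp, iso)
    idx <- walk_index(sub, iso, validate = FALSE)
    span_s <- c(min(idx$lo), max(idx$hi))
    if (!identical(as.numeric(span_t), as.numeric(span_s))) {
      stop(sprintf(
        "splice of '%s': isolate '%s' span mismatch (node [%d,%d], subgraph [%d,%d])",
        temp_node_name, iso, as.integer(span_t[1]), as.integer(span_t[2]),
        as.integer(span_s[1]), as.integer(span_s[2])), call. = FALSE)
    }
  }
  clash <- intersect(names(sub$nodes), setdiff(names(graph$nodes), temp_node_name))
  if (length(clash) > 0L) {
    stop(sprintf("splice of '%s': subgraph node names already present: %s",
                 temp_node_name, paste(clash, collapse = ", ")), call. = FALSE)
  }
  in_edges <- Filter(function(e) e$target == temp_node_name &&
                       e$source != temp_node_name, graph$edges)
  out_edges <- Filter(function(e) e$source == temp_node_name &&
                        e$target != temp_node_name, graph$edges)
  # drop temp node and all touching edges
  graph$nodes[[temp_node_name]] <- NULL
  graph$edges <- Filter(function(e) e$source != temp_node_name &&
                          e$target != temp_node_name, graph$edges)
  for (nd in sub$nodes) graph$nodes[[nd$name]] <- nd
  for (e in sub$edges) {
    graph <- add_edge(graph, e$source, e$target, e$ids)
  }
  ends <- lapply(stats::setNames(temp$ids, temp$ids),
                 function(iso) sub_endpoints(sub, iso))
  for (e in in_edges) {
    for (iso in e$ids) {
      graph <- add_edge(graph, e$source, ends[[iso]][["first"]], iso)
    }
  }
  for (e in out_edges) {
    for (iso in e$ids) {
      graph <- add_edge(graph, ends[[iso]][["last"]], e$target, iso)
    }
  }
  graph
}

# Pad rows with trailing gaps to equal width ("alignment" good enough to
# satisfy block invariants; the builder realigns multi-isolate blocks).
pad_block <- function(block_id, seqs) {
  w <- max(nchar(seqs))
  rows <- lapply(names(seqs), function(iso) {
    s <- seqs[[iso]]
    list(isolate = iso, gapped_seq = paste0(s, strrep("-", w - nchar(s))),
         start = 1, end = nchar(s), strand = "+")
  })
  aligned_block(block_id, rows)
}

# Realign a block's sequences (in block orientation) keeping its offsets.
realign_block <- function(block, aligner, scoring) {
  seqs <- stats::setNames(vapply(block$rows, function(r) ungap(r$gapped_seq),
                                 character(1)),
                          block_isolates(block))
  ab <- if (aligner == "builtin") {
    progressive_msa(seqs, scoring = scoring, block_id = block$block_id)
  } else {
    run_external_aligner(aligner, seqs, block_id = block$block_id)
  }
  rows <- ab$rows
  for (i in seq_along(rows)) {
    orig <- block$rows[[match(rows[[i]]$isolate, block_isolates(block))]]
    rows[[i]]$start <- orig$start
    rows[[i]]$end <- orig$end
    rows[[i]]$strand <- orig$strand
  }
  aligned_block(block$block_id, rows)
}

#' Build a genome graph from a set of genomes
#'
#' Two-stage construction: (1) a structural graph with one temporary
#' node per co-linear block (from an XMFA decomposition, or a single
#' whole-genome block in co-linear mode); (2) each multi-isolate block
#' is realigned with the chosen MSA tool, collapsed into
#' shared-sequence nodes, and spliced in place of its temporary node.
#' Single-isolate blocks pass through as final nodes. Every isolate's
#' reconstruction is verified against its input before the graph is
#' returned.
#'
#' @param genomes Named character vector of genome sequences (isolate ->
#'   sequence), or a character vector of FASTA paths (see
#'   [read_genomes()]). Order defines the XMFA sequence-index mapping.
#' @param xmfa Optional path to an XMFA co-linear block decomposition.
#'   When `NULL`, co-linear mode is used: the genomes are assumed
#'   rearrangement-free and aligned as one block.
#' @param aligner `"builtin"` (progressive aligner) or one of
#'   `"mafft"`, `"muscle"`, `"clustalo"`.
#' @param scoring Scoring scheme for the built-in aligner.
#' @return A validated `genome_graph`.
#' @export
build_genome_graph <- function(genomes, xmfa = NULL,
                               aligner = c("builtin", "mafft", "muscle", "clustalo"),
                               scoring = align_scoring()) {
  aligner <- match.arg(aligner)
  if (is.character(genomes) && length(genomes) >= 1L && all(file.exists(genomes))) {
    genomes <- read_genomes(genomes)
  }
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be named by isolate", call. = FALSE)
  }
  genomes <- vapply(genomes, clean_sequence, character(1), what = "genome")
  if (length(genomes) < 1L) stop("need at least one genome", call. = FALSE)
  isolates <- names(genomes)
  decomp <- if (!is.null(xmfa)) {
    parse_xmfa(xmfa, genomes)
  } else {
    block_decomposition(list(pad_block("Aln_1", genomes)),
                        stats::setNames(nchar(genomes), isolates),
                        isolates = isolates)
  }
  graph <- build_structure_graph(decomp)
  for (b in decomp$blocks) {
    if (length(b$rows) < 2L) next
    b <- normalize_block_orientation(b, isolates)
    b <- realign_block(b, aligner, scoring)
    sub <- collapse_block(b, isolates = isolates)
    graph <- splice_subgraph(graph, b$block_id, sub)
  }
  graph$metadata <- list(
    mode = if (is.null(xmfa)) "colinear" else "xmfa",
    aligner = aligner,
    n_genomes = as.character(length(genomes)),
    scoring = sprintf("match=%g,mismatch=%g,gap_open=%g,gap_extend=%g",
                      scoring$match, scoring$mismatch, scoring$gap_open,
                      scoring$gap_extend),
    builder = paste0("pangraphr ", as.character(utils::packageVersion("pangraphr"))))
  for (iso in isolates) {
    rec <- reconstruct_sequence(graph, iso)
    if (!identical(rec, genomes[[iso]])) {
      stop(sprintf("round-trip failure: reconstruction of isolate '%s' does not match its input",
                   iso), call. = FALSE)
    }
  }
  graph
}
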