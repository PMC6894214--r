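# Synthetic genome sets with recorded mutation ground truth.
#
# A random root sequence is mutated independently per derived genome
# (substitutions, short indels, tandem-repeat expansions, segmental
# inversions), and every event is recorded so that tests can use the
# truth as an oracle: the event list replays to the derived genome
# exactly, and a piecewise coordinate map links root and derived
# positions. When rearrangements are present, a matching XMFA co-linear
# block decomposition is derived from the truth, so graph construction
# is testable without an external whole-genome aligner.

#' Mutation rate settings for the synthetic generator
#'
#' @param sub_rate Per-base substitution probability.
#' @param ins_rate Per-base insertion-event probability (geometric
#'   lengths, mean `indel_mean`).
#' @param del_rate Per-base deletion-event probability (geometric
#'   lengths, mean `indel_mean`).
#' @param inv_count Number of segmental inversions.
#' @param repeat_expansions Number of tandem-repeat expansion events
#'   (a 3-bp unit gains `repeat_copies` extra copies).
#' @param indel_mean Mean indel length (geometric, >= 1).
#' @param inv_length Inversion segment length in bp.
#' @param repeat_copies Extra unit copies per tandem expansion.
#' @return A `mutation_rates` list.
#' @export
mutation_rates <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                           inv_count = 0, repeat_expansions = 0,
                           indel_mean = 3, inv_length = 500,
                           repeat_copies = 3) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0, inv_count >= 0,
            repeat_expansions >= 0, indel_mean >= 1, inv_length >= 2,
            repeat_copies >= 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, inv_count = inv_count,
                 repeat_expansions = repeat_expansions,
                 indel_mean = indel_mean, inv_length = inv_length,
                 repeat_copies = repeat_copies),
            class = "mutation_rates")
}

#' Random nucleotide sequence
#' @param length Sequence length.
#' @return A random A/C/G/T string (uses the current RNG state).
#' @export
random_genome <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

rgeom_len <- function(n, mean) 1L + stats::rgeom(n, prob = 1 / mean)

# Place `len` consecutive bases avoiding `occupied` (two-column matrix of
# intervals); errors when the root is too crowded.
place_span <- function(len, L, occupied, tries = 1000L) {
  if (len > L) stop("mutation events exhaust the root sequence", call. = FALSE)
  for (i in seq_len(tries)) {
    s <- sample.int(L - len + 1L, 1L)
    e <- s + len - 1L
    if (nrow(occupied) == 0L ||
        all(e < occupied[, 1] | s > occupied[, 2])) {
      return(c(s, e))
    }
  }
  stop("mutation rates imply overlap exhaustion on this root length", call. = FALSE)
}

#' Mutate a root genome, recording ground truth
#'
#' Draws non-overlapping mutation events on the root (inversions, then
#' tandem expansions, deletions, insertions, and per-base
#' substitutions), replays them left-to-right, and records the truth:
#' the event list and a piecewise root-to-derived coordinate map.
#'
#' @param root Root nucleotide sequence.
#' @param rates A [mutation_rates()] object.
#' @param seed Integer seed; a given (root, rates, seed) triple is fully
#'   deterministic.
#' @return A `mutation_truth` list with elements `derived` (the mutated
#'   sequence), `events` (data frame: type, root_start, root_end,
#'   payload), `segments` (the coordinate map), `root_length`,
#'   `derived_length`.
#' @export
mutate_genome <- function(root, rates = mutation_rates(), seed = 1L) {
  root <- clean_sequence(root, what = "root")
  stopifnot(inherits(rates, "mutation_rates"))
  set.seed(seed)
  L <- nchar(root)
  bases <- c("A", "C", "G", "T")
  events <- data.frame(type = character(), root_start = numeric(),
                       root_end = numeric(), payload = character(),
                       stringsAsFactors = FALSE)
  occupied <- matrix(numeric(0), ncol = 2)
  claim <- function(s, e) occupied <<- rbind(occupied, c(s, e))
  add_event <- function(type, s, e, payload) {
    events[nrow(events) + 1L, ] <<- list(type, s, e, payload)
  }
  for (i in seq_len(rates$inv_count)) {
    sp <- place_span(rates$inv_length, L, occupied)
    claim(sp[1], sp[2])
    add_event("inversion", sp[1], sp[2], "")
  }
  for (i in seq_len(rates$repeat_expansions)) {
    sp <- place_span(3L, L, occupied)
    claim(sp[1], sp[2])
    unit <- substr(root, sp[1], sp[2])
    add_event("tandem_expansion", sp[1], sp[2],
              strrep(unit, rates$repeat_copies))
  }
  n_del <- stats::rbinom(1L, L, rates$del_rate)
  for (i in seq_len(n_del)) {
    len <- rgeom_len(1L, rates$indel_mean)
    sp <- place_span(len, L, occupied)
    claim(sp[1], sp[2])
    add_event("deletion", sp[1], sp[2], "")
  }
  n_ins <- stats::rbinom(1L, L, rates$ins_rate)
  for (i in seq_len(n_ins)) {
    len <- rgeom_len(1L, rates$indel_mean)
    sp <- place_span(1L, L, occupied)   # anchor base the payload follows
    claim(sp[1], sp[2])
    add_event("insertion", sp[1], sp[1],
              paste(sample(bases, len, replace = TRUE), collapse = ""))
  }
  if (rates$sub_rate > 0) {
    cand <- which(stats::runif(L) < rates$sub_rate)
    if (nrow(occupied) > 0L) {
      cand <- cand[vapply(cand, function(p) {
        all(p < occupied[, 1] | p > occupied[, 2])
      }, logical(1))]
    }
    for (p in cand) {
      old <- substr(root, p, p)
      add_event("substitution", p, p, sample(setdiff(bases, old), 1L))
    }
  }
  events <- events[order(events$root_start, events$root_end), , drop = FALSE]
  rownames(events) <- NULL
  replay_events(root, events)
}

# Replay an event list over the root: derived text plus the piecewise
# coordinate map. Segment kinds: "identity" (root interval mapped 1:1,
# possibly substituted), "inversion" (mapped reversed), "insertion"
# (payload bases with no root interval; `anchor` = preceding root base).
replay_events <- function(root, events) {
  L <- nchar(root)
  pieces <- character(0)
  segs <- data.frame(kind = character(), root_start = numeric(),
                     root_end = numeric(), derived_start = numeric(),
                     derived_end = numeric(), anchor = numeric(),
                     stringsAsFactors = FALSE)
  pos <- 1; dpos <- 1
  emit <- function(kind, rs, re, text, anchor = NA_real_) {
    if (nchar(text) == 0L && kind != "deletion") return()
    pieces[length(pieces) + 1L] <<- text
    segs[nrow(segs) + 1L, ] <<- list(kind, rs, re, dpos,
                                     dpos + nchar(text) - 1, anchor)
    dpos <<- dpos + nchar(text)
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$root_start < pos) {
      stop(sprintf("overlapping events at root position %d",
                   as.integer(ev$root_start)), call. = FALSE)
    }
    if (ev$root_start > pos) {
      emit("identity", pos, ev$root_start - 1,
           substr(root, pos, ev$root_start - 1))
    }
    switch(ev$type,
      substitution = {
        emit("identity", ev$root_start, ev$root_start, ev$payload)
        pos <- ev$root_start + 1
      },
      deletion = {
        pos <- ev$root_end + 1
      },
      inversion = {
        emit("inversion", ev$root_start, ev$root_end,
             revcomp(substr(root, ev$root_start, ev$root_end)))
        pos <- ev$root_end + 1
      },
      insertion = {
        emit("identity", ev$root_start, ev$root_start,
             substr(root, ev$root_start, ev$root_start))
        emit("insertion", NA_real_, NA_real_, ev$payload, anchor = ev$root_start)
        pos <- ev$root_start + 1
      },
      tandem_expansion = {
        emit("identity", ev$root_start, ev$root_end,
             substr(root, ev$root_start, ev$root_end))
        emit("insertion", NA_real_, NA_real_, ev$payload, anchor = ev$root_end)
        pos <- ev$root_end + 1
      },
      stop("unknown event type: ", ev$type, call. = FALSE))
  }
  if (pos <= L) emit("identity", pos, L, substr(root, pos, L))
  derived <- paste(pieces, collapse = "")
  structure(list(derived = derived, events = events, segments = segs,
                 root_length = L, derived_length = nchar(derived)),
            class = "mutation_truth")
}

#' Translate a root coordinate to its derived-genome coordinate
#'
#' @param truth A `mutation_truth` from [mutate_genome()].
#' @param pos Position in the root sequence.
#' @return Position of the homologous base in the derived genome, or
#'   `NA` if that base was deleted.
#' @export
truth_translate <- function(truth, pos) {
  stopifnot(inherits(truth, "mutation_truth"))
  if (pos < 1 || pos > truth$root_length) {
    stop(sprintf("position %d outside root [1,%d]", as.integer(pos),
                 as.integer(truth$root_length)), call. = FALSE)
  }
  s <- truth$segments
  hit <- which(!is.na(s$root_start) & s$root_start <= pos & pos <= s$root_end)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  if (s$kind[i] == "inversion") {
    s$derived_end[i] - (pos - s$root_start[i])
  } else {
    s$derived_start[i] + (pos - s$root_start[i])
  }
}

# Root cut positions ("break after position c") for XMFA emission: an
# even grid, adjusted so no cut falls inside any genome's inversion and
# every inversion is exactly one block.
fixture_cuts <- function(truths, root_length, block_length) {
  cuts <- if (block_length >= root_length) numeric(0) else
    seq(block_length, root_length - 1, by = block_length)
  for (tr in truths) {
    inv <- tr$events[tr$events$type == "inversion", , drop = FALSE]
    for (i in seq_len(nrow(inv))) {
      s <- inv$root_start[i]; e <- inv$root_end[i]
      cuts <- cuts[!(cuts >= s & cuts <= e - 1)]
      if (s > 1) cuts <- c(cuts, s - 1)
      if (e < root_length) cuts <- c(cuts, e)
    }
  }
  sort(unique(cuts))
}

# Per derived base, the root-block index (blocks delimited by `cuts`).
derived_block_ids <- function(truth, cuts) {
  block_of <- function(p) findInterval(p - 0.5, cuts) + 1L
  out <- integer(0)
  s <- truth$segments
  for (i in seq_len(nrow(s))) {
    len <- s$derived_end[i] - s$derived_start[i] + 1
    ids <- switch(s$kind[i],
      identity = block_of(seq(s$root_start[i], s$root_end[i])),
      inversion = rep(block_of(s$root_start[i]), len),
      insertion = rep(block_of(s$anchor[i]), len))
    out <- c(out, ids)
  }
  out
}

# TRUE per block index: is this block an inversion segment of `truth`?
inverted_blocks <- function(truth, cuts, n_blocks) {
  out <- rep(FALSE, n_blocks)
  s <- truth$segments
  inv <- s[s$kind == "inversion", , drop = FALSE]
  block_of <- function(p) findInterval(p - 0.5, cuts) + 1L
  for (i in seq_len(nrow(inv))) out[block_of(inv$root_start[i])] <- TRUE
  out
}

#' Generate a fixture set of related genomes with recorded truth
#'
#' Draws a random root, derives `n_genomes` genomes from it (the first
#' is the unmutated root unless `mutate_first`), and writes per-genome
#' FASTA files, event-truth TSVs, and (optionally) an XMFA co-linear
#' block decomposition derived from the truth. Fully deterministic for
#' a given seed.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param root_length Root sequence length in bp.
#' @param rates A [mutation_rates()] object applied to each mutated
#'   genome independently.
#' @param seed Integer master seed.
#' @param dir Output directory (created if missing).
#' @param block_length Target co-linear block length for the emitted
#'   XMFA (the granularity a whole-genome aligner would produce).
#' @param write_xmfa Write `fixture.xmfa` alongside the FASTA files.
#' @param mutate_first Mutate genome 1 as well instead of keeping it as
#'   the unmutated root.
#' @param root Optional explicit root sequence (overrides
#'   `root_length`); useful for engineered fixtures such as duplicated
#'   gene cassettes.
#' @return List with `isolates`, `genomes` (named sequences), `truths`
#'   (per-isolate `mutation_truth`), `fasta_paths`, `xmfa_path` (or
#'   `NULL`), `root`, and `dir`.
#' @export
make_fixture_set <- function(n_genomes, root_length = 10000,
                             rates = mutation_rates(sub_rate = 0.001),
                             seed = 1L, dir = tempfile("fixture"),
                             block_length = 1000, write_xmfa = TRUE,
                             mutate_first = FALSE, root = NULL) {
  stopifnot(n_genomes >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (is.null(root)) {
    root <- random_genome(root_length)
  } else {
    root <- clean_sequence(root, what = "root")
    root_length <- nchar(root)
  }
  isolates <- sprintf("iso%02d", seq_len(n_genomes))
  truths <- list(); genomes <- character(0)
  for (g in seq_len(n_genomes)) {
    if (g == 1L && !mutate_first) {
      truths[[isolates[g]]] <- replay_events(
        root, data.frame(type = character(), root_start = numeric(),
                         root_end = numeric(), payload = character(),
                         stringsAsFactors = FALSE))
    } else {
      truths[[isolates[g]]] <- mutate_genome(root, rates,
                                             seed = seed + 7919L * g)
    }
    genomes[isolates[g]] <- truths[[isolates[g]]]$derived
  }
  fasta_paths <- character(0)
  for (iso in isolates) {
    p <- file.path(dir, paste0(iso, ".fasta"))
    write_fasta(stats::setNames(genomes[[iso]], iso), p)
    fasta_paths[iso] <- p
    utils::write.table(truths[[iso]]$events,
                       file.path(dir, paste0(iso, ".truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  xmfa_path <- NULL
  if (write_xmfa) {
    xmfa_path <- file.path(dir, "fixture.xmfa")
    write_fixture_xmfa(xmfa_path, genomes, truths, root_length, block_length)
  }
  list(isolates = isolates, genomes = genomes, truths = truths,
       fasta_paths = fasta_paths, xmfa_path = xmfa_path, root = root,
       dir = dir)
}

# Emit the truth-derived XMFA decomposition: blocks follow the root cut
# grid (inversions exactly one block); rows carry exact derived
# intervals and strands, right-padded to equal width (the graph builder
# realigns every multi-isolate block).
write_fixture_xmfa <- function(path, genomes, truths, root_length,
                               block_length) {
  isolates <- names(genomes)
  cuts <- fixture_cuts(truths, root_length, block_length)
  n_blocks <- length(cuts) + 1L
  rows_per_block <- rep(list(list()), n_blocks)
  for (gi in seq_along(isolates)) {
    iso <- isolates[gi]
    tr <- truths[[iso]]
    ids <- derived_block_ids(tr, cuts)
    inv <- inverted_blocks(tr, cuts, n_blocks)
    r <- rle(ids)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      b <- r$values[k]
      slice <- substr(genomes[[iso]], starts[k], ends[k])
      rows_per_block[[b]][[length(rows_per_block[[b]]) + 1L]] <- list(
        seqnum = gi, isolate = iso, start = starts[k], end = ends[k],
        strand = if (inv[b]) "-" else "+",
        text = if (inv[b]) revcomp(slice) else slice)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#FormatVersion Mauve1", con)
  for (b in seq_len(n_blocks)) {
    rows <- rows_per_block[[b]]
    if (length(rows) == 0L) next
    w <- max(vapply(rows, function(r) nchar(r$text), integer(1)))
    for (r in rows) {
      writeLines(sprintf("> %d:%d-%d %s %s", r$seqnum, as.integer(r$start),
                         as.integer(r$end), r$strand, r$isolate), con)
      padded <- paste0(r$text, strrep("-", w - nchar(r$text)))
      writeLines(substring(padded, seq(1, w, 80), pmin(seq(80, w + 79, 80), w)),
                 con)
    }
    writeLines("=", con)
  }
  invisible(path)
}

#' Derive per-isolate gene annotations from root gene intervals
#'
#' Projects gene intervals defined on the fixture root onto every
#' derived genome through the recorded coordinate maps, giving
#' generator-truth orthology: gene `g` of one isolate corresponds to
#' gene `g` of every other.
#'
#' @param fixture Result of [make_fixture_set()].
#' @param root_genes Data frame with columns `gene` (identifier),
#'   `root_start`, `root_end`. Intervals should avoid inversion and
#'   deletion breakpoints at their endpoints.
#' @return Named list, isolate -> feature data frame (columns `isolate`,
#'   `gene_id`, `gene`, `start`, `end`, `strand`), suitable for
#'   [homology_matrix()].
#' @export
fixture_genes <- function(fixture, root_genes) {
  out <- list()
  for (iso in fixture$isolates) {
    tr <- fixture$truths[[iso]]
    start <- vapply(root_genes$root_start, function(p) truth_translate(tr, p),
                    numeric(1))
    end <- vapply(root_genes$root_end, function(p) truth_translate(tr, p),
                  numeric(1))
    if (any(is.na(start)) || any(is.na(end))) {
      stop(sprintf("gene endpoint deleted in isolate '%s'; choose different root intervals",
                   iso), call. = FALSE)
    }
    out[[iso]] <- data.frame(isolate = iso,
                             gene_id = paste0(iso, "_", root_genes$gene),
                             gene = root_genes$gene,
                             start = pmin(start, end),
                             end = pmax(start, end),
                             strand = "+",
                             stringsAsFactors = FALSE)
  }
  out
}
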