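# Block alignment: a built-in global/progressive aligner plus wrappers
# around external MSA tools (mafft, muscle, clustalo).
#
# The built-in aligner exists so graphs can be built and tested without
# external binaries; external tools remain the intended path for hard
# blocks.

#' Alignment scoring scheme
#'
#' Affine gap convention: a gap run of length L scores
#' `gap_open + (L - 1) * gap_extend`. Matches score `match` per column,
#' mismatches `mismatch`; IUPAC ambiguity codes are literal characters
#' (identical-only matching, no fuzzy identity).
#'
#' @param match Score for an identical column (default 1).
#' @param mismatch Score for a differing column (default -1).
#' @param gap_open Score of the first base of a gap run (default -2).
#' @param gap_extend Score of each further gap base (default -0.5).
#' @return A named list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -0.5) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend))
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

# Literal substitution matrix over the IUPAC alphabet: identical letters
# score `match`, everything else `mismatch` (no ambiguity inference).
literal_substitution_matrix <- function(scoring) {
  n <- length(IUPAC_LETTERS)
  m <- matrix(scoring$mismatch, n, n, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  diag(m) <- scoring$match
  m
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-style global alignment (end gaps penalized) under the
#' [align_scoring()] scheme.
#'
#' @param a,b Nucleotide strings (IUPAC letters; one may be empty).
#' @param scoring An [align_scoring()] scheme.
#' @return List with `a_aligned`, `b_aligned` (equal-length gapped
#'   strings that ungap back to the inputs) and `score` (maximal for the
#'   scheme).
#' @export
pairwise_global_align <- function(a, b, scoring = align_scoring()) {
  a <- clean_sequence(a, what = "sequence a")
  b <- clean_sequence(b, what = "sequence b")
  gap_cost <- function(L) {
    if (L == 0L) 0 else scoring$gap_open + (L - 1) * scoring$gap_extend
  }
  if (nchar(a) == 0L && nchar(b) == 0L) {
    return(list(a_aligned = "", b_aligned = "", score = 0))
  }
  if (nchar(a) == 0L) {
    return(list(a_aligned = strrep("-", nchar(b)), b_aligned = b,
                score = gap_cost(nchar(b))))
  }
  if (nchar(b) == 0L) {
    return(list(a_aligned = a, b_aligned = strrep("-", nchar(a)),
                score = gap_cost(nchar(a))))
  }
  # Biostrings penalty convention: a gap run of length L costs
  # gapOpening + L * gapExtension, so shift the opening penalty.
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    substitutionMatrix = literal_substitution_matrix(scoring),
    gapOpening = scoring$gap_extend - scoring$gap_open,
    gapExtension = -scoring$gap_extend,
    type = "global")
  list(a_aligned = as.character(Biostrings::alignedPattern(pa)),
       b_aligned = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Construct an aligned block
#'
#' A block is one co-linear alignment: rows of equal gapped length, each
#' carrying the forward-strand genomic interval it came from and a strand
#' flag (`"-"` rows store the reverse complement of the forward-strand
#' segment).
#'
#' @param block_id Block identifier (e.g. `"Aln_66"`).
#' @param rows List of rows, each a list with fields `isolate`,
#'   `gapped_seq`, `start`, `end`, `strand`.
#' @return An `aligned_block`.
#' @export
aligned_block <- function(block_id, rows) {
  stopifnot(is.character(block_id), length(block_id) == 1L, nzchar(block_id))
  if (length(rows) < 1L) stop("block must contain at least one row", call. = FALSE)
  widths <- integer(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    r$gapped_seq <- clean_sequence(r$gapped_seq,
                                   what = sprintf("block %s row %d", block_id, i),
                                   allow_gap = TRUE)
    if (!r$strand %in% c("+", "-")) {
      stop(sprintf("block %s row %d: strand must be '+' or '-'", block_id, i),
           call. = FALSE)
    }
    if (!(r$start >= 1 && r$end >= r$start)) {
      stop(sprintf("block %s row %d: need 1 <= start <= end", block_id, i),
           call. = FALSE)
    }
    ug <- nchar(ungap(r$gapped_seq))
    if (ug != r$end - r$start + 1) {
      stop(sprintf(
        "block %s row %d (%s): ungapped length %d does not match interval [%d,%d]",
        block_id, i, r$isolate, ug, as.integer(r$start), as.integer(r$end)),
        call. = FALSE)
    }
    widths[i] <- nchar(r$gapped_seq)
    rows[[i]] <- r
  }
  if (length(unique(widths)) != 1L) {
    stop(sprintf("block %s: rows have unequal gapped lengths", block_id),
         call. = FALSE)
  }
  if (widths[1] < 1L) {
    stop(sprintf("block %s: zero-width alignment", block_id), call. = FALSE)
  }
  isos <- vapply(rows, `[[`, character(1), "isolate")
  if (anyDuplicated(isos)) {
    stop(sprintf("block %s: duplicate isolate row", block_id), call. = FALSE)
  }
  # no all-gap column
  mat <- block_char_matrix(rows)
  if (any(colSums(mat != "-") == 0L)) {
    stop(sprintf("block %s: all-gap column", block_id), call. = FALSE)
  }
  structure(list(block_id = block_id, rows = rows), class = "aligned_block")
}

block_char_matrix <- function(rows) {
  do.call(rbind, lapply(rows, function(r) strsplit(r$gapped_seq, "")[[1]]))
}

block_isolates <- function(block) {
  vapply(block$rows, `[[`, character(1), "isolate")
}

# Majority consensus of a gapped character matrix; per column the most
# frequent non-gap character, ties broken by the alphabetically smallest.
consensus_string <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[col != "-"]
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]
  }) |> paste(collapse = "")
}

#' Progressive multiple sequence alignment
#'
#' Deterministic profile-based progressive alignment: sequences are taken
#' in input order; each is globally aligned against the running
#' alignment's majority-character consensus, and gap columns opened in
#' the consensus are propagated to all previous rows. Adequate for the
#' highly similar sequences found within co-linear blocks; external MSA
#' tools are the intended path for divergent blocks.
#'
#' @param seqs Named character vector (isolate -> sequence), length >= 1,
#'   all sequences non-empty.
#' @param scoring An [align_scoring()] scheme.
#' @param block_id Identifier for the returned block.
#' @return An [aligned_block()] whose rows ungap to the inputs, in input
#'   order, with coordinates `[1, nchar(seq)]` on strand `"+"`.
#' @export
progressive_msa <- function(seqs, scoring = align_scoring(), block_id = "Aln_1") {
  if (length(seqs) < 1L) stop("progressive_msa: no input sequences", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("progressive_msa: sequences must be named by isolate", call. = FALSE)
  }
  seqs <- vapply(seqs, clean_sequence, character(1), what = "input sequence")
  if (any(nchar(seqs) == 0L)) {
    stop("progressive_msa: empty sequence", call. = FALSE)
  }
  aligned <- character(1)
  aligned[1] <- seqs[[1]]
  if (length(seqs) > 1L) {
    for (k in 2:length(seqs)) {
      mat <- do.call(rbind, strsplit(aligned, ""))
      cons <- consensus_string(mat)
      pa <- pairwise_global_align(cons, seqs[[k]], scoring)
      cons_chars <- strsplit(pa$a_aligned, "")[[1]]
      new_cols <- which(cons_chars == "-")   # columns inserted into the profile
      if (length(new_cols) > 0L) {
        newL <- length(cons_chars)
        old_cols <- setdiff(seq_len(newL), new_cols)
        aligned <- vapply(aligned, function(row) {
          out <- rep("-", newL)
          out[old_cols] <- strsplit(row, "")[[1]]
          paste(out, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      aligned <- c(aligned, pa$b_aligned)
    }
  }
  rows <- lapply(seq_along(seqs), function(i) {
    list(isolate = names(seqs)[i], gapped_seq = aligned[i],
         start = 1, end = nchar(seqs[[i]]), strand = "+")
  })
  aligned_block(block_id, rows)
}

#' Run an external MSA tool on a set of sequences
#'
#' Writes the sequences to a temporary FASTA, invokes the tool, and
#' parses its aligned FASTA output.
#'
#' @param tool One of `"mafft"`, `"muscle"`, `"clustalo"`.
#' @param seqs Named character vector (isolate -> sequence).
#' @param options Extra command-line options (character vector).
#' @param block_id Identifier for the returned block.
#' @return An [aligned_block()] with rows in input order.
#' @export
run_external_aligner <- function(tool = c("mafft", "muscle", "clustalo"),
                                 seqs, options = character(), block_id = "Aln_1") {
  tool <- match.arg(tool)
  if (length(seqs) < 1L) stop("no input sequences", call. = FALSE)
  exe <- Sys.which(tool)
  if (!nzchar(exe)) {
    stop(errorCondition(
      sprintf("aligner unavailable: '%s' not found on PATH", tool),
      class = c("pangraphr_aligner_unavailable", "error", "condition")))
  }
  seqs <- vapply(seqs, clean_sequence, character(1), what = "input sequence")
  infile <- tempfile(fileext = ".fa")
  outfile <- tempfile(fileext = ".afa")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  write_fasta(seqs, infile)
  args <- switch(tool,
    mafft = c("--auto", "--quiet", options, infile),
    muscle = c("-align", infile, "-output", outfile, options),
    clustalo = c("-i", infile, "-o", outfile, "--force", options))
  errfile <- tempfile(fileext = ".log")
  on.exit(unlink(errfile), add = TRUE)
  status <- if (tool == "mafft") {
    system2(exe, args, stdout = outfile, stderr = errfile)
  } else {
    system2(exe, args, stdout = errfile, stderr = errfile)
  }
  diag <- if (file.exists(errfile)) {
    paste(readLines(errfile, warn = FALSE), collapse = "\n")
  } else ""
  if (status != 0 || !file.exists(outfile) || file.size(outfile) == 0) {
    stop(sprintf("external aligner '%s' failed:\n%s", tool, diag), call. = FALSE)
  }
  out <- Biostrings::readBStringSet(outfile)
  got <- sub("\\s.*$", "", names(out))
  if (!setequal(got, names(seqs)) || length(out) != length(seqs)) {
    stop(sprintf("external aligner '%s': output rows do not match input isolates", tool),
         call. = FALSE)
  }
  rows <- lapply(names(seqs), function(iso) {
    list(isolate = iso,
         gapped_seq = toupper(as.character(out[[match(iso, got)]])),
         start = 1, end = nchar(seqs[[iso]]), strand = "+")
  })
  aligned_block(block_id, rows)
}
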