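# Shared low-level helpers: alphabet checks, reverse complement, FASTA I/O.

IUPAC_LETTERS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                   "V", "H", "D", "B", "N")

is_nucleotide_string <- function(x, allow_gap = FALSE) {
  pat <- if (allow_gap) "^[ACGTMRWSYKVHDBN-]*$" else "^[ACGTMRWSYKVHDBN]*$"
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(pat, x)
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented per the standard code table;
#' gap characters (`-`) are preserved in place.
#'
#' @param x Single nucleotide string (may contain `-`).
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Uppercase and validate one sequence; `what` names it in error messages.
clean_sequence <- function(x, what = "sequence", allow_gap = FALSE) {
  x <- toupper(x)
  if (!is_nucleotide_string(x, allow_gap = allow_gap)) {
    stop(sprintf("%s contains characters outside the nucleotide alphabet%s",
                 what, if (allow_gap) " (plus '-')" else ""), call. = FALSE)
  }
  x
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Read genomes from FASTA files
#'
#' @param paths Character vector of FASTA paths. If unnamed, isolate names
#'   are taken from each file's first record header; if named, the names
#'   are used as isolate names.
#' @return Named character vector of uppercase genome sequences, one per
#'   file, in input order (the order later used to map XMFA sequence
#'   indices to isolates).
#' @export
read_genomes <- function(paths) {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("genome FASTA file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- character(0)
  for (i in seq_along(paths)) {
    ss <- Biostrings::readDNAStringSet(paths[[i]])
    if (length(ss) < 1L) stop("empty FASTA file: ", paths[[i]], call. = FALSE)
    nm <- if (!is.null(names(paths)) && nzchar(names(paths)[i])) {
      names(paths)[i]
    } else {
      sub("\\s.*$", "", names(ss)[1])
    }
    out[nm] <- clean_sequence(as.character(ss[[1]]), what = nm)
  }
  out
}

# Write one named sequence set as FASTA, wrapped at `width` columns.
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
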