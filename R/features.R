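# Annotation input: GTF/GFF3 feature records for one isolate.

#' Read annotation features for one isolate
#'
#' Parses a GTF or GFF3 file and returns the feature intervals as a data
#' frame. The gene identifier is taken from the first of the `gene_id`,
#' `ID`, or `locus_tag` attributes present.
#'
#' @param path GTF/GFF3 file path (format detected from the extension by
#'   the underlying reader).
#' @param isolate Isolate name the annotations belong to.
#' @param feature_type Optional filter on the feature type column (e.g.
#'   `"gene"`, `"CDS"`); `NULL` keeps everything.
#' @return `data.frame` with columns `isolate`, `seqid`, `type`,
#'   `start`, `end`, `strand`, `gene_id`.
#' @export
read_features <- function(path, isolate, feature_type = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  gene_id <- rep(NA_character_, length(gr))
  for (key in c("gene_id", "ID", "locus_tag")) {
    if (key %in% colnames(md)) {
      v <- as.character(md[[key]])
      gene_id <- ifelse(is.na(gene_id) & !is.na(v) & nzchar(v), v, gene_id)
    }
  }
  df <- data.frame(isolate = isolate,
                   seqid = as.character(GenomicRanges::seqnames(gr)),
                   type = as.character(md$type),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gene_id,
                   stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  if (!is.null(feature_type)) df <- df[df$type %in% feature_type, , drop = FALSE]
  if (any(is.na(df$gene_id))) {
    stop("annotation records lack a gene identifier (gene_id/ID/locus_tag): ",
         path, call. = FALSE)
  }
  rownames(df) <- NULL
  df
}
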