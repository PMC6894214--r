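# Independent alignment-score oracles, kept free of the package's
# alignment code path.
#
# Scoring convention (shared with align_scoring): a gap run of length L
# scores gap_open + (L - 1) * gap_extend.

# Exhaustive enumeration over every alignment (every interleaving of
# match/insert/delete ops), tracking the previous op for affine gap
# runs. Exponential; for sequences up to ~4-5 bases only.
enum_align_score <- function(a, b, scoring = align_scoring()) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  sub <- function(x, y) if (x == y) scoring$match else scoring$mismatch
  gap <- function(last, op) {
    if (identical(last, op)) scoring$gap_extend else scoring$gap_open
  }
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      best <- max(best, sub(ca[i + 1], cb[j + 1]) + rec(i + 1, j + 1, "M"))
    }
    if (i < n) best <- max(best, gap(last, "X") + rec(i + 1, j, "X"))
    if (j < m) best <- max(best, gap(last, "Y") + rec(i, j + 1, "Y"))
    best
  }
  rec(0L, 0L, "")
}

# Three-state affine-gap dynamic program (Gotoh), written directly from
# the recurrences; independent of the package's aligner.
gotoh_align_score <- function(a, b, scoring = align_scoring()) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  go <- scoring$gap_open; ge <- scoring$gap_extend
  if (n == 0L && m == 0L) return(0)
  if (n == 0L) return(go + (m - 1) * ge)
  if (m == 0L) return(go + (n - 1) * ge)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)  # ends in substitution column
  X <- matrix(NEG, n + 1, m + 1)  # ends with gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # ends with gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- go + (i - 2) * ge
  for (j in 2:(m + 1)) Y[1, j] <- go + (j - 2) * ge
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (ca[i - 1] == cb[j - 1]) scoring$match else scoring$mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] + go, X[i - 1, j] + ge, Y[i - 1, j] + go)
      Y[i, j] <- max(M[i, j - 1] + go, Y[i, j - 1] + ge, X[i, j - 1] + go)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Affine score of one concrete gapped alignment (both rows same length).
score_gapped_pair <- function(ra, rb, scoring = align_scoring()) {
  ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sc <- 0; last <- ""
  for (k in seq_along(ca)) {
    if (ca[k] == "-" && cb[k] == "-") stop("all-gap column")
    if (ca[k] == "-") {
      sc <- sc + if (last == "Y") scoring$gap_extend else scoring$gap_open
      last <- "Y"
    } else if (cb[k] == "-") {
      sc <- sc + if (last == "X") scoring$gap_extend else scoring$gap_open
      last <- "X"
    } else {
      sc <- sc + if (ca[k] == cb[k]) scoring$match else scoring$mismatch
      last <- "M"
    }
  }
  sc
}

rand_seq <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
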