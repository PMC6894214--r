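test_that("XMFA parsing maps headers, strands, and coverage gaps", {
  set.seed(21)
  gA <- rand_seq(100)
  # one block, one genome, no gaps
  p1 <- tempfile(fileext = ".xmfa")
  writeLines(c("> 1:1-100 + A", gA, "="), p1)
  d1 <- parse_xmfa(p1, c(A = gA))
  expect_length(d1$blocks, 1L)
  expect_length(d1$blocks[[1]]$rows, 1L)
  expect_equal(d1$blocks[[1]]$rows[[1]]$start, 1)
  expect_equal(d1$blocks[[1]]$rows[[1]]$end, 100)

  # two blocks, one '-' strand row: the ungapped row must equal the
  # reverse complement of the forward-strand slice
  gB <- paste0(substr(gA, 1, 50), revcomp(substr(gA, 51, 100)))
  p2 <- tempfile(fileext = ".xmfa")
  writeLines(c("> 1:1-50 + A", substr(gA, 1, 50),
               "> 2:1-50 + B", substr(gB, 1, 50), "=",
               "> 1:51-100 + A", substr(gA, 51, 100),
               "> 2:51-100 - B", revcomp(substr(gB, 51, 100)), "="), p2)
  d2 <- parse_xmfa(p2, c(A = gA, B = gB))
  r <- d2$blocks[[2]]$rows[[2]]
  expect_equal(r$strand, "-")
  expect_identical(gsub("-", "", r$gapped_seq),
                   revcomp(substr(gB, 51, 100)))

  # coverage gap [51,60] becomes a synthesized singleton block
  p3 <- tempfile(fileext = ".xmfa")
  writeLines(c("> 1:1-50 + A", substr(gA, 1, 50), "=",
               "> 1:61-100 + A", substr(gA, 61, 100), "="), p3)
  d3 <- parse_xmfa(p3, c(A = gA))
  expect_length(d3$blocks, 3L)
  gap_block <- d3$blocks[[3]]
  expect_equal(gap_block$rows[[1]]$start, 51)
  expect_equal(gap_block$rows[[1]]$end, 60)
  expect_identical(gap_block$rows[[1]]$gapped_seq, substr(gA, 51, 60))

  # malformed header, inverted interval, overlapping coverage
  p4 <- tempfile(fileext = ".xmfa")
  writeLines(c("> one:1-50 +", substr(gA, 1, 50), "="), p4)
  expect_error(parse_xmfa(p4, c(A = gA)), "malformed XMFA header")
  p5 <- tempfile(fileext = ".xmfa")
  writeLines(c("> 1:50-1 + A", substr(gA, 1, 50), "="), p5)
  expect_error(parse_xmfa(p5, c(A = gA)), "start > end")
  p6 <- tempfile(fileext = ".xmfa")
  writeLines(c("> 1:1-60 + A", substr(gA, 1, 60), "=",
               "> 1:51-100 + A", substr(gA, 51, 100), "="), p6)
  expect_error(parse_xmfa(p6, c(A = gA)), "overlap")
})

test_that("the structural graph stores one temporary node per block", {
  set.seed(31)
  s <- rand_seq(60)
  blk <- progressive_msa(c(A = s, B = s), block_id = "Aln_1")
  d <- block_decomposition(list(blk), c(A = 60, B = 60))
  g <- build_structure_graph(d)
  expect_length(g$nodes, 1L)
  expect_length(g$edges, 0L)
  expect_equal(g$nodes[["Aln_1"]]$ids, c("A", "B"))
})

test_that("an inverted block is one structural node with negative reversed coords", {
  set.seed(32)
  left <- rand_seq(300); mid <- rand_seq(200); right <- rand_seq(300)
  g1 <- paste0(left, mid, right)
  g2 <- paste0(left, revcomp(mid), right)
  xmfa <- tempfile(fileext = ".xmfa")
  wrap <- function(s) substring(s, seq(1, nchar(s), 80),
                                pmin(seq(80, nchar(s) + 79, 80), nchar(s)))
  writeLines(c("> 1:1-300 + A", wrap(left), "> 2:1-300 + B", wrap(left), "=",
               "> 1:301-500 + A", wrap(mid), "> 2:301-500 - B", wrap(mid), "=",
               "> 1:501-800 + A", wrap(right), "> 2:501-800 + B", wrap(right), "="),
             xmfa)
  d <- parse_xmfa(xmfa, c(A = g1, B = g2))
  sg <- build_structure_graph(d)
  expect_length(sg$nodes, 3L)
  midnode <- sg$nodes[["Aln_2"]]
  expect_equal(unname(midnode$coords[["A"]]), c(301, 500))
  expect_equal(unname(midnode$coords[["B"]]), c(-500, -301))

  # the full build keeps the inversion in a single shared node and the
  # reconstruction reverse-complements it
  g <- build_genome_graph(c(A = g1, B = g2), xmfa = xmfa)
  expect_identical(reconstruct_sequence(g, "A"), g1)
  expect_identical(reconstruct_sequence(g, "B"), g2)
  shared_mid <- Filter(function(nd) {
    setequal(nd$ids, c("A", "B")) && nd$coords[["B"]][1] < 0
  }, g$nodes)
  expect_length(shared_mid, 1L)
  expect_equal(unname(shared_mid[[1]]$coords[["B"]]), c(-500, -301))
})

test_that("collapse groups columns by identical-character partition", {
  set.seed(41)
  # identical rows collapse to one node, no edges
  s <- rand_seq(30)
  blk <- progressive_msa(c(A = s, B = s), block_id = "Aln_9")
  sub <- collapse_block(blk)
  expect_length(sub$nodes, 1L)
  expect_length(sub$edges, 0L)
  expect_equal(sub$nodes[[1]]$ids, c("A", "B"))
  expect_equal(names(sub$nodes), "Aln_9_1")

  # tandem-repeat insertion: three nodes, middle private to the longer row
  P <- rand_seq(20); S <- rand_seq(20)
  long <- paste0(P, strrep("ATG", 5), S)
  short <- paste0(P, strrep("ATG", 2), S)
  blk2 <- progressive_msa(c(s1 = long, s2 = short))
  sub2 <- collapse_block(blk2)
  expect_length(sub2$nodes, 3L)
  private <- Filter(function(nd) length(nd$ids) == 1L, sub2$nodes)
  expect_length(private, 1L)
  expect_equal(private[[1]]$ids, "s1")
  expect_equal(nchar(private[[1]]$sequence), 9L)

  # one internal substitution: 4 nodes, inherited sequential names
  sA <- rand_seq(60)
  old <- substr(sA, 30, 30)
  sB <- paste0(substr(sA, 1, 29), setdiff(c("A", "C", "G", "T"), old)[1],
               substr(sA, 31, 60))
  blk3 <- progressive_msa(c(A = sA, B = sB), block_id = "Aln_66")
  sub3 <- collapse_block(blk3)
  expect_equal(names(sub3$nodes),
               c("Aln_66_1", "Aln_66_2", "Aln_66_3", "Aln_66_4"))
  # rows' paths spell their ungapped sequences
  expect_identical(reconstruct_sequence(sub3, "A"), sA)
  expect_identical(reconstruct_sequence(sub3, "B"), sB)
})

test_that("collapse coordinates respect genomic offsets and strands", {
  # a '-' strand row gets negative reversed coordinates advancing the
  # right way through the forward-strand interval
  rows <- list(
    list(isolate = "A", gapped_seq = "ACGTTT", start = 101, end = 106,
         strand = "+"),
    list(isolate = "B", gapped_seq = "ACCTTT", start = 201, end = 206,
         strand = "-"))
  blk <- aligned_block("Aln_5", rows)
  sub <- collapse_block(blk)
  # partition runs: AC | G/C | TTT
  expect_length(sub$nodes, 4L)
  first <- sub$nodes[["Aln_5_1"]]
  expect_equal(unname(first$coords[["A"]]), c(101, 102))
  expect_equal(unname(first$coords[["B"]]), c(-206, -205))
  last <- sub$nodes[["Aln_5_4"]]
  expect_equal(unname(last$coords[["A"]]), c(104, 106))
  expect_equal(unname(last$coords[["B"]]), c(-203, -201))
  # forward-strand genome of B: revcomp of its block-oriented sequence
  expect_identical(reconstruct_sequence(sub, "B"),
                   paste0(revcomp("ACCTTT")))
})

test_that("splice replaces a temporary node and preserves spans", {
  set.seed(51)
  s1 <- rand_seq(50); s2 <- rand_seq(50); s3 <- rand_seq(50)
  genomes <- c(A = paste0(s1, s2, s3))
  xmfa <- tempfile(fileext = ".xmfa")
  writeLines(c("> 1:1-50 + A", s1, "=",
               "> 1:51-100 + A", s2, "=",
               "> 1:101-150 + A", s3, "="), xmfa)
  d <- parse_xmfa(xmfa, genomes)
  g <- build_structure_graph(d)
  # identity splice: a single-node subgraph identical to the middle node
  sub <- genome_graph("A")
  sub <- add_node(sub, sequence_node("Aln_2_1", s2, "A", list(A = c(51, 100))))
  g2 <- splice_subgraph(g, "Aln_2", sub)
  expect_length(g2$nodes, 3L)
  expect_identical(reconstruct_sequence(g2, "A"), genomes[["A"]])

  # span mismatch is rejected
  bad <- genome_graph("A")
  bad <- add_node(bad, sequence_node("x", s2, "A", list(A = c(52, 101))))
  expect_error(splice_subgraph(g, "Aln_2", bad), "span mismatch")
  expect_error(splice_subgraph(g, "nope", sub), "no node named")
})

test_that("whole builds satisfy the round-trip and compression behaviour", {
  set.seed(61)
  # single genome: reconstruction equals input
  s <- rand_seq(500)
  g1 <- build_genome_graph(c(only = s))
  expect_identical(reconstruct_sequence(g1, "only"), s)

  # internal tandem insertion: final graph has 3 nodes
  P <- rand_seq(20); S <- rand_seq(20)
  g2 <- build_genome_graph(c(s1 = paste0(P, strrep("ATG", 5), S),
                             s2 = paste0(P, strrep("ATG", 2), S)))
  expect_length(g2$nodes, 3L)

  # identical copies stay a single node as genomes are added
  root <- rand_seq(300)
  for (k in c(2, 4)) {
    gk <- build_genome_graph(setNames(rep(root, k), paste0("g", seq_len(k))))
    expect_length(gk$nodes, 1L)
    expect_equal(gk$nodes[[1]]$ids, paste0("g", seq_len(k)))
  }
})
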