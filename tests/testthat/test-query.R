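test_that("sub-sequence extraction agrees with full-reconstruction slicing", {
  fx <- inversion_fixture()
  g <- build_genome_graph(fx$fasta_paths, xmfa = fx$xmfa_path)
  set.seed(71)
  for (iso in fx$isolates) {
    full <- reconstruct_sequence(g, iso)
    L <- nchar(full)
    expect_identical(extract_subsequence(g, iso, 1, L), full)
    for (i in 1:40) {
      a <- sample.int(L, 1); b <- sample(a:L, 1)
      expect_identical(extract_subsequence(g, iso, a, b), substr(full, a, b),
                       info = sprintf("%s [%d,%d]", iso, a, b))
    }
  }
  expect_error(extract_subsequence(g, "iso01", 0, 10), "out of range")
  expect_error(extract_subsequence(g, "iso01", 10, 5), "out of range")
  expect_error(extract_subsequence(g, "nope", 1, 5), "unknown isolate")
})

test_that("intervals inside a single forward node are direct substrings", {
  g <- insertion_graph()
  expect_identical(extract_subsequence(g, "A", 3, 7),
                   substr(g$nodes[["n1"]]$sequence, 3, 7))
})

test_that("gene extraction honours strand and node boundaries", {
  fx <- small_fixture()
  g <- build_genome_graph(fx$fasta_paths, xmfa = fx$xmfa_path)
  feat <- list(isolate = "iso02", start = 201, end = 340, strand = "+")
  truthseq <- substr(fx$genomes[["iso02"]], 201, 340)
  expect_identical(extract_gene_sequence(g, feat), truthseq)
  feat$strand <- "-"
  expect_identical(extract_gene_sequence(g, feat), revcomp(truthseq))
})

test_that("gene subgraphs isolate the covered nodes with a seq_len attribute", {
  set.seed(81)
  root <- rand_seq(600)
  # one SNP at 300 distinguishes B; gene [250,350] overlaps it
  old <- substr(root, 300, 300)
  gB <- paste0(substr(root, 1, 299), setdiff(c("A", "C", "G", "T"), old)[1],
               substr(root, 301, 600))
  g <- build_genome_graph(c(A = root, B = gB))
  snp_gene <- extract_gene_subgraph(g, list(isolate = "A", start = 250,
                                            end = 350, strand = "+"))
  expect_gte(length(snp_gene$nodes), 3L)
  parallel <- Filter(function(nd) length(nd$ids) == 1L, snp_gene$nodes)
  expect_length(parallel, 2L)
  expect_true(all(vapply(snp_gene$nodes, function(nd) {
    identical(nd$seq_len, nchar(nd$sequence))
  }, logical(1))))

  # a conserved gene is a single node containing every isolate
  cons_gene <- extract_gene_subgraph(g, list(isolate = "A", start = 10,
                                             end = 100, strand = "+"))
  expect_length(cons_gene$nodes, 1L)
  expect_setequal(cons_gene$nodes[[1]]$ids, c("A", "B"))

  # a feature spanning the whole genome returns the whole graph
  whole <- extract_gene_subgraph(g, list(isolate = "A", start = 1,
                                         end = 600, strand = "+"))
  expect_setequal(names(whole$nodes), names(g$nodes))
})

test_that("position translation follows insertions, inversions, and absences", {
  set.seed(91)
  pre <- rand_seq(100); post <- rand_seq(100)
  ins <- rand_seq(6)
  A <- paste0(pre, post)
  B <- paste0(pre, ins, post)   # 6 bp insertion upstream of positions > 100
  g <- build_genome_graph(c(A = A, B = B))
  expect_equal(translate_position(g, 150, "A", "A"), 150)
  expect_equal(translate_position(g, 150, "A", "B"), 156)
  expect_equal(translate_position(g, 156, "B", "A"), 150)
  # a position inside the B-only insertion has no A coordinate
  expect_true(is.na(translate_position(g, 103, "B", "A")))
  expect_error(translate_position(g, 0, "A", "B"), "outside")
  expect_error(translate_position(g, 1, "A", "Z"), "unknown isolate")

  # translation is its own inverse (on absolute positions) wherever defined
  fx <- inversion_fixture()
  gg <- build_genome_graph(fx$fasta_paths, xmfa = fx$xmfa_path)
  for (p in sample.int(nchar(fx$genomes[["iso01"]]), 50)) {
    q <- translate_position(gg, p, "iso01", "iso02")
    if (!is.na(q)) {
      expect_equal(abs(translate_position(gg, abs(q), "iso02", "iso01")), p,
                   info = sprintf("pos %d", p))
    }
  }
  # and it matches the generator's recorded coordinate map (iso01 is the
  # unmutated root, so root coordinates are iso01 coordinates)
  tr <- fx$truths[["iso02"]]
  for (p in sample.int(tr$root_length, 50)) {
    expected <- truth_translate(tr, p)
    got <- translate_position(gg, p, "iso01", "iso02")
    if (!is.na(expected) && !is.na(got)) {
      expect_equal(abs(got), expected, info = sprintf("pos %d", p))
    }
  }
})

test_that("the largest conserved node is found exactly", {
  g1 <- genome_graph("A")
  g1 <- add_node(g1, sequence_node("n1", "ACGT", "A", list(A = c(1, 4))))
  expect_equal(largest_conserved_node(g1)$name, "n1")

  # SNPs at 100 and 1600 leave a conserved run [101,1599] of 1499 bp
  set.seed(95)
  root <- rand_seq(2000)
  flip <- function(s, p) {
    old <- substr(s, p, p)
    paste0(substr(s, 1, p - 1), setdiff(c("A", "C", "G", "T"), old)[1],
           substr(s, p + 1, nchar(s)))
  }
  B <- flip(flip(root, 100), 1600)
  g <- build_genome_graph(c(A = root, B = B))
  top <- largest_conserved_node(g)
  expect_equal(nchar(top$sequence), 1499L)
  expect_equal(unname(top$coords[["A"]]), c(101, 1599))

  # no universal node -> NULL
  g2 <- genome_graph(c("A", "B"))
  g2 <- add_node(g2, sequence_node("a", "ACGT", "A", list(A = c(1, 4))))
  g2 <- add_node(g2, sequence_node("b", "ACGT", "B", list(B = c(1, 4))))
  expect_null(largest_conserved_node(g2))
})

test_that("isolate-specific short nodes use a strict length bound", {
  set.seed(96)
  root <- rand_seq(500)
  expect_length(isolate_specific_nodes(
    build_genome_graph(c(A = root, B = root))), 0L)

  old <- substr(root, 250, 250)
  B <- paste0(substr(root, 1, 249), setdiff(c("A", "C", "G", "T"), old)[1],
              substr(root, 251, 500))
  g <- build_genome_graph(c(A = root, B = B))
  snps <- isolate_specific_nodes(g)
  expect_length(snps, 2L)   # the two parallel 1 bp variant nodes
  expect_true(all(vapply(snps, function(nd) nchar(nd$sequence) == 1L,
                         logical(1))))

  # a 3 bp private insertion node is excluded at the default bound
  C <- paste0(substr(root, 1, 250), "TTT", substr(root, 251, 500))
  g2 <- build_genome_graph(c(A = root, C = C))
  with_default <- isolate_specific_nodes(g2)
  expect_length(with_default, 0L)
  with_larger <- isolate_specific_nodes(g2, max_len = 4)
  expect_length(with_larger, 1L)
  expect_equal(nchar(with_larger[[1]]$sequence), 3L)
})

test_that("homology mapping recovers generator truth, paralogues included", {
  set.seed(97)
  cassette <- rand_seq(200)
  root <- paste0(rand_seq(400), cassette, rand_seq(600), cassette,
                 rand_seq(400), rand_seq(200))
  fx <- make_fixture_set(
    3, root_length = nchar(root), root = root,
    rates = mutation_rates(sub_rate = 0.003, ins_rate = 3e-4, del_rate = 3e-4),
    seed = 23, block_length = 1000)
  g <- build_genome_graph(fx$fasta_paths, xmfa = fx$xmfa_path)
  root_genes <- data.frame(
    gene = c("g1", "parA", "g2", "parB", "g3"),
    root_start = c(50, 401, 750, 1201, 1500),
    root_end = c(250, 600, 1050, 1400, 1750))
  anns <- fixture_genes(fx, root_genes)
  mat <- homology_matrix(g, anns)
  for (iso in fx$isolates) {
    expect_equal(mat[[iso]], paste0(iso, "_", root_genes$gene),
                 info = iso)
  }
  # symmetry: swapping the reference transposes the 1:1 mapping
  mat2 <- homology_matrix(g, anns, reference = "iso02")
  expect_equal(rownames(mat2), paste0("iso02_", root_genes$gene))
  expect_equal(mat2[["iso01"]], paste0("iso01_", root_genes$gene))

  # self-mapping is the identity
  self <- homology_matrix(g, anns["iso01"])
  expect_equal(self[["iso01"]], rownames(self))
  expect_error(homology_matrix(g, list(iso01 = data.frame(
    gene_id = "bad", start = 1, end = 10 * nchar(root), strand = "+"))),
    "outside")
})
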