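test_that("zero rates leave the root untouched with empty truth", {
  set.seed(1)
  root <- rand_seq(500)
  tr <- mutate_genome(root, mutation_rates(), seed = 3)
  expect_identical(tr$derived, root)
  expect_equal(nrow(tr$events), 0L)
  expect_equal(tr$derived_length, 500)
})

test_that("substitution counts match an independent character recount", {
  set.seed(2)
  root <- rand_seq(1000)
  tr <- mutate_genome(root, mutation_rates(sub_rate = 0.005), seed = 9)
  n_subs <- sum(tr$events$type == "substitution")
  hamming <- sum(strsplit(root, "")[[1]] != strsplit(tr$derived, "")[[1]])
  expect_equal(nchar(tr$derived), 1000)
  expect_equal(hamming, n_subs)
  expect_gt(n_subs, 0)
})

test_that("an inversion event reverse-complements exactly its segment", {
  set.seed(3)
  root <- rand_seq(2000)
  tr <- mutate_genome(root, mutation_rates(inv_count = 1, inv_length = 300),
                      seed = 5)
  ev <- tr$events[tr$events$type == "inversion", ]
  expect_equal(nrow(ev), 1L)
  s <- ev$root_start; e <- ev$root_end
  expect_identical(substr(tr$derived, s, e), revcomp(substr(root, s, e)))
  expect_identical(substr(tr$derived, 1, s - 1), substr(root, 1, s - 1))
})

test_that("the recorded coordinate map matches naive event replay", {
  set.seed(4)
  root <- rand_seq(3000)
  tr <- mutate_genome(root, mutation_rates(sub_rate = 0.003, ins_rate = 1e-3,
                                           del_rate = 1e-3, inv_count = 1,
                                           repeat_expansions = 1),
                      seed = 13)
  origin <- naive_origin_map(root, tr$events)
  expect_equal(length(origin), tr$derived_length)
  # invert the naive map: root position -> derived position
  for (p in sample.int(nchar(root), 80)) {
    got <- truth_translate(tr, p)
    expected <- match(p, origin)
    if (is.na(expected)) {
      expect_true(is.na(got), info = sprintf("deleted root pos %d", p))
    } else {
      expect_equal(got, expected, info = sprintf("root pos %d", p))
    }
  }
  # monotone outside inverted segments
  inv <- tr$events[tr$events$type == "inversion", ]
  outside <- setdiff(seq_len(nchar(root)), inv$root_start:inv$root_end)
  mapped <- vapply(outside, function(p) truth_translate(tr, p), numeric(1))
  mapped <- mapped[!is.na(mapped)]
  expect_true(all(diff(mapped) > 0))
})

test_that("fixture sets are deterministic and shaped as declared", {
  d1 <- tempfile(); d2 <- tempfile()
  fx1 <- make_fixture_set(2, root_length = 1500,
                          rates = mutation_rates(sub_rate = 0.002),
                          seed = 99, dir = d1)
  fx2 <- make_fixture_set(2, root_length = 1500,
                          rates = mutation_rates(sub_rate = 0.002),
                          seed = 99, dir = d2)
  for (iso in fx1$isolates) {
    expect_identical(readLines(fx1$fasta_paths[[iso]]),
                     readLines(fx2$fasta_paths[[iso]]))
  }
  expect_identical(readLines(fx1$xmfa_path), readLines(fx2$xmfa_path))

  # n = 1: the single genome is the unmutated root
  fx <- make_fixture_set(1, root_length = 800, seed = 5)
  expect_identical(fx$genomes[[1]], fx$root)

  # substitutions only, block length >= root: a single all-genome block
  fx3 <- make_fixture_set(3, root_length = 900,
                          rates = mutation_rates(sub_rate = 0.002),
                          seed = 6, block_length = 900)
  d <- parse_xmfa(fx3$xmfa_path, fx3$genomes)
  expect_length(d$blocks, 1L)
  expect_length(d$blocks[[1]]$rows, 3L)

  # one inversion: three blocks, the middle one '-' strand for genome 2
  fx4 <- make_fixture_set(2, root_length = 2000,
                          rates = mutation_rates(inv_count = 1,
                                                 inv_length = 400),
                          seed = 8, block_length = 2000)
  d4 <- parse_xmfa(fx4$xmfa_path, fx4$genomes)
  expect_length(d4$blocks, 3L)
  strands <- vapply(d4$blocks, function(b) {
    r <- b$rows[[match("iso02", vapply(b$rows, `[[`, character(1), "isolate"))]]
    r$strand
  }, character(1))
  expect_equal(sum(strands == "-"), 1L)
  expect_equal(strands[2], "-")
})

test_that("rates that cannot fit the root are rejected", {
  expect_error(mutate_genome("ACGTACGT",
                             mutation_rates(inv_count = 5, inv_length = 4),
                             seed = 1),
               "exhaust")
})
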