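# Shared in-code fixtures.

# A hand-built 3-node insertion graph: isolate A carries an internal
# insertion absent from B (shared prefix / A-only middle / shared
# suffix).
insertion_graph <- function() {
  g <- genome_graph(c("A", "B"))
  g <- add_node(g, sequence_node("n1", "ACGTACGTAC", c("A", "B"),
                                 list(A = c(1, 10), B = c(1, 10))))
  g <- add_node(g, sequence_node("n2", "TTTTT", "A", list(A = c(11, 15))))
  g <- add_node(g, sequence_node("n3", "GGCCGGCC", c("A", "B"),
                                 list(A = c(16, 23), B = c(11, 18))))
  g <- add_edge(g, "n1", "n2", "A")
  g <- add_edge(g, "n2", "n3", "A")
  g <- add_edge(g, "n1", "n3", "B")
  g
}

# Two-isolate graph whose second node is inverted in B:
# B's genome is n1 + revcomp(n2).
inverted_node_graph <- function() {
  g <- genome_graph(c("A", "B"))
  g <- add_node(g, sequence_node("n1", "ACGTACGTAC", c("A", "B"),
                                 list(A = c(1, 10), B = c(1, 10))))
  g <- add_node(g, sequence_node("n2", "AACCG", c("A", "B"),
                                 list(A = c(11, 15), B = c(-15, -11))))
  g <- add_edge(g, "n1", "n2", c("A", "B"))
  g
}

# Small substitution/indel fixture (no rearrangements) built through
# the synthetic generator; deterministic for the given seed.
small_fixture <- function(n_genomes = 3, seed = 11, root_length = 2000,
                          rates = mutation_rates(sub_rate = 0.002,
                                                 ins_rate = 3e-4,
                                                 del_rate = 3e-4)) {
  make_fixture_set(n_genomes, root_length = root_length, rates = rates,
                   seed = seed, block_length = 1000)
}

# Fixture containing one segmental inversion (plus SNPs/indels).
inversion_fixture <- function(n_genomes = 3, seed = 7, root_length = 5000) {
  make_fixture_set(n_genomes, root_length = root_length,
                   rates = mutation_rates(sub_rate = 0.002, ins_rate = 2e-4,
                                          del_rate = 2e-4, inv_count = 1),
                   seed = seed, block_length = 1000)
}

# Attribute-for-attribute graph equality (nodes, edges, isolates,
# metadata), used for serialization round-trips.
graphs_equal <- function(a, b) {
  expect_equal(a$isolates, b$isolates)
  na <- names(a$metadata); if (is.null(na)) na <- character(0)
  nb <- names(b$metadata); if (is.null(nb)) nb <- character(0)
  expect_setequal(na, nb)
  for (nm in na) expect_equal(a$metadata[[nm]], b$metadata[[nm]])
  ta <- node_table(a); tb <- node_table(b)
  expect_equal(ta[order(ta$name), ], tb[order(tb$name), ],
               ignore_attr = TRUE)
  ea <- edge_table(a); eb <- edge_table(b)
  expect_equal(ea[order(ea$name), ], eb[order(eb$name), ],
               ignore_attr = TRUE)
}

# Independent root->derived coordinate map recomputed by naive event
# replay with explicit per-base origin labels (oracle for
# truth_translate).
naive_origin_map <- function(root, events) {
  L <- nchar(root)
  origin <- as.list(seq_len(L))   # per root base, start as itself
  # represent derived genome as a list of (root origin | NA) per base
  out <- integer(0)
  pos <- 1
  add_range <- function(v) out <<- c(out, v)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$root_start > pos) add_range(pos:(ev$root_start - 1))
    if (ev$type == "substitution") {
      add_range(ev$root_start)
      pos <- ev$root_start + 1
    } else if (ev$type == "deletion") {
      pos <- ev$root_end + 1
    } else if (ev$type == "inversion") {
      add_range(rev(ev$root_start:ev$root_end))
      pos <- ev$root_end + 1
    } else if (ev$type == "insertion") {
      add_range(ev$root_start)
      add_range(rep(NA_integer_, nchar(ev$payload)))
      pos <- ev$root_start + 1
    } else if (ev$type == "tandem_expansion") {
      add_range(ev$root_start:ev$root_end)
      add_range(rep(NA_integer_, nchar(ev$payload)))
      pos <- ev$root_end + 1
    }
  }
  if (pos <= L) add_range(pos:L)
  out   # derived position k arose from root position out[k] (NA = inserted)
}
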