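set.seed(53)

# candidate assemblies with no paths: every element is its own contig
plain_candidates <- function(seqs) assembly(seqs, label = "cand")

test_that("coverage matrix unions intervals without double counting", {
  seqs <- c(x = rand_seq(100), y = rand_seq(300))
  cand <- plain_candidates(seqs)
  # two alignments covering x's [0,60) and [40,100): union = 100%
  aset <- make_aset(list(aln_row("x", "y", 0, 60, 0, 60),
                         aln_row("x", "y", 40, 100, 140, 200)), seqs)
  m <- coverage_matrix(cand, list(), aset)
  expect_equal(m["x", "y"], 1.0)
  expect_equal(m["y", "x"], (60 + 60) / 300)
  # no alignments between a pair -> 0
  seqs2 <- c(seqs, z = rand_seq(50))
  m2 <- coverage_matrix(plain_candidates(seqs2), list(),
                        make_aset(list(aln_row("x", "y", 0, 60, 0, 60)),
                                  seqs2))
  expect_equal(m2["z", "x"], 0)
  expect_equal(diag(m2), c(x = 0, y = 0, z = 0))
})

test_that("coverage projects through path layouts and skips intra-path pairs", {
  op <- overlap_pair(100L, 80L, 20L)
  eg <- build_graph(op$aset)
  ps <- milps(eg)
  contigs <- op$aset$contigs
  fc <- final_candidates(ps, eg, contigs)
  # leftover contig identical in span to A: fully covered by the path
  seqs <- c(as.character(contigs$seq), z__D = rand_seq(100))
  cand <- assembly(c(MIX__path_1 = as.character(fc$assembly$seq[["MIX__path_1"]]),
                     z__D = seqs[["z__D"]]), label = "cand")
  rows <- rbind(op$aset$tab[aln_cols],
                as.data.frame(aln_row("z__D", "x__A", 0, 100, 0, 100)))
  aset <- mixasm::alignment_set(rows, assembly(seqs))
  m <- coverage_matrix(cand, fc$layouts, aset)
  expect_equal(m["z__D", "MIX__path_1"], 1.0)
  # the path is only partially covered by z__D (100 of 160 bases)
  expect_equal(m["MIX__path_1", "z__D"], 100 / 160)
})

test_that("edge direction follows ratio, then length, then id", {
  lens <- list(x = 500L, y = 800L)
  m <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  m["x", "y"] <- 0.95; m["y", "x"] <- 0.10
  g <- build_coverage_graph(m, lens)
  expect_identical(igraph::as_ids(igraph::E(g)), "x|y")
  # tie on ratio: shorter is the source
  m["y", "x"] <- 0.95
  g2 <- build_coverage_graph(m, lens)
  expect_identical(igraph::as_ids(igraph::E(g2)), "x|y")
  # tie on ratio and length: lexicographically smaller id
  g3 <- build_coverage_graph(m, list(x = 500L, y = 500L))
  expect_identical(igraph::as_ids(igraph::E(g3)), "x|y")
  # below threshold: no edge
  m[,] <- 0.5
  expect_equal(igraph::ecount(build_coverage_graph(m, lens)), 0L)
})

test_that("break_cycles keeps the longest element of each component", {
  m <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  m["x", "y"] <- 0.95; m["y", "x"] <- 0.97
  # force a 2-cycle by hand (build_coverage_graph never makes one)
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("x", "y"), to = c("y", "x"), ratio = 0.95),
    vertices = data.frame(name = c("x", "y")))
  g2 <- break_cycles(g, list(x = 900L, y = 700L))
  expect_true(igraph::is_dag(g2))
  expect_identical(igraph::as_ids(igraph::E(g2)), "y|x")  # x survives
  # acyclic input unchanged
  g3 <- igraph::graph_from_data_frame(
    data.frame(from = "x", to = "y", ratio = 0.95),
    vertices = data.frame(name = c("x", "y")))
  expect_identical(igraph::as_ids(igraph::E(break_cycles(g3, list(x = 1, y = 2)))),
                   "x|y")
  # equal lengths: lexicographic tie-break, 'a' survives a 3-cycle
  g4 <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"), ratio = 0.9),
    vertices = data.frame(name = c("a", "b", "c")))
  g5 <- break_cycles(g4, list(a = 100L, b = 100L, c = 100L))
  expect_true(igraph::is_dag(g5))
  expect_setequal(igraph::as_ids(igraph::E(g5)), c("b|a", "c|a"))
})

test_that("the covered-chain example prunes to the top element", {
  seqs <- c(A = rand_seq(300), B = rand_seq(400), C = rand_seq(500))
  cand <- plain_candidates(seqs)
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C"), ratio = 0.95),
    vertices = data.frame(name = c("A", "B", "C")))
  out <- prune_candidates(g, cand)
  expect_identical(names(out$assembly$seq), "C")
  expect_setequal(out$report$element[out$report$decision == "removed"],
                  c("A", "B"))
  # no edges: nothing pruned
  g0 <- igraph::graph_from_data_frame(
    data.frame(from = character(), to = character(), ratio = numeric()),
    vertices = data.frame(name = names(seqs)))
  expect_length(prune_candidates(g0, cand)$assembly$seq, 3L)
})

test_that("full pruning removes a 95%-contained contig and is idempotent", {
  op <- overlap_pair(100L, 80L, 20L)
  eg <- build_graph(op$aset)
  ps <- milps(eg)
  contigs <- op$aset$contigs
  fc <- final_candidates(ps, eg, contigs)
  # add a leftover contig 95% covered by the path via an alignment to A
  seqs <- c(as.character(contigs$seq), z__D = rand_seq(100))
  all_ctg <- assembly(seqs)
  rows <- rbind(op$aset$tab[aln_cols],
                as.data.frame(aln_row("z__D", "x__A", 0, 95, 0, 95)))
  aset <- mixasm::alignment_set(rows, all_ctg)
  cand <- assembly(c(MIX__path_1 = as.character(fc$assembly$seq[["MIX__path_1"]]),
                     z__D = seqs[["z__D"]]))
  out <- prune_assembly(cand, fc$layouts, aset)
  expect_identical(names(out$assembly$seq), "MIX__path_1")
  # idempotence on the surviving set
  out2 <- prune_assembly(out$assembly, fc$layouts, aset)
  expect_identical(names(out2$assembly$seq), names(out$assembly$seq))
  # protection flag keeps a covered path
  outp <- prune_candidates(
    igraph::graph_from_data_frame(
      data.frame(from = "MIX__path_1", to = "z__D", ratio = 0.99),
      vertices = data.frame(name = c("MIX__path_1", "z__D"))),
    cand, protect = "MIX__path_1")
  expect_true("MIX__path_1" %in% names(outp$assembly$seq))
})
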