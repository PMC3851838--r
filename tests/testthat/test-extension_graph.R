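set.seed(23)

test_that("is_terminal implements the four extremity disjuncts", {
  seqs <- c(A = rand_seq(100), B = rand_seq(100))
  # end of A against start of B: terminal
  t1 <- make_aset(list(aln_row("A", "B", 80, 100, 0, 20)), seqs)
  expect_true(is_terminal(t1))
  # purely internal on both: not terminal
  t2 <- make_aset(list(aln_row("A", "B", 40, 60, 40, 60)), seqs)
  expect_false(is_terminal(t2))
  # internal on one side only: not terminal
  t3 <- make_aset(list(aln_row("A", "B", 80, 100, 40, 60)), seqs)
  expect_false(is_terminal(t3))
})

test_that("end tolerance relaxes extremity membership", {
  seqs <- c(A = rand_seq(100), B = rand_seq(100))
  aset <- make_aset(list(aln_row("A", "B", 78, 98, 3, 23)), seqs)
  expect_false(is_terminal(aset, eps = 0L))
  # oracle: enumerate the four disjuncts with eps-relaxed membership
  for (eps in c(1L, 2L, 3L, 5L)) {
    near <- function(x, len) x <= eps || x >= len - eps
    cond <- (near(78, 100) || near(98, 100)) && (near(3, 100) || near(23, 100))
    expect_identical(unname(is_terminal(aset, eps = eps)), cond,
                     info = paste("eps", eps))
  }
})

test_that("one gluable alignment yields 8 nodes + In/Out and weight |Ci|+|Cj|-l", {
  op <- overlap_pair(100L, 80L, 20L)
  eg <- build_graph(op$aset)
  expect_equal(igraph::vcount(eg$graph), 10L)
  expect_equal(eg$dropped_nonterminal, 0L)
  expect_equal(eg$dropped_nongluable, 0L)
  # brute-force path enumeration on the 10-node graph (independent oracle)
  paths <- enum_simple_paths(eg$graph)
  expect_gt(length(paths), 0L)
  ws <- vapply(paths, `[[`, 0, "weight")
  expect_equal(max(ws), 100 + 80 - 20)
  # the two maximal paths are the mirror pair
  expect_equal(sum(ws == 160), 2L)
})

test_that("node count is 8 per gluable terminal alignment plus In/Out", {
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    sim <- simulate_mix(sim_spec(genome_len = 30000L, mean_contig = 10000L,
                                 ov_min = 300L, ov_max = 1500L,
                                 n_assemblies = 2L, seed = rep))
    cl <- clean_alignments(sim$aset)
    eg <- build_graph(cl$aset)
    n_used <- sum(is_terminal(cl$aset)) - eg$dropped_nongluable
    expect_equal(igraph::vcount(eg$graph), 8L * n_used + 2L)
  }
})

test_that("same-side forward terminal alignments admit no gluing", {
  seqs <- c(A = rand_seq(100), B = rand_seq(100))
  # both prefixes, forward: terminal but not a dovetail
  aset <- make_aset(list(aln_row("A", "B", 0, 20, 0, 20)), seqs)
  eg <- build_graph(aset)
  expect_equal(eg$dropped_nongluable, 1L)
  expect_equal(igraph::vcount(eg$graph), 2L)
  # same geometry on reverse strand is gluable
  aset2 <- make_aset(list(aln_row("A", "B", 0, 20, 0, 20, TRUE)), seqs)
  eg2 <- build_graph(aset2)
  expect_equal(eg2$dropped_nongluable, 0L)
  expect_equal(igraph::vcount(eg2$graph), 10L)
})

test_that("shared contig gets inter-alignment edges weighted by the gap", {
  # A--(alpha)--B--(gamma)--C with both footprints on B
  lB <- 200L; la <- 30L; lg <- 40L
  seqs <- c(A = rand_seq(100), B = rand_seq(lB), C = rand_seq(120))
  aset <- make_aset(list(
    aln_row("A", "B", 70, 100, 0, la),              # alpha: end A / start B
    aln_row("B", "C", lB - lg, lB, 0, lg)), seqs)   # gamma: end B / start C
  eg <- build_graph(aset)
  expect_equal(igraph::vcount(eg$graph), 18L)
  oe <- igraph::E(eg$graph)[igraph::E(eg$graph)$eclass == "orange"]
  expect_equal(length(oe), 2L)  # one per direction
  expect_true(all(oe$weight == lB - la - lg))
  # the best path spells A then B then C once each
  best <- milps(eg)
  expect_length(best, 1L)
  expect_equal(best[[1]]$weight, 100 + lB + 120 - la - lg)
})

test_that("overlapping footprints on a shared contig are not connected", {
  seqs <- c(A = rand_seq(100), B = rand_seq(60), C = rand_seq(120))
  aset <- make_aset(list(
    aln_row("A", "B", 60, 100, 0, 40),
    aln_row("B", "C", 30, 60, 0, 30)), seqs)  # footprints overlap on B
  eg <- build_graph(aset)
  expect_equal(eg$skipped_orange, 2L)
  expect_length(igraph::E(eg$graph)[igraph::E(eg$graph)$eclass == "orange"],
                0L)
})

test_that("the graph is mirror-symmetric", {
  set.seed(7)
  sim <- simulate_mix(sim_spec(genome_len = 40000L, mean_contig = 12000L,
                               ov_min = 300L, ov_max = 1500L, seed = 3))
  eg <- build_graph(clean_alignments(sim$aset)$aset)
  g <- eg$graph
  ft <- igraph::ends(g, igraph::E(g))
  mirror <- function(v) vapply(v, function(x)
    switch(x, In = "Out", Out = "In", reverse_variant(x)), "",
    USE.NAMES = FALSE)
  # reversing every edge and flipping direction variants maps E onto E
  key <- function(a, b) paste(a, b, sep = ">")
  orig <- sort(key(ft[, 1], ft[, 2]))
  mirr <- sort(key(mirror(ft[, 2]), mirror(ft[, 1])))
  expect_identical(orig, mirr)
  # and weights agree across the mapping
  wmap <- stats::setNames(igraph::E(g)$weight, key(ft[, 1], ft[, 2]))
  expect_equal(unname(wmap[key(mirror(ft[, 2]), mirror(ft[, 1]))]),
               unname(wmap[key(ft[, 1], ft[, 2])]))
})

test_that("no path claims more bases than its contigs contain", {
  op <- overlap_pair(120L, 90L, 30L)
  eg <- build_graph(op$aset)
  for (p in enum_simple_paths(eg$graph)) {
    ctgs <- unique(vapply(path_interior(p),
                          function(v) strsplit(v, "\x1f")[[1]][1], ""))
    expect_lte(p$weight, sum(nchar(op$seqs[ctgs])))
  }
})

test_that("reverse_variant is an involution and rejects In/Out", {
  op <- overlap_pair()
  v <- setdiff(igraph::V(eg <- build_graph(op$aset)$graph)$name,
               c("In", "Out"))
  expect_identical(reverse_variant(reverse_variant(v)), v)
  expect_false(any(reverse_variant(v) == v))
  expect_error(reverse_variant("In"), "In/Out")
})

test_that("empty cleaned set yields the bare In/Out graph", {
  op <- overlap_pair()
  eg <- build_graph(aset_subset_empty(op$aset))
  expect_equal(sort(igraph::V(eg$graph)$name), c("In", "Out"))
  expect_equal(igraph::ecount(eg$graph), 0L)
  expect_length(milps(eg), 0L)
})
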