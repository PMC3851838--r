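set.seed(11)

test_that("rule 1 removes self alignments only", {
  seqs <- c(A = rand_seq(300), B = rand_seq(300))
  aset <- make_aset(list(aln_row("A", "A", 0, 50, 100, 150),
                         aln_row("A", "B", 0, 50, 0, 50)), seqs)
  out <- remove_self_alignments(aset)
  expect_equal(out$tab$cj, "B")
  expect_equal(length(remove_self_alignments(out)), 1L)  # identity
  empty <- aset_subset_empty(aset)
  expect_length(remove_self_alignments(empty), 0L)
})

test_that("rule 2 keeps one of a reciprocal same-region pair", {
  seqs <- c(A = rand_seq(100), B = rand_seq(100))
  aset <- make_aset(list(aln_row("A", "B", 0, 20, 0, 20),
                         aln_row("B", "A", 0, 20, 0, 20)), seqs)
  out <- dedupe_reciprocal(aset)
  expect_equal(length(out), 1L)
  expect_equal(out$tab$ci, "A")  # lexicographically smaller (ci, cj) wins
  # disjoint regions on A survive as distinct alignments
  aset2 <- make_aset(list(aln_row("A", "B", 0, 20, 0, 20),
                          aln_row("B", "A", 30, 50, 50, 70)), seqs)
  expect_equal(length(dedupe_reciprocal(aset2)), 2L)
  # single alignment untouched
  aset3 <- make_aset(list(aln_row("A", "B", 0, 20, 0, 20)), seqs)
  expect_equal(length(dedupe_reciprocal(aset3)), 1L)
})

test_that("rule 2 same-region decision follows the reciprocal-overlap oracle", {
  # oracle: both projected intervals overlap >= 50% reciprocally
  seqs <- c(A = rand_seq(200), B = rand_seq(200))
  cases <- list(
    list(a = c(0, 40), b = c(0, 40), dup = TRUE),     # identical
    list(a = c(0, 40), b = c(20, 60), dup = TRUE),    # 50% of each
    list(a = c(0, 40), b = c(25, 65), dup = FALSE),   # < 50%
    list(a = c(0, 40), b = c(100, 140), dup = FALSE)) # disjoint
  for (cs in cases) {
    aset <- make_aset(list(
      aln_row("A", "B", cs$a[1], cs$a[2], cs$a[1], cs$a[2]),
      aln_row("B", "A", cs$b[1], cs$b[2], cs$b[1], cs$b[2])), seqs)
    expect_equal(length(dedupe_reciprocal(aset)), if (cs$dup) 1L else 2L,
                 info = paste(unlist(cs), collapse = ","))
  }
})

test_that("rule 3 is strict: l == t_a is removed", {
  seqs <- c(A = rand_seq(500), B = rand_seq(500))
  aset <- make_aset(list(aln_row("A", "B", 0, 120, 0, 120),
                         aln_row("A", "B", 200, 300, 200, 300)), seqs)
  out <- filter_by_length(aset, 100L)
  expect_equal(out$tab$l, 120L)
  expect_length(filter_by_length(aset, 0L), 2L)
  expect_error(filter_by_length(aset, -1L), "t_a")
})

test_that("rule 4 boundary: exactly 99% is kept, above is removed", {
  seqs <- c(A = rand_seq(1000), B = rand_seq(2000), C = rand_seq(1000))
  aset <- make_aset(list(aln_row("A", "B", 0, 995, 0, 995),     # 99.5% of A
                         aln_row("A", "B", 0, 990, 0, 990),     # exactly 99%
                         aln_row("C", "B", 0, 10, 0, 10)), seqs)
  out <- filter_containment(aset)
  expect_equal(out$tab$l, c(990L, 10L))
})

test_that("rule 5 flags count outliers per the quartile fence", {
  # counts {A:2, B:3, C:2, D:3, E:40}: Q3 = 3, IQR = 1, fence = 6 -> {E}
  seqs <- setNames(lapply(1:5, function(i) rand_seq(5000)),
                   c("A", "B", "C", "D", "E"))
  seqs <- unlist(seqs)
  rows <- list()
  pair <- function(x, y, k) aln_row(x, y, 10 * k, 10 * k + 5, 10 * k, 10 * k + 5)
  rows <- c(list(pair("A", "B", 1), pair("A", "C", 2), pair("B", "D", 3),
                 pair("C", "D", 4), pair("B", "E", 5)),
            lapply(6:24, function(k) pair("E", "E", k)))
  # counts: A2 B3 C2 D3 E39(+1 from pair B,E)=... build counts directly:
  aset <- make_aset(rows, seqs)
  cnt <- table(c(aset$tab$ci, aset$tab$cj))
  expect_true(cnt[["E"]] > 6)
  expect_identical(detect_spurious(aset), "E")
  # equal counts -> nothing flagged
  aset_eq <- make_aset(list(pair("A", "B", 1), pair("C", "D", 2)), seqs)
  expect_length(detect_spurious(aset_eq), 0L)
  expect_length(detect_spurious(aset_subset_empty(aset)), 0L)
})

test_that("clean applies rules in order and tallies the report", {
  set.seed(42)
  # fixture violating each rule exactly once
  seqs <- c(A = rand_seq(2000), B = rand_seq(2000), C = rand_seq(2000),
            D = rand_seq(300), E = rand_seq(2000))
  rows <- list(
    aln_row("A", "A", 0, 400, 600, 1000),          # rule 1
    aln_row("A", "B", 0, 400, 0, 400),             # survivor
    aln_row("B", "A", 0, 400, 0, 400),             # rule 2 duplicate
    aln_row("A", "C", 500, 650, 500, 650),         # rule 3 (l=150 <= 200)
    aln_row("D", "E", 0, 299, 0, 299),             # rule 4 (99.7% of D)
    aln_row("B", "C", 0, 300, 0, 300))             # survivor
  aset <- make_aset(rows, seqs)
  out <- clean_alignments(aset, t_a = 200L)
  r <- out$report
  expect_equal(r$removed_self, 1L)
  expect_equal(r$removed_reciprocal, 1L)
  expect_equal(r$removed_short, 1L)
  expect_equal(r$removed_contained, 1L)
  expect_equal(r$removed_spurious, 0L)
  expect_equal(r$n_in - r$n_out,
               r$removed_self + r$removed_reciprocal + r$removed_short +
                 r$removed_contained + r$removed_spurious)
  expect_equal(length(out$aset), 2L)
  # already-clean set: identity with zero report
  again <- clean_alignments(out$aset, t_a = 200L)
  expect_equal(again$report$n_in, again$report$n_out)
  expect_equal(again$aset$tab, out$aset$tab)
  # empty set
  e <- clean_alignments(aset_subset_empty(aset), t_a = 200L)
  expect_equal(e$report$n_out, 0L)
})

test_that("survivors are monotone in t_a", {
  set.seed(5)
  seqs <- setNames(vapply(1:6, function(i) rand_seq(3000), ""),
                   LETTERS[1:6])
  rows <- lapply(1:20, function(k) {
    l <- sample(50:1500, 1)
    ids <- sample(LETTERS[1:6], 2)
    aln_row(ids[1], ids[2], 0, l, 0, l)
  })
  aset <- make_aset(rows, seqs)
  prev <- NULL
  for (ta in c(0L, 100L, 400L, 1000L)) {
    ids <- filter_by_length(aset, ta)$tab$aid
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})
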