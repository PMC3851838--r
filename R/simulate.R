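# Synthetic genomes, fragmentations and ground-truth alignments.
#
# The generator emulates the situation the merger is designed for: one
# underlying (bacterial-sized) genome independently fragmented into several
# draft "assemblies" whose contigs tile the genome with staggered
# breakpoints, so that contigs of different drafts share terminal overlaps
# while contigs within one draft abut without overlap. Ground-truth
# alignments are emitted directly from the known genome intervals, standing
# in for an external aligner.

#' Simulation specification
#'
#' @param genome_len genome length in bases.
#' @param gc GC fraction of the i.i.d. genome (default 0.38, a typical
#'   bacterial value).
#' @param n_assemblies number of independent fragmentations (2 or 3).
#' @param mean_contig target mean contig length in bases.
#' @param ov_min,ov_max bounds of the terminal-overlap (breakpoint stagger)
#'   length between drafts, in bases.
#' @param error_rate per-base substitution probability applied to each
#'   contig (no indels, so alignment coordinates stay exact).
#' @param revcomp_prob probability that a contig is stored
#'   reverse-complemented (orientation recorded in the truth table).
#' @param seed integer seed fixing all randomness.
#' @export
sim_spec <- function(genome_len = 100000L, gc = 0.38, n_assemblies = 2L,
                     mean_contig = 20000L, ov_min = 500L, ov_max = 5000L,
                     error_rate = 0, revcomp_prob = 0, seed = 1L) {
  stopifnot(genome_len >= 1, gc >= 0, gc <= 1, n_assemblies >= 2,
            ov_min >= 1, ov_max >= ov_min, mean_contig > 3 * ov_max,
            genome_len > 7 * ov_max, error_rate >= 0, error_rate < 1)
  structure(list(genome_len = as.integer(genome_len), gc = gc,
                 n_assemblies = as.integer(n_assemblies),
                 mean_contig = as.integer(mean_contig),
                 ov_min = as.integer(ov_min), ov_max = as.integer(ov_max),
                 error_rate = error_rate, revcomp_prob = revcomp_prob,
                 seed = as.integer(seed)),
            class = "mix_sim_spec")
}

#' Simulate an i.i.d. genome
#'
#' @param len genome length.
#' @param gc GC fraction.
#' @return nucleotide string.
#' @export
simulate_genome <- function(len, gc = 0.38) {
  stopifnot(len >= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Fragment a genome into a draft assembly
#'
#' Contig `k` spans `[offsets[k], offsets[k+1] + overlap)` (clipped to the
#' genome; the last contig runs to the end), so `overlap > 0` extends every
#' fragment rightward into its neighbour.
#'
#' @param genome nucleotide string.
#' @param offsets strictly increasing contig start positions; first must
#'   be 0.
#' @param overlap within-assembly overlap in bases (default 0).
#' @param label assembly label.
#' @param rc logical vector (recycled) marking contigs stored
#'   reverse-complemented.
#' @return `mix_assembly` with attribute `truth`: data.frame
#'   `id, start, end, orient` of genome intervals (0-based half-open).
#' @export
fragment <- function(genome, offsets, overlap = 0L, label = "asm",
                     rc = FALSE) {
  glen <- nchar(genome)
  stopifnot(length(offsets) >= 1, offsets[1] == 0,
            all(diff(offsets) > 0), all(offsets < glen))
  base_len <- c(diff(offsets), glen - offsets[length(offsets)])
  if (length(offsets) > 1L && overlap >= min(base_len))
    stop("overlap must be smaller than every fragment length")
  ends <- pmin(c(offsets[-1] + overlap, glen), glen)
  rc <- rep_len(rc, length(offsets))
  ids <- sprintf("c%03d", seq_along(offsets))
  seqs <- substring(genome, offsets + 1L, ends)
  seqs[rc] <- revcomp(seqs[rc])
  asm <- assembly(setNames(seqs, ids), label = label)
  attr(asm, "truth") <- data.frame(id = ids, start = offsets, end = ends,
                                   orient = ifelse(rc, "-", "+"))
  asm
}

# apply i.i.d. substitutions to every contig (coordinates untouched)
mutate_assembly <- function(asm, rate) {
  if (rate <= 0) return(asm)
  seqs <- as.character(asm$seq)
  for (k in seq_along(seqs)) {
    s <- strsplit(seqs[k], "")[[1]]
    hit <- which(runif(length(s)) < rate)
    if (length(hit)) {
      for (h in hit) s[h] <- sample(setdiff(c("A", "C", "G", "T"), s[h]), 1)
      seqs[k] <- paste(s, collapse = "")
    }
  }
  out <- assembly(setNames(seqs, names(asm$seq)), label = asm$label)
  attr(out, "truth") <- attr(asm, "truth")
  out
}

#' Ground-truth alignments between two fragmentations
#'
#' Emits the exact overlap alignment for every contig pair whose genome
#' intervals intersect, with strand-correct coordinates; stands in for an
#' external aligner on simulated data. Contig ids must already be globally
#' unique (see [prefix_ids()]).
#'
#' @param asm1,asm2 `mix_assembly` objects carrying `truth` attributes from
#'   [fragment()] (after [prefix_ids()] the attribute is preserved by this
#'   function's `truth1`/`truth2` arguments).
#' @param truth1,truth2 truth tables; default to the assemblies' attributes.
#' @return data.frame of alignment rows (see [alignment_set()]).
#' @export
true_alignments <- function(asm1, asm2, truth1 = attr(asm1, "truth"),
                            truth2 = attr(asm2, "truth")) {
  stopifnot(!is.null(truth1), !is.null(truth2))
  rows <- list()
  for (a in seq_len(nrow(truth1))) for (b in seq_len(nrow(truth2))) {
    s <- max(truth1$start[a], truth2$start[b])
    t <- min(truth1$end[a], truth2$end[b])
    if (t <= s) next
    on_contig <- function(tr, k) {
      if (tr$orient[k] == "+") c(s - tr$start[k], t - tr$start[k])
      else c(tr$end[k] - t, tr$end[k] - s)
    }
    fi <- on_contig(truth1, a); fj <- on_contig(truth2, b)
    rows[[length(rows) + 1L]] <- data.frame(
      ci = names(asm1$seq)[a], cj = names(asm2$seq)[b],
      bi = fi[1], ei = fi[2], bj = fj[1], ej = fj[2], l = t - s,
      reversed_j = truth1$orient[a] != truth2$orient[b])
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(ci = character(), cj = character(), bi = integer(),
               ei = integer(), bj = integer(), ej = integer(), l = integer(),
               reversed_j = logical())
}

#' Simulate a full multi-assembly scenario
#'
#' Draws a genome, fragments it `n_assemblies` times with staggered
#' breakpoints (draft `i > 1` shifts each interior breakpoint of draft 1
#' rightward by an independent stagger in `[ov_min, ov_max]`), prefixes
#' contig ids with draft labels, and emits ground-truth alignments for all
#' draft pairs.
#'
#' @param spec a [sim_spec()].
#' @return list: `genome`, `assemblies` (list of `mix_assembly` with
#'   prefixed ids), `contigs` (combined index), `aset` (`mix_alignments`).
#' @export
simulate_mix <- function(spec) {
  stopifnot(inherits(spec, "mix_sim_spec"))
  set.seed(spec$seed)
  genome <- simulate_genome(spec$genome_len, spec$gc)
  n_ctg <- max(2L, round(spec$genome_len / spec$mean_contig))
  # interior breakpoints of draft 1, spaced at least 3*ov_max apart:
  # lay out the minimum spacings, then spread the slack uniformly
  m <- 3L * spec$ov_max
  while (n_ctg > 2L && n_ctg * m >= spec$genome_len) n_ctg <- n_ctg - 1L
  slack <- spec$genome_len - n_ctg * m
  cuts <- sort(as.integer(runif(n_ctg - 1L, 0, slack)))
  base <- m * seq_len(n_ctg - 1L) + cuts
  asms <- vector("list", spec$n_assemblies)
  for (i in seq_len(spec$n_assemblies)) {
    off <- if (i == 1L) c(0L, base) else {
      shift <- sample(seq(spec$ov_min, spec$ov_max), length(base),
                      replace = TRUE)
      c(0L, base + shift)
    }
    rc <- runif(length(off)) < spec$revcomp_prob
    a <- fragment(genome, off, overlap = 0L,
                  label = sprintf("sim%d", i), rc = rc)
    a <- mutate_assembly(a, spec$error_rate)
    tr <- attr(a, "truth")
    a <- prefix_ids(a)
    tr$id <- names(a$seq)
    attr(a, "truth") <- tr
    asms[[i]] <- a
  }
  contigs <- combine_assemblies(asms)
  rows <- list()
  for (i in seq_len(spec$n_assemblies - 1L))
    for (j in seq(i + 1L, spec$n_assemblies))
      rows[[length(rows) + 1L]] <- true_alignments(asms[[i]], asms[[j]])
  tab <- do.call(rbind, rows)
  list(genome = genome, assemblies = asms, contigs = contigs,
       aset = alignment_set(tab, contigs))
}
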