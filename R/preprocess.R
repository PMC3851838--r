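# Alignment-set cleanup: five ordered rules applied before graph
# construction. Rule order matters; rule 5's outlier statistic is computed
# on the set surviving rules 1-4.

#' Rule 1: drop self alignments
#'
#' Self alignments (a contig aligned against itself) typically come from
#' internal repeats and can never glue two contigs.
#'
#' @param aset a `mix_alignments`.
#' @export
remove_self_alignments <- function(aset) {
  aset_subset(aset, aset$tab$ci != aset$tab$cj)
}

# Reciprocal-overlap fraction of two half-open intervals: overlap width
# divided by the larger of the two widths (so >= f means each interval is
# covered >= f by the intersection).
recip_overlap <- function(b1, e1, b2, e2) {
  ov <- min(e1, e2) - max(b1, b2)
  if (ov <= 0) return(0)
  ov / max(e1 - b1, e2 - b2)
}

#' Rule 2: collapse reciprocal duplicates
#'
#' When both `<Ci,Cj>` and `<Cj,Ci>` report the same region (projected
#' intervals on each contig overlapping reciprocally by at least
#' `min_overlap`, same strand), only one is kept: the one whose `(ci, cj)`
#' pair sorts first lexicographically, ties broken by smaller `bi`.
#'
#' @param aset a `mix_alignments`.
#' @param min_overlap reciprocal-overlap fraction defining "same region"
#'   (default 0.5).
#' @export
dedupe_reciprocal <- function(aset, min_overlap = 0.5) {
  tab <- aset$tab
  n <- nrow(tab)
  if (n < 2L) return(aset)
  ord <- order(tab$ci, tab$cj, tab$bi, tab$ei)
  keep <- rep(TRUE, n)
  pair_key <- function(i) paste(sort(c(tab$ci[i], tab$cj[i])), collapse = "\r")
  keys <- vapply(seq_len(n), pair_key, "")
  for (gi in split(ord, keys[ord])) {
    if (length(gi) < 2L) next
    for (a in seq_along(gi)) {
      ia <- gi[a]
      if (!keep[ia]) next
      for (b in seq_along(gi)) {
        ib <- gi[b]
        if (ib == ia || !keep[ib]) next
        # only reciprocal orientations <X,Y> vs <Y,X> are rule-2 duplicates
        if (!(tab$ci[ia] == tab$cj[ib] && tab$cj[ia] == tab$ci[ib])) next
        if (tab$reversed_j[ia] != tab$reversed_j[ib]) next
        # ib's interval on ia's ci is its j-side interval, and vice versa
        f1 <- recip_overlap(tab$bi[ia], tab$ei[ia], tab$bj[ib], tab$ej[ib])
        f2 <- recip_overlap(tab$bj[ia], tab$ej[ia], tab$bi[ib], tab$ei[ib])
        if (f1 >= min_overlap && f2 >= min_overlap) keep[ib] <- FALSE
      }
    }
  }
  aset_subset(aset, keep)
}

#' Rule 3: drop short alignments
#'
#' Keeps only alignments strictly longer than the threshold `t_a` (an
#' alignment with `l == t_a` is removed).
#'
#' @param aset a `mix_alignments`.
#' @param t_a minimum length threshold in bases (default 200).
#' @export
filter_by_length <- function(aset, t_a = 200L) {
  if (t_a < 0) stop("t_a must be >= 0")
  aset_subset(aset, aset$tab$l > t_a)
}

#' Rule 4: drop near-containment alignments
#'
#' An alignment spanning more than `max_frac` (default 99%) of either contig
#' indicates containment rather than an extension overlap and is eliminated;
#' exactly 99% is kept.
#'
#' @param aset a `mix_alignments`.
#' @param max_frac containment fraction above which an alignment is dropped.
#' @export
filter_containment <- function(aset, max_frac = 0.99) {
  tab <- aset$tab
  if (!nrow(tab)) return(aset)
  li <- contig_length(aset, tab$ci)
  lj <- contig_length(aset, tab$cj)
  keep <- (tab$l / li) <= max_frac & (tab$l / lj) <= max_frac
  aset_subset(aset, keep)
}

#' Rule 5: flag spurious contigs
#'
#' A contig aligned an abnormally high number of times (repeat-induced) is
#' spurious. Outliers in the per-contig alignment-count distribution are
#' detected with a Tukey-style upper fence, `count > Q3 + 3 * IQR`
#' (linear-interpolation quartiles). When the IQR is zero the fallback is
#' `count > 3 * median`; if all counts are equal nothing is flagged.
#'
#' @param aset a `mix_alignments`.
#' @return character vector of spurious contig ids (possibly empty).
#' @export
detect_spurious <- function(aset) {
  tab <- aset$tab
  if (!nrow(tab)) return(character())
  cnt <- table(c(tab$ci, tab$cj))
  x <- as.numeric(cnt)
  if (length(unique(x)) == 1L) return(character())
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fence <- if (iqr > 0) q[2] + 3 * iqr else 3 * median(x)
  names(cnt)[x > fence]
}

#' Clean an alignment set (rules 1-5 in order)
#'
#' @param aset a `mix_alignments`.
#' @param t_a length threshold for rule 3 (default 200 bases).
#' @param min_overlap rule-2 reciprocal-overlap fraction.
#' @param max_frac rule-4 containment fraction.
#' @return list with elements `aset` (cleaned `mix_alignments`) and `report`
#'   (class `mix_filter_report`: per-rule removal counts and the spurious
#'   contig ids).
#' @export
clean_alignments <- function(aset, t_a = 200L, min_overlap = 0.5,
                             max_frac = 0.99) {
  n0 <- nrow(aset$tab)
  a1 <- remove_self_alignments(aset);        n1 <- nrow(a1$tab)
  a2 <- dedupe_reciprocal(a1, min_overlap);  n2 <- nrow(a2$tab)
  a3 <- filter_by_length(a2, t_a);           n3 <- nrow(a3$tab)
  a4 <- filter_containment(a3, max_frac);    n4 <- nrow(a4$tab)
  spur <- detect_spurious(a4)
  a5 <- aset_subset(a4, !(a4$tab$ci %in% spur | a4$tab$cj %in% spur))
  report <- structure(list(
    removed_self       = n0 - n1,
    removed_reciprocal = n1 - n2,
    removed_short      = n2 - n3,
    removed_contained  = n3 - n4,
    removed_spurious   = n4 - nrow(a5$tab),
    spurious_contig_ids = spur,
    n_in = n0, n_out = nrow(a5$tab)), class = "mix_filter_report")
  list(aset = a5, report = report)
}

#' @export
print.mix_filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "alignment filter: %d in -> %d out\n",
    "  rule 1 self:        -%d\n  rule 2 reciprocal:  -%d\n",
    "  rule 3 short:       -%d\n  rule 4 contained:   -%d\n",
    "  rule 5 spurious:    -%d (%d contig(s))\n"),
    x$n_in, x$n_out, x$removed_self, x$removed_reciprocal, x$removed_short,
    x$removed_contained, x$removed_spurious, length(x$spurious_contig_ids)))
  invisible(x)
}
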