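# Reference-free fragmentation statistics.

#' N50 of a set of contig lengths
#'
#' The largest length `L` such that contigs of length at least `L` together
#' cover at least half of the total assembly length.
#'
#' @param lengths positive integer vector of contig lengths.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length vector")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly summary statistics
#'
#' @param asm `mix_assembly` (or numeric vector of lengths).
#' @return data.frame: `n_contigs`, `largest`, `total`, `n50`.
#' @export
assembly_stats <- function(asm) {
  lens <- if (inherits(asm, "mix_assembly")) width(asm$seq) else asm
  data.frame(n_contigs = length(lens), largest = max(lens),
             total = sum(lens), n50 = n50(lens))
}
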