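#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement subseq width
#' @importFrom IRanges IRanges reduce
#' @importFrom igraph graph_from_data_frame components all_simple_paths
#'   topo_sort V E vcount ecount degree delete_vertices induced_subgraph
#' @importFrom stats quantile median runif setNames
#' @importFrom utils read.table write.table head tail modifyList
NULL

# Separator used to build globally unique contig ids from assembly labels.
ID_SEP <- "__"

#' Construct an assembly
#'
#' An assembly is an ordered set of contigs: nucleotide sequences over
#' `{A,C,G,T,N}` with unique identifiers. It is the atomic input and output
#' unit of the whole pipeline.
#'
#' @param seqs named character vector or `DNAStringSet` of contig sequences.
#' @param label single non-empty string naming the assembly (typically the
#'   assembler that produced it).
#' @return An object of class `mix_assembly` with elements `label` and `seq`
#'   (a `DNAStringSet` named by contig id).
#' @export
assembly <- function(seqs, label = "asm") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("assembly label must be a single non-empty string")
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (!methods::is(seqs, "DNAStringSet"))
    stop("seqs must be a character vector or DNAStringSet")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every contig needs a non-empty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate contig id(s): ", paste(dup, collapse = ", "))
  if (length(seqs) == 0L) stop("no contigs")
  if (any(width(seqs) < 1L)) stop("zero-length contig sequence")
  structure(list(label = label, seq = seqs), class = "mix_assembly")
}

#' @export
print.mix_assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s': %d contigs, %s bp>\n",
              x$label, length(x$seq),
              format(sum(width(x$seq)), big.mark = ",")))
  invisible(x)
}

#' Number of contigs in an assembly
#' @param x a `mix_assembly`.
#' @export
length.mix_assembly <- function(x) length(x$seq)

#' Read a FASTA file into an assembly
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` is
#' replaced by `N`. Record order is preserved; the record id is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file.
#' @param label assembly label; defaults to the file name without extension.
#' @return A [assembly()] object.
#' @export
read_fasta <- function(path, label = sub("\\.(fa|fasta|fna)$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)  # raw read; normalized below
  if (length(x) == 0L) stop("no contigs in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup))
    stop("duplicate record id(s) in ", path, ": ", paste(dup, collapse = ", "))
  ch <- toupper(as.character(x))
  ch <- gsub("[^ACGTN]", "N", ch)
  assembly(setNames(ch, names(x)), label = label)
}

#' Write an assembly (or named sequences) to FASTA
#'
#' @param x `mix_assembly`, `DNAStringSet`, or named character vector.
#' @param path output file; lines wrapped at 80 columns.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "mix_assembly")) x <- x$seq
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Prefix contig ids with the assembly label
#'
#' Combining assemblies requires globally unique contig ids; each id becomes
#' `<label>__<id>`.
#'
#' @param asm a `mix_assembly`.
#' @param label prefix; defaults to the assembly's own label. Must not
#'   contain the `__` separator.
#' @export
prefix_ids <- function(asm, label = asm$label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a single non-empty string")
  if (grepl(ID_SEP, label, fixed = TRUE))
    stop("label must not contain the id separator '", ID_SEP, "'")
  out <- asm$seq
  names(out) <- paste0(label, ID_SEP, names(out))
  assembly(out, label = label)
}

#' Combine assemblies into one contig index
#'
#' @param asms list of `mix_assembly` (ids must already be globally unique,
#'   see [prefix_ids()]).
#' @return A `mix_assembly` labelled `"combined"`.
#' @export
combine_assemblies <- function(asms) {
  stopifnot(length(asms) >= 1L)
  seqs <- do.call(c, lapply(asms, function(a) a$seq))
  assembly(seqs, label = "combined")
}

aln_cols <- c("ci", "cj", "bi", "ei", "bj", "ej", "l", "reversed_j")

#' Construct an alignment set
#'
#' An alignment links a region of contig `ci` (`[bi, ei)`, 0-based half-open)
#' to a region of contig `cj` (`[bj, ej)`); `l` is the alignment length on
#' the `ci` side (`l = ei - bi`); `reversed_j` is `TRUE` when `cj` is read
#' reverse-complemented. Coordinate invariants are asserted on construction.
#'
#' @param alignments data.frame with columns
#'   `ci, cj, bi, ei, bj, ej, l, reversed_j`.
#' @param contigs `mix_assembly` index resolving every referenced contig id.
#' @return An object of class `mix_alignments` with elements `tab`
#'   (data.frame, plus a stable `aid` column) and `contigs`.
#' @export
alignment_set <- function(alignments, contigs) {
  stopifnot(is.data.frame(alignments))
  miss <- setdiff(aln_cols, names(alignments))
  if (length(miss)) stop("missing alignment column(s): ", paste(miss, collapse = ", "))
  tab <- alignments[aln_cols]
  tab$ci <- as.character(tab$ci); tab$cj <- as.character(tab$cj)
  for (cc in c("bi", "ei", "bj", "ej", "l")) tab[[cc]] <- as.integer(tab[[cc]])
  tab$reversed_j <- as.logical(tab$reversed_j)
  lens <- setNames(width(contigs$seq), names(contigs$seq))
  bad_id <- setdiff(unique(c(tab$ci, tab$cj)), names(lens))
  if (length(bad_id))
    stop("alignment references unknown contig id(s): ",
         paste(bad_id, collapse = ", "))
  if (nrow(tab)) {
    ok <- tab$bi >= 0L & tab$bi < tab$ei & tab$ei <= lens[tab$ci] &
      tab$bj >= 0L & tab$bj < tab$ej & tab$ej <= lens[tab$cj] &
      tab$l == tab$ei - tab$bi & tab$l >= 1L & !is.na(tab$reversed_j)
    if (any(!ok))
      stop("alignment coordinate invariant violated at row(s): ",
           paste(which(!ok), collapse = ", "))
  }
  if (is.null(alignments$aid)) tab$aid <- seq_len(nrow(tab)) else tab$aid <- alignments$aid
  rownames(tab) <- NULL
  structure(list(tab = tab, contigs = contigs), class = "mix_alignments")
}

#' @export
print.mix_alignments <- function(x, ...) {
  cat(sprintf("<alignment set: %d alignments over %d contigs>\n",
              nrow(x$tab), length(x$contigs$seq)))
  invisible(x)
}

#' Number of alignments in a set
#' @param x a `mix_alignments`.
#' @export
length.mix_alignments <- function(x) nrow(x$tab)

contig_length <- function(aset, id) {
  unname(width(aset$contigs$seq)[match(id, names(aset$contigs$seq))])
}

#' Parse nucmer `show-coords -rcl -T` output
#'
#' Expects the tab-separated dialect: columns
#' `S1 E1 S2 E2 LEN1 LEN2 %IDY LENR LENQ [COVR COVQ] ref qry`, coordinates
#' 1-based inclusive, a reverse-strand query having `S2 > E2`. Coordinates
#' are converted to 0-based half-open; `l` is the reference-span length.
#' Rows naming contigs missing from the index are skipped and counted in
#' `attr(, "skipped")`.
#'
#' @param path coords file.
#' @param contigs combined `mix_assembly` index.
#' @return A [alignment_set()]; attribute `skipped` counts rejected rows.
#' @export
parse_coords <- function(path, contigs) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rows <- list(); skipped <- 0L
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    # headers: nucmer banner, "NUCMER", column rule lines, [S1] header
    if (length(f) < 11L || is.na(suppressWarnings(as.numeric(f[1])))) next
    num <- suppressWarnings(as.numeric(f[1:6]))
    if (any(is.na(num)))
      stop("malformed coords row at line ", k, ": ", lines[k])
    ref <- f[length(f) - 1L]; qry <- f[length(f)]
    known <- names(contigs$seq)
    if (!(ref %in% known) || !(qry %in% known)) { skipped <- skipped + 1L; next }
    s1 <- num[1]; e1 <- num[2]; s2 <- num[3]; e2 <- num[4]
    if (s1 > e1) stop("malformed coords row at line ", k,
                      ": reference coordinates must ascend")
    rev <- s2 > e2
    rows[[length(rows) + 1L]] <- data.frame(
      ci = ref, cj = qry,
      bi = s1 - 1, ei = e1,
      bj = if (rev) e2 - 1 else s2 - 1,
      ej = if (rev) s2 else e2,
      l  = e1 - s1 + 1,
      reversed_j = rev)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ci = character(), cj = character(), bi = integer(),
               ei = integer(), bj = integer(), ej = integer(), l = integer(),
               reversed_j = logical())
  out <- alignment_set(tab, contigs)
  attr(out, "skipped") <- skipped
  out
}

#' Parse the internal alignment TSV dialect
#'
#' Tab-separated with header `ci cj bi ei bj ej l reversed_j`, coordinates
#' already 0-based half-open. The written/parsed dialect round-trips exactly
#' (see [write_alignments_tsv()]).
#'
#' @param path TSV file.
#' @param contigs combined `mix_assembly` index.
#' @export
parse_tsv <- function(path, contigs) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(ci = "character", cj = "character"),
                    stringsAsFactors = FALSE)
  tryCatch(alignment_set(tab, contigs),
           error = function(e) stop("invalid alignment TSV ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write an alignment set in the internal TSV dialect
#' @param aset a `mix_alignments`.
#' @param path output file.
#' @export
write_alignments_tsv <- function(aset, path) {
  write.table(aset$tab[aln_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Subset an alignment set by row index, preserving stable alignment ids.
aset_subset <- function(aset, idx) {
  out <- aset
  out$tab <- aset$tab[idx, , drop = FALSE]
  rownames(out$tab) <- NULL
  out
}

#' Reverse-complement a nucleotide string
#' @param s character vector of sequences.
#' @return character vector of reverse complements (N maps to N).
#' @export
revcomp <- function(s) as.character(reverseComplement(DNAStringSet(s)))

# Canonical strand-insensitive form of a sequence: min(s, revcomp(s)).
canonical_seq <- function(s) {
  rc <- revcomp(s)
  ifelse(s <= rc, s, rc)
}
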