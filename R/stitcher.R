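# Path stitching: turn extension paths into merged nucleotide sequences.
#
# Each traversed edge contributes a contig chunk: In/Out edges the leading/
# trailing remainder of the first/last contig, turquoise edges the overlap
# region (taken from the contig appearing earlier in path order; no
# consensus is called over the overlap), orange edges the stretch of a
# shared contig between two alignment footprints, gray edges nothing.

footprint_of <- function(aset, aid, contig) {
  r <- aset$tab[aset$tab$aid == aid, , drop = FALSE]
  if (!nrow(r)) stop("unknown alignment id ", aid)
  if (r$ci[1] == contig) c(r$bi[1], r$ei[1])
  else if (r$cj[1] == contig) c(r$bj[1], r$ej[1])
  else stop("contig ", contig, " not part of alignment ", aid)
}

seg <- function(contig, orient, start, end)
  data.frame(contig = contig, orient = orient,
             start = as.integer(start), end = as.integer(end))

#' Convert an extension path to a stitching layout
#'
#' @param path a path from [milps()] (list with `nodes`) or a vector of
#'   vertex names.
#' @param eg the `mix_extgraph` the path was extracted from.
#' @return A data.frame (class `mix_layout`) of ordered segments
#'   `contig, orient, start, end` (0-based half-open contig coordinates)
#'   whose concatenation spells the merged sequence.
#' @export
path_to_layout <- function(path, eg) {
  stopifnot(inherits(eg, "mix_extgraph"))
  nodes <- if (is.list(path)) path$nodes else path
  g <- eg$graph
  aset <- eg$aset
  lens <- setNames(width(aset$contigs$seq), names(aset$contigs$seq))
  if (length(nodes) < 2L || nodes[1] != "In" || nodes[length(nodes)] != "Out")
    stop("not an In -> Out path")
  if (length(nodes) == 3L) {  # degenerate single-contig path
    p <- parse_node(nodes[2])
    ori <- if (p$dir == "f") "+" else "-"
    return(structure(seg(p$contig, ori, 0L, lens[[p$contig]]),
                     class = c("mix_layout", "data.frame")))
  }
  eids <- igraph::get_edge_ids(g, rbind(nodes[-length(nodes)], nodes[-1]))
  if (any(eids == 0)) stop("path edge missing from the extension graph")
  cls <- E(g)$eclass[eids]
  segs <- list()
  for (k in seq_along(eids)) {
    u <- nodes[k]; v <- nodes[k + 1L]
    cl <- cls[k]
    if (cl == "gray") next
    if (cl == "in") {
      p <- parse_node(v)
      fp <- footprint_of(aset, p$aid, p$contig)
      s <- if (p$dir == "f") seg(p$contig, "+", 0L, fp[1])
           else seg(p$contig, "-", fp[2], lens[[p$contig]])
    } else if (cl == "turquoise") {
      p <- parse_node(u)  # overlap bases come from the source contig
      fp <- footprint_of(aset, p$aid, p$contig)
      s <- seg(p$contig, if (p$dir == "f") "+" else "-", fp[1], fp[2])
    } else if (cl == "orange") {
      pu <- parse_node(u); pv <- parse_node(v)
      fpu <- footprint_of(aset, pu$aid, pu$contig)
      fpv <- footprint_of(aset, pv$aid, pv$contig)
      s <- if (pu$dir == "f") seg(pu$contig, "+", fpu[2], fpv[1])
           else seg(pu$contig, "-", fpv[2], fpu[1])
    } else if (cl == "out") {
      p <- parse_node(u)
      fp <- footprint_of(aset, p$aid, p$contig)
      s <- if (p$dir == "f") seg(p$contig, "+", fp[2], lens[[p$contig]])
           else seg(p$contig, "-", 0L, fp[1])
    } else stop("unknown edge class ", cl)
    segs[[length(segs) + 1L]] <- s
  }
  out <- do.call(rbind, segs)
  # merge nothing, but sanity-check bounds
  stopifnot(all(out$start >= 0), all(out$end <= lens[out$contig]),
            all(out$start <= out$end))
  structure(out, class = c("mix_layout", "data.frame"))
}

#' Render a layout into a nucleotide string
#'
#' Concatenates the layout's contig chunks, reverse-complementing segments
#' with orientation `-`.
#'
#' @param layout a `mix_layout` (or plain data.frame with the same columns).
#' @param contigs `mix_assembly` (or `DNAStringSet`) resolving segment ids.
#' @export
render_layout <- function(layout, contigs) {
  seqs <- if (inherits(contigs, "mix_assembly")) contigs$seq else contigs
  lens <- setNames(width(seqs), names(seqs))
  if (!nrow(layout)) return("")
  if (any(!(layout$contig %in% names(lens))))
    stop("layout references unknown contig(s)")
  if (any(layout$start < 0 | layout$end > lens[layout$contig]))
    stop("layout coordinates out of contig bounds")
  pieces <- character(nrow(layout))
  for (k in seq_len(nrow(layout))) {
    if (layout$end[k] == layout$start[k]) { pieces[k] <- ""; next }
    chunk <- as.character(subseq(seqs[[layout$contig[k]]],
                                 layout$start[k] + 1L, layout$end[k]))
    pieces[k] <- if (layout$orient[k] == "-") revcomp(chunk) else chunk
  }
  paste(pieces, collapse = "")
}

format_layout <- function(layout) {
  paste(sprintf("%s:%s:%d-%d", layout$contig, layout$orient,
                layout$start, layout$end), collapse = ",")
}

#' Assemble the pre-pruning candidate set
#'
#' One merged contig per extension path (ids `MIX__path_<k>`) plus every
#' input contig not consumed by any path. A contig is consumed when it
#' contributes at least one segment to a layout.
#'
#' @param pathset a `mix_pathset` from [milps()].
#' @param eg the `mix_extgraph` the paths came from.
#' @param contigs combined `mix_assembly` of all input contigs.
#' @return list with `assembly` (candidate `mix_assembly`), `layouts`
#'   (named list of `mix_layout`), `consumed` (character).
#' @export
final_candidates <- function(pathset, eg, contigs) {
  layouts <- list()
  merged <- character()
  for (k in seq_along(pathset)) {
    id <- sprintf("MIX__path_%d", k)
    lay <- path_to_layout(pathset[[k]], eg)
    layouts[[id]] <- lay
    merged[id] <- render_layout(lay, contigs)
  }
  consumed <- unique(unlist(lapply(layouts, function(l) l$contig)))
  leftover <- setdiff(names(contigs$seq), consumed)
  seqs <- c(merged, setNames(as.character(contigs$seq[leftover]), leftover))
  list(assembly = assembly(DNAStringSet(seqs), label = "mixed"),
       layouts = layouts, consumed = consumed %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write layouts as a tab-separated table
#' @param layouts named list of `mix_layout`.
#' @param path output TSV.
#' @export
write_layout_tsv <- function(layouts, path) {
  rows <- lapply(names(layouts), function(id) {
    l <- layouts[[id]]
    data.frame(path = id, segment = seq_len(nrow(l)), l)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), segment = integer(), contig = character(),
               orient = character(), start = integer(), end = integer())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
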