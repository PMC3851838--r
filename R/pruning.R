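# Containment pruning via the coverage graph.
#
# Output elements (merged path contigs plus leftover input contigs) are
# compared pairwise: the original alignment set is projected through the
# path layouts to measure, per ordered pair (x, y), the fraction of x's
# positions covered by alignments to contigs of y (interval union, each
# position once). Pairs above the threshold become directed edges
# source -> target, the source being the more-covered (tie: shorter, then
# lexicographically smaller) element. Cycles are broken by keeping the
# longest element of each strongly connected component; a topological sweep
# then removes, to fixpoint, every element that covers nothing but is
# covered.

# element table: id, len, and per-element layout (a mix_layout-style
# data.frame; a plain contig is its own single full-length segment)
make_elements <- function(candidates, layouts) {
  ids <- names(candidates$seq)
  lens <- setNames(width(candidates$seq), ids)
  els <- lapply(ids, function(id) {
    lay <- layouts[[id]]
    if (is.null(lay))
      lay <- data.frame(contig = id, orient = "+", start = 0L,
                        end = unname(lens[[id]]))
    off <- cumsum(c(0L, head(lay$end - lay$start, -1L)))
    lay$offset <- off
    list(id = id, len = unname(lens[[id]]), lay = lay)
  })
  setNames(els, ids)
}

# project contig interval [b, e) through an element's layout into element
# coordinates; returns matrix of rows (start, end)
project_interval <- function(el, contig, b, e) {
  lay <- el$lay
  hit <- which(lay$contig == contig)
  out <- NULL
  for (k in hit) {
    s <- max(b, lay$start[k]); t <- min(e, lay$end[k])
    if (t <= s) next
    if (lay$orient[k] == "+") {
      a0 <- lay$offset[k] + (s - lay$start[k])
      out <- rbind(out, c(a0, a0 + (t - s)))
    } else {
      a0 <- lay$offset[k] + (lay$end[k] - t)
      out <- rbind(out, c(a0, a0 + (t - s)))
    }
  }
  out
}

#' Pairwise coverage ratios between output elements
#'
#' Entry `(x, y)` is the fraction of `x`'s positions covered by alignments
#' between a contig of `x` and a contig of `y` (union of intervals, no
#' double counting). Alignments internal to one element are ignored, as is
#' the diagonal.
#'
#' @param candidates pre-pruning `mix_assembly` from [final_candidates()].
#' @param layouts named list of path layouts (from [final_candidates()]).
#' @param aset the original (uncleaned) `mix_alignments`.
#' @return numeric matrix of ratios in `[0, 1]`.
#' @export
coverage_matrix <- function(candidates, layouts, aset) {
  els <- make_elements(candidates, layouts)
  ids <- names(els)
  # contig -> element ids containing it
  owner <- list()
  for (id in ids) for (ctg in unique(els[[id]]$lay$contig))
    owner[[ctg]] <- c(owner[[ctg]], id)
  cov <- list()  # cov[[x]][[y]] = list of interval matrices on x
  tab <- aset$tab
  tab <- tab[tab$ci != tab$cj, , drop = FALSE]
  add_cov <- function(x, y, iv) {
    if (is.null(iv)) return()
    key <- paste(x, y, sep = "\r")
    cov[[key]] <<- rbind(cov[[key]], iv)
  }
  for (r in seq_len(nrow(tab))) {
    xs <- owner[[tab$ci[r]]]; ys <- owner[[tab$cj[r]]]
    if (is.null(xs) || is.null(ys)) next
    for (x in xs) for (y in ys) {
      if (x == y) next
      add_cov(x, y, project_interval(els[[x]], tab$ci[r], tab$bi[r], tab$ei[r]))
      add_cov(y, x, project_interval(els[[y]], tab$cj[r], tab$bj[r], tab$ej[r]))
    }
  }
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (key in names(cov)) {
    xy <- strsplit(key, "\r", fixed = TRUE)[[1]]
    iv <- cov[[key]]
    u <- sum(IRanges::width(reduce(IRanges(start = iv[, 1] + 1L, end = iv[, 2]))))
    m[xy[1], xy[2]] <- u / els[[xy[1]]]$len
  }
  m
}

#' Build the thresholded coverage graph
#'
#' For each unordered pair whose larger ratio reaches the threshold, one
#' edge `source -> target` is added; the source is the element with the
#' higher own-coverage ratio, ties going to the shorter element and then to
#' the lexicographically smaller id.
#'
#' @param m coverage matrix from [coverage_matrix()].
#' @param lens named element lengths.
#' @param threshold coverage fraction (default 0.90).
#' @return igraph with edge attribute `ratio`.
#' @export
build_coverage_graph <- function(m, lens, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  ids <- rownames(m)
  ed <- list()
  if (length(ids) >= 2L) for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    x <- ids[a]; y <- ids[b]
    rxy <- m[x, y]; ryx <- m[y, x]
    if (max(rxy, ryx) < threshold) next
    src <- if (rxy > ryx) x else if (ryx > rxy) y
      else if (lens[[x]] != lens[[y]]) ids[c(a, b)][which.min(c(lens[[x]], lens[[y]]))]
      else min(x, y)
    tgt <- setdiff(c(x, y), src)
    ed[[length(ed) + 1L]] <- data.frame(from = src, to = tgt,
                                        ratio = m[src, tgt])
  }
  etab <- if (length(ed)) do.call(rbind, ed) else
    data.frame(from = character(), to = character(), ratio = numeric())
  graph_from_data_frame(etab, directed = TRUE,
                        vertices = data.frame(name = ids))
}

#' Break cycles in a coverage graph
#'
#' Within each non-singleton strongly connected component the longest
#' element (ties: lexicographically smaller id) is kept as representative;
#' edges among members are replaced by one edge from every other member to
#' the representative, leaving the graph acyclic.
#'
#' @param g coverage igraph.
#' @param lens named element lengths.
#' @export
break_cycles <- function(g, lens) {
  repeat {
    sccs <- find_sccs(g)
    if (!length(sccs)) return(g)
    scc <- sccs[[1]]
    o <- order(-unlist(lens[scc]), scc)
    rep_id <- scc[o[1]]
    # drop all intra-component edges, then point members at the survivor
    ft <- igraph::ends(g, E(g))
    drop <- which(ft[, 1] %in% scc & ft[, 2] %in% scc)
    g <- igraph::delete_edges(g, drop)
    others <- setdiff(scc, rep_id)
    g <- igraph::add_edges(g, rbind(others, rep(rep_id, length(others))),
                           attr = list(ratio = rep(NA_real_, length(others))))
  }
}

#' Prune covered elements
#'
#' Processes the acyclic coverage graph in topological order and removes
#' every element that is covered by another element (out-degree >= 1) while
#' covering none itself (in-degree 0), repeating until a fixpoint.
#'
#' @param g acyclic coverage igraph.
#' @param candidates pre-pruning `mix_assembly`.
#' @param protect element ids never to remove (empty by default: a merged
#'   path that is wholly contained in another element is itself redundant
#'   and may be dropped).
#' @return list with `assembly` (pruned `mix_assembly`) and `report`
#'   (data.frame: element, decision, covered_by, ratio).
#' @export
prune_candidates <- function(g, candidates, protect = character()) {
  if (!igraph::is_dag(g)) stop("coverage graph must be acyclic; run break_cycles()")
  removed <- character(); covered_by <- character(); ratios <- numeric()
  repeat {
    deg_out <- degree(g, mode = "out")
    deg_in <- degree(g, mode = "in")
    victims <- names(deg_out)[deg_out >= 1L & deg_in == 0L]
    victims <- setdiff(victims, protect)
    if (!length(victims)) break
    for (v in victims) {
      tgts <- names(igraph::neighbors(g, v, mode = "out"))
      eid <- igraph::get_edge_ids(g, c(v, tgts[1]))
      removed <- c(removed, v)
      covered_by <- c(covered_by, tgts[1])
      ratios <- c(ratios, E(g)$ratio[eid])
    }
    g <- delete_vertices(g, victims)
  }
  keep <- setdiff(names(candidates$seq), removed)
  report <- data.frame(
    element = c(keep, removed),
    decision = c(rep("kept", length(keep)), rep("removed", length(removed))),
    covered_by = c(rep(NA_character_, length(keep)), covered_by),
    ratio = c(rep(NA_real_, length(keep)), ratios))
  list(assembly = assembly(candidates$seq[keep], label = "mix"),
       report = report)
}

#' Full pruning stage
#'
#' Convenience wrapper: coverage matrix, thresholded graph, cycle breaking,
#' and fixpoint removal.
#'
#' @inheritParams coverage_matrix
#' @inheritParams build_coverage_graph
#' @param protect element ids never to remove.
#' @export
prune_assembly <- function(candidates, layouts, aset, threshold = 0.9,
                           protect = character()) {
  m <- coverage_matrix(candidates, layouts, aset)
  lens <- as.list(setNames(width(candidates$seq), names(candidates$seq)))
  g <- build_coverage_graph(m, lens, threshold)
  g <- break_cycles(g, lens)
  out <- prune_candidates(g, candidates, protect)
  out$coverage <- m
  out
}
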