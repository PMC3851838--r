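# Extension graph construction.
#
# Every terminal alignment between contigs X and Y contributes eight
# vertices: for each contig, the two extremities of the alignment footprint
# (border "b" = the one at the contig end, internal "i" = the one inside the
# contig), each in the two reading directions (forward "f", reverse "r").
# Two artificial vertices In and Out anchor path starts and ends.
#
# An In -> Out path spells a left-to-right walk over a merged sequence:
#
#   In --[leading remainder]--> (X,a,i,d) --0--> (X,a,b,d)
#      --[overlap length l]--> (Y,a,b,d') --0--> (Y,a,i,d') --[trailing]--> Out
#
# so the sum of edge weights along a path equals the number of bases of the
# merged contig. Edge classes: "in"/"out" attachments and the remainder
# chunks they carry, zero-weight "gray" edges tracing the alignment
# footprint on one contig, "turquoise" cross-contig edges weighted by the
# overlap length, and "orange" inter-alignment edges on a shared contig
# weighted by the gap between the two footprints.
#
# Which of the four direction combinations is legal follows from requiring
# the walk to emit each contig consistently in one direction:
# a forward-read contig can only be extended through a footprint at its
# right end, a reverse-read contig through a footprint at its left end, and
# the two emitted copies of the overlap must agree in strand. A forward
# alignment therefore glues opposite footprint sides, a reverse alignment
# equal sides; same-side forward (or opposite-side reverse) terminal
# alignments admit no gluing and are dropped with a count.

NODE_SEP <- "\x1f"

node_name <- function(contig, aid, role, dir) {
  paste(contig, sprintf("%09d", as.integer(aid)), role, dir, sep = NODE_SEP)
}

parse_node <- function(name) {
  p <- strsplit(name, NODE_SEP, fixed = TRUE)[[1]]
  list(contig = p[1], aid = as.integer(p[2]), role = p[3], dir = p[4])
}

is_io_node <- function(name) name %in% c("In", "Out")

#' Flip the reading direction of an extension-graph vertex
#'
#' Involution mapping a vertex to its reverse-reading variant (same contig,
#' alignment and extremity role).
#'
#' @param name vertex name (not `In`/`Out`).
#' @export
reverse_variant <- function(name) {
  if (any(is_io_node(name))) stop("In/Out have no directional variant")
  vapply(name, function(nm) {
    p <- parse_node(nm)
    node_name(p$contig, p$aid, p$role, if (p$dir == "f") "r" else "f")
  }, "", USE.NAMES = FALSE)
}

#' Is an alignment terminal?
#'
#' An alignment is terminal when it involves an extremity of each contig: on
#' each side, the footprint begins within `eps` bases of coordinate 0 or
#' ends within `eps` bases of the contig length. `eps = 0` demands exact
#' extremities.
#'
#' @param aset a `mix_alignments`.
#' @param eps end tolerance in bases (default 0).
#' @return logical vector, one entry per alignment.
#' @export
is_terminal <- function(aset, eps = 0L) {
  tab <- aset$tab
  if (!nrow(tab)) return(logical())
  li <- contig_length(aset, tab$ci)
  lj <- contig_length(aset, tab$cj)
  (tab$bi <= eps | tab$ei >= li - eps) &
    (tab$bj <= eps | tab$ej >= lj - eps)
}

# Footprint side on one contig: "L" when anchored at the contig start, "R"
# at the end; NA when the footprint touches neither end (within eps). When
# both ends qualify (near-containment) the closer one wins, ties to "R".
footprint_side <- function(b, e, len, eps) {
  atL <- b <= eps
  atR <- e >= len - eps
  ifelse(!atL & !atR, NA_character_,
         ifelse(atL & atR, ifelse(b < len - e, "L", "R"),
                ifelse(atL, "L", "R")))
}

# Gluing geometry of one terminal alignment: the reading direction of each
# contig such that ci is the overlap source. A contig anchored at its right
# end is read forward as source; the target is read forward when anchored at
# its left end. Returns NULL when the side/strand combination admits none.
gluing_of <- function(side_i, side_j, reversed) {
  ok <- if (reversed) side_i == side_j else side_i != side_j
  if (is.na(ok) || !ok) return(NULL)
  list(di = if (side_i == "R") "f" else "r",
       dj = if (side_j == "L") "f" else "r")
}

flip_dir <- function(d) ifelse(d == "f", "r", "f")

#' Build the extension graph
#'
#' Constructs the weighted digraph over the terminal alignments of a cleaned
#' alignment set. Non-terminal alignments, and terminal alignments whose
#' side/strand geometry admits no gluing, are dropped and counted.
#' Inter-alignment ("orange") edges on a shared contig are added only when
#' the two footprints do not overlap in the walk direction, so that every
#' path weight equals the length of the sequence it spells; skipped
#' overlapping-footprint transitions are counted in `skipped_orange`.
#'
#' @param aset cleaned `mix_alignments`.
#' @param eps end tolerance in bases for extremity membership (default 0).
#' @return Object of class `mix_extgraph`: list with `graph` (igraph),
#'   `aset`, `eps`, and drop counters.
#' @export
build_graph <- function(aset, eps = 0L) {
  tab <- aset$tab
  lens <- setNames(width(aset$contigs$seq), names(aset$contigs$seq))
  term <- is_terminal(aset, eps)
  dropped_nonterminal <- sum(!term)
  tab <- tab[term, , drop = FALSE]

  edges <- list()
  add_edge <- function(from, to, w, cls) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, weight = as.numeric(w), eclass = cls)
  }
  # per (contig, alignment): footprint, and the directions in which the
  # contig acts as overlap source / target -- used for orange edges
  anno <- list()
  dropped_nongluable <- 0L

  for (r in seq_len(nrow(tab))) {
    a <- tab[r, ]
    li <- lens[[a$ci]]; lj <- lens[[a$cj]]
    si <- footprint_side(a$bi, a$ei, li, eps)
    sj <- footprint_side(a$bj, a$ej, lj, eps)
    gl <- gluing_of(si, sj, a$reversed_j)
    if (is.null(gl)) { dropped_nongluable <- dropped_nongluable + 1L; next }

    emit_gluing <- function(X, bX, eX, lenX, dX, Y, bY, eY, lenY, dY, aid) {
      # node names
      Xi <- node_name(X, aid, "i", dX); Xb <- node_name(X, aid, "b", dX)
      Yb <- node_name(Y, aid, "b", dY); Yi <- node_name(Y, aid, "i", dY)
      lead  <- if (dX == "f") bX else lenX - eX
      trail <- if (dY == "f") lenY - eY else bY
      add_edge("In", Xi, lead, "in")
      add_edge(Xi, Xb, 0, "gray")
      add_edge(Xb, Yb, eX - bX, "turquoise")
      add_edge(Yb, Yi, 0, "gray")
      add_edge(Yi, "Out", trail, "out")
    }
    # primary gluing: ci is source; mirror: cj is source with flipped dirs
    emit_gluing(a$ci, a$bi, a$ei, li, gl$di,
                a$cj, a$bj, a$ej, lj, gl$dj, a$aid)
    emit_gluing(a$cj, a$bj, a$ej, lj, flip_dir(gl$dj),
                a$ci, a$bi, a$ei, li, flip_dir(gl$di), a$aid)

    anno[[length(anno) + 1L]] <- data.frame(
      contig = c(a$ci, a$cj), aid = a$aid,
      b = c(a$bi, a$bj), e = c(a$ei, a$ej),
      src_dir = c(gl$di, flip_dir(gl$dj)),
      tgt_dir = c(flip_dir(gl$di), gl$dj))
  }

  skipped_orange <- 0L
  if (length(anno)) {
    anno <- do.call(rbind, anno)
    for (ctg in unique(anno$contig)) {
      sub <- anno[anno$contig == ctg, , drop = FALSE]
      if (nrow(sub) < 2L) next
      for (p in seq_len(nrow(sub))) for (q in seq_len(nrow(sub))) {
        if (p == q) next
        # walker leaves alignment p (contig as target) and enters q (as source)
        d <- sub$tgt_dir[p]
        if (sub$src_dir[q] != d) next
        gap <- if (d == "f") sub$b[q] - sub$e[p] else sub$b[p] - sub$e[q]
        if (gap < 0) { skipped_orange <- skipped_orange + 1L; next }
        add_edge(node_name(ctg, sub$aid[p], "i", d),
                 node_name(ctg, sub$aid[q], "i", d), gap, "orange")
      }
    }
  }

  etab <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               weight = numeric(), eclass = character())
  # drop duplicate edges (same endpoints/class can recur via containment-ish
  # geometries); keep first occurrence
  etab <- etab[!duplicated(etab[c("from", "to")]), , drop = FALSE]
  verts <- unique(c("In", "Out", etab$from, etab$to))
  g <- graph_from_data_frame(etab, directed = TRUE,
                             vertices = data.frame(name = verts))
  structure(list(graph = g, aset = aset, eps = eps,
                 dropped_nonterminal = dropped_nonterminal,
                 dropped_nongluable = dropped_nongluable,
                 skipped_orange = skipped_orange),
            class = "mix_extgraph")
}

#' @export
print.mix_extgraph <- function(x, ...) {
  cat(sprintf(
    "<extension graph: %d vertices, %d edges; dropped %d non-terminal, %d non-gluable>\n",
    vcount(x$graph), ecount(x$graph),
    x$dropped_nonterminal, x$dropped_nongluable))
  invisible(x)
}

#' Dump an extension graph in DOT format
#' @param eg a `mix_extgraph`.
#' @param path output `.dot` file.
#' @export
dump_dot <- function(eg, path) {
  g <- eg$graph
  nm <- gsub(NODE_SEP, "_", V(g)$name, fixed = TRUE)
  lines <- c("digraph extension {")
  ft <- igraph::ends(g, E(g), names = FALSE)
  lines <- c(lines, sprintf('  "%s" -> "%s" [label="%g", class="%s"];',
                            nm[ft[, 1]], nm[ft[, 2]],
                            E(g)$weight, E(g)$eclass))
  writeLines(c(lines, "}"), path)
  invisible(path)
}
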