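# Maximal Independent Longest Path Set extraction.
#
# Longest paths are extracted iteratively: each round computes a
# maximum-weight simple In -> Out path in the graph restricted to vertices
# not used by earlier paths, until none remains. Cyclic graphs are first
# made acyclic by replacing each non-singleton strongly connected component
# with one fresh chain per simple entry -> exit path inside it, while a
# relabeling map R remembers each copy's original vertex; path extraction
# rejects chains whose original labels would repeat within one path.

as_milps_graph <- function(x) {
  if (inherits(x, "mix_extgraph")) x$graph
  else if (inherits(x, "igraph")) x
  else stop("expected an igraph or mix_extgraph")
}

#' Non-singleton strongly connected components
#'
#' @param g igraph (or `mix_extgraph`).
#' @return list of character vectors of vertex names, one per SCC with at
#'   least two vertices.
#' @export
find_sccs <- function(g) {
  g <- as_milps_graph(g)
  comp <- components(g, mode = "strong")
  keep <- which(comp$csize >= 2L)
  lapply(keep, function(k) names(comp$membership)[comp$membership == k])
}

# ensure every vertex carries its original label in attribute "orig"
ensure_orig <- function(g) {
  if (is.null(igraph::vertex_attr(g, "orig")))
    g <- igraph::set_vertex_attr(g, "orig", value = V(g)$name)
  g
}

#' Expand one strongly connected component into simple-path chains
#'
#' The component's vertices are removed and, for every simple path from an
#' entry vertex (receiving an edge from outside) to an exit vertex (sending
#' an edge outside), a fresh chain of copies is inserted, reattached to the
#' outside predecessors of its first and successors of its last vertex.
#' Copies carry the original vertex label in the `orig` vertex attribute.
#' A component with no entry or no exit is deleted with a warning.
#'
#' @param g igraph with vertex attribute `orig` (added if absent).
#' @param scc character vector of vertex names forming one SCC of `g`.
#' @param path_cap abort when the component contains more than this many
#'   simple entry-to-exit paths.
#' @export
expand_scc <- function(g, scc, path_cap = 10000L) {
  g <- ensure_orig(as_milps_graph(g))
  stopifnot(all(scc %in% V(g)$name))
  ft <- igraph::ends(g, E(g))
  w <- E(g)$weight
  cls <- E(g)$eclass
  if (is.null(cls)) cls <- rep(NA_character_, length(w))
  inside <- function(v) v %in% scc
  entries <- unique(ft[, 2][inside(ft[, 2]) & !inside(ft[, 1])])
  exits   <- unique(ft[, 1][inside(ft[, 1]) & !inside(ft[, 2])])
  if (length(entries) == 0L || length(exits) == 0L) {
    warning("SCC with no entry or no exit deleted (", length(scc),
            " vertices)")
    return(delete_vertices(g, scc))
  }
  sub <- induced_subgraph(g, scc)
  paths <- list()
  for (en in entries) {
    # single-vertex path when an entry is itself an exit
    if (en %in% exits) paths[[length(paths) + 1L]] <- en
    sp <- all_simple_paths(sub, from = en, to = setdiff(exits, en),
                           mode = "out")
    for (p in sp) paths[[length(paths) + 1L]] <- names(p)
    if (length(paths) > path_cap)
      stop("SCC expansion exceeds path cap (", path_cap,
           "); consider a larger alignment length threshold t_a")
  }
  # weight lookup inside the component
  wkey <- paste(ft[, 1], ft[, 2], sep = "\r")
  wmap <- setNames(w, wkey)
  cmap <- setNames(cls, wkey)
  orig_of <- setNames(igraph::vertex_attr(g, "orig"), V(g)$name)

  new_v <- character(); new_orig <- character()
  new_e <- list()
  tag <- paste0("scc", substr(scc[1], 1, 8))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    cp <- sprintf("%s#%03d#%03d%s%s", tag, k, seq_along(p), NODE_SEP, p)
    new_v <- c(new_v, cp); new_orig <- c(new_orig, orig_of[p])
    if (length(p) > 1L) {
      key <- paste(p[-length(p)], p[-1], sep = "\r")
      new_e[[length(new_e) + 1L]] <- data.frame(
        from = cp[-length(cp)], to = cp[-1],
        weight = unname(wmap[key]), eclass = unname(cmap[key]))
    }
    # reattach outside predecessors of the chain head, successors of tail
    pre <- ft[, 1][ft[, 2] == p[1] & !inside(ft[, 1])]
    if (length(pre))
      new_e[[length(new_e) + 1L]] <- data.frame(
        from = pre, to = cp[1],
        weight = unname(wmap[paste(pre, p[1], sep = "\r")]),
        eclass = unname(cmap[paste(pre, p[1], sep = "\r")]))
    suc <- ft[, 2][ft[, 1] == p[length(p)] & !inside(ft[, 2])]
    if (length(suc))
      new_e[[length(new_e) + 1L]] <- data.frame(
        from = cp[length(cp)], to = suc,
        weight = unname(wmap[paste(p[length(p)], suc, sep = "\r")]),
        eclass = unname(cmap[paste(p[length(p)], suc, sep = "\r")]))
  }
  g2 <- delete_vertices(g, scc)
  g2 <- igraph::add_vertices(g2, length(new_v),
                             attr = list(name = new_v, orig = new_orig))
  if (length(new_e)) {
    ed <- do.call(rbind, new_e)
    g2 <- igraph::add_edges(g2, rbind(match(ed$from, V(g2)$name),
                                      match(ed$to, V(g2)$name)),
                            attr = list(weight = ed$weight,
                                        eclass = ed$eclass))
  }
  g2
}

# expand every non-singleton SCC (sequentially; original SCCs are disjoint
# and expansion never merges them)
expand_all_sccs <- function(g, path_cap = 10000L) {
  g <- ensure_orig(g)
  for (scc in find_sccs(g)) g <- expand_scc(g, scc, path_cap)
  g
}

#' Maximum-weight In-to-Out path of an acyclic graph
#'
#' Dynamic program over a topological order with a lexicographic composite
#' objective: maximize path weight, then (among equal-weight paths) the
#' number of vertices covered, then take the lexicographically smallest
#' predecessor name. The vertex-count tie-break steers equal-weight choices
#' toward larger vertex coverage; the name tie-break makes the result
#' deterministic.
#'
#' @param g acyclic igraph with edge attribute `weight`.
#' @param forbidden vertex names excluded both as path members and as
#'   predecessors.
#' @return list with `nodes` (vertex names, `In` first) and `weight`, or
#'   `NULL` when `Out` is unreachable.
#' @export
longest_path <- function(g, forbidden = character()) {
  g <- as_milps_graph(g)
  if (length(forbidden))
    g <- delete_vertices(g, intersect(forbidden, V(g)$name))
  if (!all(c("In", "Out") %in% V(g)$name)) return(NULL)
  if (!igraph::is_dag(g)) stop("longest_path requires an acyclic graph")
  ord <- names(topo_sort(g, mode = "out"))
  nm <- V(g)$name
  W <- setNames(rep(-Inf, length(nm)), nm)
  C <- setNames(rep(0L, length(nm)), nm)   # vertex count at best weight
  Pred <- setNames(rep(NA_character_, length(nm)), nm)
  W["In"] <- 0; C["In"] <- 1L
  ft <- igraph::ends(g, E(g))
  w <- E(g)$weight
  preds <- split(data.frame(p = ft[, 1], w = w), ft[, 2])
  for (v in ord) {
    pv <- preds[[v]]
    if (is.null(pv)) next
    cand <- W[pv$p] + pv$w
    ok <- is.finite(cand)
    if (!any(ok)) next
    best <- max(cand[ok])
    tie <- pv$p[ok][cand[ok] == best]
    cc <- C[tie]
    tie <- tie[cc == max(cc)]
    Pred[v] <- sort(tie)[1]
    W[v] <- best
    C[v] <- C[Pred[v]] + 1L
  }
  if (!is.finite(W["Out"])) return(NULL)
  path <- "Out"
  while (!is.na(Pred[path[1]])) path <- c(Pred[path[1]], path)
  if (path[1] != "In") return(NULL)
  list(nodes = unname(path), weight = unname(W["Out"]))
}

# exhaustive maximum-weight simple In->Out path by depth-first enumeration;
# exact on cyclic graphs, used as fallback when SCC-chain relabeling would
# repeat an original vertex within one path
exhaustive_longest <- function(g, cap = 200000L) {
  nm <- V(g)$name
  if (!all(c("In", "Out") %in% nm)) return(NULL)
  ft <- igraph::ends(g, E(g))
  w <- E(g)$weight
  adj <- split(data.frame(to = ft[, 2], w = w), ft[, 1])
  adj <- lapply(adj, function(d) d[order(d$to), , drop = FALSE])
  best <- NULL; best_w <- -Inf; steps <- 0L
  rec <- function(v, acc_w, path) {
    steps <<- steps + 1L
    if (steps > cap) stop("simple-path enumeration exceeds cap (", cap, ")")
    if (v == "Out") {
      better <- acc_w > best_w ||
        (acc_w == best_w && !is.null(best) &&
           (length(path) > length(best) ||
              (length(path) == length(best) &&
                 paste(path, collapse = "\r") <
                   paste(best, collapse = "\r"))))
      if (better) { best <<- path; best_w <<- acc_w }
      return(invisible())
    }
    av <- adj[[v]]
    if (is.null(av)) return(invisible())
    for (k in seq_len(nrow(av))) {
      to <- av$to[k]
      if (to %in% path) next
      rec(to, acc_w + av$w[k], c(path, to))
    }
  }
  rec("In", 0, "In")
  if (is.null(best)) NULL else list(nodes = best, weight = best_w)
}

# all maximum-weight In->Out paths of a DAG (up to `cap`), by storing every
# argmax predecessor during the DP and backtracking from Out
all_max_paths_dag <- function(g, cap = 64L) {
  nm <- V(g)$name
  n <- length(nm)
  src <- match("In", nm); dst <- match("Out", nm)
  if (is.na(src) || is.na(dst)) return(list())
  ord <- as.integer(topo_sort(g, mode = "out"))
  ft <- igraph::ends(g, E(g), names = FALSE)
  ew <- E(g)$weight
  preds_of <- split(seq_along(ew), factor(ft[, 2], levels = seq_len(n)))
  W <- rep(-Inf, n); W[src] <- 0
  argmax <- vector("list", n)
  for (v in ord) {
    es <- preds_of[[v]]
    if (!length(es)) next
    ps <- ft[es, 1]
    cand <- W[ps] + ew[es]
    ok <- is.finite(cand)
    if (!any(ok)) next
    best <- max(cand[ok])
    if (best > W[v]) {
      W[v] <- best
      am <- ps[ok][cand[ok] == best]
      argmax[[v]] <- am[order(nm[am])]
    }
  }
  if (!is.finite(W[dst])) return(list())
  partial <- list(dst); np <- 1L
  out <- list()
  while (np > 0L) {
    p <- partial[[np]]; np <- np - 1L
    if (p[1] == src) { out[[length(out) + 1L]] <- p; next }
    for (q in rev(argmax[[p[1]]])) {
      if (length(out) + np >= cap) break
      np <- np + 1L
      partial[[np]] <- c(q, p)
    }
  }
  lapply(out, function(p) list(nodes = nm[p], weight = unname(W[dst])))
}

# all maximum-weight simple In->Out paths of a possibly cyclic graph (up to
# cap); SCC expansion first, exhaustive fallback when every DAG optimum
# revisits an original vertex
all_max_paths <- function(g, path_cap, cap = 64L) {
  if (igraph::is_dag(g)) {
    ps <- all_max_paths_dag(g, cap)
    orig <- setNames(igraph::vertex_attr(g, "orig"), V(g)$name)
    if (is.null(orig[[1]])) orig <- setNames(V(g)$name, V(g)$name)
    return(lapply(ps, function(p)
      list(nodes = unname(orig[p$nodes]), weight = p$weight)))
  }
  dag <- expand_all_sccs(g, path_cap)
  ps <- all_max_paths_dag(dag, cap)
  if (!length(ps)) return(list())
  orig <- setNames(igraph::vertex_attr(dag, "orig"), V(dag)$name)
  lab <- lapply(ps, function(p) unname(orig[p$nodes]))
  keep <- !vapply(lab, function(x) anyDuplicated(x) > 0, NA)
  if (!any(keep)) {
    p <- exhaustive_longest(g)
    return(if (is.null(p)) list() else list(p))
  }
  uniq <- !duplicated(vapply(lab[keep], paste, "", collapse = "\r"))
  mapply(function(nodes, w) list(nodes = nodes, weight = w),
         lab[keep][uniq], vapply(ps[keep], `[[`, 0, "weight")[uniq],
         SIMPLIFY = FALSE)
}

# extract one maximum-weight simple path from the (possibly cyclic)
# restriction of g, honoring original-label simplicity
extract_one <- function(g, path_cap) {
  if (igraph::is_dag(g)) {
    p <- longest_path(g)
    if (is.null(p)) return(NULL)
    orig <- setNames(igraph::vertex_attr(g, "orig"), V(g)$name)
    if (is.null(orig[[1]])) orig <- setNames(V(g)$name, V(g)$name)
    return(list(nodes = unname(orig[p$nodes]), weight = p$weight))
  }
  dag <- expand_all_sccs(g, path_cap)
  p <- longest_path(dag)
  if (is.null(p)) return(NULL)
  orig <- setNames(igraph::vertex_attr(dag, "orig"), V(dag)$name)
  lab <- unname(orig[p$nodes])
  if (!anyDuplicated(lab)) return(list(nodes = lab, weight = p$weight))
  # the DAG optimum walks one original vertex twice (two chains of the same
  # SCC); fall back to exact enumeration on the original restriction
  exhaustive_longest(g)
}

#' Maximal Independent Longest Path Set
#'
#' Iteratively extracts maximum-weight simple `In -> Out` paths; after each
#' extraction the path's interior vertices are forbidden, which makes the
#' returned paths pairwise vertex-independent (sharing at most `In`/`Out`).
#' On extension graphs (`mix_extgraph`), the mirror-reading variants of the
#' extracted vertices are forbidden as well and of each mirror-symmetric
#' path pair only the lexicographically smaller node sequence is kept, so
#' each gluing is reported once rather than once per strand.
#'
#' On extension graphs the extracted paths are additionally independent at
#' the contig level: every vertex of a consumed contig (any alignment, role
#' or direction) is forbidden for later paths, so no input contig
#' contributes sequence to two merged contigs.
#'
#' On plain graphs, equal-weight ties are additionally explored by a
#' bounded, deterministic branch search over co-optimal longest paths
#' (enumerated by DP backtracking), returning the extraction sequence whose
#' final vertex coverage is maximal — the defining property of a maximal
#' set. On extension graphs this search is disabled: mirror symmetry makes
#' every tie astronomically wide while mirror dedup already collapses the
#' pairs, so the deterministic greedy is used.
#'
#' @param x igraph (weights in edge attribute `weight`) or `mix_extgraph`.
#' @param mirror_dedup forbid mirror-direction variants after each
#'   extraction and keep one reading of each mirror pair (default: only for
#'   extension graphs).
#' @param consume_contigs forbid all vertices of contigs used by an
#'   extracted path (default: only for extension graphs).
#' @param tie_search explore equal-weight extraction alternatives for
#'   maximum vertex coverage (default: only for plain graphs).
#' @param scc_path_cap maximum number of simple paths enumerated inside one
#'   strongly connected component.
#' @param search_paths,search_states caps on the tie search: co-optimal
#'   paths enumerated per step, and total states explored before the search
#'   degenerates to the deterministic greedy continuation.
#' @return Object of class `mix_pathset`: list of paths, each a list with
#'   `nodes` and `weight`, in non-increasing weight order.
#' @export
milps <- function(x, mirror_dedup = inherits(x, "mix_extgraph"),
                  consume_contigs = inherits(x, "mix_extgraph"),
                  tie_search = !inherits(x, "mix_extgraph"),
                  scc_path_cap = 10000L,
                  search_paths = 64L, search_states = 400L) {
  g0 <- ensure_orig(as_milps_graph(x))
  if (tie_search)
    return(milps_search(g0, scc_path_cap, search_paths, search_states))
  forbidden <- character()
  out <- list()
  seen <- character()
  repeat {
    g <- delete_vertices(g0, intersect(forbidden, V(g0)$name))
    p <- extract_one(g, scc_path_cap)
    if (is.null(p)) break
    key <- paste(p$nodes, collapse = "\r")
    if (key %in% seen) break  # degenerate direct In->Out edge repeats
    seen <- c(seen, key)
    interior <- setdiff(p$nodes, c("In", "Out"))
    nodes <- p$nodes
    if (mirror_dedup && length(interior)) {
      # of the two strand readings, keep the majority-forward one (merged
      # contigs then come out on the forward strand of their inputs);
      # tie-break on the lexicographically smaller node sequence
      mir <- c("In", rev(reverse_variant(interior)), "Out")
      n_rev <- function(nds) sum(vapply(setdiff(nds, c("In", "Out")),
                                        function(v) parse_node(v)$dir == "r",
                                        NA))
      if (n_rev(mir) < n_rev(nodes) ||
          (n_rev(mir) == n_rev(nodes) &&
           paste(mir, collapse = "\r") < paste(nodes, collapse = "\r")))
        nodes <- mir
      forbidden <- c(forbidden, interior, reverse_variant(interior))
    } else {
      forbidden <- c(forbidden, interior)
    }
    if (consume_contigs && length(interior)) {
      ctgs <- unique(vapply(interior, function(v) parse_node(v)$contig, ""))
      all_names <- V(g0)$name
      used <- all_names[!(all_names %in% c("In", "Out")) &
        vapply(all_names, function(v) parse_node(v)$contig, "") %in% ctgs]
      forbidden <- unique(c(forbidden, used))
    }
    out[[length(out) + 1L]] <- list(nodes = nodes, weight = p$weight)
  }
  structure(out, class = "mix_pathset")
}

# depth-first search over longest-first extraction sequences, branching on
# equal-weight co-optimal paths; returns the sequence with maximal final
# vertex coverage (ties: lexicographically smallest set of path keys).
# States are memoized on the forbidden set; beyond `cap_states` only the
# first (deterministic) candidate is followed.
milps_search <- function(g0, path_cap, cap_paths, cap_states) {
  nm <- V(g0)$name
  n <- length(nm)
  src <- match("In", nm); dst <- match("Out", nm)
  ft <- igraph::ends(g0, E(g0), names = FALSE)
  ew <- E(g0)$weight
  ord_nm <- order(nm)
  preds_of <- split(seq_len(nrow(ft)), factor(ft[, 2], levels = seq_len(n)))
  succ_of <- split(seq_len(nrow(ft)), factor(ft[, 1], levels = seq_len(n)))

  # fast exact enumeration of all max-weight In->Out paths over the active
  # (non-forbidden) vertices; NULL when the restriction is cyclic
  fast_max_paths <- function(active) {
    if (is.na(src) || is.na(dst) || !active[src] || !active[dst])
      return(list())
    indeg <- integer(n)
    for (e in seq_len(nrow(ft)))
      if (active[ft[e, 1]] && active[ft[e, 2]])
        indeg[ft[e, 2]] <- indeg[ft[e, 2]] + 1L
    queue <- which(active & indeg == 0L)
    topo <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      topo <- c(topo, v)
      for (e in succ_of[[v]]) {
        u <- ft[e, 2]
        if (!active[u]) next
        indeg[u] <- indeg[u] - 1L
        if (indeg[u] == 0L) queue <- c(queue, u)
      }
    }
    if (length(topo) != sum(active)) return(NULL)  # cyclic restriction
    W <- rep(-Inf, n); W[src] <- 0
    argmax <- vector("list", n)
    for (v in topo) {
      es <- preds_of[[v]]
      if (!length(es)) next
      ps <- ft[es, 1]
      keep <- active[ps] & is.finite(W[ps])
      if (!any(keep)) next
      cand <- W[ps[keep]] + ew[es[keep]]
      best <- max(cand)
      if (best > W[v]) {
        W[v] <- best
        am <- ps[keep][cand == best]
        argmax[[v]] <- am[order(nm[am])]
      }
    }
    if (!is.finite(W[dst])) return(list())
    partial <- list(dst); out <- list()
    while (length(partial)) {
      p <- partial[[1]]; partial[[1]] <- NULL
      if (p[1] == src) { out[[length(out) + 1L]] <- p; next }
      for (q in argmax[[p[1]]]) {
        if (length(out) + length(partial) >= cap_paths) break
        partial[[length(partial) + 1L]] <- c(q, p)
      }
    }
    lapply(out, function(p) list(nodes = nm[p], weight = unname(W[dst])))
  }

  memo <- new.env(parent = emptyenv())
  best <- NULL; best_cov <- -1L; best_key <- ""
  states <- 0L
  leaf <- function(chosen) {
    cov <- length(unique(unlist(lapply(chosen, `[[`, "nodes"))))
    key <- paste(sort(vapply(chosen, function(p)
      paste(p$nodes, collapse = ">"), "")), collapse = "|")
    if (cov > best_cov || (cov == best_cov && key < best_key)) {
      best <<- chosen; best_cov <<- cov; best_key <<- key
    }
  }
  rec <- function(active, chosen) {
    skey <- rawToChar(packBits(c(active, rep(FALSE, (-n) %% 8)), "raw"))
    if (!is.null(memo[[skey]])) return(invisible())
    memo[[skey]] <- TRUE
    states <<- states + 1L
    cands <- fast_max_paths(active)
    if (is.null(cands)) {  # cyclic restriction: igraph + SCC expansion
      g <- delete_vertices(g0, nm[!active])
      cands <- all_max_paths(g, path_cap, cap_paths)
    }
    if (!length(cands)) { leaf(chosen); return(invisible()) }
    if (states > cap_states) cands <- cands[1]
    for (p in cands) {
      interior <- setdiff(p$nodes, c("In", "Out"))
      if (!length(interior)) { leaf(c(chosen, list(p))); next }
      a2 <- active; a2[match(interior, nm)] <- FALSE
      rec(a2, c(chosen, list(p)))
    }
  }
  rec(rep(TRUE, n), list())
  structure(if (is.null(best)) list() else best, class = "mix_pathset")
}

#' @export
print.mix_pathset <- function(x, ...) {
  cat(sprintf("<path set: %d path(s)%s>\n", length(x),
              if (length(x)) paste0("; weights ",
                paste(vapply(x, `[[`, 0, "weight"), collapse = ", "))
              else ""))
  invisible(x)
}
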