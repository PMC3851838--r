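# Shared fixtures and independent oracles.
#
# The oracles here never call the solver's machinery: simple paths are
# enumerated by plain recursive DFS over an adjacency list, and the
# reference MILPS enumerates every longest-first-consistent maximal
# independent path set by branching over weight ties.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# alignment-set builder over an ad-hoc contig index
make_aset <- function(rows, seqs) {
  asm <- mixasm::assembly(seqs)
  mixasm::alignment_set(do.call(rbind, lapply(rows, as.data.frame)), asm)
}

aln_row <- function(ci, cj, bi, ei, bj, ej, reversed_j = FALSE)
  list(ci = ci, cj = cj, bi = bi, ei = ei, bj = bj, ej = ej,
       l = ei - bi, reversed_j = reversed_j)

# two contigs overlapping end-of-A/start-of-B by ov bases, forward strand
overlap_pair <- function(la = 100L, lb = 80L, ov = 20L,
                         ids = c("x__A", "y__B")) {
  A <- rand_seq(la)
  B <- paste0(substr(A, la - ov + 1L, la), rand_seq(lb - ov))
  seqs <- stats::setNames(c(A, B), ids)
  aset <- make_aset(list(aln_row(ids[1], ids[2], la - ov, la, 0L, ov)), seqs)
  list(seqs = seqs, aset = aset, genomeish = paste0(A, substr(B, ov + 1, lb)))
}

# ---- graph oracles -------------------------------------------------------

graph_to_adj <- function(g) {
  ft <- igraph::ends(g, igraph::E(g))
  w <- igraph::E(g)$weight
  adj <- split(data.frame(to = ft[, 2], w = w, stringsAsFactors = FALSE),
               ft[, 1])
  lapply(adj, function(d) d[order(d$to), , drop = FALSE])
}

# all simple In -> Out paths by DFS (works on cyclic graphs)
enum_simple_paths <- function(g, from = "In", to = "Out") {
  nm <- igraph::V(g)$name
  ft <- igraph::ends(g, igraph::E(g), names = FALSE)
  w <- igraph::E(g)$weight
  adj_to <- split(ft[, 2], factor(ft[, 1], levels = seq_along(nm)))
  adj_w <- split(w, factor(ft[, 1], levels = seq_along(nm)))
  # deterministic neighbour order by name
  for (i in seq_along(adj_to)) {
    o <- order(nm[adj_to[[i]]])
    adj_to[[i]] <- adj_to[[i]][o]; adj_w[[i]] <- adj_w[[i]][o]
  }
  src <- match(from, nm); dst <- match(to, nm)
  out <- list()
  if (is.na(src) || is.na(dst)) return(out)
  onpath <- logical(length(nm))
  rec <- function(v, path, wsum) {
    if (v == dst) {
      out[[length(out) + 1L]] <<- list(nodes = nm[path], weight = wsum)
      return(invisible())
    }
    tos <- adj_to[[v]]
    if (!length(tos)) return(invisible())
    for (k in seq_along(tos)) {
      u <- tos[k]
      if (onpath[u]) next
      onpath[u] <<- TRUE
      rec(u, c(path, u), wsum + adj_w[[v]][k])
      onpath[u] <<- FALSE
    }
  }
  onpath[src] <- TRUE
  rec(src, src, 0)
  out
}

path_interior <- function(p) setdiff(p$nodes, c("In", "Out"))
path_key <- function(p) paste(p$nodes, collapse = ">")

# every maximal independent path set consistent with longest-first greedy
# extraction (branching over all maximum-weight ties); returns a list of
# sorted character vectors of path keys
oracle_milps_sets <- function(g, max_sets = 20000L) {
  paths <- enum_simple_paths(g)
  if (!length(paths)) return(list(character()))
  np <- length(paths)
  keys <- vapply(paths, path_key, "")
  wts <- vapply(paths, `[[`, 0, "weight")
  ints <- lapply(paths, path_interior)
  verts <- unique(unlist(ints))
  inc <- matrix(FALSE, np, max(1L, length(verts)))
  for (i in seq_len(np)) inc[i, match(ints[[i]], verts)] <- TRUE
  conflict <- tcrossprod(inc) > 0   # paths sharing an interior vertex
  seen_states <- new.env(parent = emptyenv())
  results <- new.env(parent = emptyenv())
  rec <- function(chosen, avail) {
    if (!length(avail)) {
      key <- paste0("S:", paste(sort(keys[chosen]), collapse = "|"))
      assign(key, chosen, envir = results)
      return(invisible())
    }
    skey <- paste0("S:", paste(sort(chosen), collapse = ","))
    if (!is.null(seen_states[[skey]])) return(invisible())
    seen_states[[skey]] <- TRUE
    mx <- max(wts[avail])
    for (k in avail[wts[avail] == mx]) {
      if (length(ls(results)) >= max_sets) return(invisible())
      rec(c(chosen, k), avail[!conflict[k, avail]])
    }
  }
  rec(integer(), seq_len(np))
  lapply(ls(results), function(k) sort(keys[get(k, envir = results)]))
}

# random weighted digraph with an In source and an Out sink; cycles allowed
random_milps_graph <- function(n_mid = 5L, p = 0.35, max_w = 12L,
                               cyclic = TRUE) {
  mid <- sprintf("v%02d", seq_len(n_mid))
  nodes <- c("In", mid, "Out")
  ed <- NULL
  for (a in nodes) for (b in nodes) {
    if (a == b) next
    if (b == "In" || a == "Out") next
    if (a == "In" && b == "Out") next         # no degenerate direct edge
    if (!cyclic && a != "In" && b != "Out" && a > b) next
    if (stats::runif(1) < p)
      ed <- rbind(ed, data.frame(from = a, to = b,
                                 weight = sample.int(max_w, 1)))
  }
  if (is.null(ed))
    ed <- data.frame(from = "In", to = mid[1], weight = 1)
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

# Definition-2 style validity check of a solver result on graph g
check_ilps_conditions <- function(ps, g) {
  nm <- igraph::V(g)$name
  for (p in ps) {
    expect_identical(p$nodes[1], "In")
    expect_identical(p$nodes[length(p$nodes)], "Out")
    expect_false(anyDuplicated(p$nodes) > 0)
    expect_true(all(p$nodes %in% nm))
    # consecutive nodes connected, weight adds up
    eids <- igraph::get_edge_ids(g, rbind(p$nodes[-length(p$nodes)],
                                          p$nodes[-1]))
    expect_true(all(eids > 0))
    expect_equal(sum(igraph::E(g)$weight[eids]), p$weight)
  }
  if (length(ps) >= 2L)
    for (a in seq_along(ps)) for (b in seq_along(ps)) {
      if (a >= b) next
      expect_length(intersect(path_interior(ps[[a]]),
                              path_interior(ps[[b]])), 0)
    }
  invisible(TRUE)
}

aln_cols <- c("ci", "cj", "bi", "ei", "bj", "ej", "l", "reversed_j")

aset_subset_empty <- function(aset)
  mixasm::alignment_set(aset$tab[0, aln_cols, drop = FALSE], aset$contigs)
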