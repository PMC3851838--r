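# End-to-end orchestration: clean -> build graph -> extract paths ->
# stitch -> prune -> stats.

#' Run the full merging pipeline on in-memory objects
#'
#' @param assemblies list of `mix_assembly` with globally unique contig ids
#'   (see [prefix_ids()]).
#' @param aset `mix_alignments` over the combined contigs (all assembly
#'   pairs).
#' @param t_a alignment length threshold (rule 3), bases.
#' @param coverage_threshold pruning containment threshold.
#' @param eps end tolerance (bases) for terminal-alignment detection.
#' @param scc_path_cap cap on simple paths enumerated per strongly
#'   connected component.
#' @param protect_paths if `TRUE`, merged path elements are never pruned
#'   even when fully covered by another element.
#' @return list: `assembly` (final `mix_assembly`), `candidates`, `paths`,
#'   `layouts`, `filter_report`, `prune_report`, `stats` (per input and
#'   output), `graph` (`mix_extgraph`).
#' @export
mix_pipeline <- function(assemblies, aset, t_a = 200L,
                         coverage_threshold = 0.9, eps = 0L,
                         scc_path_cap = 10000L, protect_paths = FALSE) {
  stopifnot(length(assemblies) >= 2L)
  contigs <- combine_assemblies(assemblies)
  cl <- clean_alignments(aset, t_a = t_a)
  eg <- build_graph(cl$aset, eps = eps)
  paths <- milps(eg, scc_path_cap = scc_path_cap)
  cand <- final_candidates(paths, eg, contigs)
  protect <- if (protect_paths) names(cand$layouts) else character()
  pr <- prune_assembly(cand$assembly, cand$layouts, aset,
                       threshold = coverage_threshold, protect = protect)
  st <- do.call(rbind, c(
    lapply(assemblies, function(a)
      cbind(assembly = a$label, assembly_stats(a))),
    list(cbind(assembly = "mix", assembly_stats(pr$assembly)))))
  list(assembly = pr$assembly, candidates = cand$assembly, paths = paths,
       layouts = cand$layouts, filter_report = cl$report,
       prune_report = pr$report, stats = st, graph = eg)
}

#' Run the merging pipeline from files
#'
#' @param fasta_paths two or more FASTA files (one draft assembly each).
#' @param aln_paths alignment files covering the assembly pairs: nucmer
#'   `show-coords -rcl -T` output (`.coords`) or the internal TSV dialect
#'   (anything else). Contig ids in the alignment files must use the
#'   prefixed form `<label>__<id>`.
#' @param labels assembly labels (default: file names without extension).
#' @param out_fasta optional path for the final FASTA (path provenance in
#'   the description line).
#' @param layout_out optional path for an AGP-style layout TSV.
#' @param dump_graph optional path for a DOT dump of the extension graph.
#' @param ... passed to [mix_pipeline()].
#' @export
run_mix <- function(fasta_paths, aln_paths, labels = NULL,
                    out_fasta = NULL, layout_out = NULL, dump_graph = NULL,
                    ...) {
  if (length(fasta_paths) < 2L) stop("need at least two assemblies")
  asms <- lapply(fasta_paths, read_fasta)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(asms))
    for (k in seq_along(asms)) asms[[k]]$label <- labels[k]
  }
  asms <- lapply(asms, prefix_ids)
  contigs <- combine_assemblies(asms)
  tabs <- lapply(aln_paths, function(p) {
    a <- if (grepl("\\.coords$", p)) parse_coords(p, contigs)
         else parse_tsv(p, contigs)
    a$tab[aln_cols]
  })
  aset <- alignment_set(do.call(rbind, tabs), contigs)
  # every assembly pair must be covered by at least one alignment file
  pair_of <- function(id) sub(paste0(ID_SEP, ".*$"), "", id)
  seen <- unique(t(apply(cbind(pair_of(aset$tab$ci), pair_of(aset$tab$cj)),
                         1, sort)))
  labs <- vapply(asms, `[[`, "", "label")
  want <- t(combn(sort(labs), 2))
  missing <- want[!paste(want[, 1], want[, 2]) %in%
                    paste(seen[, 1], seen[, 2]), , drop = FALSE]
  if (nrow(missing))
    warning("no alignments seen for assembly pair(s): ",
            paste(apply(missing, 1, paste, collapse = "/"), collapse = ", "))
  res <- mix_pipeline(asms, aset, ...)
  if (!is.null(dump_graph)) dump_dot(res$graph, dump_graph)
  if (!is.null(layout_out)) write_layout_tsv(res$layouts, layout_out)
  if (!is.null(out_fasta)) {
    seqs <- res$assembly$seq
    prov <- vapply(names(seqs), function(id) {
      if (!is.null(res$layouts[[id]]))
        paste(id, format_layout(res$layouts[[id]])) else id
    }, "")
    names(seqs) <- unname(prov)
    write_fasta(seqs, out_fasta)
  }
  res
}

#' @importFrom utils combn
NULL
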