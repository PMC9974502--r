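# Ancestral linkage groups (ALGs): pre-duplication chromosome units traced
# through extant genomes. An outgroup chromosome that is itself the product of
# a lineage-specific fusion contains several ALGs; these are separated by
# clustering its homologous ingroup chromosomes on orthogroup co-occurrence
# (copies of one ancestral gene land only on the 2R quartet of its own ALG).

#' Infer ancestral linkage groups
#'
#' Splits each outgroup chromosome into ancestral linkage groups. For every
#' outgroup chromosome, candidate ingroup chromosomes (abundance at least
#' `min_fraction` of the anchor's placed orthologs) are connected whenever at
#' least `min_shared` anchored orthogroups have ingroup members on both; the
#' maximal cliques of this graph are the ALGs. Cliques rather than connected
#' components: an ingroup chromosome formed by fusion of copies from two ALGs
#' legitimately belongs to both 2R quartets, and such a chromosome connects
#' two otherwise disjoint cliques without making their union a clique. Each
#' anchored orthogroup is then assigned to the ALG holding the majority of
#' its ingroup members.
#'
#' @param orthogroups An [orthogroup_table()].
#' @param outgroup_positions,ingroup_positions [gene_position_table()]s.
#' @param min_fraction Candidate-chromosome abundance threshold.
#' @param min_shared Minimum number of shared orthogroups for a co-occurrence
#'   edge.
#' @param mode Counting mode passed to [build_profiles()].
#' @return An object of class `alg_set` with `algs` (data.frame `alg_id`,
#'   `outgroup_chrom`, `n_orthogroups`), `chromosomes` (data.frame `alg_id`,
#'   `ingroup_chrom`), `assignment` (data.frame `group_id`, `alg_id`,
#'   `outgroup_chrom`), and `profiles`, a [build_profiles()]-shaped object
#'   whose anchors are the ALG ids, for use by the downstream map and fusion
#'   analysis.
#' @export
infer_algs <- function(orthogroups, outgroup_positions, ingroup_positions,
                       min_fraction = 0.05, min_shared = 2,
                       mode = c("gene", "pair")) {
  mode <- match.arg(mode)
  profiles <- build_profiles(orthogroups, outgroup_positions,
                             ingroup_positions, mode = mode)
  m <- orthogroups$members
  out_m <- m[m$species == profiles$outgroup, c("group_id", "gene_id")]
  in_m <- m[m$species == profiles$ingroup, c("group_id", "gene_id")]
  out_m$chrom <- outgroup_positions$records$chrom[
    match(out_m$gene_id, outgroup_positions$records$gene_id)]
  in_m$chrom <- ingroup_positions$records$chrom[
    match(in_m$gene_id, ingroup_positions$records$gene_id)]
  out_m <- out_m[!is.na(out_m$chrom), ]
  in_m <- in_m[!is.na(in_m$chrom), ]

  algs <- list(); chroms <- list(); assignment <- list(); alg_counts <- list()
  alg_i <- 0L
  for (o in sort(unique(out_m$chrom))) {
    pr <- profile_for(profiles, o)
    cand <- names(pr$abundance)[pr$abundance >= min_fraction]
    if (!length(cand)) next
    groups_o <- unique(out_m$group_id[out_m$chrom == o])
    sub <- in_m[in_m$group_id %in% groups_o & in_m$chrom %in% cand, ,
                drop = FALSE]
    # distinct chromosome sets per orthogroup -> co-occurrence edge weights
    sets <- lapply(split(sub$chrom, sub$group_id), unique)
    edges <- list()
    for (s in sets) {
      if (length(s) < 2) next
      s <- sort(s)
      cmb <- utils::combn(s, 2)
      edges[[length(edges) + 1L]] <-
        data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
    }
    if (length(edges)) {
      ew <- do.call(rbind, edges)
      ew <- stats::aggregate(list(w = rep(1L, nrow(ew))),
                             by = list(a = ew$a, b = ew$b), FUN = sum)
      ew <- ew[ew$w >= min_shared, , drop = FALSE]
    } else {
      ew <- data.frame(a = character(), b = character(), w = integer())
    }
    g <- igraph::graph_from_data_frame(ew[c("a", "b")], directed = FALSE,
                                       vertices = data.frame(name = cand))
    cliques <- lapply(igraph::max_cliques(g),
                      function(v) sort(igraph::V(g)$name[v]))
    cliques <- cliques[order(vapply(cliques, `[`, "", 1L))]
    n_units <- length(cliques)
    ids <- sprintf("ALG_%s_%d", o, seq_len(n_units))
    if (n_units == 1L) ids <- sprintf("ALG_%s", o)
    # orthogroup -> unit by majority of ingroup members (ties: first unit)
    gsets <- split(sub$chrom, sub$group_id)
    for (gid in names(gsets)) {
      hits <- vapply(cliques, function(cl)
        sum(unique(gsets[[gid]]) %in% cl), integer(1))
      u <- which.max(hits)
      assignment[[length(assignment) + 1L]] <-
        data.frame(group_id = gid, alg_id = ids[u], outgroup_chrom = o,
                   stringsAsFactors = FALSE)
    }
    asg <- do.call(rbind, utils::tail(assignment, length(gsets)))
    for (u in seq_len(n_units)) {
      alg_i <- alg_i + 1L
      algs[[alg_i]] <- data.frame(
        alg_id = ids[u], outgroup_chrom = o,
        n_orthogroups = sum(asg$alg_id == ids[u]),
        stringsAsFactors = FALSE)
      chroms[[alg_i]] <- data.frame(alg_id = ids[u],
                                    ingroup_chrom = cliques[[u]],
                                    stringsAsFactors = FALSE)
    }
    # unit-level counts: per assigned orthogroup, its ingroup members
    sub$alg_id <- asg$alg_id[match(sub$group_id, asg$group_id)]
    cnt <- stats::aggregate(list(count = rep(1L, nrow(sub))),
                            by = list(anchor = sub$alg_id,
                                      ingroup_chrom = sub$chrom), FUN = sum)
    alg_counts[[length(alg_counts) + 1L]] <- cnt
  }
  assignment <- if (length(assignment)) do.call(rbind, assignment) else
    data.frame(group_id = character(), alg_id = character(),
               outgroup_chrom = character(), stringsAsFactors = FALSE)
  counts <- if (length(alg_counts)) do.call(rbind, alg_counts) else
    data.frame(anchor = character(), ingroup_chrom = character(),
               count = integer(), stringsAsFactors = FALSE)
  structure(list(
    algs = do.call(rbind, algs) %||% data.frame(alg_id = character(),
                                                outgroup_chrom = character(),
                                                n_orthogroups = integer()),
    chromosomes = do.call(rbind, chroms) %||%
      data.frame(alg_id = character(), ingroup_chrom = character()),
    assignment = assignment,
    profiles = new_homology_profiles(counts, profiles$outgroup,
                                     profiles$ingroup, mode,
                                     profiles$skipped)),
    class = "alg_set")
}

#' @export
print.alg_set <- function(x, ...) {
  cat("Ancestral linkage groups:", nrow(x$algs), "units on",
      length(unique(x$algs$outgroup_chrom)), "outgroup chromosomes\n")
  invisible(x)
}

#' Detect outgroup-lineage chromosome fusions
#'
#' An outgroup chromosome containing `k >= 2` ancestral linkage groups is the
#' product of `k - 1` fusion events on the outgroup branch (epoch
#' `"cephalochordate"` for an amphioxus-like outgroup). One call is emitted
#' per inferred event.
#'
#' @param algs An [infer_algs()] result.
#' @return A data.frame of fusion calls with columns `epoch`,
#'   `outgroup_chrom`, `units` (ALG ids, `+`-joined), `n_units`.
#' @export
detect_outgroup_fusions <- function(algs) {
  stopifnot(inherits(algs, "alg_set"))
  per_chrom <- split(algs$algs$alg_id, algs$algs$outgroup_chrom)
  calls <- list()
  for (o in names(per_chrom)) {
    k <- length(per_chrom[[o]])
    if (k < 2) next
    calls[[o]] <- data.frame(
      epoch = "cephalochordate", outgroup_chrom = o,
      units = paste(sort(per_chrom[[o]]), collapse = "+"),
      n_units = k, stringsAsFactors = FALSE)[rep(1L, k - 1L), , drop = FALSE]
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(epoch = character(), outgroup_chrom = character(),
               units = character(), n_units = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
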