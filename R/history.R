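# Fusion-event inference and epoch placement. A fused ingroup chromosome
# carries substantial ortholog contributions from two or more ancestral units
# (ALGs). The epoch of a fusion follows a sharing rule over the four
# 2R-derived chromosome copies of each unit:
#   - a unit combination present in (all) four copies  -> pre-1R fusion
#   - present in exactly the two copies descending from one 1R product
#     -> post-1R fusion (the copy pairing is chosen by parsimony)
#   - present in a single copy -> post-2R fusion
# Combinations seen in three copies are ambiguous and take the most
# parsimonious epoch (pre-1R), flagged.

#' Detect fused ingroup chromosomes
#'
#' An ingroup chromosome receiving at least `min_fraction` of its placed
#' orthologs from each of two or more anchors (ancestral units) is called
#' fused. Contributions are computed from the profile counts restricted to
#' (anchor, chromosome) pairs present in the homology map, normalised per
#' ingroup chromosome.
#'
#' @param map A [build_homology_map()] result (outgroup-chromosome or
#'   ALG-level anchors).
#' @param profiles The [build_profiles()] object the map was built from (or
#'   the ALG-level profiles from [infer_algs()]).
#' @param min_fraction Evidence threshold: minimum fraction of the ingroup
#'   chromosome's placed orthologs contributed by a unit.
#' @return An object of class `fused_chromosomes`: `contributions`
#'   (data.frame `ingroup_chrom`, `anchor`, `count`, `fraction` for every
#'   contribution passing the threshold), `fused` (chromosomes with >= 2
#'   contributing units) and the threshold used.
#' @export
detect_fused_chromosomes <- function(map, profiles, min_fraction = 0.10) {
  stopifnot(inherits(map, "homology_map"),
            inherits(profiles, "homology_profiles"))
  cnt <- profiles$counts
  key <- paste(cnt$anchor, cnt$ingroup_chrom)
  mkey <- paste(map$assignments$anchor, map$assignments$ingroup_chrom)
  cnt <- cnt[key %in% mkey, , drop = FALSE]
  if (nrow(cnt)) {
    tot <- tapply(cnt$count, cnt$ingroup_chrom, sum)
    cnt$fraction <- cnt$count / as.numeric(tot[cnt$ingroup_chrom])
    cnt <- cnt[cnt$fraction >= min_fraction, , drop = FALSE]
    cnt <- cnt[order(cnt$ingroup_chrom, -cnt$fraction, cnt$anchor), ]
  } else {
    cnt$fraction <- numeric()
  }
  rownames(cnt) <- NULL
  n_units <- table(cnt$ingroup_chrom)
  structure(list(
    contributions = data.frame(ingroup_chrom = cnt$ingroup_chrom,
                               anchor = cnt$anchor, count = cnt$count,
                               fraction = cnt$fraction,
                               stringsAsFactors = FALSE),
    fused = sort(names(n_units)[n_units >= 2]),
    min_fraction = min_fraction), class = "fused_chromosomes")
}

#' @export
print.fused_chromosomes <- function(x, ...) {
  cat("Fused-chromosome calls:", length(x$fused), "of",
      length(unique(x$contributions$ingroup_chrom)),
      "ingroup chromosomes carry >= 2 units\n")
  invisible(x)
}

#' Assign fusion events to epochs
#'
#' Classifies every co-occurring pair of ancestral units by the sharing rule
#' (see the package vignette): pairs shared by four (or, flagged, three)
#' chromosome copies are pre-1R; pairs shared by exactly two copies are
#' post-1R when those two copies can consistently be 1R siblings (chosen
#' greedily by decreasing orthogroup support, maximising the number of
#' single-event explanations); remaining co-occurrences are post-2R, counted
#' per chromosome as block merges so that chains of fusions yield one event
#' per join.
#'
#' @param calls A [detect_fused_chromosomes()] result.
#' @param map The [build_homology_map()] used for detection.
#' @return An object of class `fusion_epochs`: `events` (data.frame `epoch`,
#'   `units`, `chromosomes`, `ambiguous`; one row per inferred fusion event),
#'   `epoch_counts` (named vector), `pre1r_groups` (unit -> pre-1R linkage
#'   group id), and `n_pre1r` (number of pre-1R linkage groups).
#' @export
assign_epochs <- function(calls, map) {
  stopifnot(inherits(calls, "fused_chromosomes"),
            inherits(map, "homology_map"))
  contrib <- calls$contributions
  units <- sort(unique(map$assignments$anchor))
  units_of <- split(contrib$anchor, contrib$ingroup_chrom)
  chroms <- sort(unique(c(contrib$ingroup_chrom,
                          map$assignments$ingroup_chrom)))

  ## pairwise unit co-occurrences and their occurrence sets
  occ <- list()
  support <- list()
  for (cc in names(units_of)) {
    us <- sort(unique(units_of[[cc]]))
    if (length(us) < 2) next
    cmb <- utils::combn(us, 2)
    for (j in seq_len(ncol(cmb))) {
      k <- paste(cmb[1, j], cmb[2, j], sep = "\r")
      occ[[k]] <- c(occ[[k]], cc)
      w <- contrib$count[contrib$ingroup_chrom == cc &
                           contrib$anchor %in% cmb[, j]]
      support[[k]] <- (support[[k]] %||% 0) + sum(w)
    }
  }

  ## pre-1R: a combination shared by all four 2R copies. Three shared copies
  ## is pre-1R only when three chromosomes are ALL both units carry (one
  ## 2R copy pair was itself merged by a later fusion); if either unit still
  ## occupies four distinct chromosomes, the three-way sharing decomposes
  ## into one post-1R and one independent post-2R fusion instead.
  n_distinct <- vapply(split(map$assignments$ingroup_chrom,
                             map$assignments$anchor),
                       function(x) length(unique(x)), integer(1))
  is_pre <- vapply(names(occ), function(k) {
    uv <- strsplit(k, "\r")[[1]]
    kk <- length(occ[[k]])
    kk >= 4 || (kk == 3 && all(n_distinct[uv] <= 3))
  }, logical(1))
  pre_edges <- names(occ)[is_pre]
  ambiguous_pre <- intersect(pre_edges, names(occ)[lengths(occ) == 3])
  ## demoted three-way combinations: reduce to a sibling pair (an existing
  ## two-chromosome occurrence set when one is a subset, else the two
  ## chromosomes with the strongest joint contribution); the remaining
  ## chromosome is picked up by the post-2R block-merge stage
  demoted <- names(occ)[lengths(occ) == 3 & !is_pre]
  if (length(demoted)) {
    sets2 <- unique(lapply(occ[lengths(occ) == 2], sort))
    for (k in demoted) {
      sub2 <- Filter(function(s) all(s %in% occ[[k]]), sets2)
      if (length(sub2)) {
        occ[[k]] <- sub2[[1L]]
      } else {
        uv <- strsplit(k, "\r")[[1]]
        cw <- vapply(occ[[k]], function(cc)
          sum(contrib$count[contrib$ingroup_chrom == cc &
                              contrib$anchor %in% uv]), numeric(1))
        occ[[k]] <- sort(occ[[k]][order(-cw, occ[[k]])][1:2])
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(pre_edges)) do.call(rbind, lapply(strsplit(pre_edges, "\r"),
      function(p) data.frame(a = p[1], b = p[2]))) else
      data.frame(a = character(), b = character()),
    directed = FALSE, vertices = data.frame(name = units))
  comp <- igraph::components(g)$membership
  pre1r_of <- stats::setNames(paste0("P", comp), names(comp))
  # event tables report unit names, not internal pre-1R group labels
  units_of_p <- lapply(split(names(pre1r_of), pre1r_of), sort)
  p_label <- function(ps)
    paste(sort(unlist(units_of_p[ps], use.names = FALSE)), collapse = "+")
  events <- list()
  for (cid in unique(comp)) {
    members <- sort(names(comp)[comp == cid])
    if (length(members) < 2) next
    pair_keys <- names(occ)[vapply(strsplit(names(occ), "\r"), function(p)
      all(p %in% members), logical(1))]
    amb <- any(pair_keys %in% ambiguous_pre)
    cs <- sort(unique(unlist(occ[pair_keys])))
    for (i in seq_len(length(members) - 1L))
      events[[length(events) + 1L]] <-
        data.frame(epoch = "pre-1R", units = paste(members, collapse = "+"),
                   chromosomes = paste(cs, collapse = "+"), ambiguous = amb,
                   stringsAsFactors = FALSE)
  }

  ## post-1R: pairs shared by exactly two copies, grouped by occurrence set;
  ## greedy acceptance by decreasing support, one sibling pair per chromosome
  post1_keys <- names(occ)[lengths(occ) == 2]
  grp_key <- vapply(occ[post1_keys], function(s)
    paste(sort(s), collapse = "\r"), "")
  accepted <- list()     # list of list(S = c(c1, c2), P = pre-1R group ids)
  used <- list()         # per pre-1R group: chromosomes already in a pair
  for (S in unique(grp_key[order(-unlist(support[post1_keys]),
                                 grp_key)])) {
    keys <- post1_keys[grp_key == S]
    ps <- lapply(strsplit(keys, "\r"), function(p) unname(pre1r_of[p]))
    ps <- ps[vapply(ps, function(p) p[1] != p[2], logical(1))]
    if (!length(ps)) next
    eg <- do.call(rbind, lapply(ps, function(p)
      data.frame(a = p[1], b = p[2], stringsAsFactors = FALSE)))
    pg <- igraph::graph_from_data_frame(eg, directed = FALSE)
    pcomp <- igraph::components(pg)$membership
    sc <- strsplit(S, "\r")[[1]]
    for (cid in unique(pcomp)) {
      pset <- sort(names(pcomp)[pcomp == cid])
      if (length(pset) < 2) next
      conflict <- any(vapply(pset, function(p)
        any(sc %in% used[[p]]), logical(1)))
      if (conflict) next   # falls through to post-2R block counting
      for (p in pset) used[[p]] <- c(used[[p]], sc)
      accepted[[length(accepted) + 1L]] <- list(S = sc, P = pset)
      for (i in seq_len(length(pset) - 1L))
        events[[length(events) + 1L]] <-
          data.frame(epoch = "post-1R", units = p_label(pset),
                     chromosomes = paste(sc, collapse = "+"),
                     ambiguous = FALSE, stringsAsFactors = FALSE)
    }
  }

  ## post-2R: per chromosome, merge pre-1R blocks explained by accepted
  ## pre/post-1R events; every remaining join is one post-2R fusion
  for (cc in chroms) {
    us <- unique(units_of[[cc]] %||%
                   map$assignments$anchor[map$assignments$ingroup_chrom == cc])
    pset <- unique(unname(pre1r_of[us]))
    if (length(pset) < 2) next
    block_of <- stats::setNames(seq_along(pset), pset)
    for (acc in accepted) {
      if (!cc %in% acc$S) next
      here <- intersect(acc$P, pset)
      if (length(here) >= 2) block_of[here] <- min(block_of[here])
    }
    blocks <- split(pset, block_of)
    if (length(blocks) < 2) next
    ord <- order(vapply(blocks, min, ""))
    blocks <- blocks[ord]
    for (i in seq_along(blocks)[-1L])
      events[[length(events) + 1L]] <-
        data.frame(epoch = "post-2R",
                   units = p_label(unlist(blocks[seq_len(i)])),
                   chromosomes = cc, ambiguous = FALSE,
                   stringsAsFactors = FALSE)
  }

  ## within-unit copy merges: a fusion joining two 2R copies of the SAME
  ## unit leaves no unit-pair signal; it shows up as the unit's four copy
  ## shares concentrating on fewer chromosomes (a chromosome holding ~2/4 of
  ## the unit's orthologs). Pattern (2,2) over two chromosomes is one
  ## post-1R self-fusion; a chromosome holding k>=2 copies otherwise is k-1
  ## post-2R fusions; all four copies on one chromosome is most
  ## parsimoniously post-1R + post-2R (flagged).
  ## units that merged pre-1R travel together, so the analysis is per
  ## pre-1R linkage group (summing the member units' counts) to avoid
  ## counting one chromosomal merge once per resident unit
  for (p in unique(pre1r_of)) {
    us <- names(pre1r_of)[pre1r_of == p]
    sel <- map$assignments[map$assignments$anchor %in% us, , drop = FALSE]
    if (!nrow(sel)) next
    cnt <- tapply(sel$count, sel$ingroup_chrom, sum)
    s <- cnt / sum(cnt)
    copies <- pmax(1L, as.integer(round(4 * s)))
    if (sum(copies) <= length(copies)) next
    lab <- paste(sort(us), collapse = "+")
    pat <- sort(copies, decreasing = TRUE)
    if (identical(pat, c(2L, 2L))) {
      events[[length(events) + 1L]] <-
        data.frame(epoch = "post-1R", units = lab,
                   chromosomes = paste(sort(names(cnt)), collapse = "+"),
                   ambiguous = FALSE, stringsAsFactors = FALSE)
    } else if (pat[1L] == 4L) {
      cc <- names(cnt)[which.max(copies)]
      events[[length(events) + 1L]] <-
        data.frame(epoch = c("post-1R", "post-2R"), units = lab,
                   chromosomes = cc, ambiguous = TRUE,
                   stringsAsFactors = FALSE)
    } else {
      for (i in which(copies >= 2L))
        for (j in seq_len(copies[i] - 1L))
          events[[length(events) + 1L]] <-
            data.frame(epoch = "post-2R", units = lab,
                       chromosomes = names(cnt)[i], ambiguous = FALSE,
                       stringsAsFactors = FALSE)
    }
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(epoch = character(), units = character(),
               chromosomes = character(), ambiguous = logical(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  counts <- table(factor(events$epoch,
                         levels = c("pre-1R", "post-1R", "post-2R")))
  structure(list(events = events,
                 epoch_counts = stats::setNames(as.integer(counts),
                                                names(counts)),
                 pre1r_groups = pre1r_of,
                 n_pre1r = length(unique(pre1r_of))),
            class = "fusion_epochs")
}

#' @export
print.fusion_epochs <- function(x, ...) {
  cat("Fusion events by epoch:\n")
  for (e in names(x$epoch_counts))
    cat(sprintf("  %-8s %d\n", e, x$epoch_counts[[e]]))
  cat("  pre-1R linkage groups:", x$n_pre1r, "\n")
  invisible(x)
}

#' Reconstruct the full event history from epoch-labelled fusion calls
#'
#' Reverses the inferred events from either the number of ancestral units
#' (the chordate ancestor count) or the pre-1R linkage-group count, and lays
#' out the canonical chordate-to-jawed-vertebrate tree: pre-1R fusions, first
#' WGD, post-1R fusions, second WGD, post-2R fusions, plus an outgroup branch
#' carrying the cephalochordate-epoch fusions and optional later
#' lineage-specific branches.
#'
#' @param events A data.frame of fusion events with an `epoch` column (levels
#'   among `"cephalochordate"`, `"pre-1R"`, `"post-1R"`, `"post-2R"`), e.g.
#'   the `events` element of [assign_epochs()] combined with
#'   [detect_outgroup_fusions()] calls, or a hand-built table.
#' @param n_units Number of ancestral units (chordate ancestor chromosome
#'   count). Exactly one of `n_units` and `pre1r_count` must be given.
#' @param pre1r_count Number of pre-1R linkage groups; the chordate ancestor
#'   count is then `pre1r_count + (number of pre-1R fusions)`.
#' @param outgroup Name for the outgroup tip (branch carries the
#'   cephalochordate fusions); `NULL` to omit the branch.
#' @param lineage_fusions Named integer vector of fusion counts on additional
#'   branches descending from the jawed-vertebrate node (e.g.
#'   `c(bird_ancestor = 5)`).
#' @return An [event_history()] with nodes `chordate_ancestor`, `pre_1R`,
#'   `post_1R`, `pre_2R`, `post_2R`, `jawed_vertebrate`, the outgroup tip and
#'   any lineage nodes.
#' @examples
#' ev <- data.frame(epoch = rep("pre-1R", 6))
#' node_counts(reconstruct_history(ev, pre1r_count = 17))["chordate_ancestor"]
#' @export
reconstruct_history <- function(events, n_units = NULL, pre1r_count = NULL,
                                outgroup = NULL, lineage_fusions = c()) {
  stopifnot(is.data.frame(events), "epoch" %in% names(events))
  bad <- setdiff(unique(events$epoch),
                 c("cephalochordate", "pre-1R", "post-1R", "post-2R"))
  if (length(bad))
    stop("unknown epoch(s): ", paste(bad, collapse = ", "), call. = FALSE)
  f <- function(e) sum(events$epoch == e)
  if (is.null(n_units) == is.null(pre1r_count))
    stop("give exactly one of n_units or pre1r_count", call. = FALSE)
  root <- if (!is.null(n_units)) n_units else pre1r_count + f("pre-1R")
  if (root < 1)
    stop("inconsistent calls: implied ancestral count ", root, call. = FALSE)
  h <- event_history("chordate_ancestor", root)
  if (!is.null(outgroup))
    h <- add_branch(h, "chordate_ancestor", outgroup,
                    rep("fusion", f("cephalochordate")))
  h <- add_branch(h, "chordate_ancestor", "pre_1R",
                  rep("fusion", f("pre-1R")))
  h <- add_branch(h, "pre_1R", "post_1R", "wgd")
  h <- add_branch(h, "post_1R", "pre_2R", rep("fusion", f("post-1R")))
  h <- add_branch(h, "pre_2R", "post_2R", "wgd")
  h <- add_branch(h, "post_2R", "jawed_vertebrate",
                  rep("fusion", f("post-2R")))
  for (nm in names(lineage_fusions))
    h <- add_branch(h, "jawed_vertebrate", nm,
                    rep("fusion", lineage_fusions[[nm]]))
  h
}
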