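# Chromosome homology assignment by relative ortholog abundance: for each
# outgroup chromosome (or ancestral linkage group), tally where its orthologs
# land in the ingroup genome and assign up to four homologous chromosomes
# (the 2R quartet), ordered A-D by decreasing abundance.

new_homology_profiles <- function(counts, outgroup, ingroup, mode, skipped) {
  counts <- counts[order(counts$anchor, counts$ingroup_chrom), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts, outgroup = outgroup, ingroup = ingroup,
                 mode = mode, skipped = skipped),
            class = "homology_profiles")
}

#' Build per-anchor homology profiles from orthogroups
#'
#' For every outgroup chromosome, counts how many orthologs fall on each
#' ingroup chromosome and converts the counts to relative abundances (the
#' fraction of that anchor's placed orthologs). Only orthogroups containing at
#' least one outgroup and one ingroup gene contribute. Genes without a
#' position record are excluded and reported in the skip tally.
#'
#' @param orthogroups An [orthogroup_table()].
#' @param outgroup_positions,ingroup_positions [gene_position_table()]s for
#'   the two species.
#' @param mode Counting mode: `"gene"` (default) adds one count per ingroup
#'   gene per distinct outgroup chromosome in the group, avoiding quadratic
#'   inflation from large families; `"pair"` adds one count per (outgroup
#'   gene, ingroup gene) pair.
#' @return An object of class `homology_profiles`: `counts` (data.frame
#'   `anchor`, `ingroup_chrom`, `count`), species labels, the counting mode,
#'   and `skipped` (named vector of genes lacking positions per species).
#' @export
build_profiles <- function(orthogroups, outgroup_positions, ingroup_positions,
                           mode = c("gene", "pair")) {
  stopifnot(inherits(orthogroups, "orthogroup_table"),
            inherits(outgroup_positions, "gene_position_table"),
            inherits(ingroup_positions, "gene_position_table"))
  mode <- match.arg(mode)
  outgroup <- outgroup_positions$species
  ingroup <- ingroup_positions$species
  if (!outgroup %in% orthogroups$species)
    stop("outgroup species '", outgroup, "' absent from orthogroup table",
         call. = FALSE)
  if (!ingroup %in% orthogroups$species)
    stop("ingroup species '", ingroup, "' absent from orthogroup table",
         call. = FALSE)
  m <- orthogroups$members
  out_m <- m[m$species == outgroup, c("group_id", "gene_id")]
  in_m <- m[m$species == ingroup, c("group_id", "gene_id")]
  out_m$chrom <- outgroup_positions$records$chrom[
    match(out_m$gene_id, outgroup_positions$records$gene_id)]
  in_m$chrom <- ingroup_positions$records$chrom[
    match(in_m$gene_id, ingroup_positions$records$gene_id)]
  skipped <- c(sum(is.na(out_m$chrom)), sum(is.na(in_m$chrom)))
  names(skipped) <- c(outgroup, ingroup)
  out_m <- out_m[!is.na(out_m$chrom), ]
  in_m <- in_m[!is.na(in_m$chrom), ]
  # distinct (group, outgroup chromosome) anchors, with outgroup gene counts
  anchors <- stats::aggregate(list(n_out = out_m$gene_id),
                              by = list(group_id = out_m$group_id,
                                        anchor = out_m$chrom), FUN = length)
  joined <- merge(anchors, in_m, by = "group_id")
  if (nrow(joined)) {
    w <- if (mode == "gene") rep(1L, nrow(joined)) else joined$n_out
    counts <- stats::aggregate(list(count = w),
                               by = list(anchor = joined$anchor,
                                         ingroup_chrom = joined$chrom),
                               FUN = sum)
  } else {
    counts <- data.frame(anchor = character(), ingroup_chrom = character(),
                         count = integer(), stringsAsFactors = FALSE)
  }
  new_homology_profiles(counts, outgroup, ingroup, mode, skipped)
}

#' @export
print.homology_profiles <- function(x, ...) {
  cat("Homology profiles:", length(unique(x$counts$anchor)), "anchors (",
      x$outgroup, ") x", length(unique(x$counts$ingroup_chrom)),
      "ingroup chromosomes (", x$ingroup, "), mode =", x$mode, "\n")
  invisible(x)
}

#' Extract one anchor's profile
#'
#' @param profiles A [build_profiles()] result.
#' @param anchor Anchor (outgroup chromosome or linkage-group id).
#' @return A list with `anchor`, `counts` (named vector over ingroup
#'   chromosomes), `abundance` (counts normalised to sum to one) and
#'   `n_placed`.
#' @export
profile_for <- function(profiles, anchor) {
  stopifnot(inherits(profiles, "homology_profiles"))
  sel <- profiles$counts[profiles$counts$anchor == anchor, , drop = FALSE]
  if (!nrow(sel)) stop("empty profile for anchor: ", anchor, call. = FALSE)
  counts <- stats::setNames(sel$count, sel$ingroup_chrom)
  list(anchor = anchor, counts = counts, abundance = counts / sum(counts),
       n_placed = sum(counts))
}

#' Assign homologous ingroup chromosomes for one anchor
#'
#' Slots are the chromosomes whose abundance is at least `min_fraction`,
#' ordered by decreasing abundance (ties broken lexicographically by
#' chromosome name), capped at `max_homologs` and labelled A, B, C, D. Four
#' slots is the expected signature of two WGD rounds without fusion.
#'
#' @param profile A [profile_for()] result.
#' @param max_homologs Maximum number of slots (default 4, forced by 2R).
#' @param min_fraction Minimum abundance for a slot (default 0.05, suppressing
#'   translocation noise).
#' @return A data.frame with columns `anchor`, `slot`, `ingroup_chrom`,
#'   `count`, `abundance`; the unassigned residue fraction is attached as
#'   attribute `residual`.
#' @export
assign_homologs <- function(profile, max_homologs = 4, min_fraction = 0.05) {
  stopifnot(is.list(profile), length(profile$abundance) >= 1)
  ab <- profile$abundance
  ord <- order(-ab, names(ab))
  ab <- ab[ord]
  keep <- which(ab >= min_fraction)
  keep <- keep[seq_len(min(length(keep), max_homologs))]
  res <- data.frame(anchor = profile$anchor,
                    slot = LETTERS[seq_along(keep)],
                    ingroup_chrom = names(ab)[keep],
                    count = unname(profile$counts[names(ab)[keep]]),
                    abundance = unname(ab[keep]),
                    stringsAsFactors = FALSE)
  attr(res, "residual") <- 1 - sum(res$abundance)
  res
}

#' Build the full homology map
#'
#' Applies [assign_homologs()] to every anchor in the profiles.
#'
#' @param profiles A [build_profiles()] (or linkage-group level) profile set.
#' @param max_homologs,min_fraction Passed to [assign_homologs()].
#' @param min_placed Anchors with fewer placed orthologs than this are flagged
#'   low-confidence (not dropped).
#' @return An object of class `homology_map`: `assignments` (data.frame
#'   `anchor`, `slot`, `ingroup_chrom`, `count`, `abundance`), `residual`
#'   (named vector per anchor), `low_confidence` (anchor names), plus species
#'   labels and the thresholds used.
#' @export
build_homology_map <- function(profiles, max_homologs = 4,
                               min_fraction = 0.05, min_placed = 10) {
  stopifnot(inherits(profiles, "homology_profiles"))
  anchors <- sort(unique(profiles$counts$anchor))
  entries <- vector("list", length(anchors))
  residual <- stats::setNames(numeric(length(anchors)), anchors)
  lowconf <- character()
  for (i in seq_along(anchors)) {
    pr <- profile_for(profiles, anchors[i])
    e <- assign_homologs(pr, max_homologs, min_fraction)
    residual[i] <- attr(e, "residual")
    if (pr$n_placed < min_placed) lowconf <- c(lowconf, anchors[i])
    entries[[i]] <- e
  }
  assignments <- do.call(rbind, entries)
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, residual = residual,
                 low_confidence = lowconf,
                 outgroup = profiles$outgroup, ingroup = profiles$ingroup,
                 max_homologs = max_homologs, min_fraction = min_fraction),
            class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  n_anchor <- length(unique(x$assignments$anchor))
  cat("Homology map (", x$outgroup, "->", x$ingroup, "):", n_anchor,
      "anchors\n")
  tab <- table(table(x$assignments$anchor))
  for (k in names(tab))
    cat(sprintf("  1:%s relationships: %d\n", k, tab[[k]]))
  if (length(x$low_confidence))
    cat("  low-confidence anchors:",
        paste(x$low_confidence, collapse = ", "), "\n")
  invisible(x)
}

#' Slot chromosomes assigned to one anchor
#'
#' @param map A [build_homology_map()] result.
#' @param anchor Anchor id.
#' @return Named character vector slot -> ingroup chromosome (possibly empty).
#' @export
assigned_chromosomes <- function(map, anchor) {
  stopifnot(inherits(map, "homology_map"))
  sel <- map$assignments[map$assignments$anchor == anchor, , drop = FALSE]
  stats::setNames(sel$ingroup_chrom, sel$slot)
}

#' Write a homology map as TSV
#'
#' Columns: `outgroup_chrom`, `slot`, `ingroup_chrom`, `count`, `abundance`.
#'
#' @param map A [build_homology_map()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_map <- function(map, path) {
  stopifnot(inherits(map, "homology_map"))
  df <- map$assignments
  names(df)[names(df) == "anchor"] <- "outgroup_chrom"
  write_tsv(df, path)
}
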