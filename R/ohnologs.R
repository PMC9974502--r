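# Ohnolog extraction: within each orthogroup, the ingroup genes sitting on
# the chromosomes assigned to the group's anchor (outgroup chromosome or
# ancestral linkage group) are the retained 2R duplicates; slots A-D identify
# which of the four homologous chromosomes holds each copy.

#' Extract ohnolog groups from orthogroups
#'
#' Restricts every orthogroup to the ingroup genes lying on the homologous
#' chromosomes assigned to the group's anchor. Orthogroups whose outgroup
#' genes span several outgroup chromosomes are split, one anchor at a time,
#' so that each anchor's bookkeeping stays separate. Ingroup genes on
#' non-assigned chromosomes are excluded and tallied. Groups occupying fewer
#' than `min_slots` distinct slots are dropped. Multiple genes on one slot
#' chromosome (tandem duplicates) are all retained but the slot counts once.
#'
#' @param orthogroups An [orthogroup_table()].
#' @param map A [build_homology_map()] result.
#' @param ingroup_positions [gene_position_table()] for the ingroup species.
#' @param outgroup_positions [gene_position_table()] for the outgroup;
#'   required unless `assignment` is given.
#' @param min_slots Minimum number of distinct occupied slots (default 2: at
#'   least one retained duplicate pair).
#' @param assignment Optional data.frame `group_id`, `alg_id`,
#'   `outgroup_chrom` (from [infer_algs()]) anchoring groups at the
#'   linkage-group level instead of raw outgroup chromosomes.
#' @return An object of class `ohnolog_groups`: `members` (data.frame
#'   `group_id`, `anchor`, `species`, `slot`, `gene_id`, `chrom`), `summary`
#'   (data.frame `group_id`, `anchor`, `n_members` = occupied slots),
#'   `anchor_genes` (outgroup genes per group), `excluded` (count of ingroup
#'   genes on non-assigned chromosomes), `species`, `min_slots`.
#' @export
extract_ohnolog_groups <- function(orthogroups, map, ingroup_positions,
                                   outgroup_positions = NULL, min_slots = 2,
                                   assignment = NULL) {
  stopifnot(inherits(orthogroups, "orthogroup_table"),
            inherits(map, "homology_map"),
            inherits(ingroup_positions, "gene_position_table"))
  m <- orthogroups$members
  ingroup <- ingroup_positions$species
  in_m <- m[m$species == ingroup, c("group_id", "gene_id")]
  in_m$chrom <- ingroup_positions$records$chrom[
    match(in_m$gene_id, ingroup_positions$records$gene_id)]
  in_m <- in_m[!is.na(in_m$chrom), ]

  if (is.null(assignment)) {
    if (is.null(outgroup_positions))
      stop("need outgroup_positions (or an ALG assignment) to anchor groups",
           call. = FALSE)
    out_m <- m[m$species == outgroup_positions$species,
               c("group_id", "gene_id")]
    out_m$chrom <- outgroup_positions$records$chrom[
      match(out_m$gene_id, outgroup_positions$records$gene_id)]
    out_m <- out_m[!is.na(out_m$chrom), ]
    anchors <- unique(out_m[c("group_id", "chrom")])
    names(anchors)[2] <- "anchor"
    anchor_genes <- data.frame(group_id = out_m$group_id,
                               anchor = out_m$chrom,
                               gene_id = out_m$gene_id,
                               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("group_id", "alg_id") %in% names(assignment)))
    anchors <- data.frame(group_id = assignment$group_id,
                          anchor = assignment$alg_id,
                          stringsAsFactors = FALSE)
    anchor_genes <- data.frame(group_id = character(), anchor = character(),
                               gene_id = character(), stringsAsFactors = FALSE)
  }
  missing_anchor <- setdiff(anchors$anchor, map$assignments$anchor)
  if (length(missing_anchor))
    stop("homology map does not cover anchor(s): ",
         paste(utils::head(missing_anchor, 5), collapse = ", "),
         call. = FALSE)

  rows <- merge(anchors, in_m, by = "group_id")
  slots <- map$assignments[c("anchor", "ingroup_chrom", "slot")]
  rows <- merge(rows, slots, by.x = c("anchor", "chrom"),
                by.y = c("anchor", "ingroup_chrom"), all.x = TRUE)
  excluded <- sum(is.na(rows$slot))
  rows <- rows[!is.na(rows$slot), , drop = FALSE]
  rows <- rows[order(rows$group_id, rows$anchor, rows$slot, rows$gene_id), ]
  if (nrow(rows)) {
    key <- paste(rows$group_id, rows$anchor, sep = "\r")
    n_members <- vapply(split(rows$slot, key),
                        function(s) length(unique(s)), integer(1))
    keys <- names(n_members)[n_members >= min_slots]
    summary <- data.frame(
      group_id = vapply(strsplit(keys, "\r"), `[`, "", 1L),
      anchor = vapply(strsplit(keys, "\r"), `[`, "", 2L),
      n_members = unname(n_members[keys]), stringsAsFactors = FALSE)
    rows <- rows[key %in% keys, , drop = FALSE]
  } else {
    summary <- data.frame(group_id = character(), anchor = character(),
                          n_members = integer(), stringsAsFactors = FALSE)
  }
  members <- data.frame(group_id = rows$group_id, anchor = rows$anchor,
                        species = rep(ingroup, length.out = nrow(rows)),
                        slot = rows$slot,
                        gene_id = rows$gene_id, chrom = rows$chrom,
                        stringsAsFactors = FALSE)
  rownames(members) <- NULL
  keep_key <- paste(anchor_genes$group_id, anchor_genes$anchor) %in%
    paste(summary$group_id, summary$anchor)
  structure(list(members = members, summary = summary,
                 anchor_genes = anchor_genes[keep_key, , drop = FALSE],
                 excluded = excluded, species = ingroup,
                 min_slots = min_slots),
            class = "ohnolog_groups")
}

#' @export
print.ohnolog_groups <- function(x, ...) {
  cat("Ohnolog groups (", x$species, "):", nrow(x$summary), "groups,",
      nrow(x$members), "genes;",
      sum(x$summary$n_members >= 3), "groups with >= 3 slots\n")
  invisible(x)
}

#' Count ohnolog groups occupying at least `min_slots` slots
#'
#' @param groups An [extract_ohnolog_groups()] result.
#' @param min_slots Slot-count threshold.
#' @return Integer count; non-increasing in `min_slots`.
#' @export
count_ohnolog_groups <- function(groups, min_slots) {
  stopifnot(inherits(groups, "ohnolog_groups"))
  sum(groups$summary$n_members >= min_slots)
}

#' Transfer ohnology labels to a second species
#'
#' Replaces every ingroup ohnolog by its orthologs in a target species (via a
#' pairwise ortholog map) and slot-labels the target genes through the target
#' species' own homology map, keeping only genes that land on a chromosome
#' assigned to the group's anchor. Output is deduplicated; genes without an
#' ortholog drop out. The distinct transferred genes are returned as the
#' novelty-eligible candidate list (comparison against an external ohnolog
#' catalogue is a separate, documented post-step).
#'
#' @param groups An [extract_ohnolog_groups()] result (source species).
#' @param pairs An [ortholog_pair_map()] connecting the source species to the
#'   target (either orientation).
#' @param target_positions [gene_position_table()] for the target species.
#' @param target_map [build_homology_map()] for the target species, with the
#'   same anchor ids as the source map.
#' @return A list with `groups` (an `ohnolog_groups` object for the target
#'   species) and `candidates` (character vector of distinct transferred
#'   genes).
#' @export
transfer_ohnology <- function(groups, pairs, target_positions, target_map) {
  stopifnot(inherits(groups, "ohnolog_groups"),
            inherits(pairs, "ortholog_pair_map"),
            inherits(target_positions, "gene_position_table"),
            inherits(target_map, "homology_map"))
  pr <- pairs$pairs
  if (pairs$species_b == groups$species && pairs$species_a != groups$species)
    pr <- data.frame(gene_a = pr$gene_b, gene_b = pr$gene_a,
                     stringsAsFactors = FALSE)
  target <- target_positions$species
  rows <- merge(groups$members[c("group_id", "anchor", "gene_id")], pr,
                by.x = "gene_id", by.y = "gene_a")
  out <- data.frame(group_id = character(), anchor = character(),
                    species = character(), slot = character(),
                    gene_id = character(), chrom = character(),
                    stringsAsFactors = FALSE)
  if (nrow(rows)) {
    rows$chrom <- target_positions$records$chrom[
      match(rows$gene_b, target_positions$records$gene_id)]
    rows <- rows[!is.na(rows$chrom), , drop = FALSE]
    slots <- target_map$assignments[c("anchor", "ingroup_chrom", "slot")]
    rows <- merge(rows, slots, by.x = c("anchor", "chrom"),
                  by.y = c("anchor", "ingroup_chrom"))
    if (nrow(rows)) {
      out <- data.frame(group_id = rows$group_id, anchor = rows$anchor,
                        species = target, slot = rows$slot,
                        gene_id = rows$gene_b, chrom = rows$chrom,
                        stringsAsFactors = FALSE)
      out <- unique(out)
      out <- out[order(out$group_id, out$anchor, out$slot, out$gene_id), ]
      rownames(out) <- NULL
    }
  }
  key <- paste(out$group_id, out$anchor, sep = "\r")
  n_members <- if (nrow(out))
    vapply(split(out$slot, key), function(s) length(unique(s)), integer(1))
  else integer()
  ukey <- unique(key)
  summary <- data.frame(
    group_id = vapply(strsplit(ukey, "\r"), `[`, "", 1L),
    anchor = vapply(strsplit(ukey, "\r"), `[`, "", 2L),
    n_members = unname(n_members[ukey]), stringsAsFactors = FALSE)
  tg <- structure(list(members = out, summary = summary,
                       anchor_genes = groups$anchor_genes,
                       excluded = 0L, species = target,
                       min_slots = 1L),
                  class = "ohnolog_groups")
  list(groups = tg, candidates = sort(unique(out$gene_id)))
}

#' Write ohnolog groups in the row-per-group dataset layout
#'
#' One row per (group, anchor); columns `group_id`, `anchor_chrom`, one
#' `<species>_<slot>` member-list column per species and slot, and optional
#' `novel_<species>` flags. The layout round-trips through
#' [read_ohnolog_dataset()].
#'
#' @param groups_list A single `ohnolog_groups` object or a list of them
#'   (one per species).
#' @param path Output path.
#' @param novelty Optional data.frame `group_id`, `species`, `novel`.
#' @return `path`, invisibly.
#' @export
write_ohnolog_dataset <- function(groups_list, path, novelty = NULL) {
  if (inherits(groups_list, "ohnolog_groups")) groups_list <- list(groups_list)
  all_members <- do.call(rbind, lapply(groups_list, `[[`, "members"))
  keys <- unique(do.call(rbind, lapply(groups_list, function(g)
    g$summary[c("group_id", "anchor")])))
  keys <- keys[order(keys$group_id, keys$anchor), , drop = FALSE]
  df <- data.frame(group_id = keys$group_id, anchor_chrom = keys$anchor,
                   stringsAsFactors = FALSE)
  for (g in groups_list) {
    sp <- g$species
    for (slot in sort(unique(g$members$slot))) {
      sel <- g$members[g$members$slot == slot, ]
      cell <- vapply(paste(df$group_id, df$anchor_chrom, sep = "\r"),
                     function(k) {
        hit <- sel$gene_id[paste(sel$group_id, sel$anchor, sep = "\r") == k]
        paste(hit, collapse = ", ")
      }, "")
      df[[paste(sp, slot, sep = "_")]] <- unname(cell)
    }
  }
  if (!is.null(novelty)) {
    for (sp in unique(novelty$species)) {
      sel <- novelty[novelty$species == sp, ]
      df[[paste0("novel_", sp)]] <-
        ifelse(df$group_id %in% sel$group_id[sel$novel], "true", "false")
    }
  }
  write_tsv(df, path)
}
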