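# End-to-end pipeline: (optionally) simulate -> homology -> ohnologs ->
# history -> summary. Deterministic under a fixed seed; every threshold used
# is recorded in the machine-readable summary.

#' Derive a pairwise ortholog map from an orthogroup table
#'
#' Emits every (species-A gene, species-B gene) pair co-occurring in an
#' orthogroup (possibly many-to-many).
#'
#' @param orthogroups An [orthogroup_table()].
#' @param species_a,species_b Species to pair.
#' @return An [ortholog_pair_map()].
#' @export
orthogroup_pairs <- function(orthogroups, species_a, species_b) {
  stopifnot(inherits(orthogroups, "orthogroup_table"))
  m <- orthogroups$members
  a <- m[m$species == species_a, c("group_id", "gene_id")]
  b <- m[m$species == species_b, c("group_id", "gene_id")]
  j <- merge(a, b, by = "group_id", suffixes = c("_a", "_b"))
  ortholog_pair_map(data.frame(gene_a = j$gene_id_a, gene_b = j$gene_id_b,
                               stringsAsFactors = FALSE),
                    species_a, species_b)
}

#' Assemble a pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Integer seed driving all randomness.
#' @param simulate `NULL`, or a named list of [simulation_config()] arguments
#'   (the pipeline then generates its own inputs and keeps the truth log).
#' @param orthogroups Path to an orthogroup TSV (ignored when simulating).
#' @param positions Named list `species -> path` of BED-like position tables
#'   (ignored when simulating).
#' @param outgroup,ingroup Species roles; `ingroup` may name a second species
#'   used as the ohnology-transfer target.
#' @param min_fraction Homology-slot abundance threshold.
#' @param max_homologs Maximum slots per anchor.
#' @param min_slots Slot threshold for keeping an ohnolog group.
#' @param report_min_slots Slot threshold used for the headline group count
#'   in the summary (default 3).
#' @param fusion_min_fraction Evidence threshold for a fusion contribution.
#' @param min_shared Minimum shared orthogroups for an ALG co-occurrence
#'   edge.
#' @param min_placed Low-confidence anchor threshold.
#' @param lineage_fusions Named list/vector of user-annotated fusion counts
#'   on post-jawed-vertebrate branches.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, simulate = NULL,
                            orthogroups = NULL, positions = NULL,
                            outgroup = "amphioxus",
                            ingroup = c("chicken", "human"),
                            min_fraction = 0.05, max_homologs = 4,
                            min_slots = 2, report_min_slots = 3,
                            fusion_min_fraction = 0.10, min_shared = 2,
                            min_placed = 10, lineage_fusions = NULL) {
  if (is.null(simulate)) {
    if (is.null(orthogroups) || is.null(positions))
      stop("either 'simulate' or input paths must be given", call. = FALSE)
    for (p in c(orthogroups, unlist(positions)))
      if (!file.exists(p)) stop("input path does not exist: ", p,
                                call. = FALSE)
  }
  stopifnot(min_fraction >= 0, min_fraction <= 1, max_homologs >= 1,
            min_slots >= 1, fusion_min_fraction >= 0,
            fusion_min_fraction <= 1)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, orthogroups = orthogroups,
                 positions = positions, outgroup = outgroup,
                 ingroup = ingroup, min_fraction = min_fraction,
                 max_homologs = max_homologs, min_slots = min_slots,
                 report_min_slots = report_min_slots,
                 fusion_min_fraction = fusion_min_fraction,
                 min_shared = min_shared, min_placed = min_placed,
                 lineage_fusions = lineage_fusions),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  args <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(args$positions)) args$positions <- as.list(args$positions)
  if (!is.null(args$simulate)) args$simulate <- as.list(args$simulate)
  do.call(pipeline_config, args)
}

#' Render a chromosome-count trajectory as text
#'
#' @param history An [event_history()].
#' @param path Node path (default: the chain of first children from the
#'   root).
#' @return Character scalar, e.g.
#'   `"chordate_ancestor(23) -[6 fusions]-> pre_1R(17) -[wgd]-> ..."`.
#' @export
render_trajectory <- function(history, path = NULL) {
  stopifnot(inherits(history, "event_history"))
  if (is.null(path)) {
    path <- history$nodes$node[1L]
    repeat {
      kids <- history$nodes$node[!is.na(history$nodes$parent) &
                                   history$nodes$parent == path[length(path)]]
      if (!length(kids)) break
      path <- c(path, kids[1L])
    }
  }
  tr <- chromosome_count_trajectory(history, path)
  out <- sprintf("%s(%d)", tr$node[1L], tr$count[1L])
  for (i in seq_len(nrow(tr))[-1L]) {
    ev <- history$events[[tr$node[i]]]
    lab <- if (!length(ev)) "no events" else {
      tb <- table(ev)
      paste(vapply(names(tb), function(e)
        if (e == "fusion") sprintf("%d fusion%s", tb[[e]],
                                   if (tb[[e]] > 1) "s" else "")
        else paste(rep("wgd", tb[[e]]), collapse = " + "), ""),
        collapse = " + ")
    }
    out <- sprintf("%s -[%s]-> %s(%d)", out, lab, tr$node[i], tr$count[i])
  }
  out
}

#' Run the full reconstruction pipeline
#'
#' Executes, in order: simulation (or input loading), ancestral-linkage-group
#' inference and homology mapping, ohnolog extraction (with transfer to a
#' second ingroup species when present), fusion detection with epoch
#' assignment, and event-history reconstruction. All stage outputs are
#' written under `config$outdir`; a machine-readable `summary.json` records
#' seeds, thresholds, group counts, per-epoch fusion counts and node
#' chromosome counts. Reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @return The summary (a named list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  ## stage 1: inputs
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    cfg <- do.call(simulation_config, args)
    sim <- simulate_history(cfg)
    write_simulation(sim, file.path(config$outdir, "sim"))
    orthogroups <- sim$orthogroups
    positions <- sim$positions
    outgroup <- cfg$outgroup
    ingroup <- cfg$ingroup
  } else {
    positions <- lapply(names(config$positions), function(sp)
      read_gene_positions(config$positions[[sp]], sp))
    names(positions) <- names(config$positions)
    orthogroups <- read_orthogroups(config$orthogroups)
    outgroup <- config$outgroup
    ingroup <- config$ingroup
    sim <- NULL
  }
  primary <- ingroup[1L]

  ## stage 2: linkage groups + homology map
  algs <- infer_algs(orthogroups, positions[[outgroup]], positions[[primary]],
                     min_fraction = config$min_fraction,
                     min_shared = config$min_shared)
  map <- build_homology_map(algs$profiles,
                            max_homologs = config$max_homologs,
                            min_fraction = config$min_fraction,
                            min_placed = config$min_placed)
  write_homology_map(map, file.path(config$outdir, "homology_map.tsv"))

  ## stage 3: ohnologs (+ transfer to second ingroup species)
  ohno <- extract_ohnolog_groups(orthogroups, map, positions[[primary]],
                                 min_slots = config$min_slots,
                                 assignment = algs$assignment)
  groups_list <- list(ohno)
  transferred <- NULL
  if (length(ingroup) >= 2) {
    target <- ingroup[2L]
    pairs <- orthogroup_pairs(orthogroups, primary, target)
    t_algs <- infer_algs(orthogroups, positions[[outgroup]],
                         positions[[target]],
                         min_fraction = config$min_fraction,
                         min_shared = config$min_shared)
    t_map <- build_homology_map(t_algs$profiles,
                                max_homologs = config$max_homologs,
                                min_fraction = config$min_fraction,
                                min_placed = config$min_placed)
    transferred <- transfer_ohnology(ohno, pairs, positions[[target]], t_map)
    groups_list <- c(groups_list, list(transferred$groups))
  }
  write_ohnolog_dataset(groups_list,
                        file.path(config$outdir, "ohnolog_groups.tsv"))

  ## stage 4: fusion history
  calls <- detect_fused_chromosomes(map, algs$profiles,
                                    min_fraction = config$fusion_min_fraction)
  epochs <- assign_epochs(calls, map)
  out_calls <- detect_outgroup_fusions(algs)
  events <- rbind(epochs$events,
                  if (nrow(out_calls))
                    data.frame(epoch = out_calls$epoch,
                               units = out_calls$units,
                               chromosomes = out_calls$outgroup_chrom,
                               ambiguous = FALSE, stringsAsFactors = FALSE))
  lineage <- unlist(config$lineage_fusions) %||% c()
  history <- reconstruct_history(events, n_units = nrow(algs$algs),
                                 outgroup = outgroup,
                                 lineage_fusions = lineage)
  write_tsv(events, file.path(config$outdir, "fusion_events.tsv"))
  write_tsv(data.frame(node = names(node_counts(history)),
                       count = unname(node_counts(history))),
            file.path(config$outdir, "node_counts.tsv"))
  traj <- render_trajectory(history,
                            c("chordate_ancestor", "pre_1R", "post_1R",
                              "pre_2R", "post_2R", "jawed_vertebrate"))
  con <- file(file.path(config$outdir, "trajectory.txt"), open = "wb")
  writeLines(traj, con, sep = "\n")
  close(con)

  ## summary
  summary <- list(
    seed = config$seed,
    thresholds = config[c("min_fraction", "max_homologs", "min_slots",
                          "report_min_slots", "fusion_min_fraction",
                          "min_shared", "min_placed")],
    species = list(outgroup = outgroup, ingroup = ingroup),
    n_orthogroups = length(orthogroups$group_ids),
    n_algs = nrow(algs$algs),
    n_ohnolog_groups = nrow(ohno$summary),
    n_groups_at_report_min_slots =
      count_ohnolog_groups(ohno, config$report_min_slots),
    n_transferred_genes =
      if (is.null(transferred)) 0L else length(transferred$candidates),
    fusions_per_epoch = as.list(c(
      cephalochordate = nrow(out_calls),
      epochs$epoch_counts)),
    node_counts = as.list(node_counts(history)),
    trajectory = traj)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
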