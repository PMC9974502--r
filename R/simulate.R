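# Forward simulator of chordate -> vertebrate genome evolution: an ancestral
# genome of N0 chromosomes x G genes undergoes ordered branch events (chromosome
# fusions and whole-genome duplications), followed by per-copy gene retention
# with optional chromosome-copy-biased (asymmetric) loss and translocation
# noise in each extant species. Emits the same table formats the inference
# modules consume, plus a complete truth log.

#' Simulation configuration
#'
#' @param n_ancestral_chromosomes Number of chromosomes in the chordate
#'   ancestor (N0).
#' @param genes_per_chromosome Genes per ancestral chromosome (G); every
#'   ancestral gene founds one orthogroup.
#' @param stem_events Ordered character vector of events on the branch from
#'   the ancestor to the ingroup (`"fusion"` / `"wgd"`). The default is the
#'   inferred vertebrate history: six stem fusions, 1R, nine fusions, 2R, five
#'   fusions.
#' @param outgroup_fusions Number of fusion events on the branch to the
#'   outgroup lineage (default three, the cephalochordate-branch count).
#' @param retention_prob Probability `p` that a post-WGD gene copy is retained
#'   in an ingroup species.
#' @param asymmetry_range Optional length-2 numeric range; when given, each
#'   post-WGD chromosome draws a retention multiplier uniformly from this
#'   range (once, shared by all ingroup species), modelling asymmetric
#'   sequence loss between duplicated chromosomes. Effective probabilities
#'   are capped to `[0, 1]`. `NULL` disables the bias.
#' @param translocation_rate Probability that a retained gene moves to a
#'   uniformly chosen different chromosome of its species after all events.
#' @param min_one_copy Enforce at least one retained ingroup copy per
#'   orthogroup per species (rejection sampling, i.e. retention conditioned
#'   on survival). Default `TRUE`.
#' @param outgroup_retention_prob Retention probability in the outgroup
#'   (default 1: the outgroup keeps its single copy of every gene).
#' @param identifiable_fusions Keep fusion-partner sampling uniform but
#'   reject draws that would make the history unreconstructable from
#'   chromosome-level gene content (e.g. the same chromosome pair fusing
#'   independently on two branches, or two post-1R fusions joining copies of
#'   the same pre-1R pair -- patterns indistinguishable from single earlier
#'   events). Default `TRUE`, matching the fully resolved reference history
#'   the simulator emulates; set `FALSE` for unconstrained sampling.
#' @param seed Integer seed; fully determines the simulation.
#' @param outgroup Outgroup species name.
#' @param ingroup Character vector of ingroup species names (two by default,
#'   generated from the same post-WGD genome with independent loss).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_ancestral_chromosomes = 23,
                              genes_per_chromosome = 100,
                              stem_events = c(rep("fusion", 6), "wgd",
                                              rep("fusion", 9), "wgd",
                                              rep("fusion", 5)),
                              outgroup_fusions = 3,
                              retention_prob = 0.9,
                              asymmetry_range = NULL,
                              translocation_rate = 0,
                              min_one_copy = TRUE,
                              outgroup_retention_prob = 1,
                              identifiable_fusions = TRUE,
                              seed = 1,
                              outgroup = "amphioxus",
                              ingroup = c("chicken", "human")) {
  n_ancestral_chromosomes <- check_count(n_ancestral_chromosomes, "N0")
  genes_per_chromosome <- check_count(genes_per_chromosome, "G")
  stem_events <- check_events(stem_events)
  stopifnot(retention_prob >= 0, retention_prob <= 1,
            translocation_rate >= 0, translocation_rate <= 1,
            outgroup_retention_prob >= 0, outgroup_retention_prob <= 1,
            outgroup_fusions >= 0, length(ingroup) >= 1)
  if (!is.null(asymmetry_range))
    stopifnot(length(asymmetry_range) == 2, asymmetry_range[1] >= 0,
              asymmetry_range[1] <= asymmetry_range[2])
  # feasibility of the whole event sequence is plain arithmetic
  apply_events(n_ancestral_chromosomes, stem_events)
  if (n_ancestral_chromosomes - outgroup_fusions < 1)
    stop("outgroup_fusions would leave no outgroup chromosome", call. = FALSE)
  structure(list(n_ancestral_chromosomes = n_ancestral_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 stem_events = stem_events,
                 outgroup_fusions = as.integer(outgroup_fusions),
                 retention_prob = retention_prob,
                 asymmetry_range = asymmetry_range,
                 translocation_rate = translocation_rate,
                 min_one_copy = isTRUE(min_one_copy),
                 outgroup_retention_prob = outgroup_retention_prob,
                 identifiable_fusions = isTRUE(identifiable_fusions),
                 seed = as.integer(seed),
                 outgroup = outgroup, ingroup = ingroup),
            class = "simulation_config")
}

# merge two uniformly chosen extant chromosomes (optionally subject to an
# acceptance predicate on the pair); returns updated state
.fuse_random <- function(chrom, extant, next_id, ok = NULL,
                         max_tries = 1000L) {
  if (length(extant) < 2)
    stop("fusion requested but fewer than two chromosomes exist",
         call. = FALSE)
  for (i in seq_len(max_tries)) {
    pair <- extant[sample.int(length(extant), 2L)]
    if (is.null(ok) || ok(pair[1], pair[2])) {
      chrom[chrom %in% pair] <- next_id
      return(list(chrom = chrom, extant = c(setdiff(extant, pair), next_id),
                  pair = pair, new = next_id))
    }
  }
  stop("could not draw an identifiable fusion pair after ", max_tries,
       " tries; relax the configuration or set identifiable_fusions = FALSE",
       call. = FALSE)
}

# TRUE when fusing chromosomes a and b keeps the history reconstructable
# from chromosome-level gene content. `unit_sets` maps chromosome id ->
# vector of unit ids (ancestral or pre-1R chromosomes) it carries;
# `coresident_ok` optionally whitelists unit pairs whose co-occurrence may
# rise to three copies (pairs already sharing a 1R chromosome).
.identifiable_pair <- function(a, b, unit_sets, coresident_ok = NULL) {
  A <- unit_sets[[as.character(a)]]
  B <- unit_sets[[as.character(b)]]
  if (length(intersect(A, B))) return(FALSE)
  others <- unit_sets[!names(unit_sets) %in% as.character(c(a, b))]
  for (s in others) {
    pa <- intersect(A, s); pb <- intersect(B, s)
    if (!length(pa) || !length(pb)) next
    if (is.null(coresident_ok)) return(FALSE)
    for (p in pa) for (q in pb) {
      if (!paste(min(p, q), max(p, q)) %in% coresident_ok) return(FALSE)
      n_now <- sum(vapply(others, function(v) all(c(p, q) %in% v),
                          logical(1)))
      if (n_now >= 3L) return(FALSE)
    }
  }
  TRUE
}

# retention sampling for one species: Bernoulli per gene copy with per-copy
# probability, optionally conditioned on >= 1 survivor per orthogroup
# (rejection sampling, which realises the exact conditional distribution)
.sample_retention <- function(og, eff_p, min_one_copy) {
  keep <- stats::runif(length(eff_p)) < eff_p
  if (min_one_copy) {
    og_f <- factor(og)
    repeat {
      lost <- !tapply(keep, og_f, any)
      if (!any(lost)) break
      redo <- og_f %in% levels(og_f)[lost]
      if (all(eff_p[redo] == 0))
        stop("min_one_copy impossible: all copy retention probabilities are 0",
             call. = FALSE)
      keep[redo] <- stats::runif(sum(redo)) < eff_p[redo]
    }
  }
  keep
}

#' Simulate a chordate-to-vertebrate genome evolution history
#'
#' Runs the forward model described in [simulation_config()]: the ancestral
#' genome is carried through the outgroup branch (fusions only) and the
#' ingroup stem (fusions and WGDs, with fusion partners drawn uniformly among
#' extant chromosomes), then each extant species independently loses gene
#' copies and optionally translocates genes. Chromosomes are named `chr1`,
#' `chr2`, ... per species by decreasing retained gene count.
#'
#' @param config A [simulation_config()].
#' @return A list of class `karyo_simulation` with elements:
#'   \describe{
#'     \item{history}{an [event_history()] of the simulated tree with true
#'       chromosome counts;}
#'     \item{orthogroups}{an [orthogroup_table()] over all species;}
#'     \item{positions}{named list of [gene_position_table()] per species;}
#'     \item{truth}{truth log: `genes` (per extant gene: species, gene id,
#'       chromosome, orthogroup, ancestral chromosome, pre-1R linkage group,
#'       2R slot A-D, pre-translocation chromosome), `fusions` (branch, epoch,
#'       fused chromosome ids), `epoch_counts`, `node_counts`,
#'       `chrom_map` (species, internal post-event chromosome id, name),
#'       `emptied_orthogroups` (species-wise count of orthogroups that lost
#'       every copy, only possible when `min_one_copy = FALSE`).}
#'   }
#' @examples
#' cfg <- simulation_config(n_ancestral_chromosomes = 3,
#'                          genes_per_chromosome = 10,
#'                          stem_events = c("wgd", "wgd"),
#'                          outgroup_fusions = 0,
#'                          retention_prob = 1, seed = 7)
#' sim <- simulate_history(cfg)
#' sim$orthogroups
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  N0 <- config$n_ancestral_chromosomes
  G <- config$genes_per_chromosome
  n_genes <- N0 * G
  og_ids <- sprintf("OG%06d", seq_len(n_genes))
  anc_chrom <- rep(seq_len(N0), each = G)

  fusions <- list()
  check <- isTRUE(config$identifiable_fusions)

  ## ---- ingroup stem: ordered fusions and WGDs ----
  # per gene-copy state; grows at each WGD
  state <- data.frame(og = og_ids, anc_chrom = anc_chrom,
                      chrom = anc_chrom, r1 = NA_integer_, r2 = NA_integer_,
                      pre1r = NA_integer_, pre2r = NA_integer_,
                      stringsAsFactors = FALSE)
  in_extant <- seq_len(N0)
  next_id <- N0 + 1L
  wgd_seen <- 0L
  oneR_pairs <- character()   # unit pairs sharing a 1R chromosome
  for (ev in config$stem_events) {
    if (ev == "fusion") {
      epoch <- c("pre-1R", "post-1R", "post-2R")[wgd_seen + 1L]
      ok <- NULL
      if (check && wgd_seen > 0L) {
        # unit = pre-1R chromosome; fusions must keep every unit-pair
        # sharing pattern decodable by the epoch rules
        unit_sets <- lapply(split(state$pre1r, state$chrom), unique)
        ok <- function(a, b)
          .identifiable_pair(a, b, unit_sets,
                             if (wgd_seen == 2L) oneR_pairs else NULL)
      }
      st <- .fuse_random(state$chrom, in_extant, next_id, ok)
      state$chrom <- st$chrom; in_extant <- st$extant
      fusions[[length(fusions) + 1L]] <-
        data.frame(branch = "stem", epoch = epoch,
                   chrom_a = st$pair[1], chrom_b = st$pair[2],
                   chrom_new = st$new, stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    } else {
      wgd_seen <- wgd_seen + 1L
      if (wgd_seen > 2L) stop("at most two WGD rounds are modelled",
                              call. = FALSE)
      if (wgd_seen == 1L) state$pre1r <- state$chrom
      if (wgd_seen == 2L) {
        state$pre2r <- state$chrom
        oneR_pairs <- unique(unlist(lapply(
          split(state$pre1r, state$chrom), function(u) {
            u <- sort(unique(u))
            if (length(u) < 2) return(character())
            cmb <- utils::combn(u, 2)
            paste(cmb[1, ], cmb[2, ])
          })))
      }
      new_a <- stats::setNames(next_id + 2L * seq_along(in_extant) - 2L,
                               in_extant)
      new_b <- new_a + 1L
      copy_a <- state; copy_b <- state
      copy_a$chrom <- unname(new_a[as.character(state$chrom)])
      copy_b$chrom <- unname(new_b[as.character(state$chrom)])
      if (wgd_seen == 1L) { copy_a$r1 <- 1L; copy_b$r1 <- 2L }
      else { copy_a$r2 <- 1L; copy_b$r2 <- 2L }
      state <- rbind(copy_a, copy_b)
      in_extant <- sort(unname(c(new_a, new_b)))
      next_id <- max(in_extant) + 1L
    }
  }

  ## ---- outgroup branch: fusions only (drawn after the stem so that, when
  ## identifiability is enforced, no unit pair is fused independently on
  ## both branches) ----
  out_chrom <- anc_chrom
  out_extant <- seq_len(N0)
  pre1r_sets <- lapply(split(state$anc_chrom, state$pre1r), unique)
  for (i in seq_len(config$outgroup_fusions)) {
    ok <- NULL
    if (check) {
      out_sets <- lapply(split(anc_chrom, out_chrom), unique)
      ok <- function(a, b) {
        A <- out_sets[[as.character(a)]]; B <- out_sets[[as.character(b)]]
        !any(vapply(pre1r_sets, function(v)
          any(A %in% v) && any(B %in% v), logical(1)))
      }
    }
    st <- .fuse_random(out_chrom, out_extant, next_id, ok)
    out_chrom <- st$chrom; out_extant <- st$extant
    fusions[[length(fusions) + 1L]] <-
      data.frame(branch = "outgroup", epoch = "cephalochordate",
                 chrom_a = st$pair[1], chrom_b = st$pair[2], chrom_new = st$new,
                 stringsAsFactors = FALSE)
    next_id <- next_id + 1L
  }
  slot_code <- c("A", "B", "C", "D")
  state$slot <- ifelse(is.na(state$r1), NA_character_,
                       ifelse(is.na(state$r2), slot_code[state$r1],
                              slot_code[(state$r1 - 1L) * 2L + state$r2]))

  ## ---- chromosome-copy retention bias (drawn once, shared by species) ----
  weights <- stats::setNames(rep(1, length(in_extant)), in_extant)
  if (!is.null(config$asymmetry_range))
    weights[] <- stats::runif(length(in_extant), config$asymmetry_range[1],
                              config$asymmetry_range[2])

  ## ---- extant species: loss + translocation ----
  species_tabs <- list()
  chrom_maps <- list()
  emptied <- integer()
  make_species <- function(sp, st, extant, p, w, min_one, t_rate) {
    eff_p <- pmin(1, pmax(0, p * w[as.character(st$chrom)]))
    keep <- .sample_retention(st$og, eff_p, min_one)
    n_empty <- length(unique(st$og)) - length(unique(st$og[keep]))
    st <- st[keep, , drop = FALSE]
    st$chrom_pre_move <- st$chrom
    if (t_rate > 0 && nrow(st)) {
      move <- stats::runif(nrow(st)) < t_rate
      if (any(move) && length(extant) > 1)
        st$chrom[move] <- vapply(st$chrom[move], function(cur) {
          other <- setdiff(extant, cur)
          other[sample.int(length(other), 1L)]  # avoid sample()'s scalar rule
        }, numeric(1))
    }
    # name chromosomes by decreasing gene content (ties by internal id)
    tab <- table(factor(st$chrom, levels = extant))
    ord <- extant[order(-as.integer(tab), extant)]
    cname <- stats::setNames(paste0("chr", seq_along(ord)), ord)
    st <- st[order(match(st$chrom, ord), st$og, st$slot %||% ""), ,
             drop = FALSE]
    st$species <- sp
    st$chrom_name <- unname(cname[as.character(st$chrom)])
    st$gene_id <- sprintf("%s_g%05d", sp, seq_len(nrow(st)))
    idx <- stats::ave(seq_len(nrow(st)), st$chrom, FUN = seq_along)
    st$start <- (idx - 1L) * 1000L
    st$end <- idx * 1000L
    list(tab = st, n_empty = n_empty,
         map = data.frame(species = sp, chrom_id = ord,
                          chrom_name = unname(cname[as.character(ord)]),
                          stringsAsFactors = FALSE))
  }
  out_state <- data.frame(og = og_ids, anc_chrom = anc_chrom,
                          chrom = out_chrom, r1 = NA_integer_,
                          r2 = NA_integer_, pre1r = NA_integer_,
                          pre2r = NA_integer_, slot = NA_character_,
                          stringsAsFactors = FALSE)
  res <- make_species(config$outgroup, out_state, sort(out_extant),
                      config$outgroup_retention_prob,
                      stats::setNames(rep(1, length(out_extant)),
                                      sort(out_extant)),
                      config$min_one_copy, 0)
  species_tabs[[config$outgroup]] <- res$tab
  chrom_maps[[config$outgroup]] <- res$map
  emptied[config$outgroup] <- res$n_empty
  for (sp in config$ingroup) {
    res <- make_species(sp, state, in_extant, config$retention_prob, weights,
                        config$min_one_copy, config$translocation_rate)
    species_tabs[[sp]] <- res$tab
    chrom_maps[[sp]] <- res$map
    emptied[sp] <- res$n_empty
  }
  if (any(emptied > 0))
    message("orthogroups emptied by loss: ",
            paste(sprintf("%s=%d", names(emptied)[emptied > 0],
                          emptied[emptied > 0]), collapse = ", "))

  ## ---- assemble outputs ----
  all_genes <- do.call(rbind, unname(species_tabs))
  members <- data.frame(group_id = all_genes$og, species = all_genes$species,
                        gene_id = all_genes$gene_id, stringsAsFactors = FALSE)
  members <- members[order(match(members$group_id, og_ids),
                           match(members$species,
                                 c(config$outgroup, config$ingroup))), ]
  live_ogs <- og_ids[og_ids %in% members$group_id]
  orthogroups <- orthogroup_table(members,
                                  species = c(config$outgroup, config$ingroup),
                                  group_ids = live_ogs)
  positions <- lapply(species_tabs, function(st)
    gene_position_table(
      data.frame(chrom = st$chrom_name, start = st$start, end = st$end,
                 gene_id = st$gene_id, stringsAsFactors = FALSE),
      st$species[1]))

  fusions <- if (length(fusions)) do.call(rbind, fusions) else
    data.frame(branch = character(), epoch = character(),
               chrom_a = integer(), chrom_b = integer(),
               chrom_new = integer(), stringsAsFactors = FALSE)
  epoch_counts <- as.data.frame(table(epoch = factor(
    fusions$epoch, levels = c("cephalochordate", "pre-1R", "post-1R",
                              "post-2R"))), stringsAsFactors = FALSE)
  names(epoch_counts) <- c("epoch", "fusions")

  history <- event_history("chordate_ancestor", N0)
  history <- add_branch(history, "chordate_ancestor", config$outgroup,
                        rep("fusion", config$outgroup_fusions))
  history <- add_branch(history, "chordate_ancestor", "ingroup_ancestor",
                        config$stem_events)
  for (sp in config$ingroup)
    history <- add_branch(history, "ingroup_ancestor", sp)

  truth <- list(
    genes = data.frame(species = all_genes$species,
                       gene_id = all_genes$gene_id,
                       chrom = all_genes$chrom_name,
                       orthogroup = all_genes$og,
                       anc_chrom = all_genes$anc_chrom,
                       pre1r_chrom = all_genes$pre1r,
                       slot = all_genes$slot,
                       chrom_id = all_genes$chrom,
                       chrom_id_pre_move = all_genes$chrom_pre_move,
                       stringsAsFactors = FALSE),
    fusions = fusions,
    epoch_counts = epoch_counts,
    node_counts = node_counts(history),
    chrom_map = do.call(rbind, unname(chrom_maps)),
    emptied_orthogroups = emptied)
  structure(list(config = config, history = history,
                 orthogroups = orthogroups, positions = positions,
                 truth = truth),
            class = "karyo_simulation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.karyo_simulation <- function(x, ...) {
  cat("Simulated genome evolution history\n")
  cat("  ancestral karyotype:", x$config$n_ancestral_chromosomes,
      "chromosomes x", x$config$genes_per_chromosome, "genes\n")
  cat("  stem events:", paste(x$config$stem_events, collapse = " "), "\n")
  cat("  species:", paste(names(x$positions), collapse = ", "), "\n")
  cat("  orthogroups:", length(x$orthogroups$group_ids), "\n")
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Emits `Orthogroups.tsv`, one `<species>.bed` position table per species,
#' `truth_genes.tsv`, `truth_fusions.tsv`, `node_counts.tsv` and a
#' `config.txt` key-value file.
#'
#' @param sim A [simulate_history()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "karyo_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_orthogroups(sim$orthogroups, file.path(outdir, "Orthogroups.tsv"))
  for (sp in names(sim$positions))
    write_gene_positions(sim$positions[[sp]],
                         file.path(outdir, paste0(sp, ".bed")))
  write_tsv(sim$truth$genes, file.path(outdir, "truth_genes.tsv"))
  write_tsv(sim$truth$fusions, file.path(outdir, "truth_fusions.tsv"))
  write_tsv(data.frame(node = names(sim$truth$node_counts),
                       count = unname(sim$truth$node_counts)),
            file.path(outdir, "node_counts.tsv"))
  cfg <- sim$config
  kv <- c(n_ancestral_chromosomes = cfg$n_ancestral_chromosomes,
          genes_per_chromosome = cfg$genes_per_chromosome,
          stem_events = paste(cfg$stem_events, collapse = ","),
          outgroup_fusions = cfg$outgroup_fusions,
          retention_prob = cfg$retention_prob,
          asymmetry_range = paste(cfg$asymmetry_range, collapse = ","),
          translocation_rate = cfg$translocation_rate,
          min_one_copy = cfg$min_one_copy,
          outgroup_retention_prob = cfg$outgroup_retention_prob,
          seed = cfg$seed, outgroup = cfg$outgroup,
          ingroup = paste(cfg$ingroup, collapse = ","))
  con <- file(file.path(outdir, "config.txt"), open = "wb")
  writeLines(paste(names(kv), kv, sep = "\t"), con, sep = "\n")
  close(con)
  invisible(outdir)
}
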