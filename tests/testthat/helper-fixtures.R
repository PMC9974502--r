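# Shared fixtures: tiny in-code tables and simulation shortcuts.

# canonical chordate -> jawed-vertebrate study conditions
chordate_config <- function(seed, retention_prob = 0.9,
                            n_ancestral_chromosomes = 23,
                            genes_per_chromosome = 100, ...) {
  simulation_config(n_ancestral_chromosomes = n_ancestral_chromosomes,
                    genes_per_chromosome = genes_per_chromosome,
                    retention_prob = retention_prob, seed = seed, ...)
}

# minimal lossless two-WGD simulation without fusions
lossless_config <- function(seed = 1, n = 3, g = 20) {
  simulation_config(n_ancestral_chromosomes = n, genes_per_chromosome = g,
                    stem_events = c("wgd", "wgd"), outgroup_fusions = 0,
                    retention_prob = 1, seed = seed)
}

# orthogroup table with one outgroup gene per group, ingroup genes placed on
# chromosomes according to `dest`, a list group -> character vector of
# ingroup chromosomes (one gene per listed chromosome)
placed_orthogroups <- function(dest, outgroup = "out", ingroup = "in") {
  rows <- list()
  pos_in <- list()
  pos_out <- list()
  gi <- 0
  for (k in seq_along(dest)) {
    gid <- sprintf("OG%03d", k)
    og_gene <- sprintf("out_g%03d", k)
    rows[[length(rows) + 1]] <-
      data.frame(group_id = gid, species = outgroup, gene_id = og_gene)
    pos_out[[k]] <- data.frame(chrom = "chrOut1", start = (k - 1) * 10,
                               end = k * 10, gene_id = og_gene)
    for (chrom in dest[[k]]) {
      gi <- gi + 1
      g <- sprintf("in_g%04d", gi)
      rows[[length(rows) + 1]] <-
        data.frame(group_id = gid, species = ingroup, gene_id = g)
      pos_in[[gi]] <- data.frame(chrom = chrom, start = (gi - 1) * 10,
                                 end = gi * 10, gene_id = g)
    }
  }
  list(orthogroups = orthogroup_table(do.call(rbind, rows),
                                      species = c(outgroup, ingroup)),
       outgroup_positions = gene_position_table(do.call(rbind, pos_out),
                                                outgroup),
       ingroup_positions = gene_position_table(do.call(rbind, pos_in),
                                               ingroup))
}

# exact enumeration oracle: conditional retention distribution for one
# orthogroup with four copies, each kept with probability p, conditioned on
# at least one survivor (independent of the package's sampling code)
enumerate_retention <- function(p, n_copies = 4) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n_copies)))
  probs <- apply(outcomes, 1, function(o)
    prod(ifelse(o == 1, p, 1 - p)))
  keep <- rowSums(outcomes) >= 1
  probs <- probs[keep] / sum(probs[keep])
  outcomes <- outcomes[keep, , drop = FALSE]
  list(outcomes = outcomes, probs = probs,
       p_ge = function(k) sum(probs[rowSums(outcomes) >= k]),
       marginal = colSums(outcomes * probs))
}
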