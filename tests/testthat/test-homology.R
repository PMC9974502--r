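test_that("abundances are the hand-computed proportions", {
  dest <- c(rep(list("chrA"), 40), rep(list("chrB"), 30), rep(list("chrC"), 20),
            rep(list("chrD"), 6), rep(list("chrE"), 4))
  fx <- placed_orthogroups(dest)
  profiles <- build_profiles(fx$orthogroups, fx$outgroup_positions,
                             fx$ingroup_positions)
  pr <- profile_for(profiles, "chrOut1")
  expect_equal(pr$n_placed, 100)
  expect_equal(pr$abundance[c("chrA", "chrB", "chrC", "chrD", "chrE")],
               c(chrA = .40, chrB = .30, chrC = .20, chrD = .06, chrE = .04))
  expect_equal(sum(pr$abundance), 1)
  entry <- assign_homologs(pr)
  expect_equal(entry$slot, c("A", "B", "C", "D"))
  expect_equal(entry$ingroup_chrom, c("chrA", "chrB", "chrC", "chrD"))
  expect_equal(attr(entry, "residual"), 0.04)
})

test_that("a single destination yields a 1:1 relationship", {
  fx <- placed_orthogroups(rep(list("chrA"), 100))
  pr <- profile_for(build_profiles(fx$orthogroups, fx$outgroup_positions,
                                   fx$ingroup_positions), "chrOut1")
  expect_equal(pr$abundance, c(chrA = 1))
  expect_equal(assign_homologs(pr)$ingroup_chrom, "chrA")
})

test_that("slot order breaks abundance ties lexicographically", {
  fx <- placed_orthogroups(c(rep(list("chrB"), 10), rep(list("chrA"), 10)))
  entry <- assign_homologs(profile_for(
    build_profiles(fx$orthogroups, fx$outgroup_positions,
                   fx$ingroup_positions), "chrOut1"))
  expect_equal(entry$ingroup_chrom, c("chrA", "chrB"))
})

test_that("profiles are invariant to orthogroup row order", {
  sim <- simulate_history(chordate_config(5, genes_per_chromosome = 10))
  og <- sim$orthogroups
  set.seed(1)
  shuffled <- orthogroup_table(og$members[sample(nrow(og$members)), ],
                               species = og$species,
                               group_ids = sample(og$group_ids))
  p1 <- build_profiles(og, sim$positions$amphioxus, sim$positions$chicken)
  p2 <- build_profiles(shuffled, sim$positions$amphioxus,
                       sim$positions$chicken)
  expect_equal(p1$counts, p2$counts)
})

test_that("counting modes differ exactly by outgroup multiplicity", {
  members <- rbind(
    data.frame(group_id = "OG1", species = "out",
               gene_id = c("o1", "o2")),
    data.frame(group_id = "OG1", species = "in", gene_id = c("i1", "i2")))
  og <- orthogroup_table(members, species = c("out", "in"))
  pos_out <- gene_position_table(
    data.frame(chrom = "bb1", start = c(0, 10), end = c(10, 20),
               gene_id = c("o1", "o2")), "out")
  pos_in <- gene_position_table(
    data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20),
               gene_id = c("i1", "i2")), "in")
  gene_mode <- build_profiles(og, pos_out, pos_in, mode = "gene")
  pair_mode <- build_profiles(og, pos_out, pos_in, mode = "pair")
  expect_equal(gene_mode$counts$count, 2)   # one per ingroup gene
  expect_equal(pair_mode$counts$count, 4)   # one per (out, in) pair
})

test_that("genes without positions are skipped and tallied", {
  fx <- placed_orthogroups(rep(list("chrA"), 5))
  # drop one ingroup gene's position record
  rec <- fx$ingroup_positions$records[-1, ]
  pos <- gene_position_table(rec, "in")
  profiles <- build_profiles(fx$orthogroups, fx$outgroup_positions, pos)
  expect_equal(unname(profiles$skipped["in"]), 1)
  expect_equal(profile_for(profiles, "chrOut1")$n_placed, 4)
  expect_error(build_profiles(fx$orthogroups, fx$outgroup_positions,
                              gene_position_table(rec[0, ], "whale")),
               "absent from orthogroup table")
})

test_that("lossless simulations recover every true descendant set", {
  for (seed in 1:3) {
    sim <- simulate_history(simulation_config(
      n_ancestral_chromosomes = 8, genes_per_chromosome = 30,
      outgroup_fusions = 0, stem_events = c("wgd", "wgd"),
      retention_prob = 1, seed = seed))
    profiles <- build_profiles(sim$orthogroups, sim$positions$amphioxus,
                               sim$positions$chicken)
    tg <- sim$truth$genes[sim$truth$genes$species == "chicken", ]
    am <- sim$truth$genes[sim$truth$genes$species == "amphioxus", ]
    for (oc in unique(am$chrom)) {
      units <- unique(am$anc_chrom[am$chrom == oc])
      true_set <- sort(unique(tg$chrom[tg$anc_chrom %in% units]))
      pr <- profile_for(profiles, oc)
      expect_equal(sort(names(pr$counts)), true_set)
      expect_equal(sort(assign_homologs(pr)$ingroup_chrom), true_set)
    }
  }
})

test_that("descendant-set recovery degrades little at p = 0.8", {
  recovered <- 0; total <- 0
  for (seed in 1:10) {
    sim <- simulate_history(chordate_config(seed, retention_prob = 0.8))
    algs <- infer_algs(sim$orthogroups, sim$positions$amphioxus,
                       sim$positions$chicken)
    map <- build_homology_map(algs$profiles)
    tg <- sim$truth$genes[sim$truth$genes$species == "chicken", ]
    am <- sim$truth$genes[sim$truth$genes$species == "amphioxus", ]
    # true descendant sets per inferred unit are compared per outgroup
    # chromosome: union over its units
    for (oc in unique(am$chrom)) {
      units <- unique(am$anc_chrom[am$chrom == oc])
      true_set <- sort(unique(tg$chrom[tg$anc_chrom %in% units]))
      anchors <- algs$algs$alg_id[algs$algs$outgroup_chrom == oc]
      got <- sort(unique(unlist(lapply(anchors, function(a)
        assigned_chromosomes(map, a)))))
      total <- total + 1
      if (identical(got, true_set)) recovered <- recovered + 1
    }
  }
  expect_gte(recovered / total, 0.95)
})

test_that("low-confidence anchors are flagged, not dropped", {
  fx <- placed_orthogroups(rep(list("chrA"), 5))
  profiles <- build_profiles(fx$orthogroups, fx$outgroup_positions,
                             fx$ingroup_positions)
  map <- build_homology_map(profiles, min_placed = 10)
  expect_equal(map$low_confidence, "chrOut1")
  expect_equal(nrow(map$assignments), 1)
})
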