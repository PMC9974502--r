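# hand fixture: two anchors, four ingroup chromosomes each; one orthogroup
# occupying slots A and C, one occupying all four, one occupying one slot
ohnolog_fixture <- function() {
  dest <- list(OG1 = c("chr1", "chr3"),
               OG2 = c("chr1", "chr2", "chr3", "chr4"),
               OG3 = "chr2",
               OG4 = c("chr2", "chr4", "chr9"))  # chr9 is not homologous
  fx <- placed_orthogroups(dest)
  profiles <- build_profiles(fx$orthogroups, fx$outgroup_positions,
                             fx$ingroup_positions)
  # chr9 receives 1/9 of placed orthologs; keep the quartet only
  map <- build_homology_map(profiles, min_fraction = 0.15)
  c(fx, list(map = map))
}

test_that("slot membership is read off the homology map", {
  fx <- ohnolog_fixture()
  groups <- extract_ohnolog_groups(fx$orthogroups, fx$map,
                                   fx$ingroup_positions,
                                   fx$outgroup_positions, min_slots = 2)
  expect_equal(sort(groups$summary$group_id), c("OG001", "OG002", "OG004"))
  expect_equal(groups$summary$n_members[groups$summary$group_id == "OG001"], 2)
  expect_equal(groups$summary$n_members[groups$summary$group_id == "OG002"], 4)
  # the non-homologous chromosome is excluded and tallied
  expect_equal(groups$summary$n_members[groups$summary$group_id == "OG004"], 2)
  expect_equal(groups$excluded, 1)
  expect_false("chr9" %in% groups$members$chrom)
})

test_that("counting obeys the threshold and an independent recount", {
  fx <- ohnolog_fixture()
  groups <- extract_ohnolog_groups(fx$orthogroups, fx$map,
                                   fx$ingroup_positions,
                                   fx$outgroup_positions, min_slots = 1)
  expect_equal(count_ohnolog_groups(groups, 3), 1)
  expect_equal(count_ohnolog_groups(groups, 1), 4)
  # independent tally: scan the member table directly
  recount <- sum(tapply(groups$members$slot,
                        paste(groups$members$group_id, groups$members$anchor),
                        function(s) length(unique(s))) >= 3)
  expect_equal(count_ohnolog_groups(groups, 3), recount)
  # monotone non-increasing in min_slots
  counts <- vapply(1:5, count_ohnolog_groups, integer(1), groups = groups)
  expect_true(all(diff(counts) <= 0))
  expect_equal(count_ohnolog_groups(
    extract_ohnolog_groups(fx$orthogroups, fx$map, fx$ingroup_positions,
                           fx$outgroup_positions, min_slots = 5), 1), 0)
})

test_that("lossless extraction reproduces the truth log exactly", {
  sim <- simulate_history(lossless_config(seed = 6, n = 4, g = 25))
  algs <- infer_algs(sim$orthogroups, sim$positions$amphioxus,
                     sim$positions$chicken)
  map <- build_homology_map(algs$profiles)
  groups <- extract_ohnolog_groups(sim$orthogroups, map,
                                   sim$positions$chicken,
                                   assignment = algs$assignment)
  tg <- sim$truth$genes[sim$truth$genes$species == "chicken", ]
  expect_setequal(groups$members$gene_id, tg$gene_id)
  # four slots occupied in every group
  expect_true(all(groups$summary$n_members == 4))
  expect_equal(nrow(groups$summary), 100)
  # subset property: every member is in its source orthogroup
  key_src <- paste(sim$orthogroups$members$group_id,
                   sim$orthogroups$members$gene_id)
  expect_true(all(paste(groups$members$group_id, groups$members$gene_id)
                  %in% key_src))
})

test_that("extraction is idempotent", {
  fx <- ohnolog_fixture()
  g1 <- extract_ohnolog_groups(fx$orthogroups, fx$map, fx$ingroup_positions,
                               fx$outgroup_positions, min_slots = 2)
  # rebuild an orthogroup table from the extracted members + anchors
  members2 <- rbind(
    data.frame(group_id = g1$anchor_genes$group_id, species = "out",
               gene_id = g1$anchor_genes$gene_id),
    data.frame(group_id = g1$members$group_id, species = "in",
               gene_id = g1$members$gene_id))
  og2 <- orthogroup_table(members2, species = c("out", "in"))
  g2 <- extract_ohnolog_groups(og2, fx$map, fx$ingroup_positions,
                               fx$outgroup_positions, min_slots = 2)
  expect_equal(g2$members, g1$members)
  expect_equal(g2$summary, g1$summary)
})

test_that("ohnology transfer follows 1:1 orthologs and target homology", {
  fx <- ohnolog_fixture()
  groups <- extract_ohnolog_groups(fx$orthogroups, fx$map,
                                   fx$ingroup_positions,
                                   fx$outgroup_positions, min_slots = 2)
  # empty pair map -> empty transfer, not an error
  empty <- ortholog_pair_map(data.frame(gene_a = character(),
                                        gene_b = character()), "in", "tgt")
  t0 <- transfer_ohnology(groups, empty, fx$ingroup_positions, fx$map)
  expect_equal(nrow(t0$groups$members), 0)
  expect_length(t0$candidates, 0)

  # identity-like 1:1 pairs onto a target species with the same layout
  src_genes <- fx$ingroup_positions$records$gene_id
  pairs <- ortholog_pair_map(
    data.frame(gene_a = src_genes, gene_b = paste0("t_", src_genes)),
    "in", "tgt")
  tpos <- gene_position_table(
    transform(fx$ingroup_positions$records,
              gene_id = paste0("t_", gene_id)), "tgt")
  tr <- transfer_ohnology(groups, pairs, tpos, fx$map)
  expect_equal(tr$groups$species, "tgt")
  expect_equal(sort(tr$candidates),
               sort(paste0("t_", groups$members$gene_id)))
  expect_equal(tr$groups$summary$n_members, groups$summary$n_members)
})

test_that("transferred slots agree with the second species' truth", {
  sim <- simulate_history(chordate_config(8, retention_prob = 0.9))
  algs <- infer_algs(sim$orthogroups, sim$positions$amphioxus,
                     sim$positions$chicken)
  map <- build_homology_map(algs$profiles)
  groups <- extract_ohnolog_groups(sim$orthogroups, map,
                                   sim$positions$chicken,
                                   assignment = algs$assignment)
  t_algs <- infer_algs(sim$orthogroups, sim$positions$amphioxus,
                       sim$positions$human)
  t_map <- build_homology_map(t_algs$profiles)
  pairs <- orthogroup_pairs(sim$orthogroups, "chicken", "human")
  tr <- transfer_ohnology(groups, pairs, sim$positions$human, t_map)
  tg <- sim$truth$genes[sim$truth$genes$species == "human", ]
  # every transferred gene must genuinely be a retained duplicate: its
  # orthogroup keeps >= 2 human copies
  ncop <- table(tg$orthogroup)
  expect_true(all(ncop[tg$orthogroup[match(tr$candidates, tg$gene_id)]] >= 1))
  got <- merge(tr$groups$members, tg, by = "gene_id")
  # chromosome placement recorded during transfer matches the truth log
  expect_equal(got$chrom.x, got$chrom.y)
})
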