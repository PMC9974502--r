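# hand-made profiles/map: three anchors (units) over ingroup chromosomes
# with chosen counts
counts_fixture <- function(counts) {
  profiles <- karyevo:::new_homology_profiles(counts, "out", "in", "gene",
                                              c(out = 0L, `in` = 0L))
  map <- build_homology_map(profiles, min_placed = 0)
  list(profiles = profiles, map = map)
}

test_that("one-to-one homology yields zero fusion calls", {
  counts <- data.frame(anchor = c("bb1", "bb2"),
                       ingroup_chrom = c("chr1", "chr2"),
                       count = c(50L, 50L))
  fx <- counts_fixture(counts)
  calls <- detect_fused_chromosomes(fx$map, fx$profiles)
  expect_length(calls$fused, 0)
})

test_that("contribution thresholding keeps units above min_fraction", {
  counts <- data.frame(anchor = c("ALG1", "ALG2", "ALG3"),
                       ingroup_chrom = "chr1",
                       count = c(55L, 42L, 3L))
  fx <- counts_fixture(counts)
  calls <- detect_fused_chromosomes(fx$map, fx$profiles, min_fraction = 0.10)
  expect_equal(calls$fused, "chr1")
  expect_setequal(calls$contributions$anchor, c("ALG1", "ALG2"))
  # monotonicity: a higher threshold can only reduce the calls
  for (thr in c(0.2, 0.45, 0.6)) {
    expect_lte(length(detect_fused_chromosomes(fx$map, fx$profiles,
                                               min_fraction = thr)$fused),
               length(calls$fused))
  }
})

test_that("sharing rule: four copies pre-1R, two post-1R, one post-2R", {
  # units u1+u2 co-occur on all four copies; u3+u4 on exactly two; u5 joins
  # u6 on a single copy
  counts <- rbind(
    expand.grid(anchor = c("u1", "u2"),
                ingroup_chrom = c("c1", "c2", "c3", "c4")),
    expand.grid(anchor = c("u3", "u4"),
                ingroup_chrom = c("d1", "d2")),
    data.frame(anchor = c("u3", "u4"), ingroup_chrom = c("d3", "d4")),
    data.frame(anchor = c("u4"), ingroup_chrom = "d5"),
    data.frame(anchor = c("u5", "u6"), ingroup_chrom = "e1"),
    data.frame(anchor = c("u5", "u6", "u5", "u6"),
               ingroup_chrom = c("e2", "e3", "e4", "e5")))
  counts$count <- 100L
  counts$anchor <- as.character(counts$anchor)
  counts$ingroup_chrom <- as.character(counts$ingroup_chrom)
  fx <- counts_fixture(counts)
  calls <- detect_fused_chromosomes(fx$map, fx$profiles)
  ep <- assign_epochs(calls, fx$map)
  expect_equal(unname(ep$epoch_counts), c(1L, 1L, 1L))
  expect_equal(ep$events$units[ep$events$epoch == "pre-1R"], "u1+u2")
  expect_equal(ep$events$units[ep$events$epoch == "post-1R"], "u3+u4")
  expect_equal(ep$events$chromosomes[ep$events$epoch == "post-1R"], "d1+d2")
  expect_equal(ep$events$chromosomes[ep$events$epoch == "post-2R"], "e1")
})

test_that("simulated histories recover every epoch count (p = 1)", {
  for (seed in 4:6) {
    sim <- simulate_history(chordate_config(seed, retention_prob = 1))
    algs <- infer_algs(sim$orthogroups, sim$positions$amphioxus,
                       sim$positions$chicken)
    map <- build_homology_map(algs$profiles)
    ep <- assign_epochs(detect_fused_chromosomes(map, algs$profiles), map)
    expect_equal(unname(ep$epoch_counts), c(6L, 9L, 5L))
    expect_equal(ep$n_pre1r, 17)
    expect_equal(nrow(detect_outgroup_fusions(algs)), 3)
  }
})

test_that("outgroup fusions are located on the right chromosomes", {
  sim <- simulate_history(chordate_config(12, retention_prob = 1))
  algs <- infer_algs(sim$orthogroups, sim$positions$amphioxus,
                     sim$positions$chicken)
  of <- detect_outgroup_fusions(algs)
  am <- sim$truth$genes[sim$truth$genes$species == "amphioxus", ]
  truly_fused <- names(which(tapply(am$anc_chrom, am$chrom,
                                    function(x) length(unique(x))) >= 2))
  expect_setequal(unique(of$outgroup_chrom), truly_fused)
  expect_equal(nrow(of), 3)
  # a fusion-free outgroup yields no calls
  sim0 <- simulate_history(lossless_config(seed = 1))
  algs0 <- infer_algs(sim0$orthogroups, sim0$positions$amphioxus,
                      sim0$positions$chicken)
  expect_equal(nrow(detect_outgroup_fusions(algs0)), 0)
})

test_that("history reconstruction reverses the inferred events", {
  # six stem fusion calls + 17 pre-1R linkage groups -> 23 chordate
  ev <- data.frame(epoch = rep("pre-1R", 6))
  h <- reconstruct_history(ev, pre1r_count = 17)
  expect_equal(unname(node_counts(h)["chordate_ancestor"]), 23)
  # zero calls with two WGDs: ancestor is a quarter of the extant count
  h0 <- reconstruct_history(data.frame(epoch = character()), n_units = 11)
  expect_equal(unname(node_counts(h0)["post_2R"]), 44)
  expect_error(reconstruct_history(ev, pre1r_count = 17, n_units = 23),
               "exactly one")
  expect_error(reconstruct_history(data.frame(epoch = "pre-2R"),
                                   n_units = 5), "unknown epoch")
  expect_error(reconstruct_history(data.frame(epoch = rep("pre-1R", 8)),
                                   n_units = 5))
})

test_that("reconstructed node counts equal the simulation truth", {
  sim <- simulate_history(chordate_config(9, retention_prob = 0.95))
  algs <- infer_algs(sim$orthogroups, sim$positions$amphioxus,
                     sim$positions$chicken)
  map <- build_homology_map(algs$profiles)
  ep <- assign_epochs(detect_fused_chromosomes(map, algs$profiles), map)
  of <- detect_outgroup_fusions(algs)
  events <- rbind(ep$events,
                  data.frame(epoch = of$epoch, units = of$units,
                             chromosomes = of$outgroup_chrom,
                             ambiguous = FALSE))
  h <- reconstruct_history(events, n_units = nrow(algs$algs),
                           outgroup = "amphioxus")
  truth <- sim$truth$node_counts
  expect_equal(unname(node_counts(h)["chordate_ancestor"]),
               unname(truth["chordate_ancestor"]))
  expect_equal(unname(node_counts(h)["amphioxus"]),
               unname(truth["amphioxus"]))
  expect_equal(unname(node_counts(h)["jawed_vertebrate"]),
               unname(truth["ingroup_ancestor"]))
  # the invariant is re-verified by independent arithmetic
  expect_equal(unname(node_counts(h)["post_2R"]),
               2 * (2 * (23 - 6) - 9))
})
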