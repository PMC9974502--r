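test_that("tau matches the worked examples", {
  m <- rbind(constant = c(5, 5, 5),
             specific = c(0, 0, 9),
             graded = c(8, 2, 2))
  expect_equal(unname(tau(m)), c(0, 1, 0.75))
  expect_equal(unname(tau(matrix(c(8, 2, 2), 1))), 0.75)
})

test_that("tau is bounded, scale-invariant and flags all-zero genes", {
  set.seed(42)
  m <- matrix(rexp(200), 20, 10)
  tv <- tau(m)
  expect_true(all(tv >= 0 & tv <= 1))
  expect_equal(tau(m * 7.3), tv)
  m2 <- rbind(m, 0)
  expect_message(tv2 <- tau(m2), "all-zero")
  expect_true(is.na(tv2[nrow(m2)]))
  # log-scale option changes values but not bounds
  tl <- tau(m, log_transform = TRUE)
  expect_true(all(tl >= 0 & tl <= 1))
  expect_error(tau(m[, 1, drop = FALSE]), ">= 2 tissues")
})

# helper: one bin per chromosome, trans contacts given by a symmetric matrix
toy_contacts <- function(trans, chroms = paste0("chr", seq_len(nrow(trans)))) {
  contact_matrix(trans, data.frame(chrom = chroms,
                                   index = seq_along(chroms)))
}

test_that("uniform trans contacts give zero log2 enrichment", {
  k <- 5
  trans <- matrix(10, k, k); diag(trans) <- 0
  pe <- contact_enrichment(toy_contacts(trans))
  expect_equal(pe$log2_ratio, rep(0, choose(k, 2)))
  expect_equal(pe$observed, pe$expected)
})

test_that("a three-chromosome toy matches independent arithmetic", {
  trans <- matrix(0, 3, 3)
  trans[1, 2] <- trans[2, 1] <- 30
  trans[1, 3] <- trans[3, 1] <- 10
  trans[2, 3] <- trans[3, 2] <- 20
  pe <- contact_enrichment(toy_contacts(trans))
  # hand computation: T = (40, 50, 30), raw E ~ T_a*T_b = (2000, 1200, 1500)
  # scaled so sum(E) = 60: (25.53..., 15.31..., 19.14...)
  raw <- c(40 * 50, 40 * 30, 50 * 30)
  expected <- raw * 60 / sum(raw)
  expect_equal(pe$expected, expected)
  expect_equal(pe$log2_ratio, log2(c(30, 10, 20) / expected))
  expect_equal(sum(pe$expected), sum(pe$observed))
})

test_that("enrichment conserves totals and ignores chromosome labels' order", {
  set.seed(7)
  n <- 40
  v <- matrix(runif(n * n), n, n); v <- v + t(v)
  bins <- data.frame(chrom = rep(paste0("chr", 1:8), each = 5), index = 1:n)
  m <- contact_matrix(v, bins)
  pe <- contact_enrichment(m)
  expect_lt(abs(sum(pe$expected) - sum(pe$observed)) / sum(pe$observed),
            1e-6)
  # relabelling chromosomes permutes rows but not values
  bins2 <- bins; bins2$chrom <- sub("chr", "k", bins2$chrom)
  pe2 <- contact_enrichment(contact_matrix(v, bins2))
  expect_equal(pe2$log2_ratio, pe$log2_ratio)
})

test_that("many-chromosome random matrices have near-zero mean enrichment", {
  set.seed(11)
  n <- 200
  v <- matrix(runif(n * n, 0.5, 1.5), n, n); v <- (v + t(v)) / 2
  bins <- data.frame(chrom = rep(paste0("chr", 1:20), each = 10), index = 1:n)
  pe <- contact_enrichment(contact_matrix(v, bins))
  expect_lt(mean(abs(pe$log2_ratio)), 0.05)
})

test_that("pericentromeric bins are excluded from euchromatin statistics", {
  n <- 6
  v <- matrix(1, n, n)
  v[5, ] <- v[, 5] <- 100   # a hot pericentromeric bin on chr3
  bins <- data.frame(chrom = rep(c("chr1", "chr2", "chr3"), each = 2),
                     index = 1:n)
  m <- contact_matrix(v, bins, pericentromeric = c(rep(FALSE, 4), TRUE,
                                                   FALSE))
  with_mask <- contact_enrichment(m, exclude_pch = TRUE)
  without <- contact_enrichment(m, exclude_pch = FALSE)
  # masked observation: chr1-chr2 sums 4 unit cells, the chr3 pairs 2 each;
  # expectation from trans totals (6, 6, 4), rescaled to the observed total
  obs <- c(4, 2, 2)
  expected <- c(36, 24, 24) * sum(obs) / 84
  expect_equal(with_mask$observed, obs)
  expect_equal(with_mask$log2_ratio, log2(obs / expected))
  # the unmasked hot bin inflates every chr3 pair
  expect_gt(without$observed[2], with_mask$observed[2] * 10)
  # a chromosome with zero trans contacts yields undefined pairs
  v0 <- matrix(0, 4, 4); v0[1, 2] <- v0[2, 1] <- 5
  b0 <- data.frame(chrom = c("a", "b", "c", "c"), index = 1:4)
  pe0 <- contact_enrichment(contact_matrix(v0, b0))
  expect_true(all(is.na(pe0$log2_ratio[pe0$chrom_a == "c" |
                                         pe0$chrom_b == "c"])))
})

test_that("sparse contact dumps load with symmetrisation and PCH masking", {
  d <- withr::local_tempdir()
  writeLines(c("chrom\tindex\tstart", "chr1\t1\t0", "chr1\t2\t40000",
               "chr2\t1\t0"), file.path(d, "bins.tsv"))
  writeLines(c("1\t2\t4", "1\t3\t6", "2\t3\t8"), file.path(d, "m.tsv"))
  writeLines("chr1\t0\t20000", file.path(d, "pch.bed"))
  m <- read_contact_matrix(file.path(d, "m.tsv"), file.path(d, "bins.tsv"),
                           pch_bed = file.path(d, "pch.bed"))
  expect_equal(m$values, m$values[c(1, 2, 3), c(1, 2, 3)])
  expect_equal(m$values[2, 1], 4)
  expect_equal(m$pericentromeric, c(TRUE, FALSE, FALSE))
})

test_that("relative ChIP level is the ratio of window means", {
  track <- data.frame(ratio = c(2, 2, 0.5, 0.5),
                      annotation = c("LINE", "LINE", "unique", "unique"))
  expect_equal(relative_chip_level(track, "LINE"), 4)
  same <- data.frame(ratio = rep(1.3, 6),
                     annotation = rep(c("SAT", "unique"), 3))
  expect_equal(relative_chip_level(same, "SAT"), 1)
  # permutation invariance
  set.seed(3)
  shuffled <- track[sample(nrow(track)), ]
  expect_equal(relative_chip_level(shuffled, "LINE"), 4)
  expect_error(relative_chip_level(track, "SINE"), "no windows")
  zero <- data.frame(ratio = c(1, 0), annotation = c("LINE", "unique"))
  expect_error(relative_chip_level(zero, "LINE"), "zero")
})

test_that("amplicon expression is mean count over total length", {
  expect_equal(amplicon_expression(c(10, 20, 30), c(1000, 1000, 1000)),
               20 / 3000)
  expect_equal(amplicon_expression(7, 350), 7 / 350)
  expect_equal(amplicon_expression(c(0, 0), c(100, 200)), 0)
  expect_error(amplicon_expression(numeric(), numeric()), "no copies")
  expect_error(amplicon_expression(5, 0), "> 0")
})
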