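test_that("EHH equals the identical-pair fraction on constructed patterns", {
  # all haplotypes identical over the span
  hm1 <- hap_matrix("1", c(0, 10, 20), matrix(1L, 4, 3), rep("p", 4))
  expect_equal(ehh(hm1, 1, 3), 1)
  # 4 haplotypes with span patterns {A, A, B, C}: one identical pair of 6
  A <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(0L, 1L))
  hm2 <- hap_matrix("1", c(0, 10), A, rep("p", 4))
  expect_equal(ehh(hm2, 1, 2), 1 / 6)
  # pairwise distinct over the span
  A3 <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  hm3 <- hap_matrix("1", c(0, 10), A3, rep("p", 4))
  expect_equal(ehh(hm3, 1, 2), 0)
  expect_error(ehh(hap_matrix("1", 0, matrix(0L, 1, 1), "p"), 1, 1),
               "fewer than 2")
})

test_that("EHH matches the brute-force oracle and never grows with the span", {
  for (r in 1:30) {
    set.seed(r)
    n <- sample(3:12, 1)
    m <- sample(4:20, 1)
    hm <- rand_hm(n_hap = 2 * ceiling(n / 2), n_site = m, seed = r)
    core <- sample(seq_len(m), 1)
    vals <- vapply(seq_len(m), function(tg) ehh(hm, core, tg), 0)
    for (tg in sample(seq_len(m), min(5, m))) {
      expect_identical(vals[tg], bf_ehh(hm$alleles, core, tg))
    }
    # widening the span can only split identity groups
    expect_true(all(diff(vals[core:m]) <= 1e-15))
    expect_true(all(diff(rev(vals[1:core])) <= 1e-15))
  }
})

test_that("iHH closed forms: monomorphic span and truncation at the core", {
  pos <- seq(0, 10000, by = 1000)
  mono <- hap_matrix("1", pos, matrix(0L, 6, length(pos)), rep("p", 6))
  res <- ihh(mono, mono, core = which(pos == 5000))
  expect_equal(res$ihh, 10000)
  expect_true(res$edge_flag)

  # balanced alleles at the core give homozygosity 1/3 < cutoff 0.6:
  # the integration span collapses to the core point
  A <- matrix(c(0L, 0L, 1L, 1L), 4, 5)
  hmb <- hap_matrix("1", c(0, 100, 200, 300, 400), A, rep("p", 4))
  res0 <- ihh(hmb, hmb, core = 3, cutoff = 0.6)
  expect_equal(res0$ihh, 0)
})

test_that("iHH agrees with the brute-force prefix-grouping oracle", {
  for (r in 1:20) {
    set.seed(100 + r)
    hm <- rand_hm(n_hap = 6, n_site = 5, seed = 100 + r, span = 700)
    cutoff <- sample(c(0.05, 0.2, 0.4), 1)
    core <- sample(1:5, 1)
    pop <- subset_haps_for_test(hm, hm$hap_pop == "focal")
    got <- ihh(pop, hm, core, cutoff = cutoff)
    want <- bf_ihh(pop$alleles, hm$alleles, hm$positions, core,
                   cutoff = cutoff)
    expect_equal(got$ihh, want$ihh, tolerance = 1e-9)
  }
})

test_that("the scan's integrals match the exported iHH site by site", {
  hm <- rand_hm(n_hap = 12, n_site = 25, seed = 77, span = 5e4)
  sc <- xpehh_scan(hm)
  foc <- subset_haps_for_test(hm, hm$hap_pop == "focal")
  ref <- subset_haps_for_test(hm, hm$hap_pop == "reference")
  for (core in seq_along(hm$positions)) {
    expect_equal(sc$ihh_focal[core], ihh(foc, hm, core)$ihh,
                 tolerance = 1e-9)
    expect_equal(sc$ihh_ref[core], ihh(ref, hm, core)$ihh,
                 tolerance = 1e-9)
  }
})

test_that("XP-EHH is antisymmetric and standardised to mean 0 / sd 1", {
  sim <- simulate_two_pop_sweep(n_dip = 30, t_gen = 25, s = 0.2,
                                chrom_len = 2e5, n_sites = 250, seed = 21)
  sc <- xpehh_scan(sim$hm, focal = "focal")
  sw <- xpehh_scan(sim$hm, focal = "reference")
  ok <- is.finite(sc$xpehh_raw)
  expect_identical(ok, is.finite(sw$xpehh_raw))
  expect_equal(sw$xpehh_raw[ok], -sc$xpehh_raw[ok], tolerance = 1e-12)
  expect_lt(abs(mean(sc$xpehh_z[ok])), 1e-10)
  expect_lt(abs(stats::sd(sc$xpehh_z[ok]) - 1), 1e-10)
})

test_that("identical populations give a raw log-ratio of zero everywhere", {
  set.seed(31)
  half <- matrix(sample(0:1, 6 * 12, replace = TRUE), 6, 12)
  hm <- hap_matrix("1", sort(sample.int(2e4, 12)) - 1, rbind(half, half),
                   rep(c("focal", "reference"), each = 6))
  sc <- xpehh_scan(hm)
  ok <- is.finite(sc$xpehh_raw)
  expect_true(all(sc$xpehh_raw[ok] == 0))
})

test_that("standardisation fails loudly with fewer than two defined scores", {
  hm <- hap_matrix("1", c(0, 5000), matrix(c(0L, 1L, 0L, 1L,
                                             0L, 1L, 0L, 1L), 4, 2),
                   rep(c("focal", "reference"), each = 2))
  # with 2 haplotypes per population and balanced alleles, pooled EHH at
  # the core is below no cutoff here, but single-site spans integrate to 0
  expect_error(xpehh_scan(hm), "fewer than 2 defined")
})
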