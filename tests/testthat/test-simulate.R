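test_that("the sweep simulator is deterministic and conserves its bookkeeping", {
  a <- simulate_two_pop_sweep(n_dip = 20, t_gen = 15, s = 0.2,
                              chrom_len = 1e5, n_sites = 60, seed = 9)
  b <- simulate_two_pop_sweep(n_dip = 20, t_gen = 15, s = 0.2,
                              chrom_len = 1e5, n_sites = 60, seed = 9)
  expect_identical(a$hm$alleles, b$hm$alleles)
  expect_identical(a$truth, b$truth)
  # 2 x 2N haplotype rows, labelled focal first
  expect_equal(nrow(a$hm$alleles), 80L)
  expect_equal(a$hm$hap_pop, rep(c("focal", "reference"), each = 40))
  # retained sites are polymorphic in the pooled sample
  f <- colMeans(a$hm$alleles)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(a$hm$positions) > 0))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simulate_two_pop_sweep(n_dip = 5), "n_dip")
  expect_error(simulate_two_pop_sweep(n_dip = 20, s = 1.5), "s must")
  expect_error(simulate_two_pop_sweep(n_dip = 20, sweep_pos = 1e9), "sweep_pos")
})

test_that("neutral heterozygosity decays like (1 - 1/2N)^T", {
  n_dip <- 50
  t_gen <- 30
  ratios <- vapply(1:20, function(r) {
    sim <- simulate_two_pop_sweep(n_dip = n_dip, t_gen = t_gen, s = 0,
                                  chrom_len = 1e5, n_sites = 300,
                                  r_bp = 0, seed = 1000 + r)
    sim$truth$het_ref / sim$truth$het0
  }, 0)
  expected <- (1 - 1 / (2 * n_dip))^t_gen
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected), 4 * se + 0.01)
})

test_that("directional selection drives the focal allele above its reference frequency", {
  wins <- vapply(1:10, function(r) {
    sim <- simulate_two_pop_sweep(n_dip = 60, t_gen = 60, s = 0.2,
                                  chrom_len = 2.5e5, n_sites = 300,
                                  seed = 2000 + r)
    sim$truth$freq_focal > sim$truth$freq_ref
  }, TRUE)
  expect_gte(sum(wins), 8)
})

test_that("neutral runs are exchangeable between population labels", {
  # sign test over replicates on the difference in significant-window
  # counts when the focal/reference roles are swapped
  diffs <- vapply(1:12, function(r) {
    sim <- simulate_two_pop_sweep(n_dip = 25, t_gen = 20, s = 0,
                                  chrom_len = 2.5e5, n_sites = 250,
                                  seed = 3000 + r)
    count_sig <- function(focal) {
      sc <- xpehh_scan(sim$hm, focal = focal)
      w <- empirical_pvalues(bin_by_snp_count(make_windows(sc)))
      sum(select_significant(w, "xpehh")$significant)
    }
    count_sig("focal") - count_sig("reference")
  }, 0)
  nz <- diffs[diffs != 0]
  if (length(nz)) {
    bt <- stats::binom.test(sum(nz > 0), length(nz))
    expect_gt(bt$p.value, 0.01)
  } else {
    expect_equal(sum(diffs), 0)
  }
})

test_that("categorical gene-site generator honours its null and its skew", {
  m0 <- simulate_gene_sites(n_sites = 20, seed = 4)
  expect_equal(nrow(m0$truth), 0L)
  expect_equal(dim(m0$calls), c(60L, 20L))
  expect_equal(m0$breed, rep(c("breedA", "breedB", "breedC"), each = 20))

  # near-infinite odds fix the focal breed for the focal category
  m1 <- simulate_gene_sites(n_sites = 5, n_hap = 30,
                            enriched_sites = list(list(site = 2,
                                                       breed = "breedB",
                                                       category = "cat1",
                                                       odds = 1e12)),
                            seed = 5)
  expect_true(all(m1$calls[m1$breed == "breedB", 2] == "cat1"))

  expect_error(simulate_gene_sites(n_sites = 5,
                                   enriched_sites = list(list(site = 9,
                                                              breed = "breedA",
                                                              category = "cat1",
                                                              odds = 2))),
               "out of range")
  expect_error(simulate_gene_sites(n_sites = 5,
                                   enriched_sites = list(list(site = 1,
                                                              breed = "breedA",
                                                              category = "cat1",
                                                              odds = 0.5))),
               "odds > 1")
})

test_that("site matrices round-trip through their TSV form", {
  m <- simulate_gene_sites(n_sites = 8, n_hap = 5, seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_site_matrix(m, path)
  back <- read_site_matrix(path, gene_id = m$gene_id)
  expect_equal(unname(back$calls), unname(m$calls))
  expect_equal(back$breed, m$breed)
})
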