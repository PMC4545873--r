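test_that("test enumeration counts follow the 3*k*n and 3*2*n designs", {
  # force exactly two observed categories everywhere
  m <- simulate_gene_sites(n_sites = 100, k_categories = 2, n_hap = 30,
                           seed = 11)
  stopifnot(all(apply(m$calls, 2, function(x) length(unique(x))) == 2))
  expect_equal(nrow(enumerate_tests(m, "aa")), 600L)

  mi <- simulate_gene_sites(n_sites = 50, k_categories = 2,
                            categories = c("Y", "N"), seed = 12)
  expect_equal(nrow(enumerate_tests(mi, "indel")), 300L)
  # a requested breed missing from the data is an error naming it
  expect_error(enumerate_tests(m, "aa", breeds = c("breedA", "breedZ")),
               "breedZ")
  # aa mode: per-site test count is 3 * categories observed at that site
  m3 <- simulate_gene_sites(n_sites = 40, k_categories = 4, seed = 13)
  k_site <- apply(m3$calls, 2, function(x) length(unique(x)))
  expect_equal(nrow(enumerate_tests(m3, "aa")), sum(3L * k_site))
})

test_that("one-sided Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_one_sided(0, 5, 7, 3), 1)
  expect_equal(fisher_one_sided(10, 0, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(14)
  for (r in 1:60) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    c <- sample(0:25, 1); d <- sample(0:25, 1)
    if (a + b + c + d == 0) next
    expect_equal(fisher_one_sided(a, b, c, d), bf_fisher(a, b, c, d),
                 tolerance = 1e-12)
  }
  # monotone: moving mass onto the diagonal can only shrink the tail p
  for (r in 1:20) {
    set.seed(200 + r)
    a <- sample(1:10, 1); b <- sample(1:10, 1)
    c <- sample(1:10, 1); d <- sample(1:10, 1)
    expect_lte(fisher_one_sided(a + 1, b - 1, c - 1, d + 1) -
                 fisher_one_sided(a, b, c, d), 1e-12)
  }
})

test_that("Bonferroni correction caps, flags, and reports cutoffs", {
  rec <- data.frame(gene_id = "g1", site = 1:3, breed = "breedA",
                    category = "cat1", p_raw = c(1e-6, 0.01, 1))
  out <- bonferroni(rec, alpha = 0.05)
  expect_equal(unique(out$m_tests), 3)
  expect_equal(out$p_bonf, pmin(1, 3 * rec$p_raw))
  expect_equal(out$significant, rec$p_raw < 0.05 / 3)
  cuts <- attr(out, "cutoffs")
  expect_equal(cuts$bonferroni_cutoff, 0.05 / 3)
  # the 600-test family cutoff quoted for a typical gene
  rec600 <- data.frame(gene_id = "g", site = 1:600, breed = "b",
                       category = "c", p_raw = runif(600))
  expect_equal(attr(bonferroni(rec600), "cutoffs")$bonferroni_cutoff,
               0.05 / 600, tolerance = 1e-12)
})

test_that("full enrichment records carry consistent 2x2 tables", {
  m <- simulate_gene_sites(n_sites = 30, n_hap = 15, seed = 15)
  e <- enrich_sites(m, mode = "aa")
  expect_s3_class(e, "site_enrichment")
  # margins: a+b is always the focal breed's haplotype count
  expect_true(all(e$a + e$b == 15))
  expect_true(all(e$a + e$b + e$c + e$d == 45))
  expect_true(all(e$p_raw > 0 & e$p_raw <= 1))
  expect_equal(nrow(e), unique(e$m_tests))
  # a site with one observed category yields degenerate p = 1 tests
  m$calls[, 1] <- "cat1"
  e1 <- enrich_sites(m, mode = "aa")
  expect_true(all(e1$p_raw[e1$site == 1] == 1))
})

test_that("null categorical data keeps the type-I rate at or below nominal", {
  m <- simulate_gene_sites(n_sites = 200, seed = 16)
  e <- enrich_sites(m, mode = "aa")
  n <- nrow(e)
  expect_gt(n, 1500)
  margin <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_lte(mean(e$p_raw <= 0.05), 0.05 + margin)
})

test_that("profile tables order sites and expose both cutoff lines", {
  m <- simulate_gene_sites(n_sites = 12, seed = 17,
                           enriched_sites = list(list(site = 5,
                                                      breed = "breedC",
                                                      category = "cat3",
                                                      odds = 60)))
  e <- enrich_sites(m, mode = "aa")
  pt <- profile_table(e)
  expect_true(!is.unsorted(pt$site))
  expect_equal(pt$neg_log10_p, -log10(pt$p_raw))
  expect_equal(attr(pt, "nominal_alpha"), 0.05)
  expect_equal(attr(pt, "bonferroni_cutoff"), 0.05 / nrow(e))
  # a p of 0.001 maps to height 3
  expect_equal(-log10(0.001), 3)
  # indel-style labels flow through untouched
  mi <- simulate_gene_sites(n_sites = 6, k_categories = 2,
                            categories = c("Y", "N"), seed = 18)
  ei <- enrich_sites(mi, mode = "indel")
  expect_setequal(unique(ei$category), c("Y", "N"))
})
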