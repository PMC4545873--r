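make_ft <- function(pos, p_ref, k, n, chrom = "1") {
  ft <- data.frame(chrom = chrom, pos = pos, p_ref = p_ref, k_focal = k,
                   n_focal = n, stringsAsFactors = FALSE)
  class(ft) <- c("freq_table", "data.frame")
  ft
}

test_that("drift-variance estimator: exact zeros, single-site arithmetic, recovery", {
  # focal frequency identical to reference at every site -> omega = 0
  p <- rep(seq(0.1, 0.9, by = 0.2), 30)
  ft0 <- make_ft(seq_along(p) * 100, p, round(p * 20), 20)
  expect_equal(estimate_omega(make_ft(seq_along(p) * 100, p, p * 20, 20)), 0)
  # one eligible site, p_ref 0.5, focal 0.6: (0.1)^2 / 0.25 = 0.04
  ft1 <- make_ft(100, 0.5, 12, 20)
  expect_equal(estimate_omega(ft1, min_sites = 1), 0.04)
  expect_error(estimate_omega(ft1), "only 1 sites")
  # parameter recovery at deep sampling (the 1/n sampling term is ~0.001)
  s1 <- simulate_freq_table(n_sites = 5000, omega = 0.05, n_focal = 1000,
                            seed = 5)
  expect_lt(abs(estimate_omega(s1$ft) - 0.05), 0.01)
})

test_that("escape probability obeys its closed form and limits", {
  expect_equal(escape_probability(0, 0.1, 1e-8, 500), 0)
  expect_equal(escape_probability(1e12, 0.1, 1e-8, 500), 1)
  d <- c(1e4, 1e5, 1e6)
  s <- 0.1
  want <- 1 - exp(-1e-8 * d * log(2 * 500 * s) / s)
  expect_equal(escape_probability(d, s, 1e-8, 500), want, tolerance = 1e-12)
  expect_error(escape_probability(1e5, 0.0005, 1e-8, 500), "2\\*N\\*s")
  # the composite behaviour in s: c follows r*d*log(2Ns)/s directly
  for (s in c(0.01, 0.05, 0.2, 0.5)) {
    expect_equal(escape_probability(5e5, s, 1e-8, 500),
                 1 - exp(-1e-8 * 5e5 * log(1000 * s) / s),
                 tolerance = 1e-12)
  }
})

test_that("site log-likelihood degenerates correctly", {
  # c = 1: hitchhiking transform is the identity
  ln <- site_loglik(0.4, 7, 20, omega = 0.08, model = "neutral")
  ls <- site_loglik(0.4, 7, 20, omega = 0.08, model = "sweep", c_esc = 1)
  expect_equal(ls, ln, tolerance = 1e-12)
  # omega -> 0: the drift law collapses onto p_ref
  l0 <- site_loglik(0.5, 5, 10, omega = 1e-8, model = "neutral")
  expect_equal(l0, stats::dbinom(5, 10, 0.5, log = TRUE), tolerance = 1e-3)
})

test_that("site log-likelihood matches a Monte-Carlo integration oracle", {
  set.seed(42)
  for (r in 1:12) {
    p_ref <- runif(1, 0.05, 0.95)
    n <- sample(10:40, 1)
    k <- sample(0:n, 1)
    omega <- runif(1, 0.02, 0.3)
    c_esc <- runif(1)
    mc <- mc_site_lik(p_ref, k, n, omega, c_esc, n_draws = 2e5, seed = r)
    got <- exp(site_loglik(p_ref, k, n, omega, "sweep", c_esc))
    expect_lt(abs(got - mc$mean), 3 * mc$se + 1e-12)
  }
})

test_that("composite-likelihood scan is non-negative, local, and recovers a sweep", {
  s0 <- simulate_freq_table(n_sites = 400, chrom_len = 2e5, omega = 0.05,
                            seed = 9)
  cs <- clr_scan(s0$ft, omega = 0.05, grid_spacing = 5000)
  ok <- !is.na(cs$clr)
  expect_true(all(cs$clr[ok] >= 0))
  expect_true(all(cs$s_hat[ok] %in%
                    exp(seq(log(1e-4), log(0.5), length.out = 10))))
  # a fraction of neutral grid points sit exactly on the clr = 0 floor
  expect_gt(mean(cs$clr[ok] == 0), 0.2)

  # locality: perturbing one site only moves clr at grid points within
  # the window radius of it
  ft2 <- s0$ft
  i <- which.min(abs(ft2$pos - 1e5))
  ft2$k_focal[i] <- ft2$n_focal[i] - ft2$k_focal[i]
  cs2 <- clr_scan(ft2, omega = 0.05, grid_spacing = 5000)
  far <- abs(cs$pos - ft2$pos[i]) > 12500
  expect_equal(cs$clr[far], cs2$clr[far])

  # localisation on data simulated under the sweep transform
  hits <- vapply(1:5, function(r) {
    sw <- simulate_freq_table(n_sites = 1000, chrom_len = 1e6,
                              omega = 0.05, sweep_pos = 5e5, s = 0.05,
                              r_bp = 1e-7, seed = 600 + r)
    cc <- clr_scan(sw$ft, omega = 0.05, r_bp = 1e-7)
    abs(cc$pos[which.max(cc$clr)] - 5e5) <= 25000
  }, TRUE)
  expect_gte(sum(hits), 4)
})

test_that("frequency tables built from haplotypes carry exact counts", {
  hm <- rand_hm(n_hap = 10, n_site = 12, seed = 3)
  ft <- freq_table(hm, focal = "focal")
  foc <- hm$alleles[hm$hap_pop == "focal", ]
  ref <- hm$alleles[hm$hap_pop == "reference", ]
  expect_equal(ft$k_focal, unname(colSums(foc)))
  expect_equal(ft$n_focal, rep(5L, 12))
  expect_equal(ft$p_ref, unname(colMeans(ref)))
})
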