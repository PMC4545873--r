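# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (pair enumeration, full re-grouping per span, direct
# combinatorial sums) so they share no code path with the implementation.

# identical-pair fraction over the inclusive span [core..target]
bf_ehh <- function(A, core, target) {
  span <- seq(min(core, target), max(core, target))
  n <- nrow(A)
  id <- 0
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + 1
      if (all(A[i, span] == A[j, span])) id <- id + 1
    }
  }
  id / tot
}

bf_trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# iHH oracle: re-derives every span grouping from scratch; truncation by
# pooled EHH < cutoff, data edges and max_gap; trapezoid integration of the
# population's EHH over the retained span, both directions.
bf_ihh <- function(A_pop, A_pool, positions, core, cutoff = 0.05,
                   max_gap = 2e5) {
  if (bf_ehh(A_pool, core, core) < cutoff)
    return(list(ihh = 0, edge_flag = FALSE))
  val <- 0
  edge <- FALSE
  for (dir in c(-1L, 1L)) {
    keep_pos <- positions[core]
    keep_e <- bf_ehh(A_pop, core, core)
    j <- core
    repeat {
      nxt <- j + dir
      if (nxt < 1L || nxt > ncol(A_pool)) { edge <- TRUE; break }
      if (abs(positions[nxt] - positions[j]) > max_gap) { edge <- TRUE; break }
      if (bf_ehh(A_pool, core, nxt) < cutoff) break
      j <- nxt
      keep_pos <- c(keep_pos, positions[j])
      keep_e <- c(keep_e, bf_ehh(A_pop, core, j))
    }
    o <- order(keep_pos)
    val <- val + bf_trapz(keep_pos[o], keep_e[o])
  }
  list(ihh = val, edge_flag = edge)
}

# one-sided upper-tail Fisher p by direct combinatorial enumeration
bf_fisher <- function(a, b, c, d) {
  k <- a + b
  K <- a + c
  n <- a + b + c + d
  xs <- max(0, k - (n - K)):min(k, K)
  mass <- exp(lchoose(K, xs) + lchoose(n - K, k - xs) - lchoose(n, k))
  sum(mass[xs >= a])
}

# Monte-Carlo estimate of the binomial-against-drift-law integral; the
# boundary point masses arise from clamping the Normal draws
mc_site_lik <- function(p_ref, k, n, omega, c_esc = NULL, n_draws = 1e5,
                        seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(n_draws, p_ref, sqrt(omega * p_ref * (1 - p_ref)))
  q <- pmin(1, pmax(0, q))
  if (!is.null(c_esc)) {
    hitch <- stats::runif(n_draws) < q
    q <- ifelse(hitch, 1 - c_esc + c_esc * q, c_esc * q)
  }
  li <- stats::dbinom(k, n, q)
  list(mean = mean(li), se = stats::sd(li) / sqrt(n_draws))
}

# random small two-population hap_matrix
rand_hm <- function(n_hap = 8, n_site = 10, seed = 1, span = 1e4) {
  set.seed(seed)
  pos <- sort(sample.int(span, n_site)) - 1
  A <- matrix(sample(0:1, n_hap * n_site, replace = TRUE), n_hap, n_site)
  hap_matrix("1", pos, A,
             rep(c("focal", "reference"), each = n_hap / 2))
}

write_tmp_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile(fileext = ".vcf", tmpdir = dir)
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(pos, gts, alt = "T") {
  paste(c("1", pos, ".", "A", alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

subset_haps_for_test <- function(hm, rows) {
  hap_matrix(hm$chrom, hm$positions, hm$alleles[rows, , drop = FALSE],
             hm$hap_pop[rows])
}
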