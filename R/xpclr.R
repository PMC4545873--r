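#' Per-site allele frequencies for the composite-likelihood scan
#'
#' Summarises a two-population [hap_matrix] into the frequency table the
#' composite-likelihood sweep scan consumes: the reference population's
#' alternate-allele frequency and the focal population's alternate-allele
#' count and chromosome count at each site.
#'
#' @param hm A [hap_matrix] with exactly two population labels.
#' @param focal Focal population label.
#' @return A data frame of class `freq_table`: `chrom`, `pos`, `p_ref`,
#'   `k_focal`, `n_focal`.
#' @export
freq_table <- function(hm, focal = "focal") {
  labs <- unique(hm$hap_pop)
  if (length(labs) != 2L) stop("freq_table needs exactly two populations")
  if (!focal %in% labs) stop(sprintf("focal label '%s' not present", focal))
  rows_f <- which(hm$hap_pop == focal)
  rows_r <- which(hm$hap_pop != focal)
  out <- data.frame(chrom = hm$chrom, pos = hm$positions,
                    p_ref = colMeans(hm$alleles[rows_r, , drop = FALSE]),
                    k_focal = colSums(hm$alleles[rows_f, , drop = FALSE]),
                    n_focal = length(rows_f), stringsAsFactors = FALSE)
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Method-of-moments estimate of the drift variance
#'
#' Under a Brownian approximation to post-split drift, the focal
#' population's frequency at a site with reference frequency `p` has
#' variance `omega * p * (1 - p)`. The scale `omega` is estimated
#' genome-wide as the mean of `(p_hat_focal - p_ref)^2 / (p_ref (1 -
#' p_ref))` over sites with intermediate reference frequency.
#'
#' @param ft A [freq_table].
#' @param bounds Reference-frequency eligibility bounds (exclusive),
#'   default `c(0.05, 0.95)`.
#' @param min_sites Minimum number of eligible sites, default 100.
#' @return The scalar estimate of `omega`.
#' @export
estimate_omega <- function(ft, bounds = c(0.05, 0.95), min_sites = 100) {
  ok <- ft$p_ref > bounds[1] & ft$p_ref < bounds[2]
  if (sum(ok) < min_sites)
    stop(sprintf("only %d sites with %g < p_ref < %g (need >= %d)",
                 sum(ok), bounds[1], bounds[2], min_sites))
  p <- ft$p_ref[ok]
  q <- ft$k_focal[ok] / ft$n_focal[ok]
  mean((q - p)^2 / (p * (1 - p)))
}

#' Hitchhiking escape probability
#'
#' Probability that a neutral lineage at physical distance `d` from a
#' selected site recombines off the sweeping haplotype during the sweep:
#' `c = 1 - exp(-r_bp * d * t_s)` with sweep duration
#' `t_s = log(2 N s) / s` generations. `c = 0` means complete hitchhiking
#' (at the sweep site), `c -> 1` an effectively unlinked site.
#'
#' @param distance Physical distance(s) in bp (vectorised).
#' @param s Selection coefficient (> 0).
#' @param r_bp Per-bp per-generation recombination probability.
#' @param n_eff Diploid effective population size.
#' @return Escape probabilities clamped to `[0, 1]`.
#' @examples
#' escape_probability(1e6, s = 0.1, r_bp = 1e-8, n_eff = 500)
#' @export
escape_probability <- function(distance, s, r_bp, n_eff) {
  if (s <= 0) stop("escape_probability requires s > 0")
  if (2 * n_eff * s <= 1)
    stop("2*N*s <= 1: sweep model inapplicable at this selection coefficient")
  t_s <- log(2 * n_eff * s) / s
  pmin(1, pmax(0, 1 - exp(-r_bp * abs(distance) * t_s)))
}

# Quadrature representation of the post-drift frequency law: Normal(p_ref,
# omega * p_ref (1-p_ref)) on (0,1) with the spill-over mass below 0 /
# above 1 as point masses at the boundaries. Degenerate (sd = 0) laws
# collapse to a point mass at p_ref.
drift_quadrature <- function(p_ref, omega, n_quad = 512) {
  sd <- sqrt(omega * p_ref * (1 - p_ref))
  if (sd == 0) {
    # degenerate only at p_ref 0 or 1: all mass on the matching boundary
    q <- (seq_len(n_quad) - 0.5) / n_quad
    return(list(q = q, w = numeric(n_quad), m0 = as.numeric(p_ref == 0),
                m1 = as.numeric(p_ref == 1)))
  }
  # exact Gaussian mass per grid cell, evaluated at cell midpoints: the
  # weights and boundary masses then sum to 1 to machine precision
  cdf <- stats::pnorm(seq(0, 1, length.out = n_quad + 1), p_ref, sd)
  q <- (seq_len(n_quad) - 0.5) / n_quad
  w <- diff(cdf)
  m0 <- cdf[1]
  m1 <- 1 - cdf[n_quad + 1]
  tot <- sum(w) + m0 + m1
  if (abs(tot - 1) > 1e-6)
    stop(sprintf(paste0("quadrature weights sum to %.8f (drift sd %.2e too ",
                        "narrow for %d grid points)"), tot, sd, n_quad))
  list(q = q, w = w, m0 = m0, m1 = m1)
}

#' Per-site log-likelihood under the neutral and sweep models
#'
#' Neutral model: the focal population's pre-sampling frequency `q` follows
#' the drift law Normal(`p_ref`, `omega * p_ref (1 - p_ref)`), truncated to
#' (0, 1) with boundary point masses; the observed count is binomial given
#' `q`, and the likelihood is the binomial integrated against the drift law
#' by fixed-grid quadrature. Sweep model: `q` is first drawn from the
#' neutral law, then distorted by hitchhiking with escape probability `c` —
#' with probability `q` it becomes `1 - c + c q`, with probability `1 - q`
#' it becomes `c q` — and the binomial is integrated against this
#' two-branch mixture. At `c = 1` the transform is the identity and the two
#' models coincide.
#'
#' @param p_ref Reference-population frequency at the site.
#' @param k_focal,n_focal Focal alternate-allele count and chromosome count.
#' @param omega Drift variance scale (> 0).
#' @param model `"neutral"` or `"sweep"`.
#' @param c_esc Escape probability (required for the sweep model).
#' @param n_quad Interior quadrature points, default 512.
#' @return The log-likelihood.
#' @export
site_loglik <- function(p_ref, k_focal, n_focal, omega,
                        model = c("neutral", "sweep"), c_esc = NULL,
                        n_quad = 512) {
  model <- match.arg(model)
  if (omega <= 0) stop("omega must be > 0")
  qd <- drift_quadrature(p_ref, omega, n_quad)
  if (model == "neutral") {
    lik <- sum(qd$w * stats::dbinom(k_focal, n_focal, qd$q)) +
      qd$m0 * (k_focal == 0) + qd$m1 * (k_focal == n_focal)
  } else {
    if (is.null(c_esc)) stop("sweep model needs c_esc")
    lik <- sum(qd$w * (qd$q * stats::dbinom(k_focal, n_focal,
                                            1 - c_esc + c_esc * qd$q) +
                         (1 - qd$q) * stats::dbinom(k_focal, n_focal,
                                                    c_esc * qd$q))) +
      qd$m0 * (k_focal == 0) + qd$m1 * (k_focal == n_focal)
  }
  log(lik)
}

#' Composite-likelihood sweep scan
#'
#' Slides a grid of putative sweep positions along the chromosome. At each
#' grid point the sites within `window_radius` contribute
#' [site_loglik] terms: the neutral composite log-likelihood, and for each
#' selection coefficient in `s_grid` a sweep composite log-likelihood with
#' per-site escape probabilities computed from each site's distance to the
#' grid point. The score is `clr = 2 (max_s l_sweep - l_neutral)`, floored
#' at 0; `s_hat` is the maximising coefficient (ties resolved toward the
#' smaller, more conservative value). Grid values with `2 N s <= 1` are
#' skipped.
#'
#' @param ft A [freq_table].
#' @param omega Drift variance (e.g. from [estimate_omega]).
#' @param grid_spacing Grid step in bp, default 2500.
#' @param window_radius Half-width of the contributing-site window in bp,
#'   default 12500.
#' @param s_grid Selection-coefficient grid, default 10 geometric values in
#'   `[1e-4, 0.5]`.
#' @param r_bp Per-bp recombination probability, default 1e-8.
#' @param n_eff Diploid effective population size, default 500.
#' @param n_quad Interior quadrature points per site likelihood.
#' @return A data frame of class `clr_scores`: `chrom`, `pos` (grid
#'   position), `clr`, `s_hat`, `n_sites`. Grid points with no contributing
#'   sites carry `clr = NA`.
#' @export
clr_scan <- function(ft, omega, grid_spacing = 2500, window_radius = 12500,
                     s_grid = exp(seq(log(1e-4), log(0.5), length.out = 10)),
                     r_bp = 1e-8, n_eff = 500, n_quad = 512) {
  if (omega <= 0) stop("omega must be > 0")
  s_grid <- sort(s_grid)
  s_use <- s_grid[2 * n_eff * s_grid > 1]
  if (!length(s_use))
    stop("no usable selection coefficients: 2*N*s <= 1 across the grid")
  grid <- seq(0, max(ft$pos), by = grid_spacing)

  # the pure-drift law is degenerate at p_ref 0/1 and assigns zero
  # likelihood to any focal polymorphism there; such sites carry no
  # contrast and are excluded from the composite likelihood
  ft <- ft[ft$p_ref > 0 & ft$p_ref < 1, , drop = FALSE]

  # neutral per-site terms are grid-independent: compute once
  neut <- vapply(seq_len(nrow(ft)), function(i)
    site_loglik(ft$p_ref[i], ft$k_focal[i], ft$n_focal[i], omega,
                "neutral", n_quad = n_quad), 0)
  qpts <- (seq_len(n_quad) - 0.5) / n_quad
  W <- vapply(seq_len(nrow(ft)), function(i)
    drift_quadrature(ft$p_ref[i], omega, n_quad)$w, numeric(n_quad))
  sdv <- sqrt(omega * ft$p_ref * (1 - ft$p_ref))
  mass0 <- stats::pnorm(0, ft$p_ref, sdv)
  mass1 <- stats::pnorm(1, ft$p_ref, sdv, lower.tail = FALSE)

  clr <- s_hat <- rep(NA_real_, length(grid))
  n_sites <- integer(length(grid))
  for (gi in seq_along(grid)) {
    g <- grid[gi]
    idx <- which(ft$pos >= g - window_radius & ft$pos <= g + window_radius)
    n_sites[gi] <- length(idx)
    if (!length(idx)) next
    l0 <- sum(neut[idx])
    k <- rep(ft$k_focal[idx], each = n_quad)
    n <- rep(ft$n_focal[idx], each = n_quad)
    q <- rep(qpts, times = length(idx))
    wv <- as.vector(W[, idx, drop = FALSE])
    bound <- mass0[idx] * (ft$k_focal[idx] == 0) +
      mass1[idx] * (ft$k_focal[idx] == ft$n_focal[idx])
    best <- -Inf
    best_s <- NA_real_
    for (s in s_use) {
      ce <- escape_probability(abs(ft$pos[idx] - g), s, r_bp, n_eff)
      cc <- rep(ce, each = n_quad)
      mix <- q * stats::dbinom(k, n, 1 - cc + cc * q) +
        (1 - q) * stats::dbinom(k, n, cc * q)
      lik <- colSums(matrix(wv * mix, n_quad)) + bound
      l1 <- sum(log(lik))
      if (l1 > best) { best <- l1; best_s <- s }  # first max = smallest s
    }
    clr[gi] <- max(0, 2 * (best - l0))
    s_hat[gi] <- best_s
  }
  out <- data.frame(chrom = ft$chrom[1], pos = grid, clr = clr,
                    s_hat = s_hat, n_sites = n_sites,
                    stringsAsFactors = FALSE)
  class(out) <- c("clr_scores", "data.frame")
  out
}

#' Simulate a frequency table from the drift / sweep model
#'
#' Draws per-site focal frequencies directly from the generative model the
#' composite-likelihood scan assumes — Gaussian drift around given
#' reference frequencies, optionally distorted by the two-branch
#' hitchhiking transform around a sweep position — then binomially samples
#' focal allele counts. Used for parameter-recovery checks of
#' [estimate_omega] and [clr_scan].
#'
#' @param n_sites Number of sites.
#' @param chrom_len Chromosome length (bp); positions are uniform on it.
#' @param omega Drift variance scale.
#' @param n_focal Focal chromosome count per site.
#' @param sweep_pos Sweep position in bp, or `NULL` for a neutral table.
#' @param s,r_bp,n_eff Sweep parameters for the hitchhiking transform.
#' @param p_ref_range Reference frequencies drawn uniformly in this range.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return A list with `ft` (a [freq_table]) and `truth`.
#' @export
simulate_freq_table <- function(n_sites = 5000, chrom_len = 1e6,
                                omega = 0.05, n_focal = 20,
                                sweep_pos = NULL, s = 0.05, r_bp = 1e-8,
                                n_eff = 500, p_ref_range = c(0.05, 0.95),
                                seed = 1L, chrom = "1") {
  set.seed(derive_seed(seed, "freq_table"))
  pos <- sort(sample.int(chrom_len, n_sites) - 1)
  p_ref <- stats::runif(n_sites, p_ref_range[1], p_ref_range[2])
  q <- stats::rnorm(n_sites, p_ref, sqrt(omega * p_ref * (1 - p_ref)))
  q <- pmin(1, pmax(0, q))  # boundary point masses via clamping
  if (!is.null(sweep_pos)) {
    ce <- escape_probability(abs(pos - sweep_pos), s, r_bp, n_eff)
    hitch <- stats::runif(n_sites) < q
    q <- ifelse(hitch, 1 - ce + ce * q, ce * q)
  }
  k <- stats::rbinom(n_sites, n_focal, q)
  ft <- data.frame(chrom = chrom, pos = pos, p_ref = p_ref, k_focal = k,
                   n_focal = n_focal, stringsAsFactors = FALSE)
  class(ft) <- c("freq_table", "data.frame")
  list(ft = ft, truth = list(omega = omega, sweep_pos = sweep_pos, s = s,
                             seed = seed))
}
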