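#' Extended haplotype homozygosity over a site span
#'
#' EHH between a core site and a target site is the probability that two
#' haplotypes drawn at random (without replacement) are identical over the
#' inclusive span `[min(core, target), max(core, target)]`:
#' `EHH = sum_g C(n_g, 2) / C(n, 2)` over identity groups of sizes `n_g`.
#' At `target == core` this is the core-site homozygosity (the grouping
#' includes the core site), not 1.
#'
#' @param hm A [hap_matrix] (one population, or pooled).
#' @param core,target Site indices (1-based columns) on the chromosome.
#' @param haps Optional row indices restricting to a subset of haplotypes.
#' @return EHH in `[0, 1]`.
#' @examples
#' hm <- hap_matrix("1", c(0, 50), matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2),
#'                  rep("p1", 4))
#' ehh(hm, core = 1, target = 2)
#' @export
ehh <- function(hm, core, target, haps = NULL) {
  A <- hm$alleles
  if (!is.null(haps)) A <- A[haps, , drop = FALSE]
  n <- nrow(A)
  if (n < 2L) stop("EHH undefined for fewer than 2 haplotypes")
  if (min(core, target) < 1L || max(core, target) > ncol(A))
    stop("core/target outside the site range")
  span <- seq(min(core, target), max(core, target))
  key <- apply(A[, span, drop = FALSE], 1L, paste, collapse = "")
  cnt <- tabulate(match(key, unique(key)))
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

# EHH from an integer group-id vector (partition of haplotypes).
ehh_from_groups <- function(g) {
  n <- length(g)
  cnt <- tabulate(g)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

# Walk outward from `core` in one direction (dir = +1 right, -1 left) over
# the pooled haplotype set, extending while pooled EHH >= cutoff and gaps
# stay within max_gap. Returns the retained positions plus per-step EHH for
# the pooled set and for each subset in `subsets` (a list of row-index
# vectors into A_pool). The span always starts at the core site itself.
ehh_decay_walk <- function(A_pool, positions, core, dir, cutoff, max_gap,
                           subsets) {
  n_site <- ncol(A_pool)
  g <- match(A_pool[, core], unique(A_pool[, core]))
  pos <- positions[core]
  e_sub <- lapply(subsets, function(rw) ehh_from_groups(g[rw]))
  e_pool <- ehh_from_groups(g)
  edge <- FALSE
  if (e_pool < cutoff)
    return(list(pos = pos, ehh = e_sub, edge = FALSE,
                truncated_at_core = TRUE))
  j <- core
  repeat {
    nxt <- j + dir
    if (nxt < 1L || nxt > n_site) { edge <- TRUE; break }
    if (abs(positions[nxt] - positions[j]) > max_gap) { edge <- TRUE; break }
    key <- g * 2L + A_pool[, nxt]
    g <- match(key, unique(key))
    if (ehh_from_groups(g) < cutoff) break  # site nxt not retained
    j <- nxt
    pos <- c(pos, positions[j])
    for (k in seq_along(subsets))
      e_sub[[k]] <- c(e_sub[[k]], ehh_from_groups(g[subsets[[k]]]))
  }
  list(pos = pos, ehh = e_sub, edge = edge, truncated_at_core = FALSE)
}

#' Integrated haplotype homozygosity at a core site
#'
#' iHH is the trapezoidal integral of one population's EHH against physical
#' position, walked outward from the core in both directions. The
#' integration span is decided by the *pooled* two-population EHH: extension
#' stops at the last site before pooled EHH first drops below `cutoff`, at
#' the chromosome's data edge, or when the gap to the next site exceeds
#' `max_gap` (the latter two set `edge_flag`). Using the pooled decay for
#' truncation gives both populations a common integration span.
#'
#' @param hm_pop A [hap_matrix] holding one population's haplotypes.
#' @param hm_pooled A [hap_matrix] pooling both populations over the same
#'   sites.
#' @param core Core site index (1-based column).
#' @param cutoff EHH truncation level in (0, 1), default 0.05.
#' @param max_gap Maximum bp gap bridged between adjacent sites (default
#'   200 kb).
#' @return A list with `ihh` (bp) and `edge_flag`.
#' @export
ihh <- function(hm_pop, hm_pooled, core, cutoff = 0.05, max_gap = 2e5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  if (!identical(hm_pop$positions, hm_pooled$positions))
    stop("hm_pop and hm_pooled must cover the same sites")
  val <- 0
  edge <- FALSE
  for (dir in c(-1L, 1L)) {
    wp <- ehh_decay_walk(hm_pooled$alleles, hm_pooled$positions, core, dir,
                         cutoff, max_gap, subsets = list())
    if (wp$truncated_at_core) next
    # population EHH over the pooled-decided span, from its own matrix
    span_idx <- core + dir * (seq_along(wp$pos) - 1L)
    e_pop <- vapply(span_idx, function(j) ehh(hm_pop, core, j), 0)
    ord <- order(wp$pos)
    val <- val + trapz(wp$pos[ord], e_pop[ord])
    edge <- edge || wp$edge
  }
  list(ihh = val, edge_flag = edge)
}

#' Cross-population XP-EHH scan
#'
#' For every site, integrates each population's EHH over the common
#' pooled-EHH truncation span (see [ihh]) and forms the log-ratio
#' `xpehh_raw = ln(iHH_focal / iHH_ref)`; raw scores are then standardised
#' to `xpehh_z = (raw - mean) / sd` over all defined scores across every
#' chromosome supplied. Positive standardised scores indicate unusually
#' extended haplotypes — a recent sweep — in the focal population. Sites
#' where either iHH is 0 get an undefined raw score and are excluded from
#' standardisation.
#'
#' @param hm A [hap_matrix] with exactly two population labels, or a list of
#'   them (one per chromosome; standardisation is then genome-wide).
#' @param focal Focal population label (default `"focal"`).
#' @param cutoff Pooled-EHH truncation level, default 0.05.
#' @param max_gap Maximum bp gap bridged, default 200 kb.
#' @return A data frame of class `snp_scores`: `chrom`, `pos`, `ihh_focal`,
#'   `ihh_ref`, `xpehh_raw`, `xpehh_z`, `edge_flag`.
#' @export
xpehh_scan <- function(hm, focal = "focal", cutoff = 0.05, max_gap = 2e5) {
  hms <- if (inherits(hm, "hap_matrix")) list(hm) else hm
  parts <- lapply(hms, xpehh_scan_chrom, focal = focal, cutoff = cutoff,
                  max_gap = max_gap)
  out <- do.call(rbind, parts)
  ok <- is.finite(out$xpehh_raw)
  if (sum(ok) < 2L)
    stop("fewer than 2 defined raw scores; cannot standardise")
  out$xpehh_z <- NA_real_
  out$xpehh_z[ok] <- (out$xpehh_raw[ok] - mean(out$xpehh_raw[ok])) /
    stats::sd(out$xpehh_raw[ok])
  class(out) <- c("snp_scores", "data.frame")
  out
}

xpehh_scan_chrom <- function(hm, focal, cutoff, max_gap) {
  labs <- unique(hm$hap_pop)
  if (length(labs) != 2L)
    stop("xpehh_scan needs exactly two population labels, got: ",
         paste(labs, collapse = ", "))
  if (!focal %in% labs) stop(sprintf("focal label '%s' not present", focal))
  focal_mask <- hm$hap_pop == focal
  A <- hm$alleles
  n_site <- ncol(A)
  ihh_f <- ihh_r <- numeric(n_site)
  edge <- logical(n_site)
  for (core in seq_len(n_site)) {
    for (dir in c(-1L, 1L)) {
      w <- cpp_ihh_dir(A, hm$positions, core - 1L, dir, cutoff, max_gap,
                       focal_mask)
      ihh_f[core] <- ihh_f[core] + w[1]
      ihh_r[core] <- ihh_r[core] + w[2]
      edge[core] <- edge[core] || w[3] > 0
    }
  }
  raw <- ifelse(ihh_f > 0 & ihh_r > 0, log(ihh_f / ihh_r), NA_real_)
  data.frame(chrom = hm$chrom, pos = hm$positions, ihh_focal = ihh_f,
             ihh_ref = ihh_r, xpehh_raw = raw, xpehh_z = NA_real_,
             edge_flag = edge, stringsAsFactors = FALSE)
}
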