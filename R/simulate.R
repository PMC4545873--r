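#' Forward Wright-Fisher simulation of a two-population hard sweep
#'
#' Builds an ancestral pool of `2*n_dip` haplotypes with `n_sites`
#' segregating sites placed uniformly on `[0, chrom_len)` and derived-allele
#' frequencies drawn from the neutral site-frequency-spectrum shape
#' (probability proportional to `1/i` for derived count `i`), then evolves
#' two copies of the pool for `t_gen` generations of diploid Wright-Fisher
#' reproduction with per-meiosis recombination (crossover count Poisson with
#' mean `r_bp * chrom_len`, breakpoints uniform). In the focal copy only,
#' genotype fitness at the sweep site is additive (`1`, `1+s`, `1+2s`). If
#' the beneficial allele is lost in the focal population before `t_gen`
#' generations, the focal run restarts from the split with a fresh
#' deterministic sub-seed; the reference population's random stream is
#' independent of restarts. No new mutation arises after the split, so both
#' populations segregate the same site set, matching a jointly called
#' variant panel.
#'
#' @param n_dip Diploid population size per population (N).
#' @param t_gen Generations since the split (T).
#' @param s Selection coefficient of the beneficial allele; `0` gives a
#'   neutral run.
#' @param sweep_pos Physical coordinate (bp, 0-based) of the selected site;
#'   the nearest drawn site is relocated there so a site exists exactly at
#'   the sweep position.
#' @param chrom_len Chromosome length in bp (L).
#' @param n_sites Number of segregating sites at the split (M).
#' @param r_bp Per-bp per-generation recombination probability.
#' @param seed Top-level RNG seed; all sub-streams derive from it.
#' @param chrom Chromosome name for the output.
#' @param labels Population labels, `c(focal, reference)`.
#' @param max_restarts Maximum focal restarts before giving up.
#' @return A list of class `sweep_sim` with elements `hm` (a pooled
#'   [hap_matrix], focal haplotypes first) and `truth` (a list with
#'   `sweep_pos`, `s`, `freq_focal`, `freq_ref` — final derived-allele
#'   frequencies at the sweep site — `seed`, `restarts`, and
#'   `sweep_site_retained`, which is `FALSE` when the sweep site ended
#'   monomorphic in the pooled sample and was therefore dropped).
#' @examples
#' sim <- simulate_two_pop_sweep(n_dip = 30, t_gen = 20, s = 0.2,
#'                               chrom_len = 1e5, n_sites = 80, seed = 1)
#' sim$truth$freq_focal
#' @export
simulate_two_pop_sweep <- function(n_dip = 500, t_gen = 200, s = 0.1,
                                   sweep_pos = floor(chrom_len / 2),
                                   chrom_len = 2.5e6, n_sites = 2000,
                                   r_bp = 1e-8, seed = 1L, chrom = "1",
                                   labels = c("focal", "reference"),
                                   max_restarts = 1000L) {
  if (n_dip < 10) stop("n_dip must be >= 10")
  if (t_gen < 1) stop("t_gen must be >= 1")
  if (s < 0 || s > 1) stop("s must be in [0, 1]")
  if (sweep_pos < 0 || sweep_pos >= chrom_len)
    stop("sweep_pos must lie in [0, chrom_len)")
  if (n_sites < 2) stop("n_sites must be >= 2")
  if (r_bp < 0) stop("r_bp must be >= 0")

  n_hap <- 2L * n_dip

  # --- ancestral pool ---------------------------------------------------
  set.seed(derive_seed(seed, "ancestral"))
  positions <- sort(sample.int(chrom_len, n_sites) - 1)
  sweep_idx <- which.min(abs(positions - sweep_pos))
  positions[sweep_idx] <- sweep_pos
  positions <- sort(positions)
  sweep_idx <- match(sweep_pos, positions)

  sfs_p <- 1 / seq_len(n_hap - 1L)
  counts <- sample.int(n_hap - 1L, n_sites, replace = TRUE, prob = sfs_p)
  # a hard sweep starts from a single copy of the beneficial allele
  if (s > 0) counts[sweep_idx] <- 1L
  # sites in rows, haplotypes in columns (column-major copies dominate cost)
  anc <- matrix(0L, n_sites, n_hap)
  for (m in seq_len(n_sites)) {
    anc[m, sample.int(n_hap, counts[m])] <- 1L
  }

  # --- reference population: pure drift ---------------------------------
  ref <- wf_evolve(anc, t_gen, r_bp, chrom_len, positions,
                   seed = derive_seed(seed, "reference"))

  # --- focal population: additive sweep, restart on loss ----------------
  restarts <- 0L
  repeat {
    foc <- wf_evolve(anc, t_gen, r_bp, chrom_len, positions, s = s,
                     sweep_row = sweep_idx,
                     seed = derive_seed(seed, paste0("focal", restarts)))
    if (s == 0 || any(foc[sweep_idx, ] == 1L)) break
    restarts <- restarts + 1L
    if (restarts > max_restarts)
      stop(sprintf(paste0("selected allele lost in %d consecutive focal ",
                          "runs (initial count %d, s = %g); sweep cannot ",
                          "establish"), restarts, counts[sweep_idx], s))
  }

  freq_focal <- mean(foc[sweep_idx, ])
  freq_ref <- mean(ref[sweep_idx, ])
  # expected-heterozygosity diagnostics over all simulated sites: ancestral
  # level and the reference population's level after t_gen of drift
  p0 <- counts / n_hap
  p_ref_fin <- rowMeans(ref)
  het0 <- mean(2 * p0 * (1 - p0))
  het_ref <- mean(2 * p_ref_fin * (1 - p_ref_fin))

  pooled <- cbind(foc, ref)
  poly <- rowSums(pooled) > 0L & rowSums(pooled) < ncol(pooled)
  hm <- hap_matrix(chrom, positions[poly], t(pooled[poly, , drop = FALSE]),
                   hap_pop = rep(labels, each = n_hap))
  truth <- list(sweep_pos = sweep_pos, s = s, freq_focal = freq_focal,
                freq_ref = freq_ref, seed = seed, restarts = restarts,
                sweep_site_retained = poly[sweep_idx],
                het0 = het0, het_ref = het_ref)
  structure(list(hm = hm, truth = truth), class = "sweep_sim")
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat("Two-population Wright-Fisher sweep simulation\n")
  cat(sprintf("  sweep at %s bp, s = %g, %d focal restart(s)\n",
              format(x$truth$sweep_pos, big.mark = ","), x$truth$s,
              x$truth$restarts))
  cat(sprintf("  final selected-allele frequency: focal %.3f, reference %.3f\n",
              x$truth$freq_focal, x$truth$freq_ref))
  print(x$hm)
  invisible(x)
}

# One population's Wright-Fisher evolution. A is sites x haplotypes;
# consecutive column pairs form diploid individuals. Additive selection at
# sweep_row when s > 0; returns early (for restart) if the allele is lost.
wf_evolve <- function(A, t_gen, r_bp, chrom_len, positions, s = 0,
                      sweep_row = NA_integer_, seed = 1L) {
  set.seed(seed)
  n_hap <- ncol(A)
  n_dip <- n_hap %/% 2L
  xmean <- r_bp * chrom_len
  for (g in seq_len(t_gen)) {
    if (s > 0) {
      gt <- A[sweep_row, seq(1L, n_hap, 2L)] + A[sweep_row, seq(2L, n_hap, 2L)]
      parents <- sample.int(n_dip, n_hap, replace = TRUE, prob = 1 + s * gt)
    } else {
      parents <- sample.int(n_dip, n_hap, replace = TRUE)
    }
    start <- sample.int(2L, n_hap, replace = TRUE) - 1L
    n_x <- stats::rpois(n_hap, xmean)
    B <- A[, 2L * parents - 1L + start, drop = FALSE]
    for (j in which(n_x > 0L)) {
      bp <- sort(stats::runif(n_x[j], 0, chrom_len))
      odd <- findInterval(positions, bp) %% 2L == 1L
      other <- 2L * parents[j] - 1L + (1L - start[j])
      B[odd, j] <- A[odd, other]
    }
    A <- B
    if (s > 0 && !any(A[sweep_row, ] == 1L)) return(A)  # lost -> caller restarts
  }
  A
}

#' Simulate per-haplotype categorical gene sites with breed-specific skew
#'
#' Generates the input of the breed-enrichment stage: a matrix of
#' categorical calls (amino-acid residue classes, or Indel presence Y/N) for
#' haplotypes from several breeds. Null sites draw every haplotype's
#' category from one shared per-site distribution; enriched sites multiply
#' the focal breed's odds of the focal category by a stated factor.
#'
#' @param n_sites Number of sites in the gene.
#' @param breeds Character vector of breed labels (3 for the standard
#'   design).
#' @param n_hap Haplotypes per breed.
#' @param enriched_sites A list of `list(site =, breed =, category =,
#'   odds =)` entries with `odds > 1`; or `NULL` for an all-null matrix.
#' @param k_categories Number of possible categories per site.
#' @param categories Category labels (default `cat1..catK`; use
#'   `c("Y", "N")` with `k_categories = 2` for Indel-style data).
#' @param gene_id Gene identifier attached to the output.
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration of the shared per-site
#'   baseline distribution (1 = uniform over the simplex).
#' @return A list of class `site_matrix`: `gene_id`, `calls` (character
#'   matrix, haplotypes x sites), `breed` (label per row), and `truth`
#'   (data frame of enriched site/breed/category/odds; empty when none).
#' @export
simulate_gene_sites <- function(n_sites = 100,
                                breeds = c("breedA", "breedB", "breedC"),
                                n_hap = 20, enriched_sites = NULL,
                                k_categories = 4,
                                categories = paste0("cat", seq_len(k_categories)),
                                gene_id = "geneSim", seed = 1L,
                                concentration = 1) {
  if (k_categories < 2) stop("k_categories must be >= 2")
  if (length(categories) != k_categories)
    stop("categories must have length k_categories")
  truth <- data.frame(site = integer(0), breed = character(0),
                      category = character(0), odds = numeric(0))
  for (e in enriched_sites) {
    if (e$site < 1 || e$site > n_sites)
      stop("enriched site index out of range: ", e$site)
    if (e$odds <= 1) stop("enriched sites need odds > 1")
    if (!e$breed %in% breeds) stop("unknown breed: ", e$breed)
    if (!e$category %in% categories) stop("unknown category: ", e$category)
    truth <- rbind(truth, data.frame(site = e$site, breed = e$breed,
                                     category = e$category, odds = e$odds))
  }
  set.seed(derive_seed(seed, "gene_sites"))
  n_row <- length(breeds) * n_hap
  breed <- rep(breeds, each = n_hap)
  calls <- matrix(NA_character_, n_row, n_sites)
  for (m in seq_len(n_sites)) {
    base <- stats::rgamma(k_categories, concentration)
    base <- base / sum(base)
    hits <- truth[truth$site == m, , drop = FALSE]
    for (b in breeds) {
      p <- base
      hb <- hits[hits$breed == b, , drop = FALSE]
      for (i in seq_len(nrow(hb))) {
        ci <- match(hb$category[i], categories)
        p[ci] <- p[ci] * hb$odds[i]
      }
      p <- p / sum(p)
      rows <- which(breed == b)
      calls[rows, m] <- categories[sample.int(k_categories, length(rows),
                                              replace = TRUE, prob = p)]
    }
  }
  rownames(calls) <- paste0(breed, "_hap", stats::ave(seq_len(n_row), breed,
                                                      FUN = seq_along))
  colnames(calls) <- paste0("site", seq_len(n_sites))
  structure(list(gene_id = gene_id, calls = calls, breed = breed,
                 truth = truth),
            class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("site_matrix: gene %s, %d haplotypes x %d sites, breeds: %s\n",
              x$gene_id, nrow(x$calls), ncol(x$calls),
              paste(unique(x$breed), collapse = ", ")))
  if (nrow(x$truth))
    cat(sprintf("  %d enriched site(s) in truth\n", nrow(x$truth)))
  invisible(x)
}

#' Write / read a categorical site matrix as TSV
#'
#' Rows are haplotypes with `hap_id`, `breed` columns, then one column per
#' site.
#' @param m A `site_matrix`.
#' @param path Output path.
#' @return The path (write) or a `site_matrix` (read).
#' @export
write_site_matrix <- function(m, path) {
  df <- data.frame(hap_id = rownames(m$calls), breed = m$breed,
                   m$calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_matrix
#' @param gene_id Gene identifier to attach on read.
#' @export
read_site_matrix <- function(path, gene_id = "gene") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  calls <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(calls) <- df$hap_id
  structure(list(gene_id = gene_id, calls = calls, breed = df$breed,
                 truth = data.frame()),
            class = "site_matrix")
}
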