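#' Enumerate breed-specific enrichment tests
#'
#' Amino-acid mode: for each site, one test per (breed, observed category)
#' pair — `n_breeds * k_site` tests per site, where `k_site` is the number
#' of distinct categories observed at the site across all breeds. Indel
#' mode: categories are fixed at `{Y, N}`, giving `n_breeds * 2` tests per
#' site regardless of what is observed. Sites showing a single category in
#' amino-acid mode still contribute their (degenerate, p = 1) tests.
#'
#' @param m A `site_matrix` (see [simulate_gene_sites] /
#'   [read_site_matrix]).
#' @param mode `"aa"` or `"indel"`.
#' @param breeds Breeds to test as focal (default: all breeds present).
#' @return A data frame with one row per (site, breed, category) test.
#' @export
enumerate_tests <- function(m, mode = c("aa", "indel"), breeds = NULL) {
  mode <- match.arg(mode)
  present <- unique(m$breed)
  if (length(present) < 2L)
    stop("need >= 2 breeds for a breed-vs-rest contrast")
  if (is.null(breeds)) breeds <- present
  missing <- setdiff(breeds, present)
  if (length(missing))
    stop("breed(s) absent from input: ", paste(missing, collapse = ", "))
  n_sites <- ncol(m$calls)
  out <- vector("list", n_sites)
  for (j in seq_len(n_sites)) {
    cats <- if (mode == "indel") c("Y", "N") else
      sort(unique(m$calls[, j]))
    out[[j]] <- expand.grid(site = j, breed = breeds, category = cats,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' One-sided Fisher's exact test (odds ratio > 1)
#'
#' Upper-tail exact test on a 2x2 table with cells `a` (focal breed, focal
#' category), `b` (focal breed, other), `c` (other breeds, focal category),
#' `d` (other breeds, other): `p = P(X >= a)` for `X` hypergeometric with
#' the table's margins.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The one-sided p-value.
#' @examples
#' fisher_one_sided(10, 0, 0, 10)  # 1 / choose(20, 10)
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(a + b + c + d < 1))
    stop("cell counts must be non-negative with a positive total")
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Bonferroni correction for enrichment records
#'
#' Adds `p_bonf = min(1, m * p_raw)` and a significance flag
#' `p_raw < alpha / m`, where `m` counts the tests in the chosen scope:
#' all tests of the record's gene (`per_gene`, the default, matching a
#' per-targeted-gene correction) or all records supplied (`global`).
#'
#' @param records A data frame of test records with `gene_id` and `p_raw`.
#' @param alpha Family-wise error level, default 0.05.
#' @param scope `"per_gene"` or `"global"`.
#' @return `records` with `m_tests`, `p_bonf`, `significant`, and a
#'   `cutoffs` attribute holding, per gene, the Bonferroni cutoff
#'   `alpha / m` and the nominal `alpha` (the two reference lines of a
#'   per-site profile plot).
#' @export
bonferroni <- function(records, alpha = 0.05,
                       scope = c("per_gene", "global")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    records$m_tests <- nrow(records)
  } else {
    records$m_tests <- stats::ave(records$p_raw, records$gene_id,
                                  FUN = length)
  }
  records$p_bonf <- pmin(1, records$m_tests * records$p_raw)
  records$significant <- records$p_raw < alpha / records$m_tests
  cut_tab <- unique(records[, c("gene_id", "m_tests")])
  attr(records, "cutoffs") <- data.frame(
    gene_id = cut_tab$gene_id,
    bonferroni_cutoff = alpha / cut_tab$m_tests,
    nominal_alpha = alpha)
  records
}

#' Breed-specific enrichment test of categorical gene sites
#'
#' For every (site, focal breed, focal category) combination (see
#' [enumerate_tests]) builds the 2x2 haplotype-count table focal-breed /
#' other-breeds versus focal-category / other-category and applies the
#' one-sided Fisher's exact test for odds ratio > 1, then Bonferroni
#' correction. Counting is per haplotype (two per diploid animal).
#'
#' @inheritParams enumerate_tests
#' @inheritParams bonferroni
#' @return An object of class `site_enrichment`: the record data frame
#'   (`gene_id`, `site`, `breed`, `category`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_raw`, `m_tests`, `p_bonf`, `significant`) with the
#'   `cutoffs` attribute of [bonferroni].
#' @examples
#' m <- simulate_gene_sites(n_sites = 10, seed = 2)
#' head(enrich_sites(m, mode = "aa"))
#' @export
enrich_sites <- function(m, mode = c("aa", "indel"), breeds = NULL,
                         alpha = 0.05, scope = c("per_gene", "global")) {
  mode <- match.arg(mode)
  tests <- enumerate_tests(m, mode, breeds)
  n <- nrow(tests)
  a <- b <- cc <- d <- integer(n)
  for (i in seq_len(n)) {
    col <- m$calls[, tests$site[i]]
    in_breed <- m$breed == tests$breed[i]
    in_cat <- col == tests$category[i]
    a[i] <- sum(in_breed & in_cat)
    b[i] <- sum(in_breed & !in_cat)
    cc[i] <- sum(!in_breed & in_cat)
    d[i] <- sum(!in_breed & !in_cat)
  }
  records <- data.frame(gene_id = m$gene_id, tests,
                        a = a, b = b, c = cc, d = d,
                        odds_ratio = ifelse(b * cc == 0,
                                            ifelse(a * d > 0, Inf, NaN),
                                            (a * d) / (b * cc)),
                        p_raw = fisher_one_sided(a, b, cc, d),
                        stringsAsFactors = FALSE)
  records <- bonferroni(records, alpha = alpha, scope = scope)
  class(records) <- c("site_enrichment", "data.frame")
  records
}

#' @export
print.site_enrichment <- function(x, ...) {
  cat(sprintf("site_enrichment: %d one-sided Fisher tests over %d site(s)\n",
              nrow(x), length(unique(x$site))))
  cat(sprintf("  %d significant after Bonferroni\n", sum(x$significant)))
  NextMethod()
}

#' @export
summary.site_enrichment <- function(object, ...) {
  cuts <- attr(object, "cutoffs")
  cat("Breed-specific enrichment summary\n")
  cat(sprintf("  tests: %d; genes: %s\n", nrow(object),
              paste(unique(object$gene_id), collapse = ", ")))
  cat(sprintf("  Bonferroni cutoff(s): %s (nominal alpha %.3g)\n",
              paste(signif(cuts$bonferroni_cutoff, 3), collapse = ", "),
              cuts$nominal_alpha[1]))
  sig <- object[object$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant records:\n")
    print(sig[order(sig$p_raw),
              c("gene_id", "site", "breed", "category", "odds_ratio",
                "p_raw", "p_bonf")])
  } else cat("  no significant records\n")
  invisible(object)
}

#' Per-site -log10(p) profile table
#'
#' Arranges one gene's enrichment records for a per-site profile plot:
#' sites in reference order on the x-axis, `-log10(p_raw)` on the y-axis,
#' one series per (breed, category), plus the two horizontal reference
#' values (Bonferroni cutoff and nominal alpha).
#'
#' @param records A `site_enrichment` object restricted to one gene.
#' @return A data frame `site`, `breed`, `category`, `p_raw`,
#'   `neg_log10_p`, with attributes `bonferroni_cutoff` and
#'   `nominal_alpha` (as `-log10` line heights in `*_line`).
#' @export
profile_table <- function(records) {
  if (length(unique(records$gene_id)) != 1L)
    stop("profile_table expects records from a single gene")
  cuts <- attr(records, "cutoffs")
  cuts <- cuts[cuts$gene_id == records$gene_id[1], , drop = FALSE]
  out <- data.frame(site = records$site, breed = records$breed,
                    category = records$category, p_raw = records$p_raw,
                    neg_log10_p = -log10(records$p_raw),
                    stringsAsFactors = FALSE)
  out <- out[order(out$site, out$breed, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bonferroni_cutoff") <- cuts$bonferroni_cutoff
  attr(out, "nominal_alpha") <- cuts$nominal_alpha
  attr(out, "bonferroni_line") <- -log10(cuts$bonferroni_cutoff)
  attr(out, "nominal_line") <- -log10(cuts$nominal_alpha)
  out
}

#' @export
#' @rdname enrich_sites
#' @param x A `site_enrichment` object (one gene) to plot.
#' @param ... Passed to [graphics::plot].
plot.site_enrichment <- function(x, ...) {
  pt <- profile_table(x)
  graphics::plot(pt$site, pt$neg_log10_p, pch = 20,
                 xlab = "site (reference order)",
                 ylab = expression(-log[10](p)), ...)
  graphics::abline(h = attr(pt, "bonferroni_line"), col = "red", lty = 3)
  graphics::abline(h = attr(pt, "nominal_line"), col = "red", lty = 3)
  invisible(pt)
}
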