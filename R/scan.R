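#' Fit a cross-population selection scan
#'
#' The main user-facing entry point. Runs either the haplotype-based
#' XP-EHH scan ([xpehh_scan]) or the allele-frequency composite-likelihood
#' scan ([clr_scan]) on a phased two-population [hap_matrix], summarises
#' per-site scores over consecutive non-overlapping windows
#' ([make_windows]), and assigns significance — SNP-count-binned empirical
#' p-values below `alpha` for XP-EHH, the top-`top_frac` empirical
#' threshold for the composite-likelihood scan ([select_significant]).
#'
#' @param hm A [hap_matrix] (or list of them, one per chromosome) with two
#'   population labels.
#' @param focal Focal population label.
#' @param method `"xpehh"` or `"xpclr"`.
#' @param window_size Summary window width in bp, default 25000.
#' @param alpha Empirical-p cutoff for XP-EHH windows, default 0.01.
#' @param top_frac Upper-tail fraction for composite-likelihood windows,
#'   default 0.01.
#' @param cutoff,max_gap XP-EHH integration controls (see [ihh]).
#' @param grid_spacing,window_radius,s_grid,r_bp,n_eff,n_quad
#'   Composite-likelihood controls (see [clr_scan]).
#' @param omega Drift variance for the composite-likelihood scan; estimated
#'   from the data with [estimate_omega] when `NULL`.
#' @return An object of class `sweep_scan`: a list with `method`, `focal`,
#'   `scores` (per-SNP or per-grid-point data frame), `windows` (a
#'   `window_records` data frame with significance flags), `threshold`
#'   (xpclr mode), `omega` (xpclr mode), and `params`.
#' @examples
#' sim <- simulate_two_pop_sweep(n_dip = 40, t_gen = 30, s = 0.3,
#'                               chrom_len = 2e5, n_sites = 150, seed = 7)
#' fit <- sweep_scan(sim$hm, method = "xpehh")
#' summary(fit)
#' @export
sweep_scan <- function(hm, focal = "focal", method = c("xpehh", "xpclr"),
                       window_size = 25000, alpha = 0.01, top_frac = 0.01,
                       cutoff = 0.05, max_gap = 2e5, grid_spacing = 2500,
                       window_radius = 12500,
                       s_grid = exp(seq(log(1e-4), log(0.5),
                                        length.out = 10)),
                       r_bp = 1e-8, n_eff = 500, n_quad = 512,
                       omega = NULL) {
  method <- match.arg(method)
  hms <- if (inherits(hm, "hap_matrix")) list(hm) else hm
  threshold <- NULL
  if (method == "xpehh") {
    scores <- xpehh_scan(hms, focal = focal, cutoff = cutoff,
                         max_gap = max_gap)
    win <- make_windows(scores, window_size, stat = "xpehh_z")
    win <- empirical_pvalues(bin_by_snp_count(win))
    win <- select_significant(win, "xpehh", alpha = alpha)
  } else {
    fts <- lapply(hms, freq_table, focal = focal)
    if (is.null(omega)) {
      pooled_ft <- do.call(rbind, fts)
      omega <- estimate_omega(pooled_ft)
    }
    scores <- do.call(rbind, lapply(fts, clr_scan, omega = omega,
                                    grid_spacing = grid_spacing,
                                    window_radius = window_radius,
                                    s_grid = s_grid, r_bp = r_bp,
                                    n_eff = n_eff, n_quad = n_quad))
    win <- make_windows(scores, window_size, stat = "clr")
    win <- select_significant(win, "xpclr", top_frac = top_frac)
    threshold <- attr(win, "threshold")
  }
  structure(list(method = method, focal = focal, scores = scores,
                 windows = win, threshold = threshold,
                 omega = if (method == "xpclr") omega else NULL,
                 params = list(window_size = window_size, alpha = alpha,
                               top_frac = top_frac, cutoff = cutoff,
                               max_gap = max_gap,
                               grid_spacing = grid_spacing,
                               window_radius = window_radius,
                               s_grid = s_grid, r_bp = r_bp, n_eff = n_eff,
                               n_quad = n_quad)),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat(sprintf("sweep_scan (%s), focal population '%s'\n", x$method,
              x$focal))
  cat(sprintf("  %d scored positions, %d windows (%d significant)\n",
              sum(is.finite(x$scores[[stat_col(x)]])), nrow(x$windows),
              sum(x$windows$significant)))
  if (!is.null(x$threshold))
    cat(sprintf("  top-%g%% threshold: %.4f\n",
                100 * x$params$top_frac, x$threshold))
  if (!is.null(x$omega))
    cat(sprintf("  drift variance omega: %.4f\n", x$omega))
  invisible(x)
}

stat_col <- function(x) if (x$method == "xpehh") "xpehh_z" else "clr"

#' @export
summary.sweep_scan <- function(object, ...) {
  print(object)
  sig <- significant_windows(object)
  if (nrow(sig)) {
    cat("  top windows:\n")
    print(utils::head(sig[order(-sig$stat_max),
                          setdiff(names(sig), "significant")], 10))
  }
  invisible(object)
}

#' Significant windows of a fitted scan
#' @param x A `sweep_scan` object.
#' @return The significant rows of the window table.
#' @export
significant_windows <- function(x) {
  x$windows[x$windows$significant, , drop = FALSE]
}

#' @export
#' @rdname sweep_scan
#' @param x A `sweep_scan` object.
#' @param ... Passed to [graphics::plot].
plot.sweep_scan <- function(x, ...) {
  w <- x$windows
  mid <- (w$start + w$end) / 2
  graphics::plot(mid, w$stat_max, pch = 20,
                 col = ifelse(w$significant, "red", "grey40"),
                 xlab = "window midpoint (bp)",
                 ylab = sprintf("max %s per window", stat_col(x)), ...)
  if (!is.null(x$threshold))
    graphics::abline(h = x$threshold, lty = 3, col = "red")
  invisible(x)
}
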