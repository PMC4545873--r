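#' Summarise per-site statistics over non-overlapping 25-kb windows
#'
#' Tiles each chromosome with consecutive half-open windows `[0, w)`,
#' `[w, 2w)`, ... and represents each window by the maximum defined
#' statistic among the sites it contains (the per-window summary used for
#' both scan statistics). Windows containing no scored site are dropped:
#' they have no maximum to rank.
#'
#' @param scores A data frame with `chrom`, `pos`, and the statistic column
#'   (per-SNP scores or per-grid-point scores).
#' @param window_size Window width in bp, default 25000.
#' @param stat Name of the statistic column; by default the first of
#'   `xpehh_z`, `clr`, `stat` found in `scores`.
#' @return A data frame of class `window_records`: `chrom`, `start`, `end`,
#'   `snp_count`, `stat_max`.
#' @export
make_windows <- function(scores, window_size = 25000, stat = NULL) {
  scores <- as.data.frame(scores)
  if (is.null(stat))
    stat <- intersect(c("xpehh_z", "clr", "stat"), names(scores))[1]
  if (is.na(stat) || is.null(stat) || !stat %in% names(scores))
    stop("no statistic column found; pass 'stat'")
  ok <- is.finite(scores[[stat]])
  scores <- scores[ok, , drop = FALSE]
  if (!nrow(scores))
    return(structure(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), snp_count = integer(0),
                                stat_max = numeric(0)),
                     class = c("window_records", "data.frame")))
  win_start <- (scores$pos %/% window_size) * window_size
  key <- paste(scores$chrom, win_start, sep = ":")
  agg_max <- tapply(scores[[stat]], key, max)
  agg_n <- tapply(scores[[stat]], key, length)
  parts <- strsplit(names(agg_max), ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = as.numeric(vapply(parts, `[`, "", 2L)),
                    snp_count = as.integer(agg_n),
                    stat_max = as.numeric(agg_max),
                    stringsAsFactors = FALSE)
  out$end <- out$start + window_size
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "snp_count", "stat_max")]
  rownames(out) <- NULL
  class(out) <- c("window_records", "data.frame")
  out
}

#' Bin windows by SNP count
#'
#' Windows are binned by the number of scored SNPs they contain, in
#' increments of `bin_width` SNPs (upper edges inclusive: 1-200, 201-400,
#' 401-600 at the defaults), with every window above `overflow` SNPs
#' combined into a single overflow bin. Ranking a window only against
#' windows of comparable SNP count removes the dependence of the maximum
#' statistic on the number of sites it is taken over.
#'
#' @param windows A `window_records` data frame.
#' @param bin_width Bin increment in SNPs, default 200.
#' @param overflow SNP count above which all windows share one bin,
#'   default 600.
#' @return `windows` with an integer `bin_id` column (overflow bin =
#'   `overflow / bin_width + 1`).
#' @export
bin_by_snp_count <- function(windows, bin_width = 200, overflow = 600) {
  if (any(windows$snp_count < 1)) stop("windows must contain >= 1 SNP")
  windows$bin_id <- ifelse(windows$snp_count > overflow,
                           as.integer(overflow / bin_width) + 1L,
                           as.integer(ceiling(windows$snp_count / bin_width)))
  windows
}

#' Rank-based empirical p-values within SNP-count bins
#'
#' Within each bin of size `B`, windows are ranked by `stat_max`
#' descending; the empirical p-value is `rank / B` with rank 1 for the
#' largest value. Tied windows all take the worst (largest) rank of the
#' tied set, the conservative convention.
#'
#' @param windows A `window_records` data frame with `bin_id`.
#' @return `windows` with an `empirical_p` column in `(0, 1]`.
#' @export
empirical_pvalues <- function(windows) {
  if (is.null(windows$bin_id)) stop("assign bins first (bin_by_snp_count)")
  windows$empirical_p <- NA_real_
  for (b in unique(windows$bin_id)) {
    idx <- which(windows$bin_id == b)
    r <- rank(-windows$stat_max[idx], ties.method = "max")
    windows$empirical_p[idx] <- r / length(idx)
  }
  windows
}

#' Flag significant windows
#'
#' XP-EHH mode: a window is significant when its SNP-count-binned empirical
#' p-value is strictly below `alpha` (default 0.01). XP-CLR mode: the
#' threshold is the empirical top-`top_frac` order statistic of `stat_max`
#' over all windows (the value of the `ceiling(top_frac * W)`-th largest
#' window, no interpolation) and a window is significant when `stat_max >=
#' threshold`; the threshold value is recorded in the `threshold`
#' attribute.
#'
#' @param windows A `window_records` data frame (with `empirical_p` for
#'   xpehh mode).
#' @param mode `"xpehh"` or `"xpclr"`.
#' @param alpha Empirical-p cutoff for xpehh mode, default 0.01.
#' @param top_frac Upper-tail fraction for xpclr mode, default 0.01.
#' @return `windows` with a logical `significant` column (and a
#'   `threshold` attribute in xpclr mode).
#' @export
select_significant <- function(windows, mode = c("xpehh", "xpclr"),
                               alpha = 0.01, top_frac = 0.01) {
  mode <- match.arg(mode)
  if (mode == "xpehh") {
    if (is.null(windows$empirical_p))
      stop("xpehh mode needs empirical_p (run empirical_pvalues)")
    windows$significant <- windows$empirical_p < alpha
  } else {
    k <- max(1L, ceiling(top_frac * nrow(windows)))
    threshold <- sort(windows$stat_max, decreasing = TRUE)[k]
    windows$significant <- windows$stat_max >= threshold
    attr(windows, "threshold") <- threshold
  }
  windows
}
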