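#' Map significant windows to overlapping genes
#'
#' A gene is hit when its interval intersects at least one significant
#' window by at least one bp under the shared 0-based half-open convention
#' (`gene_start < window_end && window_start < gene_end`), optionally
#' extended by a flank. Each gene is reported once with all supporting
#' windows listed. Overlap is computed with `IRanges::findOverlaps`.
#'
#' @param windows A `window_records` data frame with a `significant`
#'   column (only significant windows are used).
#' @param genes A gene-interval data frame from [read_genes] (columns
#'   `chrom`, `start`, `end`, `gene_id`).
#' @param comparison Label recorded on every hit (e.g.
#'   `"focal-vs-ref1"`).
#' @param method Method label recorded on every hit (`"xpehh"` /
#'   `"xpclr"`).
#' @param flank Extra bp added to both gene ends before intersection,
#'   default 0.
#' @return A data frame of class `gene_hits`: `gene_id`, `chrom`,
#'   `comparison`, `method`, `n_windows`, `windows` (comma-separated
#'   `start-end` spans).
#' @export
overlap_genes <- function(windows, genes, comparison = "focal-vs-reference",
                          method = "xpehh", flank = 0) {
  if (is.null(windows$significant)) stop("windows need a 'significant' flag")
  sig <- windows[windows$significant, , drop = FALSE]
  hits <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    w <- sig[sig$chrom == ch, , drop = FALSE]
    if (!nrow(w)) next  # chromosome absent from windows: genes unhit
    # half-open [s,e) -> 1-based closed [s+1, e] keeps intersection exact
    gr <- IRanges::IRanges(start = g$start - flank + 1L,
                           end = g$end + flank)
    wr <- IRanges::IRanges(start = w$start + 1L, end = w$end)
    ov <- IRanges::findOverlaps(gr, wr)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (gi in unique(qh)) {
      wi <- sh[qh == gi]
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = g$gene_id[gi], chrom = ch, comparison = comparison,
        method = method, n_windows = length(wi),
        windows = paste(sprintf("%d-%d", as.integer(w$start[wi]),
                                as.integer(w$end[wi])), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(0), chrom = character(0),
               comparison = character(0), method = character(0),
               n_windows = integer(0), windows = character(0))
  out <- out[order(out$chrom, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_hits", "data.frame")
  out
}

#' Set algebra over gene-hit sets
#'
#' Evaluates a set-algebra expression over named gene sets, supporting
#' intersection (`&`), union (`|`), difference (`-`), and parentheses —
#' e.g. the cross-comparison intersections of candidate-gene lists from
#' different scans.
#'
#' @param sets A named list of character vectors (gene ids), or a
#'   `gene_hits` data frame (sets are then formed per
#'   `comparison:method` label).
#' @param expr A set expression as a string over the set names, e.g.
#'   `"A & B"` or `"(A | B) - C"`.
#' @return A sorted character vector of gene ids with a `count` attribute.
#' @examples
#' intersect_gene_sets(list(A = c("g1", "g2"), B = c("g2", "g3")), "A & B")
#' @export
intersect_gene_sets <- function(sets, expr) {
  if (inherits(sets, "gene_hits") || is.data.frame(sets)) {
    lab <- paste(sets$comparison, sets$method, sep = ":")
    sets <- split(sets$gene_id, lab)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  ops <- list(`&` = function(x, y) intersect(x, y),
              `|` = function(x, y) union(x, y),
              `-` = function(x, y) setdiff(x, y),
              `(` = function(x) x)
  e <- parse(text = expr)[[1]]
  check_names <- function(e) {
    if (is.name(e)) {
      nm <- as.character(e)
      if (!nm %in% names(sets)) stop("unknown set name: ", nm)
    } else if (is.call(e)) {
      op <- as.character(e[[1]])
      if (!op %in% names(ops)) stop("unsupported operator: ", op)
      for (i in seq_along(e)[-1]) check_names(e[[i]])
    } else stop("unsupported token in set expression")
  }
  check_names(e)
  res <- sort(eval(e, c(ops, sets)))
  attr(res, "count") <- length(res)
  res
}
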