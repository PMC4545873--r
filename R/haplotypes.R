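#' Phased haplotype matrix
#'
#' Container for one chromosome's phased biallelic haplotypes: a 0/1 allele
#' matrix with one row per haplotype and one column per site, physical
#' positions in 0-based coordinates, and a population label per haplotype.
#' All downstream scan statistics consume this structure.
#'
#' @param chrom Chromosome name (scalar character).
#' @param positions Integer/numeric vector of 0-based physical coordinates,
#'   strictly increasing, one per site.
#' @param alleles Integer matrix of 0/1 values, haplotypes in rows, sites in
#'   columns. 0 is the reference allele, 1 the alternate; no polarisation to
#'   ancestral/derived is attempted (the log-ratio and frequency models used
#'   downstream are insensitive to a global polarity flip).
#' @param hap_pop Character vector of population labels, one per haplotype
#'   row.
#' @param hap_id Optional haplotype identifiers (default `hap1..hapN`).
#' @return An object of class `hap_matrix`.
#' @examples
#' hm <- hap_matrix("1", c(0, 100, 250),
#'                  matrix(c(0, 1, 0, 1, 1, 0, 0, 0, 1, 1, 0, 1), 4, 3),
#'                  hap_pop = rep(c("focal", "reference"), each = 2))
#' hm
#' @export
hap_matrix <- function(chrom, positions, alleles, hap_pop, hap_id = NULL) {
  positions <- as.numeric(positions)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(chrom) != 1L) stop("'chrom' must be a single chromosome name")
  if (ncol(alleles) != length(positions))
    stop("number of allele columns must equal number of positions")
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing with no duplicates")
  if (length(positions) && any(positions < 0))
    stop("positions are 0-based and must be non-negative")
  if (length(alleles) && !all(alleles %in% c(0L, 1L)))
    stop("alleles must contain only 0/1 (biallelic sites)")
  if (nrow(alleles) != length(hap_pop))
    stop("every haplotype row needs a population label")
  if (is.null(hap_id)) hap_id <- paste0("hap", seq_len(nrow(alleles)))
  structure(list(chrom = as.character(chrom), positions = positions,
                 alleles = alleles, hap_pop = as.character(hap_pop),
                 hap_id = as.character(hap_id)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: chromosome %s, %d haplotypes x %d sites\n",
              x$chrom, nrow(x$alleles), ncol(x$alleles)))
  tab <- table(x$hap_pop)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (length(x$positions))
    cat(sprintf("  span: %s-%s bp\n", format(min(x$positions), big.mark = ","),
                format(max(x$positions), big.mark = ",")))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

# Row indices of one population; errors if the label is absent.
pop_rows <- function(hm, pop) {
  idx <- which(hm$hap_pop == pop)
  if (!length(idx)) stop(sprintf("population label '%s' not present", pop))
  idx
}

# Restrict a hap_matrix to a subset of haplotype rows.
subset_haps <- function(hm, rows) {
  hap_matrix(hm$chrom, hm$positions, hm$alleles[rows, , drop = FALSE],
             hm$hap_pop[rows], hm$hap_id[rows])
}

#' Read phased genotypes from a VCF file
#'
#' Parses a multi-sample VCF (plain or bgzipped) into one [hap_matrix] per
#' chromosome. Only phased, biallelic sites with complete genotypes are
#' retained; sites that are multi-allelic, unphased, or contain missing
#' calls are dropped and counted. VCF 1-based positions are converted to the
#' internal 0-based convention.
#'
#' @param path Path to the VCF file.
#' @param popmap Either a two-column data frame (`sample`, `population`) or
#'   the path of a headerless two-column TSV with those fields. Every sample
#'   in the VCF must appear in the map.
#' @return A named list of [hap_matrix] objects, one per chromosome, with an
#'   attribute `excluded` giving the per-reason exclusion counts
#'   (multiallelic, unphased, missing, duplicate position).
#' @export
read_phased_vcf <- function(path, popmap) {
  if (is.character(popmap) && length(popmap) == 1L) {
    popmap <- utils::read.table(popmap, header = FALSE, sep = "\t",
                                col.names = c("sample", "population"),
                                colClasses = "character")
  }
  popmap <- as.data.frame(popmap)
  names(popmap)[1:2] <- c("sample", "population")

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(samples, popmap$sample)
  if (length(missing_samples))
    stop("sample(s) missing from popmap: ",
         paste(missing_samples, collapse = ", "))
  pops <- popmap$population[match(samples, popmap$sample)]

  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)

  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | alt == "." | is.na(alt)
  has_missing <- apply(gt, 1, function(g) any(is.na(g) | grepl("\\.", g)))
  unphased <- !has_missing & apply(gt, 1, function(g) any(!grepl("\\|", g)))
  keep <- !(multi | has_missing | unphased)

  excluded <- c(multiallelic = sum(multi),
                missing = sum(has_missing & !multi),
                unphased = sum(unphased & !multi),
                duplicate_position = 0L)

  chroms <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"]) - 1  # 1-based VCF -> 0-based internal
  out <- list()
  for (ch in unique(chroms)) {
    idx <- which(keep & chroms == ch)
    idx <- idx[order(pos[idx])]
    dup <- duplicated(pos[idx])
    excluded["duplicate_position"] <- excluded["duplicate_position"] + sum(dup)
    idx <- idx[!dup]
    if (!length(idx)) {
      warning(sprintf("chromosome %s: no phased biallelic sites retained", ch))
      out[[ch]] <- hap_matrix(ch, numeric(0),
                              matrix(integer(0), 2 * length(samples), 0),
                              rep(pops, each = 2))
      next
    }
    # one column per retained site; split "a|b" into two haplotype rows
    g <- gt[idx, , drop = FALSE]
    n_hap <- 2L * length(samples)
    alleles <- matrix(0L, n_hap, length(idx))
    for (j in seq_along(samples)) {
      parts <- strsplit(g[, j], "|", fixed = TRUE)
      a <- vapply(parts, `[`, "", 1L)
      b <- vapply(parts, `[`, "", 2L)
      alleles[2L * j - 1L, ] <- as.integer(a)
      alleles[2L * j, ] <- as.integer(b)
    }
    hap_id <- paste0(rep(samples, each = 2), c("_1", "_2"))
    out[[ch]] <- hap_matrix(ch, pos[idx], alleles, rep(pops, each = 2),
                            hap_id)
  }
  attr(out, "excluded") <- excluded
  out
}

#' Read gene intervals from BED or GFF3
#'
#' BED intervals are taken as already 0-based half-open; GFF3 `gene`
#' features are converted from 1-based inclusive to 0-based half-open.
#'
#' @param path Path to a BED (>=4 columns) or GFF3 file; the format is taken
#'   from the extension unless `format` is supplied.
#' @param format One of `"bed"`, `"gff3"`, or `NULL` to guess.
#' @return A data frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `gene_name` (0-based half-open coordinates).
#' @export
read_genes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  format <- match.arg(format, c("bed", "gff3"))
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    types <- as.character(gr$type)
    if (any(types == "gene")) gr <- gr[types == "gene"]
    ids <- as.character(gr$ID %||% gr$gene_id %||% gr$Name)
    nm <- as.character(gr$Name %||% gr$ID)
  } else {
    ids <- as.character(gr$name)
    nm <- ids
  }
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop("gene records without a gene_id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  # GRanges is 1-based inclusive; start-1 restores 0-based half-open
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    gene_id = ids, gene_name = nm,
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("gene interval with start >= end")
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write a result table as TSV
#'
#' Writes any homogeneous record table with a header row, floats at six
#' significant digits, and deterministic row order (`chrom` then
#' `start`/`pos` when present).
#'
#' @param records A data frame.
#' @param path Output path.
#' @param digits Significant digits for floating-point columns.
#' @return The path, invisibly.
#' @export
write_table <- function(records, path, digits = 6) {
  records <- as.data.frame(records)
  ord_cols <- intersect(c("chrom", "start", "pos", "site"), names(records))
  if (length(ord_cols))
    records <- records[do.call(order, records[ord_cols]), , drop = FALSE]
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         trimws(formatC(out[[j]], digits = digits,
                                        format = "g")))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a hap_matrix as a phased VCF plus population map
#'
#' Emits a minimal phased VCF 4.2 (consecutive haplotype pairs become
#' diploid samples) and a two-column sample-to-population TSV, so that
#' simulated data can be consumed through the same file interfaces as real
#' data.
#'
#' @param hm A [hap_matrix].
#' @param vcf_path Output VCF path.
#' @param popmap_path Output popmap TSV path (default alongside the VCF).
#' @return `vcf_path`, invisibly.
#' @export
write_phased_vcf <- function(hm, vcf_path,
                             popmap_path = sub("\\.vcf$", ".popmap.tsv",
                                               vcf_path)) {
  n_hap <- nrow(hm$alleles)
  if (n_hap %% 2L != 0L)
    stop("need an even number of haplotypes to form diploid samples")
  pair_pop <- hm$hap_pop[seq(1L, n_hap, by = 2L)]
  if (!all(pair_pop == hm$hap_pop[seq(2L, n_hap, by = 2L)]))
    stop("haplotype pairs must share a population to form samples")
  samples <- sprintf("%s_ind%03d", pair_pop,
                     stats::ave(seq_along(pair_pop), pair_pop,
                                FUN = seq_along))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", hm$chrom),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  a1 <- hm$alleles[seq(1L, n_hap, by = 2L), , drop = FALSE]
  a2 <- hm$alleles[seq(2L, n_hap, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow(a1), ncol(a1))
  body <- vapply(seq_along(hm$positions), function(j) {
    paste(c(hm$chrom, format(hm$positions[j] + 1, scientific = FALSE),
            ".", "A", "T", ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), vcf_path)
  utils::write.table(data.frame(samples, pair_pop), popmap_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(vcf_path)
}
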