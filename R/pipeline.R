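pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "sweepscan_run",
    focal = "focal",
    simulate = list(n_dip = 500, t_gen = 200, s = 0.1, sweep_pos = NULL,
                    chrom_len = 2.5e6, n_sites = 2000, r_bp = 1e-8,
                    chrom = "1"),
    input = list(vcf = NULL, popmap = NULL, genes = NULL),
    xpehh = list(cutoff = 0.05, max_gap = 2e5),
    xpclr = list(grid_spacing = 2500, window_radius = 12500, r_bp = 1e-8,
                 n_eff = 500, n_quad = 512),
    windows = list(window_size = 25000, alpha = 0.01, top_frac = 0.01),
    enrich = list(enabled = TRUE, n_sites = 100, n_hap = 20,
                  k_categories = 4, odds = 50, alpha = 0.05,
                  scope = "per_gene", mode = "aa"),
    annotate = list(gene_length = 20000, gene_spacing = 50000, flank = 0)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the full selection-scan pipeline
#'
#' Chains every stage through plain-text file interfaces: simulate (or load)
#' phased haplotypes, run the XP-EHH and composite-likelihood scans, window
#' and flag both, annotate significant windows against gene intervals,
#' intersect the candidate gene sets, and run the breed-enrichment stage on
#' a simulated categorical site matrix. All stage outputs are TSV files in
#' `out_dir`, and a `manifest.yaml` records package version, seed, every
#' parameter, and input/output checksums; a rerun with the same config
#' reproduces the outputs byte for byte.
#'
#' @param config A named list overriding the defaults (see
#'   `sweepscan:::pipeline_defaults()`), or the path of a YAML file with the
#'   same structure. Unknown keys are rejected before any stage runs.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the fitted `sweep_scan` objects, the
#'   enrichment records, the gene-hit tables, and the manifest path.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_stage <- function(...) message("[sweepscan] ", sprintf(...))

  # --- stage: haplotype input ------------------------------------------
  if (is.null(cfg$input$vcf)) {
    log_stage("simulate: two-population sweep (seed %d)", cfg$seed)
    sim_args <- cfg$simulate
    if (is.null(sim_args$sweep_pos))
      sim_args$sweep_pos <- floor(sim_args$chrom_len / 2)
    sim <- do.call(simulate_two_pop_sweep,
                   c(sim_args, list(seed = cfg$seed)))
    write_phased_vcf(sim$hm, out("haplotypes.vcf"), out("popmap.tsv"))
    write_table(data.frame(sim$truth), out("truth.tsv"))
    vcf_path <- out("haplotypes.vcf")
    popmap_path <- out("popmap.tsv")
  } else {
    sim <- NULL
    vcf_path <- cfg$input$vcf
    popmap_path <- cfg$input$popmap
  }
  hms <- read_phased_vcf(vcf_path, popmap_path)

  # --- stage: XP-EHH ----------------------------------------------------
  log_stage("xpehh: scanning %d chromosome(s)", length(hms))
  fit_ehh <- sweep_scan(hms, focal = cfg$focal, method = "xpehh",
                        window_size = cfg$windows$window_size,
                        alpha = cfg$windows$alpha,
                        cutoff = cfg$xpehh$cutoff,
                        max_gap = cfg$xpehh$max_gap)
  write_table(fit_ehh$scores, out("snp_scores.tsv"))
  write_table(fit_ehh$windows, out("windows_xpehh.tsv"))

  # --- stage: composite likelihood -------------------------------------
  log_stage("xpclr: composite-likelihood scan")
  fit_clr <- sweep_scan(hms, focal = cfg$focal, method = "xpclr",
                        window_size = cfg$windows$window_size,
                        top_frac = cfg$windows$top_frac,
                        grid_spacing = cfg$xpclr$grid_spacing,
                        window_radius = cfg$xpclr$window_radius,
                        r_bp = cfg$xpclr$r_bp, n_eff = cfg$xpclr$n_eff,
                        n_quad = cfg$xpclr$n_quad)
  write_table(fit_clr$scores, out("clr.tsv"))
  write_table(fit_clr$windows, out("windows_xpclr.tsv"))

  # --- stage: gene annotation ------------------------------------------
  if (!is.null(cfg$input$genes)) {
    genes <- read_genes(cfg$input$genes)
  } else {
    # synthetic regular gene tiling over the simulated chromosome span
    span <- max(vapply(hms, function(h) max(c(0, h$positions)), 0))
    starts <- seq(0, max(0, span - cfg$annotate$gene_length),
                  by = cfg$annotate$gene_spacing)
    genes <- data.frame(chrom = hms[[1]]$chrom, start = starts,
                        end = starts + cfg$annotate$gene_length,
                        gene_id = sprintf("gene%04d", seq_along(starts)),
                        gene_name = sprintf("gene%04d", seq_along(starts)))
  }
  log_stage("annotate: %d gene interval(s)", nrow(genes))
  hits <- rbind(
    overlap_genes(fit_ehh$windows, genes, method = "xpehh",
                  flank = cfg$annotate$flank),
    overlap_genes(fit_clr$windows, genes, method = "xpclr",
                  flank = cfg$annotate$flank))
  write_table(hits, out("genes.tsv"))
  inter <- intersect_gene_sets(
    list(xpehh = hits$gene_id[hits$method == "xpehh"],
         xpclr = hits$gene_id[hits$method == "xpclr"]),
    "xpehh & xpclr")
  writeLines(inter, out("genes_intersection.txt"))

  # --- stage: enrichment ------------------------------------------------
  enr <- NULL
  if (isTRUE(cfg$enrich$enabled)) {
    log_stage("enrich: breed-specific Fisher tests")
    m <- simulate_gene_sites(
      n_sites = cfg$enrich$n_sites, n_hap = cfg$enrich$n_hap,
      k_categories = cfg$enrich$k_categories,
      enriched_sites = list(list(site = 1L,
                                 breed = "breedA", category = "cat1",
                                 odds = cfg$enrich$odds)),
      seed = cfg$seed)
    write_site_matrix(m, out("site_matrix.tsv"))
    enr <- enrich_sites(m, mode = cfg$enrich$mode,
                        alpha = cfg$enrich$alpha, scope = cfg$enrich$scope)
    write_table(as.data.frame(enr), out("enrichment.tsv"))
  }

  # --- manifest ---------------------------------------------------------
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.yaml$", files)]
  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = cfg$seed,
    config = cfg,
    checksums = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  log_stage("done: %s", cfg$out_dir)
  invisible(list(xpehh = fit_ehh, xpclr = fit_clr, genes = hits,
                 intersection = inter, enrichment = enr, sim = sim,
                 manifest = out("manifest.yaml"), out_dir = cfg$out_dir))
}
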