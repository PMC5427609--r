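#' Pipeline configuration
#'
#' Describes one end-to-end run: either a simulation config or paths to a
#' VCF / label TSV / gene annotation, the target-vs-contrast breed pair,
#' and the stage parameters.  Defaults follow the standard workflow:
#' adjacent-pair MIE threshold at half the breed-label entropy, wMI with
#' `alpha = 0.5`, gene selection at permutation `p < 1e-3`, scan empirical
#' `p < 0.01`, XP-CLR top 1%, candidate-gene flank 25 kb, and network cuts
#' (0.9, -0.4).
#'
#' @param sim a [sim_config()], or `NULL` when reading files.
#' @param vcf,labels,genes input paths (ignored when `sim` is given).
#' @param target_breed,contrast_breed the breed pair analysed
#'   (target-vs-contrast; defaults to the first two breed labels).
#' @param alpha wMI interpolation constant.
#' @param theta_frac adjacent-pair MIE threshold as a fraction of the
#'   breed-label entropy H(C).
#' @param n_perm label permutations for wMI and pair significance.
#' @param wmi_p_cutoff permutation p cutoff for the wMI gene list.
#' @param pair_p_cutoff permutation p cutoff for selected SNP pairs.
#' @param scan_p_cutoff empirical p cutoff for XP-EHH windows.
#' @param window_bp scan window size (bp).
#' @param flank_bp candidate-gene flank (bp).
#' @param pos_cut,neg_cut network correlation thresholds (strict).  The
#'   default is the published preset for networks of a hundred-plus genes;
#'   `network_presets` lists the alternatives, including (0.45, -0.25)
#'   for small (tens of genes) networks.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param seed master seed; overrides `sim$seed` and feeds every
#'   permutation stream.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), vcf = NULL, labels = NULL,
                            genes = NULL, target_breed = NULL,
                            contrast_breed = NULL, alpha = 0.5,
                            theta_frac = 0.5, n_perm = 1999L,
                            wmi_p_cutoff = 1e-3, pair_p_cutoff = 1e-3,
                            scan_p_cutoff = 0.01, window_bp = 50000L,
                            flank_bp = 25000L, pos_cut = 0.9,
                            neg_cut = -0.4, out_dir = NULL, seed = 42L) {
  if (is.null(sim)) {
    for (p in c(vcf, labels, genes))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else {
    sim$seed <- as.integer(seed)
    validate_sim_config(sim)
  }
  if (!is.null(target_breed) && !is.null(contrast_breed) &&
      identical(target_breed, contrast_breed))
    stop("target and contrast breed must differ")
  structure(list(sim = sim, vcf = vcf, labels = labels, genes = genes,
                 target_breed = target_breed,
                 contrast_breed = contrast_breed,
                 alpha = alpha, theta_frac = theta_frac,
                 n_perm = as.integer(n_perm),
                 wmi_p_cutoff = wmi_p_cutoff,
                 pair_p_cutoff = pair_p_cutoff,
                 scan_p_cutoff = scan_p_cutoff,
                 window_bp = as.integer(window_bp),
                 flank_bp = as.integer(flank_bp),
                 pos_cut = pos_cut, neg_cut = neg_cut,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full signature-discovery workflow
#'
#' Simulate or ingest -> major/minor recode -> per-site MI and
#' adjacent-pair MIE selection -> gene aggregation, wMI and permutation
#' significance -> XP-EHH and XP-CLR-style scans with empirical p ->
#' candidate-gene assignment and intersections -> per-chromosome Fisher
#' enrichment and case-control tests -> zygosity correlation network and
#' hub ranking.  Every table is written to `config$out_dir` (when set) as
#' TSV; reruns with the same config and seed reproduce the files
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return A report list with the per-stage tables (`gene_stats`,
#'   `selected_pairs`, `xpehh`, `xpclr`, gene lists and intersections,
#'   `enrichment`, `assoc`, `network`, `hubs`, `truth` when simulated, and
#'   a `provenance` block).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  dat <- run_stage("input", {
    if (!is.null(config$sim)) simulate_panel(config$sim)
    else {
      lab <- read_breed_labels(config$labels)
      list(panel = read_vcf(config$vcf, lab),
           genes = read_genes(config$genes), truth = NULL)
    }
  })
  panel <- dat$panel
  breeds <- unique(panel$samples$breed)
  target <- if (is.null(config$target_breed)) breeds[1] else config$target_breed
  contrast <- if (is.null(config$contrast_breed)) breeds[2] else
    config$contrast_breed
  if (identical(target, contrast))
    stop("target and contrast breed must differ")
  if (!all(c(target, contrast) %in% breeds))
    stop("breed pair not present in panel")

  pair_panel <- run_stage("recode", {
    recode_major_minor(subset_breeds(panel, c(target, contrast)))
  })
  tern <- run_stage("ternary", ternary_encode(pair_panel))
  gene_map <- run_stage("gene_map", map_snps_to_genes(pair_panel, dat$genes))

  h_class <- entropy(table(hap_breeds(pair_panel)))
  pairs <- run_stage("mi_pairs", select_discriminative_pairs(
    pair_panel, theta = config$theta_frac * h_class,
    n_perm = config$n_perm, p_cutoff = config$pair_p_cutoff,
    seed = config$seed + 2L))
  snp_selected <- seq_len(n_sites(pair_panel)) %in%
    attr(pairs, "selected_sites")

  gene_stats <- run_stage("wmi", wmi_significance(
    pair_panel, gene_map, alpha = config$alpha, n_perm = config$n_perm,
    seed = config$seed + 1L, p_cutoff = config$wmi_p_cutoff))
  mi_genes <- gene_stats$gene_id[gene_stats$selected]

  xpehh <- run_stage("xpehh", {
    sc <- xpehh_scan(subset_breeds(pair_panel, target),
                     subset_breeds(pair_panel, contrast),
                     window_bp = config$window_bp)
    sc$windows <- bin_empirical_p(sc$windows, p_cutoff = config$scan_p_cutoff)
    sc
  })
  xpehh_genes <- assign_candidate_genes(
    xpehh$windows[xpehh$windows$selected, , drop = FALSE], dat$genes,
    flank_bp = config$flank_bp)

  xpclr <- run_stage("xpclr", xpclr_lite(
    ternary_encode(recode_major_minor(subset_breeds(panel, target))),
    ternary_encode(recode_major_minor(subset_breeds(panel, contrast))),
    window_bp = config$window_bp))
  xpclr_genes <- assign_candidate_genes(
    xpclr[xpclr$selected, , drop = FALSE], dat$genes,
    flank_bp = config$flank_bp)

  mi_xpclr <- intersect_gene_lists(mi_genes, xpclr_genes)
  mi_xpehh <- intersect_gene_lists(mi_genes, xpehh_genes)

  enrichment <- run_stage("enrichment", chromosome_enrichment(
    snp_selected, pair_panel$sites$chrom))

  assoc <- run_stage("assoc", do.call(rbind, lapply(
    c("dominant", "recessive", "codominant"),
    function(m) case_control_test(tern, model = m))))

  network <- run_stage("network", {
    if (length(mi_genes) >= 2L) {
      prof <- gene_variation(tern, gene_map, mi_genes)
      corr <- correlation_matrix(prof)
      build_network(corr, pos_cut = config$pos_cut,
                    neg_cut = config$neg_cut)
    } else NULL
  })
  hubs <- if (!is.null(network)) hub_genes(network) else NULL

  report <- list(
    target = target, contrast = contrast,
    panel = pair_panel, tern = tern, genes = dat$genes,
    gene_map = gene_map, truth = dat$truth,
    site_mi = data.frame(chrom = pair_panel$sites$chrom,
                         pos = pair_panel$sites$pos,
                         mi = site_mi(pair_panel),
                         selected = snp_selected,
                         stringsAsFactors = FALSE),
    selected_pairs = pairs, gene_stats = gene_stats,
    mi_genes = mi_genes, xpehh = xpehh, xpehh_genes = xpehh_genes,
    xpclr = xpclr, xpclr_genes = xpclr_genes,
    mi_xpclr_genes = mi_xpclr, mi_xpehh_genes = mi_xpehh,
    enrichment = enrichment, assoc = assoc,
    network = network, hubs = hubs,
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("breedsig")))
  )
  if (!is.null(config$out_dir))
    run_stage("write_report", write_report(report, config$out_dir))
  report
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  dput(cfg[order(names(cfg))], file = tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the report tables of a pipeline run
#'
#' @param report a [run_full_pipeline()] result.
#' @param out_dir directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  f <- function(x) file.path(out_dir, x)
  write_tsv(report$site_mi, f("site_mi.tsv"))
  write_tsv(report$selected_pairs, f("selected_pairs.tsv"))
  write_tsv(report$gene_stats, f("gene_stats.tsv"))
  write_tsv(report$xpehh$sites, f("xpehh_sites.tsv"))
  write_tsv(report$xpehh$windows, f("xpehh_windows.tsv"))
  write_tsv(report$xpclr, f("xpclr_windows.tsv"))
  sel <- report$xpehh$windows[report$xpehh$windows$selected, , drop = FALSE]
  write_tsv(data.frame(chrom = sel$chrom, start = sel$start, end = sel$end),
            f("xpehh_selected_windows.bed"))
  gl <- function(ids) data.frame(gene_id = ids, stringsAsFactors = FALSE)
  write_tsv(gl(report$mi_genes), f("genes_mi.tsv"))
  write_tsv(gl(report$xpehh_genes), f("genes_xpehh.tsv"))
  write_tsv(gl(report$xpclr_genes), f("genes_xpclr.tsv"))
  write_tsv(gl(report$mi_xpclr_genes), f("genes_mi_xpclr.tsv"))
  write_tsv(gl(report$mi_xpehh_genes), f("genes_mi_xpehh.tsv"))
  write_tsv(report$enrichment, f("enrichment.tsv"))
  write_tsv(report$assoc, f("assoc_tests.tsv"))
  if (!is.null(report$network)) {
    export_network(report$network, f("network_edges.tsv"), "tsv")
    export_network(report$network, f("network.graphml"), "graphml")
    write_tsv(report$hubs, f("network_hubs.tsv"))
  }
  prov <- report$provenance
  write_tsv(data.frame(key = names(prov),
                       value = unlist(lapply(prov, as.character)),
                       stringsAsFactors = FALSE),
            f("provenance.tsv"))
  invisible(list.files(out_dir, full.names = TRUE))
}

#' Summarise gene lists and intersections of a pipeline run
#'
#' Per-measure and per-intersection gene counts plus per-chromosome
#' selected-SNP counts (the inputs of the enrichment figure).
#'
#' @param report a [run_full_pipeline()] result.
#' @return List with `gene_counts` (data.frame) and `snp_counts`
#'   (per-chromosome data.frame).
#' @export
intersect_and_summarize <- function(report) {
  gene_counts <- data.frame(
    measure = c("wMI", "XP-EHH", "XP-CLR", "MI&XP-CLR", "MI&XP-EHH"),
    n_genes = c(length(report$mi_genes), length(report$xpehh_genes),
                length(report$xpclr_genes), length(report$mi_xpclr_genes),
                length(report$mi_xpehh_genes)),
    stringsAsFactors = FALSE)
  stopifnot(
    length(report$mi_xpclr_genes) <=
      min(length(report$mi_genes), length(report$xpclr_genes)),
    length(report$mi_xpehh_genes) <=
      min(length(report$mi_genes), length(report$xpehh_genes)))
  snp <- report$site_mi
  snp_counts <- do.call(rbind, lapply(unique(snp$chrom), function(cc)
    data.frame(chrom = cc, n_snps = sum(snp$chrom == cc),
               n_selected = sum(snp$selected & snp$chrom == cc),
               stringsAsFactors = FALSE)))
  list(gene_counts = gene_counts, snp_counts = snp_counts)
}
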