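#' Simulation configuration for a multi-breed genotype panel
#'
#' Defaults describe the standard desk-scale stand-in for a multi-breed
#' cattle resequencing panel: two breeds of 10 and 9 diploid samples,
#' 20,000 biallelic SNPs on one 10-Mb chromosome, Balding-Nichols drift at
#' FST 0.1 around uniform ancestral frequencies, 200 genes of 20 kb tiling
#' the chromosome, 10 planted breed-specific signature genes, one planted
#' heterozygous (opposite-zygosity) gene, and one hard sweep in breed 1
#' (carrier fraction 0.9 over a 200-kb footprint).
#'
#' @param n_breeds number of breed groups.
#' @param samples_per_breed integer vector, diploid samples per breed.
#' @param n_sites number of biallelic SNP sites.
#' @param chrom_length chromosome length in bp.
#' @param base_freq_beta length-2 shape parameters of the Beta distribution
#'   of ancestral allele frequencies (clamped into \[0.01, 0.99\]).
#' @param sig_freq_beta Beta shape parameters for the ancestral ALT
#'   frequency at sites inside planted genes.  The low-frequency default
#'   makes planted genes near-fixed in the target breed for haplotypes that
#'   are rare in the other breeds — the defining property of a
#'   breed-specific signature.
#' @param fst Balding-Nichols drift parameter, one value or one per breed,
#'   strictly inside (0, 1).
#' @param n_genes,gene_length number and length (bp) of gene annotations
#'   tiling the chromosome.
#' @param signature_genes number of genes planted as breed-1 signatures
#'   (breed 1 fixed homozygous for the minor allele at every gene SNP).
#' @param het_genes number of genes planted heterozygous in breed 1 with
#'   the other breeds major-homozygous (the opposite-zygosity pattern).
#' @param sweep_specs list of sweeps, each a list with `breed` (index),
#'   `core` (bp), `carrier` (fraction in \[0,1\]) and `footprint` (bp).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 2L,
                       samples_per_breed = c(10L, 9L),
                       n_sites = 20000L,
                       chrom_length = 1e7,
                       base_freq_beta = c(1, 1),
                       sig_freq_beta = c(1, 19),
                       fst = 0.1,
                       n_genes = 200L,
                       gene_length = 20000L,
                       signature_genes = 10L,
                       het_genes = 1L,
                       sweep_specs = list(list(breed = 1L, core = 7.5e6,
                                               carrier = 0.9,
                                               footprint = 5e5)),
                       seed = 42L) {
  cfg <- list(n_breeds = as.integer(n_breeds),
              samples_per_breed = as.integer(samples_per_breed),
              n_sites = as.integer(n_sites),
              chrom_length = as.numeric(chrom_length),
              base_freq_beta = as.numeric(base_freq_beta),
              sig_freq_beta = as.numeric(sig_freq_beta),
              fst = as.numeric(fst),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              signature_genes = as.integer(signature_genes),
              het_genes = as.integer(het_genes),
              sweep_specs = sweep_specs,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_breeds >= 1L,
    length(cfg$samples_per_breed) == cfg$n_breeds,
    all(cfg$samples_per_breed >= 1L),
    cfg$n_sites >= 1L, cfg$chrom_length >= cfg$n_sites,
    length(cfg$base_freq_beta) == 2L, all(cfg$base_freq_beta > 0),
    length(cfg$sig_freq_beta) == 2L, all(cfg$sig_freq_beta > 0),
    all(cfg$fst > 0 & cfg$fst < 1),
    length(cfg$fst) %in% c(1L, cfg$n_breeds),
    cfg$n_genes >= 0L, cfg$gene_length >= 1L,
    cfg$signature_genes >= 0L, cfg$het_genes >= 0L
  )
  if (cfg$n_genes > 0 && cfg$gene_length > cfg$chrom_length / cfg$n_genes)
    stop("infeasible placement: n_genes * gene_length exceeds chrom_length")
  if (cfg$signature_genes + cfg$het_genes > cfg$n_genes)
    stop("infeasible placement: more planted genes than genes")
  for (sw in cfg$sweep_specs) {
    stopifnot(all(c("breed", "core", "carrier", "footprint") %in% names(sw)))
    if (sw$carrier < 0 || sw$carrier > 1)
      stop("sweep carrier fraction must be in [0, 1]")
    if (sw$core < 1 || sw$core > cfg$chrom_length)
      stop("sweep core position outside chromosome")
    if (sw$breed < 1 || sw$breed > cfg$n_breeds)
      stop("sweep breed index out of range")
  }
  invisible(cfg)
}

#' Simulate a multi-breed haplotype panel with planted signatures
#'
#' Ancestral allele frequencies are drawn from the configured Beta
#' distribution; each breed's site frequencies follow the Balding-Nichols
#' construction `Beta(p(1-F)/F, (1-p)(1-F)/F)`, and haplotype alleles are
#' independent Bernoulli draws at those frequencies.  Signature genes,
#' heterozygous genes and sweeps are then planted (breed 1 is the target)
#' and the truth table records what was planted where.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (a [haplotype_panel()], raw REF/ALT
#'   coding with allele 1 = ALT), `genes` (gene annotation data.frame with
#'   0-based half-open `start`/`end`), and `truth` (list with
#'   `signature_gene_ids`, `het_gene_ids`, `sweep_windows`,
#'   `ancestral_freq`).
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    nb <- config$n_breeds
    ns <- config$samples_per_breed
    S <- config$n_sites
    fst <- rep(config$fst, length.out = nb)

    pos <- sort(sample.int(as.integer(config$chrom_length), S))
    p_anc <- rbeta(S, config$base_freq_beta[1], config$base_freq_beta[2])

    genes <- tile_genes(config)

    # choose planted genes before drawing haplotypes: among SNP-bearing
    # genes outside sweep footprints
    sweep_rng <- lapply(config$sweep_specs, function(sw)
      c(sw$core - sw$footprint / 2, sw$core + sw$footprint / 2))
    in_sweep <- rep(FALSE, nrow(genes))
    for (r in sweep_rng)
      in_sweep <- in_sweep | (genes$start < r[2] & genes$end > r[1])
    n_in_gene <- count_sites_in_genes(pos, genes)
    eligible <- which(!in_sweep & n_in_gene > 0L)
    n_plant <- config$signature_genes + config$het_genes
    if (length(eligible) < n_plant)
      stop("infeasible placement: not enough SNP-bearing genes outside sweeps")
    planted <- sort(sample(eligible, n_plant))
    sig_idx <- planted[seq_len(config$signature_genes)]
    het_idx <- setdiff(planted, sig_idx)

    # planted genes carry ancestral ALT frequencies from the signature
    # (low-frequency) distribution
    for (i in planted) {
      in_g <- which(pos - 1L >= genes$start[i] & pos - 1L < genes$end[i])
      p_anc[in_g] <- rbeta(length(in_g), config$sig_freq_beta[1],
                           config$sig_freq_beta[2])
    }
    p_anc <- pmin(pmax(p_anc, 0.01), 0.99)

    H <- matrix(0L, nrow = 2L * sum(ns), ncol = S)
    row0 <- 0L
    for (k in seq_len(nb)) {
      F <- fst[k]
      pk <- rbeta(S, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
      nh <- 2L * ns[k]
      H[row0 + seq_len(nh), ] <-
        matrix(rbinom(nh * S, 1L, rep(pk, each = nh)), nrow = nh)
      row0 <- row0 + nh
    }

    nucs <- c("A", "C", "G", "T")
    ref <- sample(nucs, S, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1L), character(1))

    sites <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = sprintf("%s_%02d",
                          rep(paste0("breed", seq_len(nb)), ns),
                          unlist(lapply(ns, seq_len))),
      breed = rep(paste0("breed", seq_len(nb)), ns),
      stringsAsFactors = FALSE
    )
    panel <- haplotype_panel(H, sites, samples)

    target <- panel$samples$breed[1]
    for (i in sig_idx)
      panel <- plant_signature_gene(panel, genes[i, ], target)
    for (i in het_idx)
      panel <- plant_heterozygous_gene(panel, genes[i, ], target)
    for (sw in config$sweep_specs)
      panel <- plant_sweep(panel, sw)

    truth <- list(
      signature_gene_ids = genes$gene_id[sig_idx],
      het_gene_ids = genes$gene_id[het_idx],
      sweep_windows = lapply(config$sweep_specs, function(sw)
        list(chrom = "chr1",
             start = max(0, sw$core - sw$footprint / 2),
             end = min(config$chrom_length, sw$core + sw$footprint / 2),
             breed = paste0("breed", sw$breed), core = sw$core)),
      ancestral_freq = p_anc
    )
    list(panel = panel, genes = genes, truth = truth)
  })
}

# evenly spaced gene annotations tiling the chromosome (0-based half-open)
tile_genes <- function(config) {
  n <- config$n_genes
  if (n == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  start <- floor((seq_len(n) - 1L) * config$chrom_length / n)
  data.frame(gene_id = sprintf("gene_%04d", seq_len(n)),
             chrom = "chr1",
             start = as.integer(start),
             end = as.integer(start + config$gene_length),
             stringsAsFactors = FALSE)
}

count_sites_in_genes <- function(pos, genes) {
  vapply(seq_len(nrow(genes)), function(i)
    sum(pos - 1L >= genes$start[i] & pos - 1L < genes$end[i]), integer(1))
}

gene_site_idx <- function(panel, gene) {
  which(panel$sites$chrom == gene$chrom &
          panel$sites$pos - 1L >= gene$start &
          panel$sites$pos - 1L < gene$end)
}

# allele (0/1) that is currently the minor allele at each given site;
# exact 50/50 ties count ALT (code 1) as minor, matching the REF-major
# recoding convention.
minor_allele <- function(panel, idx) {
  c1 <- colSums(panel$H[, idx, drop = FALSE])
  ifelse(c1 <= nrow(panel$H) - c1, 1L, 0L)
}

#' Plant a breed-specific signature gene
#'
#' Every haplotype of the target breed is set to the (panel-wide) minor
#' allele at every SNP inside the gene, making the breed homozygous for the
#' alternative haplotype there.  All other breeds are untouched.
#'
#' @param panel a [haplotype_panel()].
#' @param gene one row of a gene annotation data.frame (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param target_breed breed label to plant in.
#' @return The modified panel.
#' @export
plant_signature_gene <- function(panel, gene, target_breed) {
  idx <- gene_site_idx(panel, gene)
  if (!length(idx))
    stop("gene ", gene$gene_id, " contains no SNP sites; cannot plant")
  rows <- breed_hap_rows(panel, target_breed)
  panel$H[rows, idx] <- matrix(minor_allele(panel, idx),
                               nrow = length(rows), ncol = length(idx),
                               byrow = TRUE)
  panel
}

#' Plant a heterozygous (opposite-zygosity) gene
#'
#' Every sample of the target breed becomes heterozygous (one minor, one
#' major allele) at every SNP in the gene, while all other breeds are set
#' major-homozygous.  After ternary encoding the gene's zygosity profile is
#' high in the target breed and zero elsewhere, the opposite of the planted
#' signature genes, so it anti-correlates with them in the gene network.
#'
#' @inheritParams plant_signature_gene
#' @return The modified panel.
#' @export
plant_heterozygous_gene <- function(panel, gene, target_breed) {
  idx <- gene_site_idx(panel, gene)
  if (!length(idx))
    stop("gene ", gene$gene_id, " contains no SNP sites; cannot plant")
  minor <- minor_allele(panel, idx)
  tgt <- which(panel$samples$breed == target_breed)
  if (!length(tgt)) stop("no samples with breed label '", target_breed, "'")
  oth <- setdiff(seq_len(n_samples(panel)), tgt)
  panel$H[2L * tgt - 1L, idx] <- matrix(minor, length(tgt), length(idx),
                                        byrow = TRUE)
  panel$H[2L * tgt, idx] <- matrix(1L - minor, length(tgt), length(idx),
                                   byrow = TRUE)
  if (length(oth)) {
    rows <- sort(c(2L * oth - 1L, 2L * oth))
    panel$H[rows, idx] <- matrix(1L - minor, length(rows), length(idx),
                                 byrow = TRUE)
  }
  panel
}

#' Plant a hard selective sweep
#'
#' In the swept breed, a fraction `carrier` of haplotypes is overwritten
#' with copies of one core haplotype across the footprint.  Each carrier
#' copies the core haplotype exactly over a contiguous extent around the
#' core whose endpoints are drawn uniformly within the footprint half on
#' each side — emulating recombination erosion of a hard sweep — so the
#' per-site probability that a carrier still matches the core decays
#' linearly from 1 at the core to 0 (the drifted background) at the
#' footprint edges.  With `decay = FALSE` every carrier copies the whole
#' footprint.
#'
#' @param panel a [haplotype_panel()].
#' @param spec list with `breed` (index or label), `core` (bp), `carrier`
#'   (fraction in \[0,1\]), `footprint` (bp).
#' @param decay logical; linear copy-fidelity decay toward the edges.
#' @return The modified panel.
#' @export
plant_sweep <- function(panel, spec, decay = TRUE) {
  if (spec$carrier < 0 || spec$carrier > 1)
    stop("sweep carrier fraction must be in [0, 1]")
  if (spec$carrier == 0) return(panel)
  breeds <- unique(panel$samples$breed)
  breed <- if (is.numeric(spec$breed)) breeds[spec$breed] else spec$breed
  rows <- breed_hap_rows(panel, breed)
  half <- spec$footprint / 2
  idx <- which(panel$sites$pos >= spec$core - half &
                 panel$sites$pos <= spec$core + half)
  if (!length(idx)) return(panel)
  core_hap <- panel$H[rows[1], idx]
  n_car <- round(spec$carrier * length(rows))
  if (n_car < 1) return(panel)
  carriers <- rows[sample.int(length(rows), n_car)]
  d <- panel$sites$pos[idx] - spec$core
  for (r in carriers) {
    ext <- if (decay) runif(2) * half else c(half, half)
    copy <- d >= -ext[1] & d <= ext[2]
    panel$H[r, idx[copy]] <- core_hap[copy]
  }
  panel
}

#' Write a simulated panel to standard plain-text files
#'
#' Emits a phased VCF 4.2 (`panel.vcf`), a BED of gene intervals
#' (`genes.bed`), a sample-to-breed label TSV (`labels.tsv`) and, when a
#' truth table is supplied, `truth.tsv` listing planted features.  Reading
#' the VCF back with [read_vcf()] round-trips the panel exactly.
#'
#' @param panel a [haplotype_panel()] (raw REF/ALT coding).
#' @param genes gene annotation data.frame (0-based half-open).
#' @param out_dir output directory, created if absent.
#' @param truth optional truth list from [simulate_panel()].
#' @return Named character vector of the files written (invisibly).
#' @export
write_fixture <- function(panel, genes, out_dir, truth = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(vcf = file.path(out_dir, "panel.vcf"),
             bed = file.path(out_dir, "genes.bed"),
             labels = file.path(out_dir, "labels.tsv"))
  write_panel_vcf(panel, paths[["vcf"]])
  write.table(genes[, c("chrom", "start", "end", "gene_id")],
              paths[["bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(panel$samples[, c("sample_id", "breed")], paths[["labels"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(out_dir, "truth.tsv")
    tr <- rbind(
      data.frame(feature = "signature_gene", id = truth$signature_gene_ids,
                 detail = "", stringsAsFactors = FALSE),
      data.frame(feature = "het_gene", id = truth$het_gene_ids,
                 detail = "", stringsAsFactors = FALSE),
      do.call(rbind, lapply(truth$sweep_windows, function(w)
        data.frame(feature = "sweep", id = w$breed,
                   detail = sprintf("%s:%d-%d", w$chrom,
                                    as.integer(w$start), as.integer(w$end)),
                   stringsAsFactors = FALSE)))
    )
    write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

write_panel_vcf <- function(panel, path) {
  H <- panel$H
  odd <- seq(1L, nrow(H), by = 2L)
  gt <- matrix(paste0(H[odd, , drop = FALSE], "|", H[odd + 1L, , drop = FALSE]),
               nrow = length(odd))
  chroms <- unique(panel$sites$chrom)
  clen <- vapply(chroms, function(cc)
    max(panel$sites$pos[panel$sites$chrom == cc]) + 1L, numeric(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=breedsig_simulate",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(clen)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  )
  body <- do.call(paste, c(
    list(panel$sites$chrom, panel$sites$pos,
         sprintf("snp%06d", seq_len(n_sites(panel))),
         panel$sites$ref, panel$sites$alt, ".", ".", ".", "GT"),
    lapply(seq_len(nrow(gt)), function(i) gt[i, ]),
    sep = "\t"))
  con <- file(path, "wb")  # binary mode: LF line endings on any platform
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
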