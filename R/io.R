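#' Read a sample-to-breed label table
#'
#' @param path TSV with header columns `sample_id` and `breed`.
#' @return data.frame with `sample_id` and `breed`.
#' @export
read_breed_labels <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  lab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "breed") %in% names(lab)))
    stop("label table ", path, " must have columns sample_id and breed")
  if (anyDuplicated(lab$sample_id))
    stop("duplicate sample ids in ", path)
  lab
}

#' Read phased biallelic genotypes from a VCF
#'
#' Retains only biallelic SNP records (single-base REF and ALT); multi-allelic
#' and indel records are dropped and counted.  Phased genotypes are split into
#' two haplotypes per sample.  Unphased genotypes are an error unless
#' `allow_unphased = TRUE`, in which case the panel is flagged unphased and
#' haplotype-level operations (EHH, haplotype MI) refuse to run on it.
#'
#' @param path VCF 4.x file.
#' @param labels data.frame from [read_breed_labels()]; every listed sample
#'   must be present in the VCF, and the panel is restricted to these samples
#'   in this order.
#' @param allow_unphased accept `/`-separated genotypes.
#' @param missing `"error"` (default) or `"impute"`: fill missing genotypes
#'   with the site's modal genotype (logged).
#' @return A [haplotype_panel()] with raw REF/ALT allele coding
#'   (0 = REF, 1 = ALT).
#' @export
read_vcf <- function(path, labels, allow_unphased = FALSE,
                     missing = c("error", "impute")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix)))   # single record drops to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) stop("no usable sites in ", path)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop,
            " non-biallelic-SNP record(s) from ", basename(path))
  if (!any(keep)) stop("no usable sites in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  vcf_samples <- colnames(gt)
  miss_s <- setdiff(labels$sample_id, vcf_samples)
  if (length(miss_s))
    stop("sample(s) missing from VCF: ", paste(miss_s, collapse = ", "))
  gt <- gt[, labels$sample_id, drop = FALSE]

  is_missing <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(is_missing)) {
    if (missing == "error")
      stop("missing genotypes in ", path,
           " (", sum(is_missing), " calls); use missing = \"impute\"")
    for (i in which(rowSums(is_missing) > 0L)) {
      obs <- gt[i, !is_missing[i, ]]
      if (!length(obs)) stop("site with all genotypes missing in ", path)
      modal <- names(sort(table(obs), decreasing = TRUE))[1]
      gt[i, is_missing[i, ]] <- modal
    }
    message("read_vcf: imputed ", sum(is_missing),
            " missing genotype call(s) with the site modal genotype")
  }

  unphased <- grepl("/", gt, fixed = TRUE)
  phased <- TRUE
  if (any(unphased)) {
    if (!allow_unphased)
      stop("unphased genotypes in ", path,
           " (", sum(unphased), " calls); use allow_unphased = TRUE")
    phased <- FALSE
    gt[unphased] <- sub("/", "|", gt[unphased], fixed = TRUE)
  }

  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  if (anyNA(a1) || anyNA(a2) || any(a1 > 1L) || any(a2 > 1L))
    stop("malformed GT field in ", path)

  S <- nrow(gt); N <- ncol(gt)
  H <- matrix(0L, nrow = 2L * N, ncol = S)
  H[seq(1L, 2L * N, 2L), ] <- t(matrix(a1, S, N))
  H[seq(2L, 2L * N, 2L), ] <- t(matrix(a2, S, N))

  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  haplotype_panel(H, sites, labels, recoded = FALSE, phased = phased)
}

#' Recode alleles to major (0) / minor (1)
#'
#' Per site, the most frequent allele across all haplotypes of all samples
#' becomes 0 ("conserved") and the other allele 1 ("mutated").  An exact
#' 50/50 tie keeps REF as the major allele, so the result does not depend on
#' sample order.  Monomorphic sites come out all-0.  Idempotent.
#'
#' @param panel a [haplotype_panel()].
#' @return The panel with binary major/minor coding, `recoded = TRUE`, and a
#'   per-site logical attribute `swapped` recording where REF/ALT were
#'   flipped.
#' @export
recode_major_minor <- function(panel) {
  c_alt <- colSums(panel$H)
  swap <- c_alt > nrow(panel$H) - c_alt   # strict: ties keep REF major
  if (any(swap))
    panel$H[, swap] <- 1L - panel$H[, swap, drop = FALSE]
  prev <- if (panel$recoded && !is.null(panel$swapped)) panel$swapped
          else rep(FALSE, n_sites(panel))
  panel$swapped <- xor(prev, swap)
  panel$recoded <- TRUE
  panel
}

#' Collapse a binary panel to ternary genotype codes
#'
#' Per sample per site, code = allele1 + allele2: 0 = major homozygote,
#' 1 = heterozygote, 2 = alternative homozygote.
#'
#' @param panel a recoded [haplotype_panel()] (see [recode_major_minor()]).
#' @return A [ternary_matrix()].
#' @export
ternary_encode <- function(panel) {
  if (!panel$recoded)
    stop("panel must be major/minor recoded before ternary encoding")
  odd <- seq(1L, nrow(panel$H), by = 2L)
  G <- panel$H[odd, , drop = FALSE] + panel$H[odd + 1L, , drop = FALSE]
  rownames(G) <- panel$samples$sample_id
  ternary_matrix(G, panel$sites, panel$samples)
}

#' Read gene annotations from BED or GFF3
#'
#' BED is taken as 0-based half-open; GFF3 (1-based inclusive) is converted.
#' For GFF3, records of type `gene` are used when present.
#'
#' @param path `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted by (chrom, start).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene annotation not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene"))
    gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- if ("name" %in% names(md)) as.character(md$name)
         else if ("ID" %in% names(md)) as.character(md$ID)
         else if ("gene_id" %in% names(md)) as.character(md$gene_id)
         else sprintf("gene_%05d", seq_along(gr))
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  out <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("empty gene interval in ", path)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Assign SNP sites to gene intervals
#'
#' A site belongs to a gene iff its 0-based position falls in
#' `[start - flank_bp, end + flank_bp)`; a site may belong to several
#' overlapping genes, and genes without SNPs get empty entries.
#'
#' @param sites site data.frame (`chrom`, `pos` 1-based) or a panel.
#' @param genes gene annotation data.frame (0-based half-open).
#' @param flank_bp symmetric flank added to each gene.
#' @return A list of class `gene_snp_map`: `map` (named list, gene id ->
#'   sorted site indices) and `n_snps` (named integer vector).
#' @export
map_snps_to_genes <- function(sites, genes, flank_bp = 0) {
  if (inherits(sites, "haplotype_panel") || inherits(sites, "ternary_matrix"))
    sites <- sites$sites
  snp_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1L, genes$start - flank_bp + 1L),
                     end = genes$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  map <- split(S4Vectors::queryHits(hits),
               factor(S4Vectors::subjectHits(hits),
                      levels = seq_len(nrow(genes))))
  map <- lapply(map, function(ix) sort(as.integer(ix)))
  names(map) <- genes$gene_id
  structure(list(map = map,
                 n_snps = setNames(lengths(map), genes$gene_id)),
            class = "gene_snp_map")
}

#' @export
print.gene_snp_map <- function(x, ...) {
  cat(sprintf("<gene_snp_map> %d genes, %d site assignments (%d genes empty)\n",
              length(x$map), sum(x$n_snps), sum(x$n_snps == 0L)))
  invisible(x)
}
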