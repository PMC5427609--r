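#' Haplotype panel container
#'
#' Bundles a haplotype allele matrix with its site table and sample/breed
#' table.  Rows `2i - 1` and `2i` of the matrix are the two haplotypes of
#' sample `i`; columns are sites sorted by (chrom, pos).  Allele codes are
#' 0/1: REF/ALT as read from a VCF, or major/minor after
#' [recode_major_minor()].
#'
#' @param H integer matrix of 0/1 allele codes, `2 * nrow(samples)` rows and
#'   `nrow(sites)` columns.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, sorted by (chrom, pos) with unique positions per chromosome.
#' @param samples data.frame with columns `sample_id` (unique) and `breed`.
#' @param recoded logical; `TRUE` once alleles are major/minor recoded.
#' @param phased logical; haplotype-level operations require `TRUE`.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(H, sites, samples, recoded = FALSE, phased = TRUE) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  stopifnot(
    is.data.frame(sites), all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    is.data.frame(samples), all(c("sample_id", "breed") %in% names(samples)),
    nrow(H) == 2L * nrow(samples), ncol(H) == nrow(sites)
  )
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in panel")
  if (any(H != 0L & H != 1L))
    stop("allele codes must be 0/1")
  if (any(sites$pos < 1L))
    stop("site positions must be >= 1")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    H <- H[, ord, drop = FALSE]
  }
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("duplicate site positions in panel")
  rownames(sites) <- NULL
  structure(
    list(H = H, sites = sites, samples = samples,
         recoded = isTRUE(recoded), phased = isTRUE(phased)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d samples (%d haplotypes), %d sites, %d breed(s)%s%s\n",
    n_samples(x), nrow(x$H), n_sites(x), length(unique(x$samples$breed)),
    if (x$recoded) ", major/minor recoded" else ", raw REF/ALT",
    if (x$phased) "" else ", UNPHASED"
  ))
  invisible(x)
}

#' @rdname haplotype_panel
#' @param panel a `haplotype_panel` or `ternary_matrix`.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' @rdname haplotype_panel
#' @export
n_sites <- function(panel) nrow(panel$sites)

# breed label of each haplotype row (sample label repeated twice)
hap_breeds <- function(panel) rep(panel$samples$breed, each = 2L)

# haplotype row indices of one breed
breed_hap_rows <- function(panel, breed) {
  idx <- which(panel$samples$breed == breed)
  if (!length(idx)) stop("no samples with breed label '", breed, "'")
  sort(c(2L * idx - 1L, 2L * idx))
}

#' Subset a panel to a set of breeds
#'
#' @param panel a [haplotype_panel()].
#' @param breeds character vector of breed labels to keep.
#' @return A `haplotype_panel` containing only those samples.
#' @export
subset_breeds <- function(panel, breeds) {
  keep <- panel$samples$breed %in% breeds
  if (!any(keep)) stop("no samples left after breed subset")
  rows <- sort(c(2L * which(keep) - 1L, 2L * which(keep)))
  haplotype_panel(panel$H[rows, , drop = FALSE], panel$sites,
                  panel$samples[keep, , drop = FALSE],
                  recoded = panel$recoded, phased = panel$phased)
}

#' Ternary genotype matrix container
#'
#' Per-sample genotype codes 0/1/2 (major homozygote / heterozygote /
#' alternative homozygote), the sum of the sample's two binary allele codes.
#'
#' @param G integer matrix, samples x sites, values in 0:2.
#' @param sites,samples as in [haplotype_panel()].
#' @return An object of class `ternary_matrix`.
#' @export
ternary_matrix <- function(G, sites, samples) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  stopifnot(nrow(G) == nrow(samples), ncol(G) == nrow(sites))
  if (any(G < 0L | G > 2L)) stop("genotype codes must be in 0:2")
  structure(list(G = G, sites = sites, samples = samples),
            class = "ternary_matrix")
}

#' @export
print.ternary_matrix <- function(x, ...) {
  cat(sprintf("<ternary_matrix> %d samples, %d sites\n",
              nrow(x$G), ncol(x$G)))
  invisible(x)
}
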