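#' Aggregate per-site MI values to gene level
#'
#' For every gene, the number of assigned SNPs and the mean, maximum and sum
#' of their MI values.  Genes without SNPs get `n_snps = 0` and `NA` stats.
#'
#' @param mi_values numeric vector of per-site MI values (one per site of
#'   the panel the map was built from), e.g. from [site_mi()].
#' @param gene_map a [map_snps_to_genes()] result.
#' @return data.frame with columns `gene_id`, `n_snps`, `mi_mean`,
#'   `mi_max`, `mi_sum`.
#' @export
aggregate_gene_mi <- function(mi_values, gene_map) {
  stopifnot(inherits(gene_map, "gene_snp_map"))
  if (length(gene_map$map) &&
      max(unlist(gene_map$map, use.names = FALSE), 0L) > length(mi_values))
    stop("gene map refers to sites beyond the MI vector")
  agg <- function(f) vapply(gene_map$map, function(ix)
    if (length(ix)) f(mi_values[ix]) else NA_real_, numeric(1))
  data.frame(gene_id = names(gene_map$map),
             n_snps = as.integer(gene_map$n_snps),
             mi_mean = agg(mean), mi_max = agg(max), mi_sum = agg(sum),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted mutual information (wMI) gene score
#'
#' `wMI = alpha * mean_MI + (1 - alpha) * n_snps / max(n_snps)`: a convex
#' interpolation of the gene's mean per-SNP MI and its SNP count normalised
#' by the largest SNP count over the gene universe.  Genes without SNPs
#' score 0.
#'
#' @param gene_stats data.frame from [aggregate_gene_mi()]; the rows define
#'   the gene universe used for the count normalisation.
#' @param alpha interpolation constant in \[0, 1\].
#' @return `gene_stats` with an added `wmi` column.
#' @export
weighted_mi <- function(gene_stats, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!nrow(gene_stats) || max(gene_stats$n_snps) == 0L)
    stop("empty gene universe: no gene contains SNPs")
  mean_term <- ifelse(gene_stats$n_snps > 0L, gene_stats$mi_mean, 0)
  gene_stats$wmi <- alpha * mean_term +
    (1 - alpha) * gene_stats$n_snps / max(gene_stats$n_snps)
  gene_stats
}

# x log x with 0 log 0 := 0, elementwise
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  dim(out) <- dim(x)
  out
}

# Per-site binary-marker MI against a 2-class split, for many permutations
# at once.  c1a: S x B matrix of allele-1 counts in class A per permutation;
# tot1: allele-1 count per site; na, n: class-A size and total observations.
.mi_binary_two_class <- function(c1a, tot1, na, n) {
  n1b <- tot1 - c1a
  n0a <- na - c1a
  n0b <- (n - na) - n1b
  joint <- xlogx(c1a) + xlogx(n1b) + xlogx(n0a) + xlogx(n0b)
  marg <- xlogx(tot1) + xlogx(n - tot1) + xlogx(na) + xlogx(n - na)
  mi <- (joint - marg) / n + log(n)
  pmax(mi, 0)
}

#' Permutation significance of wMI gene scores
#'
#' Recomputes per-site MI and per-gene wMI under label permutations at the
#' sample level (both haplotypes of a sample move together) and reports the
#' add-one permutation p-value per gene.  Genes without SNPs get `p = 1`.
#'
#' @param panel a recoded [haplotype_panel()] restricted to the two breeds
#'   under comparison.
#' @param gene_map a [map_snps_to_genes()] result on the same sites.
#' @param alpha wMI interpolation constant.
#' @param n_perm number of label permutations (>= 1).
#' @param seed RNG seed.
#' @param p_cutoff selection cutoff recorded in the `selected` column.
#' @param level `"haplotype"` or `"genotype"` per-site MI.
#' @return data.frame from [weighted_mi()] with added `p_value` and
#'   `selected` columns.
#' @export
wmi_significance <- function(panel, gene_map, alpha = 0.5, n_perm = 1000L,
                             seed = NULL, p_cutoff = 1e-3,
                             level = c("haplotype", "genotype")) {
  level <- match.arg(level)
  stopifnot(n_perm >= 1L)
  mi_obs <- site_mi(panel, level = level)
  stats <- weighted_mi(aggregate_gene_mi(mi_obs, gene_map), alpha = alpha)

  has_snps <- stats$n_snps > 0L
  site_idx <- unlist(gene_map$map, use.names = FALSE)
  gene_idx <- rep(seq_along(gene_map$map), gene_map$n_snps)
  nsnp <- gene_map$n_snps[has_snps]
  count_term <- (1 - alpha) * stats$n_snps / max(stats$n_snps)
  obs_wmi <- stats$wmi

  labs <- as.factor(panel$samples$breed)
  K <- nlevels(labs)
  hits <- integer(nrow(stats))

  gene_wmi_from_site_mi <- function(M) {
    # M: sites x B matrix of per-site MI for B permutations
    sums <- rowsum(M[site_idx, , drop = FALSE], gene_idx, reorder = TRUE)
    means <- sums / nsnp
    alpha * means + count_term[has_snps]
  }

  use_fast <- level == "haplotype" && K == 2L
  chunk <- 200L
  with_seed(seed, {
    if (use_fast) {
      Hn <- panel$H; storage.mode(Hn) <- "double"
      tot1 <- colSums(Hn)
      n <- nrow(Hn)
      classA <- levels(labs)[1]
      na <- 2 * sum(labs == classA)
      done <- 0L
      while (done < n_perm) {
        b <- min(chunk, n_perm - done)
        Z <- matrix(0, n, b)
        for (j in seq_len(b))
          Z[rep(perm_labels(labs) == classA, each = 2L), j] <- 1
        c1a <- crossprod(Hn, Z)
        M <- .mi_binary_two_class(c1a, tot1, na, n)
        W <- gene_wmi_from_site_mi(M)
        hits[has_snps] <- hits[has_snps] +
          rowSums(W >= obs_wmi[has_snps] - 1e-12)
        done <- done + b
      }
    } else {
      sym <- if (level == "haplotype") panel$H else ternary_encode(panel)$G
      n_sym <- if (level == "haplotype") 2L else 3L
      each <- if (level == "haplotype") 2L else 1L
      for (b in seq_len(n_perm)) {
        perm <- rep(perm_labels(labs), each = each)
        M <- matrix(site_mi_vec(sym, perm, n_sym = n_sym), ncol = 1L)
        W <- gene_wmi_from_site_mi(M)
        hits[has_snps] <- hits[has_snps] +
          (W[, 1] >= obs_wmi[has_snps] - 1e-12)
      }
    }
  })
  stats$p_value <- ifelse(has_snps, (1 + hits) / (n_perm + 1), 1)
  stats$selected <- stats$p_value < p_cutoff
  stats
}

#' Per-gene MI ratio profiles between two breed-pair analyses
#'
#' For every gene present in both analyses, the ratios
#' `(mean_A + eps) / (mean_B + eps)` and `(max_A + eps) / (max_B + eps)`.
#' Genes missing from either side (or without SNPs) are excluded and
#' counted in a message.
#'
#' @param stats_a,stats_b data.frames from [aggregate_gene_mi()].
#' @param epsilon pseudocount guarding against division by zero.
#' @return data.frame with `gene_id`, `ratio_mean`, `ratio_max`.
#' @export
mi_ratio_profiles <- function(stats_a, stats_b, epsilon = 1e-6) {
  a <- stats_a[stats_a$n_snps > 0L, ]
  b <- stats_b[stats_b$n_snps > 0L, ]
  common <- intersect(a$gene_id, b$gene_id)
  n_excl <- length(union(a$gene_id, b$gene_id)) - length(common)
  if (n_excl > 0)
    message("mi_ratio_profiles: excluded ", n_excl,
            " gene(s) absent or SNP-free on one side")
  ia <- match(common, a$gene_id); ib <- match(common, b$gene_id)
  data.frame(gene_id = common,
             ratio_mean = (a$mi_mean[ia] + epsilon) / (b$mi_mean[ib] + epsilon),
             ratio_max = (a$mi_max[ia] + epsilon) / (b$mi_max[ib] + epsilon),
             stringsAsFactors = FALSE)
}

#' KL divergence between the gene-level MI distributions of two analyses
#'
#' Bins the `mi_mean` (and `mi_max`) values of both analyses on shared
#' edges spanning their pooled range and reports the KL divergence in both
#' directions for each summary.
#'
#' @param stats_a,stats_b data.frames from [aggregate_gene_mi()].
#' @param n_bins number of shared histogram bins (>= 2).
#' @return data.frame with `summary` ("mean"/"max"), `kl_ab`, `kl_ba`.
#' @export
compare_pair_analyses_kl <- function(stats_a, stats_b, n_bins = 50L) {
  stopifnot(n_bins >= 2L)
  one <- function(col) {
    va <- stats_a[[col]][stats_a$n_snps > 0L]
    vb <- stats_b[[col]][stats_b$n_snps > 0L]
    pooled <- c(va, vb)
    if (!length(pooled) || diff(range(pooled)) == 0)
      stop("degenerate MI distribution: all values identical, cannot bin")
    edges <- seq(min(pooled), max(pooled), length.out = n_bins + 1L)
    ha <- tabulate(findInterval(va, edges, rightmost.closed = TRUE,
                                all.inside = TRUE), n_bins)
    hb <- tabulate(findInterval(vb, edges, rightmost.closed = TRUE,
                                all.inside = TRUE), n_bins)
    c(kl_divergence(ha, hb), kl_divergence(hb, ha))
  }
  m1 <- one("mi_mean"); m2 <- one("mi_max")
  data.frame(summary = c("mean", "max"),
             kl_ab = c(m1[1], m2[1]), kl_ba = c(m1[2], m2[2]),
             stringsAsFactors = FALSE)
}
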