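#' Per-chromosome enrichment of selected SNPs
#'
#' For each chromosome, a two-sided Fisher exact test on the 2x2 table
#' (on-chromosome vs off-chromosome) x (selected vs not), plus the
#' negative-log10 ratio of selected to total SNPs on the chromosome (the
#' per-chromosome line statistic; lower values mean a higher proportion of
#' selected SNPs).
#'
#' @param selected logical vector, one flag per SNP.
#' @param chrom chromosome of each SNP.
#' @return data.frame with `chrom`, `n_snps`, `n_selected`, `odds_ratio`,
#'   `p_value`, `bonferroni_p`, `neg_log10_ratio`.
#' @export
chromosome_enrichment <- function(selected, chrom) {
  stopifnot(length(selected) == length(chrom))
  chroms <- unique(chrom)
  rows <- lapply(chroms, function(cc) {
    on_c <- chrom == cc
    if (!any(on_c)) {
      warning("chromosome ", cc, " has no SNPs; skipped")
      return(NULL)
    }
    tab <- matrix(c(sum(selected & on_c), sum(!selected & on_c),
                    sum(selected & !on_c), sum(!selected & !on_c)),
                  nrow = 2)
    ft <- fisher.test(tab, alternative = "two.sided")
    ratio <- sum(selected & on_c) / sum(on_c)
    data.frame(chrom = cc, n_snps = sum(on_c),
               n_selected = sum(selected & on_c),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               neg_log10_ratio = -log10(ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- bonferroni(out$p_value)
  rownames(out) <- NULL
  out[, c("chrom", "n_snps", "n_selected", "odds_ratio", "p_value",
          "bonferroni_p", "neg_log10_ratio")]
}

# genotype counts (codes 0/1/2) per group: 2 x 3 matrix
geno_counts <- function(g, grp1) {
  rbind(tabulate(g[grp1] + 1L, 3L), tabulate(g[!grp1] + 1L, 3L))
}

#' Case-control genotype tests under a genetic model
#'
#' Per site, compares the two groups' ternary genotype codes under the
#' chosen coding: `dominant` collapses carriers ({1,2} vs {0}) and
#' `recessive` alternative homozygotes ({2} vs {0,1}) into 2x2 Fisher exact
#' tests; `codominant` applies the Cochran-Armitage trend test to the 2x3
#' table with scores (0, 1, 2).  Bonferroni correction is over all tested
#' sites.  Monomorphic sites get `p = 1` and are flagged.
#'
#' @param tern a [ternary_matrix()].
#' @param labels two-group labels, one per sample (or `NULL` to use the
#'   panel's breed labels, which must then have exactly two levels).
#' @param model `"dominant"`, `"recessive"` or `"codominant"`.
#' @return data.frame with `chrom`, `pos`, `model`, `p_value`,
#'   `bonferroni_p`, `effect_direction` (+1 if group 1 carries more
#'   alternative alleles, -1 if fewer, 0 if balanced), `monomorphic`.
#' @export
case_control_test <- function(tern, labels = NULL,
                              model = c("dominant", "recessive",
                                        "codominant")) {
  model <- match.arg(model)
  if (is.null(labels)) labels <- tern$samples$breed
  stopifnot(length(labels) == nrow(tern$G))
  lv <- unique(labels)
  if (length(lv) != 2L) stop("case-control tests need exactly two groups")
  grp1 <- labels == lv[1]

  S <- ncol(tern$G)
  p <- numeric(S)
  dir_ <- integer(S)
  mono <- logical(S)
  for (s in seq_len(S)) {
    cnt <- geno_counts(tern$G[, s], grp1)
    alt1 <- sum(cnt[1, ] * 0:2) / (2 * sum(cnt[1, ]))
    alt2 <- sum(cnt[2, ] * 0:2) / (2 * sum(cnt[2, ]))
    dir_[s] <- sign(alt1 - alt2)
    if (sum(colSums(cnt) > 0L) < 2L) {   # monomorphic coding
      mono[s] <- TRUE
      p[s] <- 1
      next
    }
    p[s] <- switch(model,
      dominant = fisher.test(cbind(cnt[, 1], cnt[, 2] + cnt[, 3]))$p.value,
      recessive = fisher.test(cbind(cnt[, 1] + cnt[, 2], cnt[, 3]))$p.value,
      codominant = {
        use <- colSums(cnt) > 0L
        x <- cnt[1, use]; n <- colSums(cnt)[use]
        if (sum(use) < 2L || sum(x) == 0L || sum(x) == sum(n)) 1
        else suppressWarnings(
          prop.trend.test(x, n, score = (0:2)[use])$p.value)
      })
    if (is.na(p[s])) p[s] <- 1   # degenerate table (e.g. no variation)
  }
  data.frame(chrom = tern$sites$chrom, pos = tern$sites$pos, model = model,
             p_value = p, bonferroni_p = bonferroni(p),
             effect_direction = dir_, monomorphic = mono,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' Each p-value multiplied by the number of tests, capped at 1.
#'
#' @param p_values numeric p-values.
#' @param m number of tests (defaults to `length(p_values)`).
#' @return Corrected p-values, order preserved.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(m >= 1L)
  if (m == length(p_values)) p.adjust(p_values, method = "bonferroni")
  else pmin(1, p_values * m)
}
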