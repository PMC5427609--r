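#' Shannon entropy of a count vector
#'
#' Plug-in estimate `-sum(p * log(p))` in nats, with `0 log 0 := 0`.
#'
#' @param counts nonnegative counts with positive total.
#' @return Entropy in nats.
#' @export
entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  N <- sum(counts)
  if (N <= 0) stop("counts must have a positive total")
  p <- counts[counts > 0] / N
  -sum(p * log(p))
}

# MI in nats from a joint contingency table (plug-in, joint-sum form)
.mi_from_table <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  if (N <= 0) stop("empty contingency table")
  rm_ <- rowSums(tab); cm <- colSums(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  n <- tab[idx]
  max(0, sum((n / N) * (log(n) + log(N) - log(rm_[idx[, 1]]) -
                          log(cm[idx[, 2]]))))
}

#' Mutual information between a marker and class labels
#'
#' Plug-in MI in nats, computed in the joint-sum form
#' `sum p(snp,c) log( p(snp,c) / (p(snp) p(c)) )`, which equals
#' `H(SNP) - H(SNP|C)`.  Optionally attaches a label-permutation p-value
#' (add-one convention, see [permutation_pvalue()]).
#'
#' @param x marker values (any discrete coding), one per observation.
#' @param labels class labels, at least two distinct values.
#' @param n_perm number of label permutations for the p-value (0 = none).
#' @param seed seed for the permutation stream.
#' @return An object of class `mi_estimate` with fields `value` (nats),
#'   `p_value` (`NA` when `n_perm = 0`), `n_perm`, `seed`.
#' @export
mutual_information <- function(x, labels, n_perm = 0L, seed = NULL) {
  stopifnot(length(x) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("mutual information needs at least two classes")
  value <- .mi_from_table(table(x, labels))
  p <- NA_real_
  if (n_perm > 0L)
    p <- permutation_pvalue(function(v, l) .mi_from_table(table(v, l)),
                            x, labels, n_perm = n_perm, seed = seed)
  structure(list(value = value, p_value = p,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("MI = %.6f nats%s\n", x$value,
              if (is.na(x$p_value)) ""
              else sprintf(" (permutation p = %.4g, %d perms)",
                           x$p_value, x$n_perm)))
  invisible(x)
}

#' Conditional mutual information I(C; S1 | S2)
#'
#' Triple-sum plug-in estimate over (c, s1, s2); tiny negative
#' floating-point values are clamped to 0.
#'
#' @param s1,s2 marker value vectors.
#' @param labels class labels.
#' @return Conditional MI in nats (nonnegative).
#' @export
conditional_mi <- function(s1, s2, labels) {
  stopifnot(length(s1) == length(s2), length(s1) == length(labels))
  N <- length(s1)
  tab <- table(labels, s1, s2)
  p_s2 <- table(s2)
  p_cs2 <- table(labels, s2)
  p_s1s2 <- table(s1, s2)
  idx <- which(tab > 0, arr.ind = TRUE)
  n <- tab[idx]
  val <- sum((n / N) * (log(p_s2[idx[, 3]]) + log(n) -
                          log(p_cs2[cbind(idx[, 1], idx[, 3])]) -
                          log(p_s1s2[cbind(idx[, 2], idx[, 3])])))
  if (val < -1e-9) stop("conditional MI numerically negative: ", val)
  max(0, val)
}

#' Two-locus mutual information estimator I(C; S1, S2)
#'
#' MI between the class labels and the joint (S1, S2) haplotype symbol;
#' satisfies the chain rule `I(C; S1, S2) = I(C; S1 | S2) + I(C; S2)`.
#'
#' @inheritParams conditional_mi
#' @return MIE in nats.
#' @export
mie_two_locus <- function(s1, s2, labels) {
  stopifnot(length(s1) == length(s2), length(s1) == length(labels))
  joint <- paste(s1, s2, sep = "\r")
  .mi_from_table(table(joint, labels))
}

#' Label-permutation p-value
#'
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`; only the labels are
#' permuted, and the stream is deterministic under `seed`.  Draws that
#' exactly reproduce the observed labeling are redrawn — the observed
#' labeling is already counted once by the add-one term, and with few
#' samples its recurrence would otherwise censor the test.
#'
#' @param stat_fn function of `(values, labels)` returning a scalar.
#' @param values,labels data passed to `stat_fn`.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(stat_fn, values, labels, n_perm, seed = NULL) {
  stopifnot(n_perm >= 1L)
  obs <- stat_fn(values, labels)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm))
      if (stat_fn(values, perm_labels(labels)) >= obs) hits <- hits + 1L
    (1 + hits) / (n_perm + 1)
  })
}

#' Kullback-Leibler divergence between two histograms
#'
#' `sum p log(p / q)` after add-epsilon smoothing and renormalisation.
#' Accepts plain count/density vectors of equal length, or two `histogram`
#' objects (from [graphics::hist()]) whose bin edges must match exactly.
#'
#' @param p,q histograms on shared bin edges.
#' @param eps smoothing constant added to every bin before renormalising.
#' @return KL(P || Q) in nats (nonnegative).
#' @export
kl_divergence <- function(p, q, eps = 1e-12) {
  if (inherits(p, "histogram") || inherits(q, "histogram")) {
    if (!(inherits(p, "histogram") && inherits(q, "histogram")))
      stop("mix of histogram object and plain vector")
    if (length(p$breaks) != length(q$breaks) ||
        any(abs(p$breaks - q$breaks) > 1e-9))
      stop("histograms have mismatched bin edges")
    p <- p$counts; q <- q$counts
  }
  if (length(p) != length(q))
    stop("histograms have mismatched bin edges (different bin counts)")
  if (any(p < 0) || any(q < 0)) stop("negative histogram mass")
  pp <- (p + eps) / sum(p + eps)
  qq <- (q + eps) / sum(q + eps)
  max(0, sum(pp * log(pp / qq)))
}

# ---- vectorised per-site machinery ------------------------------------

# Per-site MI (nats) for every column of a symbol matrix against labels.
# sym: integer matrix (observations x sites), symbols in 0:(n_sym-1);
# labels: factor over observations.
site_mi_vec <- function(sym, labels, n_sym = max(sym) + 1L) {
  labels <- as.factor(labels)
  K <- nlevels(labels)
  N <- nrow(sym)
  S <- ncol(sym)
  nk <- tabulate(labels, K)
  mi <- numeric(S)
  cnt <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- which(as.integer(labels) == k)
    cnt_k <- matrix(0, S, n_sym)
    for (s in seq_len(n_sym) - 1L)
      cnt_k[, s + 1L] <- colSums(sym[rows, , drop = FALSE] == s)
    cnt[[k]] <- cnt_k
  }
  marg <- Reduce(`+`, cnt)   # S x n_sym symbol marginals
  for (k in seq_len(K)) for (s in seq_len(n_sym)) {
    n <- cnt[[k]][, s]
    pos <- n > 0
    mi[pos] <- mi[pos] + (n[pos] / N) *
      (log(n[pos]) + log(N) - log(marg[pos, s]) - log(nk[k]))
  }
  pmax(mi, 0)
}

#' Per-site mutual information across a panel
#'
#' Haplotype-level MI uses each haplotype as one observation carrying its
#' sample's breed label (2N observations per site); genotype-level MI uses
#' the ternary genotype code per sample.
#'
#' @param panel a recoded [haplotype_panel()].
#' @param level `"haplotype"` (default) or `"genotype"`.
#' @return Numeric vector of per-site MI values in nats.
#' @export
site_mi <- function(panel, level = c("haplotype", "genotype")) {
  level <- match.arg(level)
  if (level == "haplotype") {
    if (!panel$phased)
      stop("haplotype-level MI requires phased genotypes")
    site_mi_vec(panel$H, hap_breeds(panel), n_sym = 2L)
  } else {
    tern <- ternary_encode(if (panel$recoded) panel
                           else recode_major_minor(panel))
    site_mi_vec(tern$G, panel$samples$breed, n_sym = 3L)
  }
}

# MIE for each adjacent same-chromosome site pair (haplotype level).
# Returns data.frame(site1, site2, chrom, pos1, pos2, mie).
adjacent_pair_mie <- function(panel) {
  S <- n_sites(panel)
  if (S < 2L) return(NULL)
  i1 <- seq_len(S - 1L)
  same <- panel$sites$chrom[i1] == panel$sites$chrom[i1 + 1L]
  i1 <- i1[same]
  if (!length(i1)) return(NULL)
  J <- 2L * panel$H[, i1, drop = FALSE] + panel$H[, i1 + 1L, drop = FALSE]
  mie <- site_mi_vec(J, hap_breeds(panel), n_sym = 4L)
  data.frame(site1 = i1, site2 = i1 + 1L,
             chrom = panel$sites$chrom[i1],
             pos1 = panel$sites$pos[i1], pos2 = panel$sites$pos[i1 + 1L],
             mie = mie, stringsAsFactors = FALSE)
}

#' Select discriminative adjacent-locus SNP pairs
#'
#' Evaluates the two-locus MIE on every consecutive same-chromosome site
#' pair at the haplotype level and keeps pairs with `MIE > theta`; when
#' `n_perm > 0`, a label-permutation p-value is attached to each kept pair
#' and pairs with `p >= p_cutoff` are dropped.  The union of member sites
#' of the kept pairs is the discriminative SNP set.
#'
#' @param panel a recoded, phased [haplotype_panel()].
#' @param theta MIE selection threshold in nats.
#' @param n_perm permutations per kept pair (0 = no p-values).
#' @param p_cutoff permutation p-value cutoff applied when `n_perm > 0`.
#' @param seed RNG seed for the permutation stream.
#' @return data.frame with columns `chrom`, `pos1`, `pos2`, `site1`,
#'   `site2`, `mie`, `p_value`; attribute `selected_sites` holds the sorted
#'   union of member site indices.
#' @export
select_discriminative_pairs <- function(panel, theta, n_perm = 0L,
                                        p_cutoff = 0.05, seed = NULL) {
  if (!panel$phased) stop("pair selection requires phased genotypes")
  pairs <- adjacent_pair_mie(panel)
  if (is.null(pairs)) {
    warning("fewer than 2 sites on every chromosome; no pairs to test")
    out <- data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), site1 = integer(), site2 = integer(),
                      mie = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "selected_sites") <- integer()
    return(out)
  }
  keep <- pairs$mie > theta
  out <- pairs[keep, , drop = FALSE]
  out$p_value <- rep(NA_real_, nrow(out))
  if (n_perm > 0L && nrow(out)) {
    labs <- panel$samples$breed
    H <- panel$H
    J <- 2L * H[, out$site1, drop = FALSE] + H[, out$site2, drop = FALSE]
    obs <- out$mie
    hits <- with_seed(seed, {
      h <- integer(nrow(out))
      for (b in seq_len(n_perm)) {
        perm <- rep(perm_labels(labs), each = 2L)
        h <- h + (site_mi_vec(J, perm, n_sym = 4L) >= obs - 1e-12)
      }
      h
    })
    out$p_value <- (1 + hits) / (n_perm + 1)
    out <- out[out$p_value < p_cutoff, , drop = FALSE]
  }
  out <- out[, c("chrom", "pos1", "pos2", "site1", "site2", "mie", "p_value")]
  rownames(out) <- NULL
  attr(out, "selected_sites") <- sort(unique(c(out$site1, out$site2)))
  out
}

#' Combine a target breed's MI analyses against several contrast breeds
#'
#' For a target breed compared against each of several contrast breeds,
#' either averages the per-site MI values across the pairwise analyses
#' (`combine = "mean"`) or intersects the discriminative SNP sets selected
#' per pair at threshold `theta` (`combine = "intersect"`).
#'
#' @param panel a recoded [haplotype_panel()] holding all breeds.
#' @param target target breed label.
#' @param contrasts character vector of contrast breed labels.
#' @param combine `"mean"` or `"intersect"`.
#' @param theta MIE threshold for per-pair selection (required for
#'   `"intersect"`).
#' @param level per-site MI level, see [site_mi()].
#' @return For `"mean"`, a numeric vector of averaged per-site MI values;
#'   for `"intersect"`, a sorted integer vector of site indices selected in
#'   every pairwise analysis.
#' @export
combine_contrasts <- function(panel, target, contrasts,
                              combine = c("mean", "intersect"),
                              theta = NULL,
                              level = c("haplotype", "genotype")) {
  combine <- match.arg(combine)
  level <- match.arg(level)
  stopifnot(length(contrasts) >= 1L, !target %in% contrasts)
  if (combine == "mean") {
    per_pair <- vapply(contrasts, function(cb)
      site_mi(subset_breeds(panel, c(target, cb)), level = level),
      numeric(n_sites(panel)))
    rowMeans(per_pair)
  } else {
    if (is.null(theta)) stop("theta is required for combine = \"intersect\"")
    sets <- lapply(contrasts, function(cb)
      attr(select_discriminative_pairs(
        subset_breeds(panel, c(target, cb)), theta = theta),
        "selected_sites"))
    sort(Reduce(intersect, sets))
  }
}
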