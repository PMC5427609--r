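#' Extended haplotype homozygosity curve from a core site
#'
#' Starting at the core (EHH = 1 at distance 0), haplotypes are progressively
#' partitioned by their alleles at successive flanking sites and
#' `EHH = sum_h C(n_h, 2) / C(n, 2)` over the extended-haplotype groups h.
#' The walk stops at the first site whose EHH falls below `truncation`; that
#' point is excluded from the curve.
#'
#' @param H 0/1 haplotype matrix (haplotypes x sites) of one population on
#'   one chromosome, columns in position order.
#' @param core core site index (column of `H`).
#' @param direction `"left"` or `"right"`.
#' @param positions bp position of every column of `H`.
#' @param truncation EHH level below which the curve is truncated.
#' @return data.frame with columns `distance` (bp, starting at 0) and `ehh`.
#' @export
ehh <- function(H, core, direction = c("left", "right"), positions,
                truncation = 0.05) {
  direction <- match.arg(direction)
  n <- nrow(H)
  if (n < 2L) stop("need at least 2 haplotypes")
  stopifnot(core >= 1L, core <= ncol(H), length(positions) == ncol(H))
  step <- if (direction == "left") -1L else 1L
  denom <- choose(n, 2)
  g <- rep(1L, n)
  dist <- 0
  val <- 1
  j <- core
  repeat {
    j <- j + step
    if (j < 1L || j > ncol(H)) break
    key <- g * 2L + H[, j]
    g <- match(key, unique(key))
    cnt <- tabulate(g)
    e <- sum(cnt * (cnt - 1) / 2) / denom
    if (e < truncation) break
    dist <- c(dist, abs(positions[j] - positions[core]))
    val <- c(val, e)
    if (e <= 0) break
  }
  data.frame(distance = dist, ehh = val)
}

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of the EHH curves against physical distance (bp),
#' left and right areas summed.
#'
#' @param curve_left,curve_right data.frames from [ehh()].
#' @return Area in bp (>= 0).
#' @export
ihh <- function(curve_left, curve_right) {
  area <- function(cv) {
    if (is.null(cv) || nrow(cv) < 2L) {
      warning("EHH curve collapsed immediately; iHH contribution is 0")
      return(0)
    }
    sum(diff(cv$distance) * (cv$ehh[-1] + cv$ehh[-nrow(cv)]) / 2)
  }
  area(curve_left) + area(curve_right)
}

# iHH for every site of a panel (compiled kernel), per chromosome
panel_ihh <- function(panel, truncation = 0.05) {
  if (!panel$phased) stop("iHH requires phased haplotypes")
  out <- numeric(n_sites(panel))
  for (cc in unique(panel$sites$chrom)) {
    idx <- which(panel$sites$chrom == cc)
    out[idx] <- ihh_scan_cpp(panel$H[, idx, drop = FALSE],
                             as.numeric(panel$sites$pos[idx]), truncation)
  }
  out
}

# 0-based window start per site and full tiling per chromosome
site_windows <- function(sites, window_bp) {
  floor((sites$pos - 1L) / window_bp) * window_bp
}

# Per-window maximum of a per-site score; emits the full non-overlapping
# tiling from 0 to the last occupied window of each chromosome (windows
# without usable scores carry NA).
window_scores_from_sites <- function(sites, score, window_bp = 50000L) {
  ws <- site_windows(sites, window_bp)
  out <- do.call(rbind, lapply(unique(sites$chrom), function(cc) {
    on_c <- sites$chrom == cc
    starts <- seq(0L, max(ws[on_c]), by = window_bp)
    key <- match(ws[on_c], starts)
    n_snps <- tabulate(key, length(starts))
    stat <- rep(NA_real_, length(starts))
    ok <- on_c & !is.na(score)
    if (any(ok)) {
      agg <- tapply(score[ok], match(ws[ok], starts), max)
      stat[as.integer(names(agg))] <- agg
    }
    data.frame(chrom = cc, start = starts, end = starts + window_bp,
               n_snps = n_snps, stat = stat, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-population XP-EHH scan
#'
#' Per shared site, `raw = ln(iHH_A / iHH_B)`; positive scores indicate
#' selection in population A.  Raw scores are normalised to genome-wide
#' mean 0 / sd 1, the genome is tiled into non-overlapping windows, and the
#' per-window statistic is the maximum (normalised, by default) score of
#' the window's SNPs.  Sites where either iHH is 0 are skipped and counted.
#'
#' @param panel_a,panel_b phased [haplotype_panel()]s of the two populations
#'   on identical sites.
#' @param window_bp window size in bp.
#' @param truncation EHH truncation level.
#' @param window_stat `"normalized"` or `"raw"` per-window maximum.
#' @return List with `sites` (chrom, pos, ihh_a, ihh_b, xpehh_raw,
#'   xpehh_norm) and `windows` (chrom, start, end, n_snps, stat).
#' @export
xpehh_scan <- function(panel_a, panel_b, window_bp = 50000L,
                       truncation = 0.05,
                       window_stat = c("normalized", "raw")) {
  window_stat <- match.arg(window_stat)
  if (!identical(panel_a$sites[c("chrom", "pos")],
                 panel_b$sites[c("chrom", "pos")]))
    stop("panels must share identical sites")
  ihh_a <- panel_ihh(panel_a, truncation)
  ihh_b <- panel_ihh(panel_b, truncation)
  ok <- ihh_a > 0 & ihh_b > 0
  if (!all(ok))
    message("xpehh_scan: skipped ", sum(!ok), " site(s) with zero iHH")
  raw <- rep(NA_real_, length(ihh_a))
  raw[ok] <- log(ihh_a[ok] / ihh_b[ok])
  mu <- mean(raw[ok])
  sdv <- sd(raw[ok])
  norm <- (raw - mu) / if (sdv > 0) sdv else 1
  sites <- data.frame(chrom = panel_a$sites$chrom, pos = panel_a$sites$pos,
                      ihh_a = ihh_a, ihh_b = ihh_b,
                      xpehh_raw = raw, xpehh_norm = norm,
                      stringsAsFactors = FALSE)
  score <- if (window_stat == "normalized") norm else raw
  list(sites = sites,
       windows = window_scores_from_sites(sites, score, window_bp))
}

#' SNP-count binning and empirical window p-values
#'
#' Windows are binned by SNP count in increments of `bin_increment`
#' (`bin = floor(n_snps / bin_increment)`); within each bin the empirical
#' p-value of window i is the fraction of windows in the bin whose
#' statistic is strictly greater.  The selection flag marks windows with a
#' positive statistic and `empirical_p < p_cutoff`.  Windows with `NA`
#' statistics are excluded from the bins.
#'
#' @param windows data.frame with columns `n_snps` and `stat` (e.g. from
#'   [xpehh_scan()]).
#' @param bin_increment SNP-count bin width.
#' @param p_cutoff empirical p-value cutoff for the selection flag.
#' @return `windows` with added `bin`, `empirical_p` and `selected`.
#' @export
bin_empirical_p <- function(windows, bin_increment = 500L, p_cutoff = 0.01) {
  windows$bin <- windows$n_snps %/% bin_increment
  windows$empirical_p <- NA_real_
  usable <- !is.na(windows$stat)
  if (any(!usable & windows$n_snps > 0L))
    message("bin_empirical_p: ", sum(!usable & windows$n_snps > 0L),
            " SNP-bearing window(s) without a statistic excluded")
  for (b in unique(windows$bin[usable])) {
    ix <- which(usable & windows$bin == b)
    st <- windows$stat[ix]
    gt <- vapply(st, function(v) sum(st > v), numeric(1))
    windows$empirical_p[ix] <- gt / length(ix)
  }
  windows$selected <- !is.na(windows$empirical_p) &
    windows$stat > 0 & windows$empirical_p < p_cutoff
  windows
}

#' Simplified XP-CLR-style windowed differentiation scan
#'
#' Composite log-likelihood-ratio scan for excess multi-locus allele
#' frequency differentiation of population A from population B.  Under the
#' neutral model, A's sample frequency at a site varies around B's with
#' drift variance `omega * p(1-p)` (`omega` estimated genome-wide unless
#' supplied); the differentiated model inflates the variance by a factor
#' `c` maximised over `grid`.  Per 50-kb window the `max_snps`
#' most-differentiated SNPs are kept, and any SNP whose genotype
#' correlation with an already-kept SNP exceeds `redundancy_r` contributes
#' weight 0.  Windows are ranked and the top `top_fraction` flagged.
#'
#' @param tern_a,tern_b [ternary_matrix()]es of the two populations on
#'   identical sites.
#' @param window_bp window size in bp.
#' @param max_snps maximum SNPs scored per window.
#' @param redundancy_r correlation level above which a SNP's contribution
#'   is down-weighted to zero.
#' @param grid candidate drift-inflation factors (> 1).
#' @param top_fraction fraction of windows flagged as candidate sweeps.
#' @param omega neutral drift variance scale; `NULL` to estimate from all
#'   polymorphic sites.
#' @return data.frame of windows with `n_snps`, `stat` (composite LR),
#'   `bin`, `empirical_p` and `selected` (top-fraction rule).
#' @export
xpclr_lite <- function(tern_a, tern_b, window_bp = 50000L, max_snps = 600L,
                       redundancy_r = 0.95,
                       grid = c(2.5, 5, 10, 25, 50, 100),
                       top_fraction = 0.01, omega = NULL) {
  stopifnot(redundancy_r > 0, redundancy_r <= 1, length(grid) >= 1L,
            all(grid > 1))
  if (!identical(tern_a$sites[c("chrom", "pos")],
                 tern_b$sites[c("chrom", "pos")]))
    stop("matrices must share identical sites")
  na <- 2L * nrow(tern_a$G); nb <- 2L * nrow(tern_b$G)
  fa <- colSums(tern_a$G) / na
  xb <- colSums(tern_b$G)
  pb <- (xb + 0.5) / (nb + 1)          # shrunk away from 0/1
  vb <- pb * (1 - pb)
  poly <- (colSums(tern_a$G) + xb) > 0 & (colSums(tern_a$G) + xb) < na + nb
  if (is.null(omega)) {
    if (!any(poly)) stop("no polymorphic sites; cannot estimate omega")
    omega <- mean((fa[poly] - pb[poly])^2 / vb[poly])
  }
  loglik <- function(idx, c_fac) {
    v <- vb[idx] * (c_fac * omega + 1 / (2 * na))
    sum(-0.5 * log(2 * pi * v) - (fa[idx] - pb[idx])^2 / (2 * v))
  }

  sites <- tern_a$sites
  ws <- site_windows(sites, window_bp)
  windows <- window_scores_from_sites(sites, rep(0, nrow(sites)), window_bp)
  windows$stat <- 0
  for (w in seq_len(nrow(windows))) {
    idx <- which(sites$chrom == windows$chrom[w] &
                   ws == windows$start[w] & poly)
    if (!length(idx)) next
    idx <- idx[order(-abs(fa[idx] - pb[idx]), idx)]
    if (length(idx) > max_snps) idx <- idx[seq_len(max_snps)]
    if (length(idx) > 1L) {
      X <- rbind(tern_a$G[, idx, drop = FALSE], tern_b$G[, idx, drop = FALSE])
      cm <- suppressWarnings(abs(cor(X)))
      cm[is.na(cm)] <- 0
      keep <- logical(length(idx))
      keep[1] <- TRUE
      for (j in seq_along(idx)[-1])
        keep[j] <- all(cm[j, keep] <= redundancy_r)
      idx <- idx[keep]
    }
    ll0 <- loglik(idx, 1)
    ll1 <- max(vapply(grid, function(cf) loglik(idx, cf), numeric(1)))
    windows$stat[w] <- max(0, ll1 - ll0)
  }
  windows <- bin_empirical_p(windows)
  occupied <- windows$n_snps > 0L
  top_n <- max(1L, floor(top_fraction * sum(occupied)))
  rank_ <- rank(-windows$stat, ties.method = "first")
  windows$selected <- occupied & windows$stat > 0 & rank_ <= top_n
  attr(windows, "omega") <- omega
  windows
}

#' Assign candidate genes to selected windows
#'
#' A gene is a candidate iff its interval intersects a selected window
#' extended by `flank_bp` on both sides (partial overlap counts).
#'
#' @param windows data.frame of (selected) windows with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param genes gene annotation data.frame (0-based half-open).
#' @param flank_bp symmetric window extension in bp.
#' @return Sorted character vector of candidate gene ids.
#' @export
assign_candidate_genes <- function(windows, genes, flank_bp = 25000L) {
  if (!nrow(windows)) return(character())
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = pmax(1L, windows$start - flank_bp + 1L),
                     end = windows$end + flank_bp))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, win_gr)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Intersect two candidate gene lists
#'
#' @param list_a,list_b character vectors of gene ids.
#' @return Their intersection, sorted by gene id.
#' @export
intersect_gene_lists <- function(list_a, list_b) {
  sort(intersect(list_a, list_b))
}

#' Read an external per-site selection score file
#'
#' Whitespace-delimited `chrom pos score` (no header), e.g. scores produced
#' by external XP-CLR/XP-EHH programs, usable as a drop-in replacement for
#' the built-in scans via [window_scores()].
#'
#' @param path score file.
#' @return data.frame with `chrom`, `pos`, `score`.
#' @export
read_score_file <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 2L) df <- cbind(chrom = "chr1", df)
  if (ncol(df) < 3L) stop("expected columns: chrom pos score in ", path)
  names(df)[1:3] <- c("chrom", "pos", "score")
  df[order(df$chrom, df$pos), 1:3]
}

#' Per-window maximum of per-site scores
#'
#' @param scores data.frame with `chrom`, `pos`, `score` (e.g. from
#'   [read_score_file()]).
#' @param window_bp window size in bp.
#' @return Window data.frame as in [xpehh_scan()].
#' @export
window_scores <- function(scores, window_bp = 50000L) {
  window_scores_from_sites(scores, scores$score, window_bp)
}
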