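test_that("EHH curves match a pairwise-identity oracle and are non-increasing", {
  set.seed(301)
  for (rep_i in 1:5) {
    H <- matrix(rbinom(8 * 20, 1, runif(1, 0.3, 0.7)), nrow = 8)
    pos <- sort(sample.int(5000, 20))
    core <- sample(3:18, 1)
    for (dir in c("left", "right")) {
      cv <- ehh(H, core, dir, pos, truncation = 0)
      step <- if (dir == "left") -1L else 1L
      # oracle: fraction of haplotype pairs identical over the whole span
      for (k in seq_len(nrow(cv))[-1]) {
        j <- core + step * (k - 1L)
        span <- if (dir == "left") j:core else core:j
        span <- setdiff(span, core)
        n_id <- 0
        for (a in 1:7) for (b in (a + 1):8)
          if (all(H[a, span] == H[b, span])) n_id <- n_id + 1
        expect_equal(cv$ehh[k], n_id / choose(8, 2), tolerance = 1e-12)
        expect_equal(cv$distance[k], abs(pos[j] - pos[core]))
      }
      expect_true(all(diff(cv$ehh) <= 1e-12))
      expect_equal(cv$ehh[1], 1)
      expect_equal(cv$distance[1], 0)
    }
  }
  # 4 haplotypes split into 4 singleton groups two sites out -> EHH = 0
  H2 <- matrix(c(0L, 1L, 0L, 1L,     # core site
                 0L, 0L, 1L, 1L,     # splits into pairs
                 0L, 1L, 1L, 0L),    # completes the split
               nrow = 4)
  cv <- ehh(H2, 1, "right", c(100, 200, 300), truncation = 0)
  expect_equal(cv$ehh[length(cv$ehh)], 0)
  expect_error(ehh(H2[1, , drop = FALSE], 1, "right", c(100, 200, 300)),
               "2 haplotypes")
})

test_that("iHH integrates EHH curves: rectangle, collapse, refinement", {
  # EHH == 1 over d bp on each side -> area 2d
  H <- matrix(0L, nrow = 6, ncol = 11)
  pos <- seq(0, 10000, by = 1000) + 1
  cvL <- ehh(H, 6, "left", pos)
  cvR <- ehh(H, 6, "right", pos)
  expect_equal(ihh(cvL, cvR), 10000)
  # immediate collapse -> 0 (with a warning per collapsed side)
  flat <- data.frame(distance = 0, ehh = 1)
  expect_warning(expect_warning(expect_equal(ihh(flat, flat), 0),
                                "collapsed"), "collapsed")
  # trapezoid equals a 10x-finer linear-interpolation oracle
  set.seed(302)
  cv <- data.frame(distance = c(0, sort(sample.int(5000, 15))),
                   ehh = c(1, sort(runif(15, 0.05, 1), decreasing = TRUE)))
  fine_d <- seq(0, max(cv$distance), length.out = 10 * nrow(cv))
  fine_e <- approx(cv$distance, cv$ehh, xout = fine_d)$y
  oracle <- sum(diff(fine_d) * (fine_e[-1] + fine_e[-length(fine_e)]) / 2)
  expect_equal(suppressWarnings(ihh(cv, flat)), oracle, tolerance = 0.005)
})

test_that("compiled iHH scan equals the R EHH + trapezoid path site by site", {
  set.seed(303)
  for (rep_i in 1:3) {
    p <- random_panel(8, 60, rep(c("a", "b"), 4), seed = 303 + rep_i)
    p <- recode_major_minor(p)
    fast <- breedsig:::panel_ihh(p, truncation = 0.05)
    for (j in sample(60, 15)) {
      slow <- ihh(ehh(p$H, j, "left", p$sites$pos, truncation = 0.05),
                  ehh(p$H, j, "right", p$sites$pos, truncation = 0.05))
      expect_equal(fast[j], slow, tolerance = 1e-9)
    }
  }
})

test_that("XP-EHH: identity gives zero, swapping populations negates, moments hold", {
  p <- recode_major_minor(random_panel(12, 150, rep(c("a", "b"), 6),
                                       seed = 304))
  a <- subset_breeds(p, "a"); b <- subset_breeds(p, "b")
  self_scan <- xpehh_scan(a, a)
  expect_true(all(abs(self_scan$sites$xpehh_raw) < 1e-12, na.rm = TRUE))
  ab <- xpehh_scan(a, b)
  ba <- xpehh_scan(b, a)
  expect_equal(ab$sites$xpehh_raw, -ba$sites$xpehh_raw, tolerance = 1e-12)
  ok <- !is.na(ab$sites$xpehh_raw)
  expect_equal(mean(ab$sites$xpehh_norm[ok]), 0, tolerance = 1e-9)
  expect_equal(sd(ab$sites$xpehh_norm[ok]), 1, tolerance = 1e-9)
  # window tiling is a partition of the SNPs
  expect_equal(sum(ab$windows$n_snps), n_sites(a))
  b_short <- haplotype_panel(b$H[, -1], b$sites[-1, ], b$samples,
                             recoded = TRUE)
  expect_error(xpehh_scan(a, b_short), "identical sites")
})

test_that("a planted sweep puts the top genome-wide window inside the footprint", {
  sim <- simulate_panel(sim_config(seed = 7))
  p <- recode_major_minor(sim$panel)
  sc <- xpehh_scan(subset_breeds(p, "breed1"), subset_breeds(p, "breed2"))
  w <- bin_empirical_p(sc$windows)
  sw <- sim$truth$sweep_windows[[1]]
  imax <- which.max(w$stat)
  expect_true(w$start[imax] < sw$end && w$end[imax] > sw$start)
  expect_lt(w$empirical_p[imax], 0.01)
  expect_true(w$selected[imax])
})

test_that("empirical window p-values match brute force and use strict ties", {
  set.seed(305)
  w <- data.frame(chrom = "chr1", start = (0:199) * 50000,
                  end = (1:200) * 50000,
                  n_snps = sample.int(1500, 200), stat = rnorm(200))
  out <- bin_empirical_p(w)
  expect_equal(out$bin, w$n_snps %/% 500L)
  for (i in sample(200, 50)) {
    same_bin <- which(out$bin == out$bin[i])
    expect_equal(out$empirical_p[i],
                 sum(w$stat[same_bin] > w$stat[i]) / length(same_bin))
  }
  # the top window of its bin has p = 0
  for (b in unique(out$bin)) {
    ix <- which(out$bin == b)
    expect_equal(out$empirical_p[ix[which.max(out$stat[ix])]], 0)
  }
  # all-tied windows all get p = 0 (strict inequality)
  w2 <- w; w2$stat <- 1
  expect_true(all(bin_empirical_p(w2)$empirical_p == 0))
})

test_that("xpclr-lite: redundancy rule, null vs planted contrast, top-1% rank", {
  set.seed(306)
  mk_tern <- function(G, pos) {
    n <- nrow(G)
    ternary_matrix(G, data.frame(chrom = "chr1", pos = as.integer(pos),
                                 ref = "A", alt = "T",
                                 stringsAsFactors = FALSE),
                   data.frame(sample_id = sprintf("s%02d", 1:n),
                              breed = "x", stringsAsFactors = FALSE))
  }
  n_sites <- 2000
  pos <- sort(sample.int(5e6, n_sites))
  freq <- runif(n_sites, 0.1, 0.9)
  draw <- function() matrix(rbinom(10 * n_sites, 2, rep(freq, each = 10)),
                            nrow = 10)
  Ga <- draw(); Gb <- draw()
  # plant strong differentiation: 10 sites in one window near-fixed in A,
  # ~0.5 in B
  win_sites <- which(pos >= 2e6 & pos < 2.05e6)[1:10]
  Ga[, win_sites] <- 2L
  Gb[, win_sites] <- matrix(rbinom(10 * 10, 2, 0.5), nrow = 10)
  ta <- mk_tern(Ga, pos); tb <- mk_tern(Gb, pos)
  sc <- xpclr_lite(ta, tb)
  planted_w <- which(sc$start == 2e6)
  expect_true(sc$selected[planted_w])
  occupied <- sc$n_snps > 0
  expect_lte(rank(-sc$stat)[planted_w], max(1, floor(0.01 * sum(occupied))))

  # identical matrices: no window beats the planted-differentiation window
  for (sd in 1:5) {
    set.seed(400 + sd)
    Gn <- draw()
    null_sc <- xpclr_lite(mk_tern(Gn, pos), mk_tern(Gn, pos))
    expect_lt(max(null_sc$stat), sc$stat[planted_w])
  }

  # duplicating a SNP column (r = 1 > 0.95) leaves the window stat
  # unchanged (omega fixed so the genome-wide variance estimate does not
  # shift with the extra column)
  om <- attr(sc, "omega")
  sc_fixed <- xpclr_lite(ta, tb, omega = om)
  dup <- win_sites[1]
  ins <- function(G, j) cbind(G[, 1:j, drop = FALSE], G[, j, drop = FALSE],
                              G[, (j + 1):ncol(G), drop = FALSE])
  pos2 <- sort(c(pos, pos[dup] + 1L))
  sc2 <- xpclr_lite(mk_tern(ins(Ga, dup), pos2), mk_tern(ins(Gb, dup), pos2),
                    omega = om)
  expect_equal(sc2$stat[sc2$start == 2e6],
               sc_fixed$stat[sc_fixed$start == 2e6], tolerance = 1e-9)
})

test_that("candidate-gene assignment respects the 25-kb flank boundaries", {
  win <- data.frame(chrom = "chr1", start = 100000L, end = 150000L)
  g <- function(id, s, e) data.frame(gene_id = id, chrom = "chr1",
                                     start = s, end = e,
                                     stringsAsFactors = FALSE)
  genes <- rbind(
    g("inside", 110000L, 120000L),        # wholly inside
    g("flank_only", 160000L, 170000L),    # overlaps only the +25kb flank
    g("touch_edge", 50000L, 75001L),      # last base = start - 25kb exactly
    g("too_far", 40000L, 75000L),         # ends 1 bp before the flank
    g("other_chr", 110000L, 120000L))
  genes$chrom[genes$gene_id == "other_chr"] <- "chr2"
  out <- assign_candidate_genes(win, genes, flank_bp = 25000L)
  expect_setequal(out, c("inside", "flank_only", "touch_edge"))
  expect_equal(assign_candidate_genes(win[0, ], genes), character())
})

test_that("gene list intersection is a sorted set intersection", {
  expect_equal(intersect_gene_lists(c("b", "a"), c("c", "d")), character())
  expect_equal(intersect_gene_lists(c("b", "a"), c("c", "a", "b")),
               c("a", "b"))
  expect_equal(intersect_gene_lists(character(), "a"), character())
})

test_that("external score files feed the same windowing machinery", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "scores.txt")
  writeLines(c("chr1 10000 1.5", "chr1 60000 2.5", "chr1 61000 0.5"), f)
  sc <- read_score_file(f)
  w <- window_scores(sc, window_bp = 50000L)
  expect_equal(nrow(w), 2L)
  expect_equal(w$stat, c(1.5, 2.5))
  expect_equal(w$n_snps, c(1L, 2L))
})
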