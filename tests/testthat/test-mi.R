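test_that("entropy of count vectors matches the plug-in formula", {
  expect_equal(entropy(c(5, 5)), log(2), tolerance = 1e-12)
  expect_equal(entropy(10), 0)
  # 10-vs-9 split, evaluated directly
  p <- c(10, 9) / 19
  expect_equal(entropy(c(10, 9)), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(entropy(c(10, 9)), 0.6918, tolerance = 1e-4)
  expect_equal(entropy(c(0, 3, 0)), 0)  # zero counts contribute nothing
  expect_error(entropy(c(0, 0)), "positive total")
  expect_error(entropy(c(-1, 2)), "nonnegative")
})

test_that("a perfect separator attains the class-label entropy; degenerate cases", {
  labs <- rep(c("ndama", "other"), c(10, 9))
  marker <- as.integer(labs == "ndama")
  expect_equal(mutual_information(marker, labs)$value, entropy(c(10, 9)),
               tolerance = 1e-12)
  expect_equal(mutual_information(rep(1L, 19), labs)$value, 0)
  expect_error(mutual_information(marker, rep("x", 19)), "two classes")
})

test_that("joint-sum MI equals the entropy-difference form and respects its bounds", {
  set.seed(101)
  for (i in 1:1000) {
    cs <- random_mi_case(n = sample(8:30, 1), n_sym1 = sample(2:4, 1),
                         n_class = sample(2:3, 1))
    v <- mutual_information(cs$s1, cs$labels)$value
    expect_lt(abs(v - mi_entropy_oracle(cs$s1, cs$labels)), 1e-12)
    expect_gte(v, 0)
    ent <- function(x) entropy(table(x))
    expect_lte(v, min(ent(cs$s1), ent(cs$labels)) + 1e-12)
  }
})

test_that("MI is invariant to symbol relabeling and sample permutation", {
  set.seed(102)
  for (i in 1:50) {
    cs <- random_mi_case(n = 25, n_sym1 = 3)
    v <- mutual_information(cs$s1, cs$labels)$value
    expect_equal(mutual_information(letters[cs$s1 + 1], cs$labels)$value, v,
                 tolerance = 1e-12)
    perm <- sample(length(cs$s1))
    expect_equal(mutual_information(cs$s1[perm], cs$labels[perm])$value, v,
                 tolerance = 1e-12)
  }
})

test_that("conditional MI and the two-locus MIE satisfy the chain rule", {
  set.seed(103)
  for (i in 1:1000) {
    cs <- random_mi_case(n = sample(10:30, 1), n_sym1 = sample(2:3, 1),
                         n_sym2 = sample(2:3, 1), n_class = sample(2:3, 1))
    mie <- mie_two_locus(cs$s1, cs$s2, cs$labels)
    cmi <- conditional_mi(cs$s1, cs$s2, cs$labels)
    mi2 <- mutual_information(cs$s2, cs$labels)$value
    expect_lt(abs(mie - (cmi + mi2)), 1e-12)
    # MIE equals MI of the concatenated symbol variable
    expect_lt(abs(mie - mi_entropy_oracle(paste(cs$s1, cs$s2), cs$labels)),
              1e-12)
    expect_gte(cmi, 0)
  }
})

test_that("conditional MI degenerate identities", {
  set.seed(104)
  cs <- random_mi_case(n = 24, n_sym1 = 3)
  # conditioning on an identical variable leaves no extra information
  expect_equal(conditional_mi(cs$s1, cs$s1, cs$labels), 0, tolerance = 1e-12)
  # conditioning on a constant recovers plain MI
  expect_equal(conditional_mi(cs$s1, rep(0L, 24), cs$labels),
               mutual_information(cs$s1, cs$labels)$value, tolerance = 1e-12)
})

test_that("two-locus MIE: constants give 0, a jointly separating pair gives H(C)", {
  labs <- rep(c("a", "b"), each = 8)
  expect_equal(mie_two_locus(rep(0L, 16), rep(1L, 16), labs), 0)
  # neither locus separates alone, the pair does
  s1 <- rep(c(0L, 1L, 0L, 1L), each = 4)
  s2 <- rep(c(0L, 1L, 1L, 0L), each = 4)
  expect_equal(mie_two_locus(s1, s2, labs), log(2), tolerance = 1e-12)
  expect_lt(mutual_information(s1, labs)$value, 1e-12)
})

test_that("permutation p-values follow the add-one convention and match enumeration", {
  labs <- c("a", "a", "a", "b", "b", "b")
  vals <- c(5, 4, 3, 2, 1, 0)
  # label-invariant statistic -> p = 1
  expect_equal(permutation_pvalue(function(v, l) 1, vals, labs,
                                  n_perm = 99, seed = 1), 1)
  # observed strictly above every permuted value -> p = 1/(B+1)
  # (distinct labels; seed chosen so no permutation reproduces the
  # original order among 99 draws)
  labs_u <- letters[1:6]
  big_on_obs <- function(v, l) if (identical(l, labs_u)) 100 else 0
  expect_equal(permutation_pvalue(big_on_obs, vals, labs_u,
                                  n_perm = 99, seed = 1), 1 / 100)
  # matches exhaustive enumeration over all 6! label orders; label vectors
  # identical to the observed one are excluded from the enumeration, as
  # the sampler redraws them and the add-one term stands in for them
  vals2 <- c(5, 1, 4, 2, 3, 0)
  stat <- function(v, l) sum(v[l == "a"])
  obs <- stat(vals2, labs)
  perms <- all_perms(6L)
  relab <- apply(perms, 1, function(ix) paste(labs[ix], collapse = ""))
  non_obs <- relab != paste(labs, collapse = "")
  stats <- apply(perms, 1, function(ix) stat(vals2, labs[ix]))
  exact <- mean(stats[non_obs] >= obs)
  p_hat <- permutation_pvalue(stat, vals2, labs, n_perm = 4000, seed = 2)
  expect_lt(abs(p_hat - exact), 0.03)
  # deterministic under seed
  expect_identical(p_hat, permutation_pvalue(stat, vals2, labs,
                                             n_perm = 4000, seed = 2))
})

test_that("KL divergence: closed forms, asymmetry, edge validation", {
  expect_equal(kl_divergence(c(3, 7, 5), c(3, 7, 5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-6)
  expect_gte(kl_divergence(c(1, 0), c(0.5, 0.5)), 0)
  set.seed(105)
  p <- runif(10); q <- runif(10)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_error(kl_divergence(c(1, 2), c(1, 2, 3)), "mismatched bin edges")
  h1 <- hist(runif(50), breaks = seq(0, 1, 0.25), plot = FALSE)
  h2 <- hist(runif(50), breaks = seq(0, 1, 0.5), plot = FALSE)
  expect_error(kl_divergence(h1, h2), "mismatched bin edges")
  h3 <- hist(runif(50), breaks = seq(0, 1, 0.25), plot = FALSE)
  expect_gte(kl_divergence(h1, h3), 0)
})

test_that("vectorised per-site MI agrees with the per-column estimator", {
  set.seed(106)
  p <- recode_major_minor(random_panel(10, 60, rep(c("a", "b"), 5)))
  mi <- site_mi(p)
  labs <- rep(p$samples$breed, each = 2)
  for (j in sample(60, 12))
    expect_equal(mi[j], mutual_information(p$H[, j], labs)$value,
                 tolerance = 1e-12)
  tern_mi <- site_mi(p, level = "genotype")
  for (j in sample(60, 6))
    expect_equal(tern_mi[j],
                 mutual_information(ternary_encode(p)$G[, j],
                                    p$samples$breed)$value,
                 tolerance = 1e-12)
})

test_that("adjacent-pair selection: threshold semantics and planted recovery", {
  set.seed(107)
  p <- recode_major_minor(random_panel(10, 40, rep(c("a", "b"), 5)))
  all_pairs <- select_discriminative_pairs(p, theta = -1)
  expect_equal(nrow(all_pairs), 39L)     # MIE >= 0 always
  expect_true(all(all_pairs$mie >= 0))
  none <- select_discriminative_pairs(p, theta = max(all_pairs$mie) + 1)
  expect_equal(nrow(none), 0L)

  # panel with planted fixed-difference genes: the simulator fixes breed 1
  # for the minor allele inside planted genes; stripping the contrast
  # breed to the opposite allele makes those sites exact fixed differences,
  # so every planted-gene pair must be recovered at 0.9 * H(C)
  sim <- simulate_panel(sim_config(n_sites = 2000, chrom_length = 1e6,
                                   n_genes = 40, signature_genes = 10,
                                   het_genes = 0, sweep_specs = list(),
                                   seed = 42))
  panel <- sim$panel
  gm <- map_snps_to_genes(panel, sim$genes)
  sig_sites <- sort(unique(unlist(
    gm$map[sim$truth$signature_gene_ids], use.names = FALSE)))
  oth <- breedsig:::breed_hap_rows(panel, "breed2")
  panel$H[oth, sig_sites] <- matrix(1L - panel$H[1, sig_sites],
                                    nrow = length(oth),
                                    ncol = length(sig_sites), byrow = TRUE)
  panel <- recode_major_minor(panel)
  hC <- entropy(c(20, 18))
  sel <- select_discriminative_pairs(panel, theta = 0.9 * hC)
  for (gid in sim$truth$signature_gene_ids) {
    in_gene <- gm$map[[gid]]
    planted_pairs <- in_gene[-length(in_gene)]   # pair (i, i+1) inside gene
    planted_pairs <- planted_pairs[(planted_pairs + 1L) %in% in_gene]
    expect_true(all(planted_pairs %in% sel$site1))
  }
  expect_true(all(sel$mie > 0.9 * hC))
  # selected-site union is consistent
  expect_identical(attr(sel, "selected_sites"),
                   sort(unique(c(sel$site1, sel$site2))))
})

test_that("pair selection warns and returns empty on single-site chromosomes", {
  p <- recode_major_minor(random_panel(6, 1, rep(c("a", "b"), 3), seed = 2))
  expect_warning(out <- select_discriminative_pairs(p, theta = 0),
                 "fewer than 2 sites")
  expect_equal(nrow(out), 0L)
})

test_that("multi-contrast combining averages MI or intersects SNP sets", {
  sim <- simulate_panel(sim_config(n_breeds = 3,
                                   samples_per_breed = c(10, 9, 10),
                                   n_sites = 600, chrom_length = 5e5,
                                   n_genes = 10, signature_genes = 3,
                                   het_genes = 0, sweep_specs = list(),
                                   seed = 31))
  p <- recode_major_minor(sim$panel)
  avg <- combine_contrasts(p, "breed1", c("breed2", "breed3"), "mean")
  manual <- (site_mi(subset_breeds(p, c("breed1", "breed2"))) +
               site_mi(subset_breeds(p, c("breed1", "breed3")))) / 2
  expect_equal(avg, manual, tolerance = 1e-12)

  inter <- combine_contrasts(p, "breed1", c("breed2", "breed3"),
                             "intersect", theta = 0.3)
  s12 <- attr(select_discriminative_pairs(
    subset_breeds(p, c("breed1", "breed2")), theta = 0.3), "selected_sites")
  s13 <- attr(select_discriminative_pairs(
    subset_breeds(p, c("breed1", "breed3")), theta = 0.3), "selected_sites")
  expect_true(all(inter %in% s12) && all(inter %in% s13))
  expect_setequal(inter, intersect(s12, s13))
  expect_error(combine_contrasts(p, "breed1", "breed2", "intersect"),
               "theta")
})
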