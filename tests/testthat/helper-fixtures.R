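# Shared fixture builders.  Everything is generated in code; no data files.

# A raw (REF/ALT-coded) panel built directly from a haplotype matrix.
# H: 2N x S matrix of 0/1; breeds: one label per sample.
make_panel <- function(H, breeds, pos = NULL, chrom = "chr1") {
  H <- as.matrix(H)
  n <- nrow(H) / 2L
  if (is.null(pos)) pos <- seq_len(ncol(H)) * 100L
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      ref = rep("A", ncol(H)), alt = rep("T", ncol(H)),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        breed = breeds, stringsAsFactors = FALSE)
  haplotype_panel(H, sites, samples)
}

# Random panel: per-haplotype Bernoulli(freq) alleles.
random_panel <- function(n_samples, n_sites, breeds, freq = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(n_sites, 0.05, 0.95)
  H <- matrix(rbinom(2L * n_samples * n_sites, 1L,
                     rep(freq, each = 2L * n_samples)),
              nrow = 2L * n_samples)
  make_panel(H, breeds)
}

# Random joint observation set for MI oracles: discrete markers + labels
# (every class guaranteed present).
random_mi_case <- function(n = 20L, n_sym1 = 2L, n_sym2 = 2L, n_class = 2L) {
  stopifnot(n > n_class)
  labels <- c(letters[seq_len(n_class)],
              sample(letters[seq_len(n_class)], n - n_class, replace = TRUE))
  list(s1 = sample.int(n_sym1, n, replace = TRUE) - 1L,
       s2 = sample.int(n_sym2, n, replace = TRUE) - 1L,
       labels = sample(labels))
}

# Independent plug-in MI oracle: H(X) + H(C) - H(X, C) from explicit tables
# (clamped at 0 against -1e-17-scale float residue).
mi_entropy_oracle <- function(x, labels) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  max(0, ent(x) + ent(labels) - ent(paste(x, labels)))
}

# All permutations of seq_len(n) (small n), for exhaustive permutation tests.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# The standard planted fixture shared by recovery tests (cached per session).
standard_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_panel(sim_config(seed = 42L))
    cache
  }
})

expect_tsv_identical <- function(dir1, dir2) {
  f1 <- list.files(dir1)
  expect_setequal(f1, list.files(dir2))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = paste("file differs:", f))
}
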