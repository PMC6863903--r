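test_that("strain simulation is deterministic and tree-consistent", {
  t1 <- small_truth(seed = 7)
  t2 <- small_truth(seed = 7)
  expect_identical(t1, t2)

  # Hamming distance between strains equals the substitution count on the
  # tree path separating them (no back-mutation at this scale)
  h <- truth_haplotypes(t1)
  d <- pairwise_snv_distance(h)
  co <- ape::cophenetic.phylo(t1$tree)[rownames(d), colnames(d)]
  expect_equal(unname(co), unname(d * 1.0))

  # materialized sequences agree with the state matrix
  ss <- strain_sequences(t1)
  expect_equal(as.integer(Biostrings::neditAt(ss[[1]], ss[[4]])), d[1, 4])
})

test_that("a single strain yields no variation", {
  tr <- small_truth(n_strains = 1L, clade_sizes = 1L)
  expect_equal(sum(tr$sites$type == "assigned"), 0)
})

test_that("two-strain divergence follows the Poisson substitution model", {
  tr <- small_truth(n_strains = 2L, clade_sizes = c(1L, 1L), d_between = 100,
                    d_within = 0, seed = 1)
  h <- truth_haplotypes(tr)
  d <- pairwise_snv_distance(h)[1, 2]
  expect_gte(d, qpois(0.005, 100))
  expect_lte(d, qpois(0.995, 100))
})

test_that("single-linkage clustering of Hamming distances recovers planted clades", {
  tr <- small_truth(seed = 3)
  d <- pairwise_snv_distance(truth_haplotypes(tr))
  # independent oracle: hclust single linkage cut at the midpoint scale
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  k <- stats::cutree(hc, h = mean(range(d[upper.tri(d)])))
  expect_equal(length(unique(k)), 2)
  expect_true(all(tapply(tr$clade_map, k, function(x) length(unique(x))) == 1))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(clade_sizes = c(2, 2)), "sum to n_strains")
  expect_error(sim_config(seq_error = 0.3), "seq_error")
  expect_error(sim_config(coverage = 1), "coverage")
  expect_error(sim_config(genome_length = 30001, n_genes = 10), "multiple of 3")
  # back-mutation guard: expected substitutions above 10% of the genome
  expect_error(sim_config(d_between = 2e5, genome_length = 30000L,
                          n_genes = 10L),
               "back-mutation")
})

test_that("counts reflect true allele frequencies", {
  # one strain at frequency 1, no error: all sites monomorphic
  tr <- small_truth(n_strains = 1L, clade_sizes = 1L, seq_error = 0,
                    invariant_snv_rate = 0, n_samples = 2L)
  cm <- simulate_counts(tr, n_monomorphic = 60)
  pc <- pooled_counts(cm)
  expect_true(all(rowSums(pc > 0) == 1))

  # 0.5/0.5 mixture at high coverage: alt fraction inside binomial 99% CI
  tr2 <- small_truth(n_strains = 2L, clade_sizes = c(1L, 1L),
                     d_between = 100, d_within = 0, seq_error = 0,
                     invariant_snv_rate = 0, n_samples = 1L,
                     coverage = 1000, seed = 5)
  tr2$strain_freqs[1, ] <- c(0.5, 0.5)
  tr2$true_freq <- tr2$states %*% t(tr2$strain_freqs)
  cm2 <- simulate_counts(tr2)
  x <- cm2$counts[, 1, ]
  cov <- rowSums(x)
  alt_i <- match(tr2$sites$alt, c("A", "C", "G", "T"))
  altc <- x[cbind(seq_len(nrow(x)), alt_i)]
  lo <- qbinom(0.005, cov, 0.5)
  hi <- qbinom(0.995, cov, 0.5)
  expect_gt(mean(altc >= lo & altc <= hi), 0.95)

  # sequencing error alone: non-reference fraction about seq_error
  tr3 <- small_truth(n_strains = 1L, clade_sizes = 1L, seq_error = 0.01,
                     invariant_snv_rate = 0, n_samples = 1L,
                     coverage = 200, seed = 9)
  cm3 <- simulate_counts(tr3, n_monomorphic = 100)
  pc3 <- pooled_counts(cm3)
  ref_i <- match(tr3$ref_genome[cm3$sites$pos +
                                  (match(cm3$sites$gene_id,
                                         sprintf("gene%04d", 1:10)) - 1) *
                                  tr3$gene_length], c("A", "C", "G", "T"))
  nonref <- 1 - pc3[cbind(seq_len(nrow(pc3)), ref_i)] / rowSums(pc3)
  n_tot <- sum(rowSums(pc3))
  expect_lt(abs(mean(nonref) - 0.01), 3 * sqrt(0.01 * 0.99 / (n_tot / 100)))
})

test_that("invariant sites share one global frequency across samples", {
  tr <- small_truth(seed = 21, invariant_snv_rate = 0.2)
  inv <- tr$sites$type == "invariant"
  expect_gt(sum(inv), 0)
  tf <- tr$true_freq[inv, , drop = FALSE]
  expect_true(all(apply(tf, 1, function(r) diff(range(r)) == 0)))
  expect_true(all(tf[, 1] >= 0.05 & tf[, 1] <= 0.95))
})

test_that("true allele frequencies are the strain-weighted mixtures", {
  tr <- small_truth(seed = 11, seq_error = 0)
  asn <- tr$sites$type == "assigned"
  expected <- tr$states[asn, , drop = FALSE] %*% t(tr$strain_freqs)
  expect_equal(unname(tr$true_freq[asn, ]), unname(expected))
  # empirical count fractions approach them at high coverage
  cfg <- tr$config
  cfg$coverage <- 2000
  cm <- simulate_counts(tr, config = cfg)
  alt_i <- match(tr$sites$alt, c("A", "C", "G", "T"))
  x <- cm$counts[, 1, ]
  f_hat <- x[cbind(seq_len(nrow(x)), alt_i)] / rowSums(x)
  expect_lt(max(abs(f_hat[asn] - tr$true_freq[asn, 1])), 0.06)
})

test_that("gene abundance simulation plants exact groups and outliers", {
  ga <- simulate_gene_abundances(720, 2, 10, noise_sd = 0, outlier_rate = 0,
                                 seed = 2)
  grp <- split(ga$truth$gene_id, ga$truth$group)
  for (g in grp) {
    sub <- ga$coverage[g, , drop = FALSE]
    if (nrow(sub) > 1)
      expect_true(all(abs(stats::cor(t(sub)) - 1) < 1e-12))
  }
  ga2 <- simulate_gene_abundances(800, 2, 12, noise_sd = 0.05,
                                  outlier_rate = 0.01, seed = 2)
  expect_equal(sum(ga2$truth$is_outlier), 8)
  expect_error(simulate_gene_abundances(500), ">= 700")
})

test_that("founder scenario is reproducible and yields valid mixtures", {
  tr <- small_truth(seed = 4, scenario = "founder")
  tr2 <- small_truth(seed = 4, scenario = "founder")
  expect_identical(tr$strain_freqs, tr2$strain_freqs)
  expect_true(all(abs(rowSums(tr$strain_freqs) - 1) < 1e-9))
})
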