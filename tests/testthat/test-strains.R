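test_that("pairwise SNV distances are a Hamming metric on planted truth", {
  tr <- small_truth(seed = 17)
  h <- truth_haplotypes(tr)
  d <- pairwise_snv_distance(h)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # equals planted per-pair substitution counts
  expect_equal(d[1, 2], sum(tr$states[, 1] != tr$states[, 2]))
  # triangle inequality
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j])
})

test_that("percent identity arithmetic and bounds", {
  expect_equal(percent_identity(0, 1000), 100.00)
  expect_equal(percent_identity(5, 1000), 99.50)
  expect_error(percent_identity(5, 0), "> 0")
  expect_error(percent_identity(20, 10), "exceed")
})

test_that("clade assignment respects thresholds and input order", {
  tr <- small_truth(seed = 19)
  d <- pairwise_snv_distance(truth_haplotypes(tr))
  cl <- assign_clades(d)  # largest-gap default
  expect_equal(unname(table(cl)), unname(table(tr$clade_map)))
  expect_true(all(tapply(tr$clade_map, cl, function(x) length(unique(x))) == 1))
  # extreme thresholds
  expect_equal(length(unique(assign_clades(d, threshold = 1))), nrow(d))
  expect_equal(length(unique(assign_clades(d, threshold = max(d) + 1))), 1)
  # permuting strain order permutes labels consistently
  p <- sample(nrow(d))
  clp <- assign_clades(d[p, p])
  same <- outer(cl, cl, "==")
  samep <- outer(clp[rownames(d)], clp[rownames(d)], "==")
  expect_equal(unname(same), unname(samep))
})

test_that("presence and dominance thresholds are inclusive", {
  f <- rbind(A = c(0.96, 0.04), B = c(0.5, 0.5), C = c(0.90, 0.10))
  colnames(f) <- c("s1", "s2")
  r <- strain_presence_and_dominance(f)
  expect_equal(r$present, c("s1", "s1,s2", "s1,s2"))
  expect_equal(r$dominant, c("s1", NA, "s1"))
  expect_error(strain_presence_and_dominance(rbind(c(0.5, 0.2))), "sum to 1")
})

test_that("dominant haplotype reconstruction follows the 90% rule", {
  m <- make_acm(list(S1 = rbind(c(95, 5, 0, 0), c(89, 11, 0, 0),
                                c(0, 0, 0, 0))))
  hap <- dominant_haplotype(m, "S1")
  expect_equal(unname(hap), c("A", NA, NA))

  # a sample dominated by one strain reproduces that strain's alleles
  tr <- small_truth(seed = 23, seq_error = 0, invariant_snv_rate = 0,
                    coverage = 300, n_samples = 1L)
  tr$strain_freqs[1, ] <- c(0.97, 0.03, 0, 0, 0, 0)
  tr$true_freq <- tr$states %*% t(tr$strain_freqs)
  cm <- simulate_counts(tr)
  hap <- dominant_haplotype(cm, "M01")
  truth_allele <- ifelse(tr$states[, 1] == 1, tr$sites$alt, tr$sites$ref)
  ok <- !is.na(hap)
  expect_gt(mean(ok), 0.95)
  expect_equal(unname(hap[ok]), truth_allele[ok])
})

test_that("differential SNVs exclude sites undefined in either haplotype", {
  h1 <- c(a = "A", b = "C", c = NA, d = "G", e = "T")
  h2 <- c(a = "A", b = "G", c = "A", d = NA, e = "C")
  r <- differential_snvs(h1, h2)
  expect_equal(as.integer(r), 2)
  expect_equal(attr(r, "n_excluded"), 2)
  expect_equal(as.integer(differential_snvs(h1, h1)), 0)
  expect_error(differential_snvs(h1, h2[c(2, 1, 3, 4, 5)]), "same site set")
})

test_that("ancestral states use strain majority with designated tie break", {
  states <- rbind(c(0, 0, 1), c(0, 0, 0), c(1, 1, 1))
  colnames(states) <- c("a", "b", "c")
  h <- strain_haplotypes(states, data.frame(gene_id = "g", pos = 1:3,
                                            ref = "A", alt = "G"),
                         alignment_length = 5)
  anc <- ancestral_states(h, "c")
  expect_equal(anc$state, c(0L, 0L, 1L))
  expect_equal(anc$allele, c("A", "A", "G"))
  # even split: tie-break tip decides
  st2 <- cbind(a = c(0L), b = c(1L))
  h2 <- strain_haplotypes(st2, data.frame(gene_id = "g", pos = 1,
                                          ref = "A", alt = "G"),
                          alignment_length = 1)
  expect_equal(ancestral_states(h2, "b")$allele, "G")
  expect_equal(ancestral_states(h2, "a")$allele, "A")
  expect_error(ancestral_states(h2, "zz"), "unknown strain")
})

test_that("derived allele frequencies are complements of ancestral ones", {
  m <- make_acm(list(S1 = rbind(c(10, 90, 0, 0))))
  anc <- data.frame(gene_id = "g1", pos = 1, allele = "C")
  a <- derived_afs(m, "S1", anc, n_bins = 10)
  expect_equal(a$freqs, 0.1)
  expect_equal(sum(a$counts), 1)
  expect_equal(a$counts[1], 1L)  # 0.1 falls in the (0,0.1] bin
})

test_that("AFS modes sit at the strain-mixture frequencies", {
  tr <- small_truth(n_strains = 2L, clade_sizes = c(1L, 1L), d_between = 200,
                    d_within = 0, seq_error = 0, invariant_snv_rate = 0,
                    coverage = 800, n_samples = 1L, seed = 29)
  tr$strain_freqs[1, ] <- c(0.7, 0.3)
  tr$true_freq <- tr$states %*% t(tr$strain_freqs)
  cm <- simulate_counts(tr)
  h <- truth_haplotypes(tr)
  anc <- ancestral_states(h, colnames(h$states)[1])
  a <- derived_afs(cm, "M01", anc, n_bins = 20)
  # sites where the two strains differ have derived frequency near 0.3 or 0.7
  support <- a$mids[a$counts > 0]
  gap <- apply(abs(outer(support, c(0.3, 0.7), "-")), 1, min)
  expect_true(all(gap < 0.1))
  # single dominant strain: mass collapses to the spectrum edges
  tr2 <- small_truth(n_strains = 1L, clade_sizes = 1L, seq_error = 0,
                     invariant_snv_rate = 0.3, coverage = 500,
                     n_samples = 1L, seed = 31)
  cm2 <- simulate_counts(tr2, n_monomorphic = 30)
  h2 <- truth_haplotypes(tr2)
  anc2 <- ancestral_states(h2, colnames(h2$states)[1])
  a2 <- derived_afs(cm2, "M01", anc2)
  expect_equal(sum(a2$counts), a2$n_sites)
})

test_that("haplotype and frequency TSV round trips preserve content", {
  tr <- small_truth(seed = 37)
  h <- truth_haplotypes(tr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes_tsv(h, path, header = "unit test")
  h2 <- read_haplotypes_tsv(path, alignment_length = h$alignment_length)
  expect_equal(unname(h2$states), unname(h$states))
  expect_equal(h2$sites$pos, h$sites$pos)

  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_frequencies_tsv(tr$strain_freqs, fpath)
  f2 <- read_frequencies_tsv(fpath)
  expect_equal(f2, tr$strain_freqs, tolerance = 1e-12)
})
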