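test_that("pi_intra matches hand-derived single-site values", {
  m <- make_acm(list(S1 = matrix(c(3, 1, 0, 0), 1)))
  expect_equal(pi_intra(m, "S1", 1)$value, 0.5)
  m2 <- make_acm(list(S1 = matrix(c(2, 2, 0, 0), 1)))
  expect_equal(pi_intra(m2, "S1", 1)$value, 2 / 3)
  m3 <- make_acm(list(S1 = matrix(c(7, 0, 0, 0), 1)))
  expect_equal(pi_intra(m3, "S1", 1)$value, 0)
  expect_error(pi_intra(m, "S1", 0), "genome_length")
  expect_error(pi_intra(m, "nope", 1), "unknown sample")
})

test_that("pi_intra equals exhaustive read-pair enumeration", {
  set.seed(101)
  n <- 1000
  counts <- matrix(rpois(4 * n, 2), n, 4)
  counts[rowSums(counts) < 2, 1] <- 2  # ensure usable coverage
  m <- make_acm(list(S1 = counts))
  got <- pi_intra(m, "S1", n)$value
  want <- mean(vapply(seq_len(n), function(i) pi_site_pair_oracle(counts[i, ]),
                      0))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("pi_inter matches independent-draw enumeration and is symmetric", {
  m <- make_acm(list(S1 = matrix(c(4, 0, 0, 0), 1),
                     S2 = matrix(c(7, 0, 0, 0), 1)))
  expect_equal(pi_inter(m, "S1", "S2", 1)$value, 0)
  m2 <- make_acm(list(S1 = matrix(c(2, 2, 0, 0), 1),
                      S2 = matrix(c(1, 3, 0, 0), 1)))
  expect_equal(pi_inter(m2, "S1", "S2", 1)$value, 0.5)
  m3 <- make_acm(list(S1 = matrix(c(4, 0, 0, 0), 1),
                      S2 = matrix(c(0, 5, 0, 0), 1)))
  expect_equal(pi_inter(m3, "S1", "S2", 1)$value, 1.0)

  set.seed(202)
  n <- 1000
  c1 <- matrix(rpois(4 * n, 2), n, 4); c1[rowSums(c1) == 0, 2] <- 1
  c2 <- matrix(rpois(4 * n, 2), n, 4); c2[rowSums(c2) == 0, 3] <- 1
  m4 <- make_acm(list(S1 = c1, S2 = c2))
  got <- pi_inter(m4, "S1", "S2", n)$value
  want <- mean(vapply(seq_len(n), function(i)
    pi_inter_site_oracle(c1[i, ], c2[i, ]), 0))
  expect_equal(got, want, tolerance = 1e-10)
  expect_equal(pi_inter(m4, "S2", "S1", n)$value, got)
})

test_that("F_ST follows its defining identity and degenerate cases", {
  # fixed difference at every site: F_ST = 1 exactly
  d <- 20
  c1 <- matrix(0, d, 4); c1[, 1] <- 30
  c2 <- matrix(0, d, 4); c2[, 2] <- 30
  m <- make_acm(list(S1 = c1, S2 = c2))
  expect_equal(fst(m, "S1", "S2", d)$value, 1.0)

  m2 <- make_acm(list(S1 = matrix(c(2, 2, 0, 0), 1),
                      S2 = matrix(c(1, 3, 0, 0), 1)))
  expect_equal(fst(m2, "S1", "S2", 1)$value,
               1 - (2 / 3 + 1 / 2) / (2 * 0.5))

  m3 <- make_acm(list(S1 = matrix(c(5, 0, 0, 0), 1),
                      S2 = matrix(c(9, 0, 0, 0), 1)))
  expect_warning(r <- fst(m3, "S1", "S2", 1), "undefined")
  expect_true(is.na(r$value))
})

test_that("F_ST never exceeds 1 on random count data", {
  set.seed(33)
  for (rep in 1:20) {
    cc <- lapply(1:2, function(i) matrix(rpois(40, 3) + 1, 10, 4))
    m <- make_acm(list(S1 = cc[[1]], S2 = cc[[2]]))
    v <- suppressWarnings(fst(m, "S1", "S2", 10)$value)
    if (!is.na(v)) expect_lte(v, 1)
  }
})

test_that("expected N/S enumeration matches per-codon brute force", {
  expect_equal(expected_ns_ratio("TTT"), c(N = 8, S = 1))
  expect_equal(expected_ns_ratio("ATG"), c(N = 9, S = 0))
  expect_equal(expected_ns_ratio("TTTATG"), c(N = 17, S = 1))
  expect_warning(expected_ns_ratio("TTN"), "non-ACGT")
  expect_error(expected_ns_ratio("TTTA"), "divisible by 3")
  # additivity over a random gene
  set.seed(5)
  gene <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  parts <- substring(gene, seq(1, 30, 3), seq(3, 30, 3))
  per <- rowSums(vapply(parts, expected_ns_ratio, c(N = 0, S = 0)))
  expect_equal(suppressWarnings(expected_ns_ratio(gene)), per)
})

test_that("pN/pS handles observed SNVs and the pseudocount", {
  # TTT -> TTC at codon position 3 is synonymous
  r <- pnps(data.frame(pos = 3, ref = "T", alt = "C"), "TTTTTC")
  expect_equal(r$obs_n, 0)
  expect_equal(r$obs_s, 1)
  expect_equal(r$pnps, 0)
  r2 <- pnps(data.frame(pos = integer(), ref = character(),
                        alt = character()), "TTTTTC")
  expect_equal(r2$pnps, 0)
  # nonsynonymous change with no synonymous observed: pseudocount keeps it finite
  r3 <- pnps(data.frame(pos = 1, ref = "T", alt = "G"), "TTTTTC")
  expect_equal(r3$obs_n, 1)
  expect_true(is.finite(r3$pnps))
})

test_that("genome-wide pN/pS is near 1 for uniformly placed SNVs", {
  tr <- small_truth(seed = 13, genome_length = 60000L, n_genes = 20L,
                    d_between = 1500, d_within = 300)
  genes <- reference_genes(tr)
  snvs <- data.frame(gene_id = tr$sites$gene_id, pos = tr$sites$pos,
                     ref = tr$sites$ref, alt = tr$sites$alt)
  gw <- suppressWarnings(pnps_pooled(split(snvs, snvs$gene_id), genes))
  # binomial test of observed N fraction against the mutational opportunity
  p0 <- gw$exp_n / (gw$exp_n + gw$exp_s)
  pv <- binom.test(gw$obs_n, gw$obs_n + gw$obs_s, p = p0)$p.value
  expect_gt(pv, 0.001)
})

test_that("divergence classification separates strain and clade level", {
  states <- rbind(c(0, 0, 1), c(0, 1, 1), c(0, 0, 0))
  colnames(states) <- c("a", "b", "c")
  h <- strain_haplotypes(states,
                         data.frame(gene_id = "g", pos = 1:3,
                                    ref = "A", alt = "G"),
                         clade_map = c(a = "C1", b = "C1", c = "C2"),
                         alignment_length = 10)
  # site 1: varies, uniform within clades -> divergent at both levels
  # site 2: varies within clade C1 -> clade-level polymorphic
  # site 3: invariant -> polymorphic at both levels
  expect_equal(classify_divergence(h, "strain"),
               c("divergent", "divergent", "polymorphic"))
  expect_equal(classify_divergence(h, "clade"),
               c("divergent", "polymorphic", "polymorphic"))
  h$clade_map <- NULL
  expect_error(classify_divergence(h, "clade"), "clade_map")
})

test_that("neutrality index is the ratio of the two component ratios", {
  r <- neutrality_index(100, 100, 100, 100)
  expect_equal(r$ni, 1.0)
  expect_equal(r$dn_ds, 1.0)
  expect_warning(r0 <- neutrality_index(5, 0, 3, 2), "dS = 0")
  expect_true(is.na(r0$ni))
  expect_warning(neutrality_index(5, 2, 3, 0), "pS = 0")
  expect_error(neutrality_index(-1, 2, 3, 4), "nonnegative")
})
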