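# Independent oracles kept deliberately naive: they re-derive the target
# quantities by enumeration rather than sharing code with the package.

# Fraction of differing unordered read pairs at one site, by explicit
# enumeration of every pair of reads.
pi_site_pair_oracle <- function(counts4) {
  reads <- rep(c("A", "C", "G", "T"), counts4)
  n <- length(reads)
  if (n < 2) return(0)
  diff <- 0L
  tot <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1L
    if (reads[i] != reads[j]) diff <- diff + 1L
  }
  diff / tot
}

# P(one read from each sample differs) by summation over ordered allele pairs.
pi_inter_site_oracle <- function(c1, c2) {
  f1 <- c1 / sum(c1)
  f2 <- c2 / sum(c2)
  s <- 0
  for (a in 1:4) for (b in 1:4) if (a != b) s <- s + f1[a] * f2[b]
  s
}

# Weighted UniFrac via an independent traversal: per-edge descendant tip sets
# from phangorn::Descendants instead of postorder accumulation.
unifrac_oracle <- function(tree, a, b) {
  a <- a[tree$tip.label]
  b <- b[tree$tip.label]
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- phangorn::Descendants(tree, tree$edge[e, 2], type = "tips")[[1]]
    pa <- sum(a[tips])
    pb <- sum(b[tips])
    num <- num + tree$edge.length[e] * abs(pa - pb)
    den <- den + tree$edge.length[e] * (pa + pb)
  }
  num / den
}

# Build a one-or-more-site allele_counts from a list of per-sample count
# vectors: counts_list[[sample]][site, base].
make_acm <- function(counts_list, samples = names(counts_list)) {
  ns <- nrow(counts_list[[1]])
  cnt <- array(0, c(ns, length(counts_list), 4))
  for (j in seq_along(counts_list)) cnt[, j, ] <- counts_list[[j]]
  allele_counts(cnt, data.frame(gene_id = "g1", pos = seq_len(ns)), samples)
}

small_truth <- function(seed = 42, scenario = "dirichlet", ...) {
  args <- utils::modifyList(
    list(n_strains = 6L, clade_sizes = c(3L, 3L), d_between = 300,
         d_within = 60, genome_length = 30000L, n_genes = 10L,
         n_samples = 6L, coverage = 100, seq_error = 0.001, seed = seed),
    list(...))
  simulate_strains(do.call(sim_config, args), scenario = scenario)
}

truth_haplotypes <- function(truth) {
  strain_haplotypes(truth$states,
                    truth$sites[, c("gene_id", "pos", "ref", "alt")],
                    tree = truth$tree, clade_map = truth$clade_map,
                    alignment_length = truth$config$genome_length)
}

bin_labels <- function(bins, gene_ids) {
  lab <- rep("unbinned", length(gene_ids))
  names(lab) <- gene_ids
  for (i in seq_along(bins)) lab[bins[[i]]$members] <- paste0("bin", i)
  lab
}
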