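#' Configuration for the synthetic symbiont community simulator
#'
#' Defaults emulate the sulfur-oxidizer (SOX) data regime of the study system
#' this package was developed for: 11 strains in four clades (4 + 3 + 3 + 1)
#' over a ~1.27 Mbp core genome, 19 host samples, ~482x mean coverage, a
#' Dirichlet(0.3) strain mixture per sample that yields dominant-strain hosts,
#' and ~4.7 percent of SNV sites carrying unassigned ("invariant") variation.
#' Within-clade strain pairs then differ by roughly \code{d_within} SNVs and
#' between-clade pairs by roughly \code{d_between + d_within}.
#'
#' @param n_strains number of strains.
#' @param clade_sizes integer partition of \code{n_strains} into clades.
#' @param d_between expected number of substitutions separating two clades
#'   (placed on the inter-clade branches of the strain tree).
#' @param d_within expected number of substitutions separating two strains of
#'   the same clade.
#' @param genome_length core-genome length in bp; must be a multiple of 3 and
#'   of \code{n_genes}, with a gene length that is a whole number of codons.
#' @param n_genes number of equal-length core genes the genome is split into.
#' @param n_samples number of metagenomic samples (hosts).
#' @param coverage mean reads per site (per-site depth is Poisson with this
#'   mean).
#' @param seq_error per-base sequencing error probability; an erroneous read
#'   base is replaced by one of the three other nucleotides uniformly.
#' @param dirichlet_alpha concentration of the per-sample Dirichlet strain
#'   mixture; small values produce dominant-strain samples.
#' @param invariant_snv_rate fraction of the total SNV set that is invariant
#'   in the strain alignment (population-wide unassigned variants).
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_strains = 11L,
                       clade_sizes = c(4L, 3L, 3L, 1L),
                       d_between = 6000,
                       d_within = 1200,
                       genome_length = 1269900L,
                       n_genes = 100L,
                       n_samples = 19L,
                       coverage = 482,
                       seq_error = 0.001,
                       dirichlet_alpha = 0.3,
                       invariant_snv_rate = 0.047,
                       seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              clade_sizes = as.integer(clade_sizes),
              d_between = d_between, d_within = d_within,
              genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              coverage = coverage, seq_error = seq_error,
              dirichlet_alpha = dirichlet_alpha,
              invariant_snv_rate = invariant_snv_rate,
              seed = as.integer(seed))
  if (sum(cfg$clade_sizes) != cfg$n_strains)
    stop_strainpop("clade_sizes must sum to n_strains")
  if (any(cfg$clade_sizes < 1)) stop_strainpop("clade sizes must be >= 1")
  if (cfg$seq_error < 0 || cfg$seq_error >= 0.25)
    stop_strainpop("seq_error must be in [0, 0.25)")
  if (cfg$coverage < 2) stop_strainpop("coverage must be >= 2")
  if (cfg$genome_length %% 3L != 0L)
    stop_strainpop("genome_length must be a multiple of 3")
  if (cfg$genome_length %% cfg$n_genes != 0L ||
      (cfg$genome_length %/% cfg$n_genes) %% 3L != 0L)
    stop_strainpop("genome_length must split into n_genes whole-codon genes")
  if (cfg$invariant_snv_rate < 0 || cfg$invariant_snv_rate >= 1)
    stop_strainpop("invariant_snv_rate must be in [0, 1)")
  # Substitutions are placed without back-mutation; that approximation only
  # holds while the expected substitution load is a small fraction of the
  # genome.
  exp_subs <- length(cfg$clade_sizes) * cfg$d_between / 2 +
    cfg$n_strains * cfg$d_within / 2
  if (exp_subs > 0.1 * cfg$genome_length)
    stop_strainpop("expected substitutions exceed 10% of genome_length; ",
                   "back-mutation would no longer be negligible")
  class(cfg) <- "sim_config"
  cfg
}

# Dirichlet(alpha) rows via normalized gamma draws.
rdirichlet_rows <- function(n, k, alpha) {
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  # guard against all-zero rows at tiny alpha
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, sample.int(k, sum(zero), replace = TRUE)] <- 1
  g / rowSums(g)
}

#' Simulate clade-structured strain core genomes and sample mixtures
#'
#' Builds a strain tree (clade ancestors attached to the root, strains
#' attached to their clade ancestor), draws Poisson-distributed substitution
#' counts per branch with expectations \code{d_between / 2} on root-to-clade
#' branches and \code{d_within / 2} on clade-to-strain branches, and assigns
#' each substitution to a distinct genome position so that the Hamming
#' distance between two strains equals the number of substitutions on the
#' tree path separating them (no back-mutation). Invariant SNV sites --
#' population-wide variants that belong to no strain -- are added at distinct
#' positions, each with a single global alternative-allele frequency shared
#' across samples. Per-sample strain mixtures are Dirichlet draws; the
#' \code{"founder"} scenario instead passes a common pool through per-host
#' serial bottlenecks, a qualitative emulation of symbiont self-infection.
#'
#' @param config a \code{\link{sim_config}}.
#' @param scenario \code{"dirichlet"} (default) or \code{"founder"}.
#' @param bottleneck founder scenario only: number of cells resampled per
#'   colonization round.
#' @return an object of class \code{synthetic_truth}: reference genome,
#'   per-site truth table, strain state matrix, strain tree (edge lengths in
#'   substitution counts), clade map, per-sample strain frequencies and true
#'   per-site alternative-allele frequencies per sample.
#' @seealso \code{\link{simulate_counts}}, \code{\link{strain_sequences}}
#' @export
simulate_strains <- function(config, scenario = c("dirichlet", "founder"),
                             bottleneck = 10L) {
  stopifnot(inherits(config, "sim_config"))
  scenario <- match.arg(scenario)
  set.seed(substream_seed(config$seed, 1L))
  L <- config$genome_length
  n <- config$n_strains
  k <- length(config$clade_sizes)
  strain_ids <- sprintf("S%02d", seq_len(n))
  clade_map <- stats::setNames(rep(sprintf("C%d", seq_len(k)),
                                   config$clade_sizes), strain_ids)

  ref <- sample(NUCS, L, replace = TRUE)

  # edges: one per clade (root -> clade ancestor) and one per strain
  # (ancestor -> tip); singleton clades collapse both into the tip edge.
  # Root-to-clade edges only create variation when there are >= 2 clades
  # (a single clade's edge would mutate every strain identically).
  has_clade_edges <- n > 1 && k > 1
  edge_exp <- c(if (has_clade_edges) rep(config$d_between / 2, k),
                if (n > 1) rep(config$d_within / 2, n))
  edge_desc <- c(if (has_clade_edges)
                   lapply(sprintf("C%d", seq_len(k)), function(cl)
                     strain_ids[clade_map == cl]),
                 if (n > 1) as.list(strain_ids))
  if (n == 1) { edge_exp <- 0; edge_desc <- list(strain_ids) }
  n_sub <- stats::rpois(length(edge_exp), edge_exp)
  total <- sum(n_sub)
  if (total > L) stop_strainpop("drew more substitutions than genome sites")
  pos <- sort(sample.int(L, total))
  edge_of <- rep(seq_along(n_sub), n_sub)[sample.int(max(total, 0))]

  states <- matrix(0L, nrow = total, ncol = n,
                   dimnames = list(NULL, strain_ids))
  for (i in seq_len(total))
    states[i, edge_desc[[edge_of[i]]]] <- 1L
  alt <- vapply(pos, function(p) sample(setdiff(NUCS, ref[p]), 1), "")

  # invariant SNVs: r/(1-r) relative to the assigned set
  r <- config$invariant_snv_rate
  n_inv <- if (total > 0) round(r / (1 - r) * total) else 0L
  inv_pos <- if (n_inv > 0)
    sort(sample(setdiff(seq_len(L), pos), n_inv)) else integer(0)
  inv_alt <- vapply(inv_pos, function(p) sample(setdiff(NUCS, ref[p]), 1), "")
  inv_freq <- stats::runif(n_inv, 0.05, 0.95)

  gene_len <- L %/% config$n_genes
  all_pos <- c(pos, inv_pos)
  o <- order(all_pos)
  sites <- data.frame(
    pos_genome = all_pos,
    gene_id = sprintf("gene%04d", (all_pos - 1L) %/% gene_len + 1L),
    pos = (all_pos - 1L) %% gene_len + 1L,
    ref = ref[all_pos],
    alt = c(alt, inv_alt),
    type = rep(c("assigned", "invariant"), c(total, n_inv)),
    invariant_freq = c(rep(NA_real_, total), inv_freq))[o, , drop = FALSE]
  rownames(sites) <- NULL
  states_all <- rbind(states, matrix(0L, n_inv, n))[o, , drop = FALSE]
  colnames(states_all) <- strain_ids

  # strain tree in Newick, edge lengths = realized substitution counts
  tree <- NULL
  if (n >= 2) {
    tip_sub <- n_sub[(if (has_clade_edges) k else 0) + seq_len(n)]
    clade_sub <- if (has_clade_edges) n_sub[seq_len(k)] else rep(0L, k)
    tip_lab <- function(members)
      paste(sprintf("%s:%d", members, tip_sub[match(members, strain_ids)]),
            collapse = ",")
    if (k == 1) {
      txt <- paste0("(", tip_lab(strain_ids), ");")
    } else {
      clade_str <- vapply(seq_len(k), function(ci) {
        members <- strain_ids[clade_map == sprintf("C%d", ci)]
        if (length(members) == 1)
          sprintf("%s:%d", members,
                  tip_sub[match(members, strain_ids)] + clade_sub[ci])
        else sprintf("(%s):%d", tip_lab(members), clade_sub[ci])
      }, "")
      txt <- paste0("(", paste(clade_str, collapse = ","), ");")
    }
    tree <- ape::read.tree(text = txt)
  }

  sample_ids <- sprintf("M%02d", seq_len(config$n_samples))
  freqs <- switch(scenario,
    dirichlet = rdirichlet_rows(config$n_samples, n, config$dirichlet_alpha),
    founder = {
      pool <- as.vector(rdirichlet_rows(1, n, config$dirichlet_alpha))
      t(vapply(seq_len(config$n_samples), function(s) {
        f <- pool
        for (rnd in seq_len(s %% 5 + 1))  # serial bottlenecks deepen with host age rank
          f <- as.vector(stats::rmultinom(1, bottleneck, f)) / bottleneck
        f
      }, numeric(n)))
    })
  dimnames(freqs) <- list(sample_ids, strain_ids)

  true_freq <- states_all[, , drop = FALSE] %*% t(freqs)  # sites x samples
  inv_rows <- sites$type == "invariant"
  true_freq[inv_rows, ] <- sites$invariant_freq[inv_rows]
  colnames(true_freq) <- sample_ids

  structure(list(config = config, ref_genome = ref, sites = sites,
                 states = states_all, tree = tree, clade_map = clade_map,
                 strain_freqs = freqs, true_freq = true_freq,
                 gene_length = gene_len, scenario = scenario),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", x$config$n_strains, "strains /",
      length(x$config$clade_sizes), "clades,",
      sum(x$sites$type == "assigned"), "assigned +",
      sum(x$sites$type == "invariant"), "invariant SNV sites,",
      x$config$n_samples, "samples\n")
  invisible(x)
}

#' Materialize full strain genome sequences
#'
#' @param truth a \code{synthetic_truth}.
#' @return \code{Biostrings::DNAStringSet} with one genome per strain.
#' @export
strain_sequences <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  seqs <- vapply(colnames(truth$states), function(st) {
    g <- truth$ref_genome
    mut <- truth$states[, st] == 1L
    g[truth$sites$pos_genome[mut]] <- truth$sites$alt[mut]
    paste(g, collapse = "")
  }, "")
  Biostrings::DNAStringSet(seqs)
}

#' Reference gene sequences of a synthetic genome
#'
#' @param truth a \code{synthetic_truth}.
#' @return \code{DNAStringSet} of the equal-length, in-frame core genes.
#' @export
reference_genes <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  gl <- truth$gene_length
  n <- truth$config$n_genes
  seqs <- vapply(seq_len(n), function(i)
    paste(truth$ref_genome[((i - 1) * gl + 1):(i * gl)], collapse = ""), "")
  names(seqs) <- sprintf("gene%04d", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate pileup allele counts from a synthetic community
#'
#' At each SNV site (assigned and invariant) and sample, read depth is drawn
#' as Poisson(\code{coverage}) and reads are drawn from the true
#' alternative-allele frequency of the sample; each read base is then flipped
#' to one of the other three nucleotides with probability \code{seq_error}.
#' A configurable number of monomorphic background sites can be included to
#' exercise error-rate and filtering code.
#'
#' @param truth a \code{synthetic_truth}.
#' @param config simulation config; defaults to \code{truth$config}.
#' @param n_monomorphic number of invariant (truly monomorphic) background
#'   sites to include.
#' @return an \code{\link{allele_counts}} object.
#' @export
simulate_counts <- function(truth, config = truth$config, n_monomorphic = 0L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(substream_seed(config$seed, 2L))
  sites <- truth$sites[, c("gene_id", "pos", "ref", "alt", "pos_genome")]
  tf <- truth$true_freq
  if (n_monomorphic > 0) {
    free <- setdiff(seq_len(config$genome_length), truth$sites$pos_genome)
    mp <- sort(sample(free, n_monomorphic))
    gl <- truth$gene_length
    mono <- data.frame(gene_id = sprintf("gene%04d", (mp - 1L) %/% gl + 1L),
                       pos = (mp - 1L) %% gl + 1L,
                       ref = truth$ref_genome[mp],
                       alt = NA_character_, pos_genome = mp)
    sites <- rbind(sites, mono)
    tf <- rbind(tf, matrix(0, n_monomorphic, ncol(tf)))
  }
  ns <- nrow(sites); nsam <- ncol(tf)
  e <- config$seq_error
  cnt <- array(0L, c(ns, nsam, 4L))
  ref_i <- match(sites$ref, NUCS)
  alt_i <- match(sites$alt, NUCS)
  for (j in seq_len(nsam)) {
    depth <- stats::rpois(ns, config$coverage)
    for (i in seq_len(ns)) {
      p <- numeric(4)
      p[ref_i[i]] <- 1 - tf[i, j]
      if (!is.na(alt_i[i])) p[alt_i[i]] <- p[alt_i[i]] + tf[i, j]
      p_err <- p * (1 - e) + (1 - p) * e / 3
      cnt[i, j, ] <- stats::rmultinom(1, depth[i], p_err)
    }
  }
  allele_counts(cnt, sites[, c("gene_id", "pos")],
                rownames(truth$strain_freqs))
}

#' Simulate a gene abundance matrix with planted co-abundant groups
#'
#' Generates one large planted group (an MGS-sized core genome of
#' \code{n_core_genes} genes) plus \code{n_cag_groups} smaller co-abundant
#' gene groups. Genes of a group share one latent per-sample abundance
#' profile (log-normal across samples) multiplied by gene- and cell-level
#' multiplicative log-normal noise of relative standard deviation
#' \code{noise_sd}. A fraction \code{outlier_rate} of core genes is displaced
#' by about 30 unscaled MADs from the group median in one random sample, so
#' the 24 x MAD core-genome filter has true positives to find.
#'
#' @param n_core_genes size of the planted MGS group (>= 700 so an MGS
#'   exists under the >= 700 genes rule).
#' @param n_cag_groups number of smaller planted groups (sizes drawn in
#'   10..60).
#' @param n_samples number of samples.
#' @param noise_sd relative multiplicative noise (sd of log-normal on log
#'   scale).
#' @param outlier_rate fraction of core genes displaced to coverage outliers.
#' @param seed integer seed.
#' @return list of class \code{gene_abundance_sim}: \code{coverage} (gene x
#'   sample matrix) and \code{truth} (gene_id, group, is_outlier).
#' @export
simulate_gene_abundances <- function(n_core_genes = 800L, n_cag_groups = 5L,
                                     n_samples = 19L, noise_sd = 0.05,
                                     outlier_rate = 0.01, seed = 1L) {
  if (n_core_genes < 700)
    stop_strainpop("n_core_genes must be >= 700 so a planted MGS exists")
  set.seed(substream_seed(seed, 3L))
  sizes <- c(n_core_genes,
             if (n_cag_groups > 0) sample(10:60, n_cag_groups, replace = TRUE))
  groups <- rep(sprintf("G%02d", seq_along(sizes)), sizes)
  n_genes <- length(groups)
  profiles <- t(vapply(seq_along(sizes), function(g)
    stats::rlnorm(n_samples, meanlog = log(30), sdlog = 1), numeric(n_samples)))
  covm <- profiles[match(groups, sprintf("G%02d", seq_along(sizes))), ,
                   drop = FALSE]
  if (noise_sd > 0)
    covm <- covm * matrix(stats::rlnorm(n_genes * n_samples,
                                        -noise_sd^2 / 2, noise_sd),
                          n_genes, n_samples)
  rownames(covm) <- sprintf("g%05d", seq_len(n_genes))
  colnames(covm) <- sprintf("M%02d", seq_len(n_samples))

  # Coverage outliers emulate mapping artifacts: a ~30 unscaled-MAD
  # displacement in one sample. They are planted in low-coverage samples so
  # the gene's overall covariation (hence its bin membership) is preserved
  # and the displacement is a pure test of the MAD rule.
  is_outlier <- rep(FALSE, n_genes)
  core <- which(groups == "G01")
  n_out <- round(outlier_rate * length(core))
  if (n_out > 0) {
    out_genes <- sample(core, n_out)
    is_outlier[out_genes] <- TRUE
    med_s <- apply(covm[core, , drop = FALSE], 2, stats::median)
    low <- order(med_s)[seq_len(max(1L, n_samples %/% 4))]
    for (g in out_genes) {
      s <- low[sample.int(length(low), 1)]
      med <- med_s[s]
      mad_u <- stats::median(abs(covm[core, s] - med))
      covm[g, s] <- med + 30 * mad_u + 0.01 * med
    }
  }
  structure(list(coverage = covm,
                 truth = data.frame(gene_id = rownames(covm), group = groups,
                                    is_outlier = is_outlier)),
            class = "gene_abundance_sim")
}

#' Write all synthetic-community artifacts to a directory
#'
#' Emits strain genomes (FASTA), reference genes (FASTA), the strain tree
#' (Newick), strain haplotypes (TSV), per-sample strain frequencies (TSV),
#' pileup counts (TSV) and a truth summary (JSON).
#'
#' @param truth a \code{synthetic_truth}.
#' @param counts an \code{allele_counts} from \code{\link{simulate_counts}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(truth, counts, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(strains = file.path(dir, "strains.fasta"),
             genes = file.path(dir, "genes.fasta"),
             tree = file.path(dir, "strains.nwk"),
             haplotypes = file.path(dir, "haplotypes.tsv"),
             frequencies = file.path(dir, "strain_frequencies.tsv"),
             counts = file.path(dir, "counts.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(strain_sequences(truth), paths["strains"])
  Biostrings::writeXStringSet(reference_genes(truth), paths["genes"])
  if (!is.null(truth$tree)) ape::write.tree(truth$tree, paths["tree"])
  h <- strain_haplotypes(states = truth$states,
                         sites = truth$sites[, c("gene_id", "pos", "ref", "alt")],
                         tree = truth$tree, clade_map = truth$clade_map,
                         alignment_length = truth$config$genome_length)
  write_haplotypes_tsv(h, paths["haplotypes"],
                       header = sprintf("seed=%d", truth$config$seed))
  write_frequencies_tsv(truth$strain_freqs, paths["frequencies"],
                        header = sprintf("seed=%d", truth$config$seed))
  write_counts_tsv(counts, paths["counts"],
                   header = c("simulated pileup counts",
                              sprintf("seed=%d coverage=%g seq_error=%g",
                                      truth$config$seed, truth$config$coverage,
                                      truth$config$seq_error)))
  jsonlite::write_json(
    list(config = unclass(truth$config), scenario = truth$scenario,
         n_assigned = sum(truth$sites$type == "assigned"),
         n_invariant = sum(truth$sites$type == "invariant"),
         clade_map = as.list(truth$clade_map)),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
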