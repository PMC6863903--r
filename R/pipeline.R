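#' Pipeline configuration
#'
#' Collects the input paths (or in-memory objects), thresholds and seed for
#' a full analysis run. All thresholds default to the values used
#' throughout the package; the seed is mandatory because coverage
#' normalization and consensus tie-breaking are stochastic.
#'
#' @param counts allele counts: path to a counts TSV or an
#'   \code{allele_counts}.
#' @param haplotypes strain haplotypes: path to a haplotype TSV or a
#'   \code{strain_haplotypes}.
#' @param tree strain tree: Newick path or \code{phylo}.
#' @param frequencies per-sample strain frequencies: TSV path or matrix.
#' @param genes core gene sequences: FASTA path or \code{DNAStringSet}.
#' @param outdir output directory.
#' @param seed integer seed.
#' @param genome_length core genome length |G|; defaults to the summed gene
#'   lengths.
#' @param normalize thin samples to the smallest median coverage before
#'   analysis (default TRUE).
#' @param present_min,dominant_min,major_min strain presence, dominance and
#'   major-allele thresholds.
#' @param poly_lo,poly_hi polymorphic frequency bounds.
#' @param afs_bins number of AFS histogram bins.
#' @param tie_break_tip strain breaking ancestral-state ties (default:
#'   first strain).
#' @param clade_threshold SNV-distance threshold for clade assignment
#'   (default: largest-gap heuristic).
#' @param n_perm permutations for the matrix association test.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(counts, haplotypes, tree, frequencies, genes,
                            outdir, seed = 1L, genome_length = NULL,
                            normalize = TRUE, present_min = 0.05,
                            dominant_min = 0.90, major_min = 0.90,
                            poly_lo = 0.05, poly_hi = 0.95, afs_bins = 20L,
                            tie_break_tip = NULL, clade_threshold = NULL,
                            n_perm = 999L) {
  structure(list(counts = counts, haplotypes = haplotypes, tree = tree,
                 frequencies = frequencies, genes = genes, outdir = outdir,
                 seed = as.integer(seed), genome_length = genome_length,
                 normalize = normalize, present_min = present_min,
                 dominant_min = dominant_min, major_min = major_min,
                 poly_lo = poly_lo, poly_hi = poly_hi,
                 afs_bins = as.integer(afs_bins),
                 tie_break_tip = tie_break_tip,
                 clade_threshold = clade_threshold,
                 n_perm = as.integer(n_perm)),
            class = "pipeline_config")
}

load_input <- function(x, reader, class_ok) {
  if (inherits(x, class_ok)) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(reader(x))
  stop_strainpop("cannot interpret input of class ", class(x)[1])
}

#' Run the full strain population-genetics pipeline
#'
#' From allele counts, strain haplotypes, a strain tree, per-sample strain
#' frequencies and the core gene sequences, computes: per-sample nucleotide
#' diversity; the pairwise F_ST matrix; per-gene and genome-wide pN/pS; the
#' Neutrality Index at strain and clade level; per-sample derived
#' allele-frequency spectra; strain presence/dominance calls; phylogenetic
#' species evenness per sample; the weighted UniFrac matrix; Spearman
#' association of pi with alpha-diversity and a Mantel-style association of
#' the F_ST and UniFrac matrices. All tables are written to
#' \code{config$outdir} with provenance headers, plus a machine-readable
#' \code{manifest.json}; outputs are byte-identical across reruns with the
#' same seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list of all results (class
#'   \code{strainpop_results}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- load_input(config$counts, read_counts_tsv, "allele_counts")
  h <- load_input(config$haplotypes, read_haplotypes_tsv, "strain_haplotypes")
  tree <- load_input(config$tree, ape::read.tree, "phylo")
  freqs <- load_input(config$frequencies, read_frequencies_tsv, "matrix")
  genes <- load_input(config$genes, Biostrings::readDNAStringSet,
                      "DNAStringSet")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- input consistency -------------------------------------------------
  mism <- c(setdiff(counts$samples, rownames(freqs)),
            setdiff(rownames(freqs), counts$samples))
  if (length(mism) > 0)
    stop_strainpop("sample ids disagree between counts and frequencies: ",
                   paste(unique(mism), collapse = ", "))
  if (!all(colnames(h$states) %in% tree$tip.label))
    stop_strainpop("strains missing from the tree: ",
                   paste(setdiff(colnames(h$states), tree$tip.label),
                         collapse = ", "))
  key_h <- paste(h$sites$gene_id, h$sites$pos, sep = ":")
  key_c <- site_ids(counts)
  gl <- if (is.null(config$genome_length))
    sum(Biostrings::width(genes)) else config$genome_length

  if (config$normalize) counts <- normalize_coverage(counts, seed = seed)
  samples <- counts$samples
  hdr <- function(stat, ...) c(sprintf("statistic=%s", stat),
                               sprintf("seed=%d", seed), ...)

  # --- nucleotide diversity and F_ST ------------------------------------
  pi_tab <- do.call(rbind, lapply(samples, function(s) {
    p <- pi_intra(counts, s, gl)
    data.frame(sample = s, pi = p$value, n_sites_used = p$n_sites_used)
  }))
  write_tsv_header(pi_tab, file.path(config$outdir, "pi.tsv"),
                   hdr("intra-sample nucleotide diversity",
                       sprintf("genome_length=%g", gl)))

  fst_mat <- matrix(NA_real_, length(samples), length(samples),
                    dimnames = list(samples, samples))
  fst_rows <- list()
  if (length(samples) >= 2) {
    for (i in seq_along(samples)) for (j in seq_along(samples)) {
      if (j <= i) next
      f <- suppressWarnings(fst(counts, samples[i], samples[j], gl))
      fst_mat[i, j] <- fst_mat[j, i] <- f$value
      fst_rows[[length(fst_rows) + 1L]] <-
        data.frame(sample1 = samples[i], sample2 = samples[j],
                   fst = f$value, pi_within = f$pi_within,
                   pi_between = f$pi_between)
    }
    diag(fst_mat) <- 0
  } else {
    warning("single sample: F_ST matrix is empty")
  }
  fst_tab <- if (length(fst_rows) > 0) do.call(rbind, fst_rows) else
    data.frame(sample1 = character(), sample2 = character(), fst = numeric(),
               pi_within = numeric(), pi_between = numeric())
  write_tsv_header(fst_tab, file.path(config$outdir, "fst.tsv"),
                   hdr("pairwise fixation index",
                       sprintf("genome_length=%g", gl)))

  # --- biallelic SNVs and pN/pS -----------------------------------------
  mi <- match(key_c, key_h)
  pooled_major <- NUCS[max.col(pooled_counts(counts), ties.method = "first")]
  summ <- site_allele_summary(
    counts, ref = ifelse(is.na(mi), pooled_major, h$sites$ref[mi]))
  biallelic <- summ$n_alleles <= 2
  snv_df <- data.frame(gene_id = counts$sites$gene_id,
                       pos = counts$sites$pos, ref = summ$ref,
                       alt = summ$alt)[biallelic & summ$ref != summ$alt, ,
                                       drop = FALSE]
  snvs_by_gene <- split(snv_df, snv_df$gene_id)
  per_gene <- do.call(rbind, lapply(names(genes), function(g) {
    r <- suppressWarnings(
      pnps(snvs_by_gene[[g]] %||% data.frame(pos = integer(),
                                             ref = character(),
                                             alt = character()),
           as.character(genes[[g]]), pseudocount_s = 1))
    data.frame(gene_id = g, pnps = r$pnps, obs_n = r$obs_n, obs_s = r$obs_s,
               exp_n = r$exp_n, exp_s = r$exp_s)
  }))
  write_tsv_header(per_gene, file.path(config$outdir, "pnps_per_gene.tsv"),
                   hdr("per-gene pN/pS", "pseudocount_s=1"))
  gw <- suppressWarnings(pnps_pooled(snvs_by_gene, genes, pseudocount_s = 0))

  # --- Neutrality Index --------------------------------------------------
  clade_map <- h$clade_map
  if (is.null(clade_map))
    clade_map <- assign_clades(pairwise_snv_distance(h),
                               threshold = config$clade_threshold)
  site_cls <- vapply(seq_len(nrow(h$sites)), function(i) {
    gs <- genes[[h$sites$gene_id[i]]]
    classify_site_ns(as.character(gs), h$sites$pos[i], h$sites$ref[i],
                     h$sites$alt[i])
  }, "")
  ni_tab <- do.call(rbind, lapply(c("strain", "clade"), function(lv) {
    div <- classify_divergence(h, lv, clade_map = clade_map)
    cnts <- table(factor(div, c("divergent", "polymorphic")),
                  factor(site_cls, c("N", "S")))
    r <- suppressWarnings(neutrality_index(cnts["divergent", "N"],
                                           cnts["divergent", "S"],
                                           cnts["polymorphic", "N"],
                                           cnts["polymorphic", "S"]))
    data.frame(level = lv, dn = r$dn, ds = r$ds, pn = r$pn, ps = r$ps,
               dn_ds = r$dn_ds, pn_ps = r$pn_ps, ni = r$ni)
  }))
  write_tsv_header(ni_tab, file.path(config$outdir, "neutrality_index.tsv"),
                   hdr("Neutrality Index at strain and clade level"))

  # --- allele frequency spectra ------------------------------------------
  tie_tip <- config$tie_break_tip %||% colnames(h$states)[1]
  anc <- ancestral_states(h, tie_tip)
  afs_tab <- do.call(rbind, lapply(samples, function(s) {
    a <- derived_afs(counts, s, anc, n_bins = config$afs_bins)
    data.frame(sample = s, bin_lo = a$breaks[-length(a$breaks)],
               bin_hi = a$breaks[-1], count = a$counts)
  }))
  write_tsv_header(afs_tab, file.path(config$outdir, "afs.tsv"),
                   hdr("derived allele frequency spectra",
                       sprintf("n_bins=%d tie_break_tip=%s",
                               config$afs_bins, tie_tip)))

  # --- strain presence / dominance ---------------------------------------
  pres <- strain_presence_and_dominance(freqs, config$present_min,
                                        config$dominant_min)
  write_tsv_header(pres, file.path(config$outdir, "strain_presence.tsv"),
                   hdr("strain presence and dominance",
                       sprintf("present_min=%g dominant_min=%g",
                               config$present_min, config$dominant_min)))

  # --- alpha / beta diversity and associations ---------------------------
  alpha <- vapply(rownames(freqs), function(s)
    suppressWarnings(pse(tree, freqs[s, ])), 0)
  alpha_tab <- data.frame(sample = rownames(freqs), pse = alpha)
  write_tsv_header(alpha_tab, file.path(config$outdir, "alpha.tsv"),
                   hdr("phylogenetic species evenness"))

  beta <- matrix(0, nrow(freqs), nrow(freqs),
                 dimnames = list(rownames(freqs), rownames(freqs)))
  if (nrow(freqs) >= 2)
    for (i in seq_len(nrow(freqs))) for (j in seq_len(nrow(freqs)))
      if (j > i) beta[i, j] <- beta[j, i] <-
          weighted_unifrac(tree, freqs[i, ], freqs[j, ])
  beta_tab <- data.frame(sample = rownames(beta), as.data.frame(beta),
                         check.names = FALSE)
  write_tsv_header(beta_tab, file.path(config$outdir, "beta.tsv"),
                   hdr("weighted UniFrac distance matrix"))

  assoc <- list()
  ord <- match(samples, rownames(freqs))
  if (length(samples) >= 4 && stats::sd(pi_tab$pi) > 0 &&
      sum(!is.na(alpha[ord])) >= 4) {
    ra <- suppressWarnings(rank_association(pi_tab$pi[!is.na(alpha[ord])],
                                            alpha[ord][!is.na(alpha[ord])]))
    assoc$pi_alpha <- data.frame(test = "pi_vs_alpha_spearman",
                                 statistic = ra$rho, rho2 = ra$rho2,
                                 p = ra$p)
  }
  if (length(samples) >= 4 && !any(is.na(fst_mat)) &&
      stats::sd(stats::as.dist(fst_mat)) > 0) {
    ma <- matrix_association(fst_mat, beta[samples, samples],
                             n_perm = config$n_perm, seed = seed)
    assoc$fst_beta <- data.frame(test = "fst_vs_beta_mantel_spearman",
                                 statistic = ma$statistic, rho2 = NA_real_,
                                 p = ma$p)
  }
  assoc_tab <- if (length(assoc) > 0) do.call(rbind, assoc) else
    data.frame(test = character(), statistic = numeric(), rho2 = numeric(),
               p = numeric())
  write_tsv_header(assoc_tab, file.path(config$outdir, "associations.tsv"),
                   hdr("diversity association tests",
                       sprintf("n_perm=%d", config$n_perm)))

  manifest <- list(
    package = "strainpop",
    version = as.character(utils::packageVersion("strainpop")),
    seed = seed,
    genome_length = gl,
    inputs = list(
      counts = if (is.character(config$counts)) config$counts else "<object>",
      haplotypes = if (is.character(config$haplotypes)) config$haplotypes
                   else "<object>",
      tree = if (is.character(config$tree)) config$tree else "<object>",
      frequencies = if (is.character(config$frequencies)) config$frequencies
                    else "<object>",
      genes = if (is.character(config$genes)) config$genes else "<object>"),
    thresholds = list(present_min = config$present_min,
                      dominant_min = config$dominant_min,
                      major_min = config$major_min, poly_lo = config$poly_lo,
                      poly_hi = config$poly_hi, afs_bins = config$afs_bins,
                      n_perm = config$n_perm, normalize = config$normalize),
    outputs = c("pi.tsv", "fst.tsv", "pnps_per_gene.tsv",
                "neutrality_index.tsv", "afs.tsv", "strain_presence.tsv",
                "alpha.tsv", "beta.tsv", "associations.tsv"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(list(pi = pi_tab, fst = fst_mat, fst_table = fst_tab,
                           pnps_per_gene = per_gene, pnps_genomewide = gw,
                           neutrality_index = ni_tab, afs = afs_tab,
                           presence = pres, alpha = alpha_tab,
                           beta = beta, associations = assoc_tab,
                           manifest = manifest),
                      class = "strainpop_results"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strainpop_results <- function(x, ...) {
  cat("strainpop pipeline results\n")
  cat("  samples:", nrow(x$pi), " mean pi:", signif(mean(x$pi$pi), 4), "\n")
  if (nrow(x$fst_table) > 0)
    cat("  mean F_ST:", signif(mean(x$fst_table$fst, na.rm = TRUE), 4), "\n")
  cat("  genome-wide pN/pS:", signif(x$pnps_genomewide$pnps, 4), "\n")
  cat("  NI:", paste(sprintf("%s=%.3g", x$neutrality_index$level,
                             x$neutrality_index$ni), collapse = ", "), "\n")
  invisible(x)
}
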