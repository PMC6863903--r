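#' Strain haplotype set
#'
#' Allele states of reconstructed strains at the core-genome SNV sites, as
#' produced by a strain-deconvolution tool or by the simulator. States are
#' coded 0 (reference) / 1 (alternative). Sites at which the matrix is
#' constant are the "invariant" SNVs: metagenome variants that could not be
#' assigned to any strain, so the strain alignment carries no variation
#' there.
#'
#' @param states integer matrix, sites x strains, values 0/1; column names
#'   are strain ids.
#' @param sites data.frame with columns \code{gene_id}, \code{pos},
#'   \code{ref}, \code{alt}, one row per state row.
#' @param tree optional \code{ape::phylo} strain tree.
#' @param clade_map optional named character vector, strain -> clade label.
#' @param alignment_length length in bp of the strain alignment the SNVs were
#'   called on (>= number of sites); used for percent-identity arithmetic.
#' @return object of class \code{strain_haplotypes}.
#' @export
strain_haplotypes <- function(states, sites, tree = NULL, clade_map = NULL,
                              alignment_length) {
  states <- as.matrix(states)
  if (!all(states %in% c(0L, 1L)))
    stop_strainpop("haplotype states must be 0 (ref) or 1 (alt)")
  if (nrow(states) != nrow(sites))
    stop_strainpop("states rows must match sites rows")
  if (is.null(colnames(states)))
    stop_strainpop("states must have strain ids as column names")
  if (alignment_length < nrow(sites))
    stop_strainpop("alignment_length must be >= number of SNV sites")
  if (!is.null(clade_map) && !all(colnames(states) %in% names(clade_map)))
    stop_strainpop("clade_map must cover every strain")
  structure(list(states = states, sites = as.data.frame(sites), tree = tree,
                 clade_map = clade_map,
                 alignment_length = as.numeric(alignment_length)),
            class = "strain_haplotypes")
}

#' @export
print.strain_haplotypes <- function(x, ...) {
  inv <- sum(apply(x$states, 1, function(r) length(unique(r)) == 1))
  cat("strain_haplotypes:", ncol(x$states), "strains,", nrow(x$states),
      "SNV sites (", inv, "invariant ) over", x$alignment_length, "bp\n")
  invisible(x)
}

#' Pairwise SNV (Hamming) distances between strains
#'
#' @param h a \code{strain_haplotypes}.
#' @return symmetric strain x strain matrix of differing-site counts.
#' @export
pairwise_snv_distance <- function(h) {
  stopifnot(inherits(h, "strain_haplotypes"))
  d <- as.matrix(stats::dist(t(h$states), method = "manhattan"))
  storage.mode(d) <- "integer"
  d
}

#' Percent sequence identity from a SNV count
#'
#' \code{100 * (1 - n_diff / alignment_length)}, reported at two decimals:
#' the arithmetic that turns "669 SNVs over a 1.27 Mbp core genome" into
#' "99.95\% identity".
#'
#' @param n_diff number of differing sites.
#' @param alignment_length alignment length in bp.
#' @return percent identity rounded to 2 decimal places.
#' @examples
#' percent_identity(669, 1270000)   # 99.95
#' @export
percent_identity <- function(n_diff, alignment_length) {
  if (any(alignment_length == 0)) stop_strainpop("alignment_length must be > 0")
  if (any(n_diff > alignment_length))
    stop_strainpop("n_diff cannot exceed alignment_length")
  round(100 * (1 - n_diff / alignment_length), 2)
}

#' Assign strains to clades by single-linkage distance components
#'
#' Strains are joined whenever their SNV distance is strictly below the
#' threshold; connected components are the clades. The default threshold is
#' the midpoint of the largest gap in the sorted pairwise distances, which
#' mimics reading clades off long internal branches of a splits network.
#'
#' @param d symmetric strain x strain distance matrix.
#' @param threshold distance threshold (> 0); \code{NULL} for the
#'   largest-gap default.
#' @return named character vector strain -> clade label (\code{"C1"},
#'   \code{"C2"}, ... ordered by first strain appearance).
#' @export
assign_clades <- function(d, threshold = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(threshold)) {
    dv <- sort(unique(d[upper.tri(d)]))
    if (length(dv) < 2) threshold <- max(dv, 1)
    else {
      gaps <- diff(dv)
      i <- which.max(gaps)
      threshold <- (dv[i] + dv[i + 1]) / 2
    }
  }
  if (threshold <= 0) stop_strainpop("threshold must be > 0")
  adj <- d < threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  lab <- sprintf("C%d", match(comp, unique(comp)))
  stats::setNames(lab, rownames(d))
}

#' Strain presence and dominance calls per sample
#'
#' A strain is present in a sample when its relative frequency is at least
#' \code{present_min}; a sample has a dominant strain when a (necessarily
#' unique) strain reaches \code{dominant_min}.
#'
#' @param freqs samples x strains matrix of relative abundances (rows sum
#'   to 1).
#' @param present_min presence threshold (default 0.05).
#' @param dominant_min dominance threshold (default 0.90).
#' @return data.frame with one row per sample: \code{sample},
#'   \code{n_present}, \code{present} (comma-separated ids),
#'   \code{dominant} (id or \code{NA}).
#' @export
strain_presence_and_dominance <- function(freqs, present_min = 0.05,
                                          dominant_min = 0.90) {
  freqs <- as.matrix(freqs)
  if (any(freqs < 0) || any(abs(rowSums(freqs) - 1) > 1e-9))
    stop_strainpop("each sample's strain frequencies must be >= 0 and sum to 1")
  strains <- colnames(freqs)
  res <- lapply(seq_len(nrow(freqs)), function(i) {
    f <- freqs[i, ]
    pres <- strains[f >= present_min]
    dom <- strains[f >= dominant_min]
    data.frame(sample = rownames(freqs)[i], n_present = length(pres),
               present = paste(pres, collapse = ","),
               dominant = if (length(dom) == 1) dom else NA_character_)
  })
  do.call(rbind, res)
}

#' Dominant haplotype of a sample
#'
#' Per site, the allele whose read frequency reaches \code{major_min};
#' \code{NA} where no allele does (or at zero coverage). Intended for samples
#' that carry a dominant strain, where the call approximates that strain's
#' genome at the SNV sites.
#'
#' @param m an \code{allele_counts}.
#' @param sample sample id.
#' @param major_min major-allele frequency threshold (default 0.90).
#' @return named character vector (site id "gene:pos" -> nucleotide or
#'   \code{NA}).
#' @export
dominant_haplotype <- function(m, sample, major_min = 0.90) {
  stopifnot(inherits(m, "allele_counts"))
  if (!sample %in% m$samples) stop_strainpop("unknown sample: ", sample)
  x <- m$counts[, match(sample, m$samples), ]
  dim(x) <- c(nrow(m$sites), 4L)
  cov <- rowSums(x)
  f <- x / ifelse(cov > 0, cov, NA_real_)
  top <- max.col(f, ties.method = "first")
  allele <- ifelse(!is.na(cov) & cov > 0 &
                     f[cbind(seq_len(nrow(f)), top)] >= major_min,
                   NUCS[top], NA_character_)
  stats::setNames(allele, site_ids(m))
}

#' Count differential SNVs between two dominant haplotypes
#'
#' Sites undefined (\code{NA}) in either haplotype are excluded from the
#' comparison; the number excluded is reported as an attribute.
#'
#' @param h1,h2 named allele vectors over the same site set (as returned by
#'   \code{\link{dominant_haplotype}}).
#' @return integer count of defined, differing sites, with attribute
#'   \code{n_excluded}.
#' @export
differential_snvs <- function(h1, h2) {
  if (!identical(names(h1), names(h2)))
    stop_strainpop("haplotypes must be over the same site set")
  ok <- !is.na(h1) & !is.na(h2)
  structure(sum(h1[ok] != h2[ok]), n_excluded = sum(!ok))
}

#' Ancestral SNV states by strain majority
#'
#' The ancestral state at each site is the allele carried by the larger
#' number of strains; ties are resolved by the state of a designated tip of
#' the strain tree.
#'
#' @param h a \code{strain_haplotypes}.
#' @param tie_break_tip strain id whose state decides ties.
#' @return data.frame per site: \code{gene_id}, \code{pos}, \code{state}
#'   (0/1) and \code{allele} (nucleotide).
#' @export
ancestral_states <- function(h, tie_break_tip) {
  stopifnot(inherits(h, "strain_haplotypes"))
  if (!tie_break_tip %in% colnames(h$states))
    stop_strainpop("unknown strain: ", tie_break_tip)
  n_alt <- rowSums(h$states)
  n <- ncol(h$states)
  state <- ifelse(n_alt * 2 > n, 1L,
                  ifelse(n_alt * 2 < n, 0L, h$states[, tie_break_tip]))
  data.frame(gene_id = h$sites$gene_id, pos = h$sites$pos, state = state,
             allele = ifelse(state == 1L, h$sites$alt, h$sites$ref))
}

#' Unfolded (derived) allele-frequency spectrum of a sample
#'
#' For each biallelic SNV site with a defined ancestral state, the derived
#' allele frequency is one minus the read frequency of the ancestral allele
#' in the sample. Frequencies are histogrammed over [0, 1] in equal-width,
#' right-closed bins.
#'
#' @param m an \code{allele_counts}.
#' @param sample sample id.
#' @param ancestral data.frame from \code{\link{ancestral_states}} (or any
#'   frame with \code{gene_id}, \code{pos}, \code{allele}).
#' @param n_bins number of histogram bins (default 20).
#' @return object of class \code{afs}: \code{breaks}, \code{mids},
#'   \code{counts}, \code{freqs} (the raw derived frequencies) and
#'   \code{n_sites}.
#' @export
derived_afs <- function(m, sample, ancestral, n_bins = 20L) {
  stopifnot(inherits(m, "allele_counts"))
  if (!sample %in% m$samples) stop_strainpop("unknown sample: ", sample)
  key_m <- site_ids(m)
  key_a <- paste(ancestral$gene_id, ancestral$pos, sep = ":")
  i <- match(key_a, key_m)
  keep <- !is.na(i)
  x <- m$counts[, match(sample, m$samples), ]
  dim(x) <- c(nrow(m$sites), 4L)
  cov <- rowSums(x)
  # restrict to biallelic sites (pooled across samples) with coverage
  n_alleles <- rowSums(pooled_counts(m) > 0)
  idx <- i[keep]
  anc_allele <- ancestral$allele[keep]
  ok <- cov[idx] > 0 & n_alleles[idx] <= 2
  idx <- idx[ok]; anc_allele <- anc_allele[ok]
  f_anc <- x[cbind(idx, match(anc_allele, NUCS))] / cov[idx]
  fd <- 1 - f_anc
  breaks <- seq(0, 1, length.out = n_bins + 1)
  cuts <- cut(fd, breaks = breaks, include.lowest = TRUE, right = TRUE)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-n_bins - 1]) / 2,
                 counts = as.integer(table(cuts)), freqs = fd,
                 n_sites = length(fd), sample = sample),
            class = "afs")
}

#' @export
print.afs <- function(x, ...) {
  cat("derived allele frequency spectrum:", x$n_sites, "sites,",
      length(x$counts), "bins (sample", x$sample, ")\n")
  invisible(x)
}

#' Read / write strain haplotype TSV
#'
#' Site rows with columns \code{gene_id}, \code{pos}, \code{ref}, \code{alt}
#' followed by one 0/1 column per strain.
#'
#' @param path file path.
#' @param alignment_length alignment length passed through to the object.
#' @param tree optional \code{phylo} attached on read.
#' @param clade_map optional clade map attached on read.
#' @return a \code{strain_haplotypes}.
#' @export
read_haplotypes_tsv <- function(path, alignment_length = NULL, tree = NULL,
                                clade_map = NULL) {
  df <- read_tsv_header(path)
  meta <- c("gene_id", "pos", "ref", "alt")
  if (!all(meta %in% names(df)))
    stop_strainpop("haplotype TSV must have columns ",
                   paste(meta, collapse = ", "))
  states <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  if (is.null(alignment_length)) alignment_length <- nrow(df)
  strain_haplotypes(states, df[, meta], tree = tree, clade_map = clade_map,
                    alignment_length = alignment_length)
}

#' @rdname read_haplotypes_tsv
#' @param h a \code{strain_haplotypes}.
#' @param header provenance comment lines.
#' @export
write_haplotypes_tsv <- function(h, path, header = character()) {
  stopifnot(inherits(h, "strain_haplotypes"))
  df <- cbind(h$sites[, c("gene_id", "pos", "ref", "alt")],
              as.data.frame(h$states))
  write_tsv_header(df, path, c("strain haplotypes (0=ref, 1=alt)", header))
}

#' Read / write per-sample strain frequency TSV
#'
#' Wide format: a \code{sample} column followed by one column per strain.
#'
#' @param path file path.
#' @return samples x strains numeric matrix with row/column names.
#' @export
read_frequencies_tsv <- function(path) {
  df <- read_tsv_header(path)
  if (names(df)[1] != "sample")
    stop_strainpop("frequency TSV must start with a 'sample' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  m
}

#' @rdname read_frequencies_tsv
#' @param freqs samples x strains matrix.
#' @param header provenance comment lines.
#' @export
write_frequencies_tsv <- function(freqs, path, header = character()) {
  df <- data.frame(sample = rownames(freqs), as.data.frame(freqs),
                   check.names = FALSE)
  write_tsv_header(df, path, c("per-sample strain relative abundances", header))
}
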