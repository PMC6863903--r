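#' Per-site, per-sample nucleotide count matrix
#'
#' The backbone data structure of the package: read counts of A, C, G and T at
#' a set of core-genome sites (identified by gene and 1-based position within
#' the gene) in each metagenomic sample, as obtained from a pileup of mapped
#' reads. Nucleotide diversity, the fixation index, allele-frequency spectra
#' and dominant-haplotype reconstruction all consume this container.
#'
#' @param counts numeric array of dimension \code{n_sites x n_samples x 4};
#'   the third dimension is ordered A, C, G, T. Non-negative integers.
#' @param sites data.frame with columns \code{gene_id} and \code{pos}
#'   (1-based position within the gene), one row per site.
#' @param samples character vector of sample identifiers.
#' @return An object of class \code{allele_counts} with elements
#'   \code{sites}, \code{samples} and \code{counts}.
#' @examples
#' cnt <- array(0, c(1, 1, 4))
#' cnt[1, 1, ] <- c(3, 1, 0, 0)
#' m <- allele_counts(cnt, data.frame(gene_id = "g1", pos = 5L), "S1")
#' coverage(m)
#' @export
allele_counts <- function(counts, sites, samples) {
  if (length(dim(counts)) != 3L || dim(counts)[3] != 4L)
    stop_strainpop("'counts' must be a sites x samples x 4 array")
  if (nrow(sites) != dim(counts)[1])
    stop_strainpop("'sites' rows must match dim(counts)[1]")
  if (length(samples) != dim(counts)[2])
    stop_strainpop("'samples' must match dim(counts)[2]")
  if (!all(c("gene_id", "pos") %in% names(sites)))
    stop_strainpop("'sites' needs columns gene_id and pos")
  if (any(counts < 0)) stop_strainpop("negative read counts")
  if (any(sites$pos < 1)) stop_strainpop("positions are 1-based within genes")
  dimnames(counts) <- list(NULL, samples, NUCS)
  structure(list(sites = as.data.frame(sites), samples = as.character(samples),
                 counts = counts),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  cat("  genes:", length(unique(x$sites$gene_id)),
      " median coverage:", stats::median(coverage(x)), "\n")
  invisible(x)
}

#' Site coverage of an allele count matrix
#'
#' @param m an \code{allele_counts} object.
#' @return sites x samples matrix of read depths (sum of the four nucleotide
#'   counts).
#' @export
coverage <- function(m) {
  stopifnot(inherits(m, "allele_counts"))
  cov <- apply(m$counts, c(1, 2), sum)
  dim(cov) <- c(nrow(m$sites), length(m$samples))
  colnames(cov) <- m$samples
  cov
}

site_ids <- function(m) paste(m$sites$gene_id, m$sites$pos, sep = ":")

#' Pooled nucleotide counts across samples
#'
#' @param m an \code{allele_counts} object.
#' @return sites x 4 matrix of counts summed over samples.
#' @export
pooled_counts <- function(m) {
  stopifnot(inherits(m, "allele_counts"))
  pc <- apply(m$counts, c(1, 3), sum)
  dim(pc) <- c(nrow(m$sites), 4L)
  colnames(pc) <- NUCS
  pc
}

#' Call major/minor alleles and per-sample allele frequencies
#'
#' Pools counts across samples, calls the major allele (reference, unless a
#' reference vector is supplied) and the most abundant remaining allele as the
#' alternative, and reports the per-sample alternative-allele frequency along
#' with the number of distinct nucleotides observed at the site (a site is
#' biallelic when at most two are seen).
#'
#' @param m an \code{allele_counts} object.
#' @param ref optional character vector of reference alleles per site; when
#'   missing the pooled major allele is taken as reference.
#' @return list with \code{ref}, \code{alt}, \code{n_alleles} (per site) and
#'   \code{alt_freq} (sites x samples matrix, \code{NA} at zero coverage).
#' @export
site_allele_summary <- function(m, ref = NULL) {
  pc <- pooled_counts(m)
  n_alleles <- rowSums(pc > 0)
  if (is.null(ref)) {
    ref <- NUCS[max.col(pc, ties.method = "first")]
  } else if (length(ref) != nrow(pc)) {
    stop_strainpop("'ref' length must equal the number of sites")
  }
  pc_alt <- pc
  pc_alt[cbind(seq_len(nrow(pc)), match(ref, NUCS))] <- -1L
  alt <- NUCS[max.col(pc_alt, ties.method = "first")]
  cov <- coverage(m)
  alt_counts <- vapply(seq_along(m$samples), function(j)
    m$counts[, j, ][cbind(seq_len(nrow(pc)), match(alt, NUCS))],
    numeric(nrow(pc)))
  dim(alt_counts) <- dim(cov)
  alt_freq <- ifelse(cov > 0, alt_counts / cov, NA_real_)
  colnames(alt_freq) <- m$samples
  list(ref = ref, alt = alt, n_alleles = n_alleles, alt_freq = alt_freq)
}

#' Read / write the canonical counts TSV
#'
#' Long format with columns \code{gene_id}, \code{pos}, \code{sample},
#' \code{nA}, \code{nC}, \code{nG}, \code{nT}. Lines starting with '#' are
#' treated as header comments.
#'
#' @param path file path.
#' @return \code{read_counts_tsv} returns an \code{allele_counts} object.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_header(path)
  need <- c("gene_id", "pos", "sample", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(df)))
    stop_strainpop("counts TSV must have columns ", paste(need, collapse = ", "))
  key <- paste(df$gene_id, df$pos, sep = ":")
  sites <- unique(df[, c("gene_id", "pos")])
  skey <- paste(sites$gene_id, sites$pos, sep = ":")
  samples <- sort(unique(df$sample))
  cnt <- array(0, c(nrow(sites), length(samples), 4L))
  i <- match(key, skey)
  j <- match(df$sample, samples)
  for (b in 1:4) cnt[cbind(i, j, b)] <- df[[c("nA", "nC", "nG", "nT")[b]]]
  allele_counts(cnt, sites, samples)
}

#' @rdname read_counts_tsv
#' @param m an \code{allele_counts} object.
#' @param header character vector of provenance lines written as '# ' comments.
#' @export
write_counts_tsv <- function(m, path, header = character()) {
  stopifnot(inherits(m, "allele_counts"))
  ns <- nrow(m$sites); nsam <- length(m$samples)
  df <- data.frame(
    gene_id = rep(m$sites$gene_id, times = nsam),
    pos = rep(m$sites$pos, times = nsam),
    sample = rep(m$samples, each = ns),
    nA = as.vector(m$counts[, , "A"]),
    nC = as.vector(m$counts[, , "C"]),
    nG = as.vector(m$counts[, , "G"]),
    nT = as.vector(m$counts[, , "T"]))
  write_tsv_header(df, path, header)
}
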