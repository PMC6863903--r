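#' Intra-sample nucleotide diversity from pooled read counts
#'
#' For a sample S over a genome G of length |G|, nucleotide diversity is the
#' probability that two reads drawn without replacement at a site carry
#' different nucleotides, averaged over the genome:
#' \deqn{\pi(S,G) = \frac{1}{|G|}\sum_i \sum_{B_1}\sum_{B_2 \ne B_1}
#'   \frac{X_{i,B_1}}{C_i}\,\frac{X_{i,B_2}}{C_i - 1}}
#' where \eqn{X_{i,B}} is the read count of nucleotide B at site i and
#' \eqn{C_i} the coverage. Sites with coverage below 2 contribute 0 and are
#' excluded from \code{n_sites_used}. The denominator |G| is the full genome
#' length (monomorphic sites included), not the SNV count.
#'
#' @param m an \code{\link{allele_counts}}; sites absent from it are assumed
#'   monomorphic (zero contribution).
#' @param sample sample id.
#' @param genome_length |G| in bp.
#' @return object of class \code{pi_result}: \code{value},
#'   \code{genome_length}, \code{n_sites_used}.
#' @examples
#' cnt <- array(c(3, 1, 0, 0), c(1, 1, 4))
#' m <- allele_counts(cnt, data.frame(gene_id = "g", pos = 1L), "S1")
#' pi_intra(m, "S1", genome_length = 1)$value  # 0.5
#' @export
pi_intra <- function(m, sample, genome_length) {
  stopifnot(inherits(m, "allele_counts"))
  if (genome_length <= 0) stop_strainpop("genome_length must be > 0")
  if (genome_length < nrow(m$sites))
    stop_strainpop("genome_length smaller than the number of sites")
  if (!sample %in% m$samples) stop_strainpop("unknown sample: ", sample)
  x <- m$counts[, match(sample, m$samples), ]
  dim(x) <- c(nrow(m$sites), 4L)
  cc <- rowSums(x)
  ok <- cc >= 2
  # sum over ordered pairs B1 != B2 of (X1/C)(X2/(C-1)) = (C^2 - sum X^2)/(C(C-1))
  contrib <- (cc[ok]^2 - rowSums(x[ok, , drop = FALSE]^2)) /
    (cc[ok] * (cc[ok] - 1))
  structure(list(value = sum(contrib) / genome_length,
                 genome_length = genome_length, n_sites_used = sum(ok)),
            class = "pi_result")
}

#' Inter-sample nucleotide diversity
#'
#' Probability that one read from sample S1 and one from sample S2 differ at
#' a site, averaged over the genome:
#' \deqn{\pi(S_1,S_2,G) = \frac{1}{|G|}\sum_i \sum_{B_1}\sum_{B_2 \ne B_1}
#'   \frac{X_{i,B_1,S_1}}{C_{i,S_1}}\,\frac{X_{i,B_2,S_2}}{C_{i,S_2}}}
#' Sites lacking coverage in either sample contribute 0. Symmetric in the
#' two samples.
#'
#' @inheritParams pi_intra
#' @param sample1,sample2 sample ids.
#' @return a \code{pi_result}.
#' @export
pi_inter <- function(m, sample1, sample2, genome_length) {
  stopifnot(inherits(m, "allele_counts"))
  if (genome_length <= 0) stop_strainpop("genome_length must be > 0")
  for (s in c(sample1, sample2))
    if (!s %in% m$samples) stop_strainpop("unknown sample: ", s)
  x1 <- m$counts[, match(sample1, m$samples), ]
  x2 <- m$counts[, match(sample2, m$samples), ]
  dim(x1) <- dim(x2) <- c(nrow(m$sites), 4L)
  c1 <- rowSums(x1); c2 <- rowSums(x2)
  ok <- c1 >= 1 & c2 >= 1
  p_same <- rowSums((x1[ok, , drop = FALSE] / c1[ok]) *
                      (x2[ok, , drop = FALSE] / c2[ok]))
  structure(list(value = sum(1 - p_same) / genome_length,
                 genome_length = genome_length, n_sites_used = sum(ok)),
            class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("pi = %.6g over |G| = %g bp (%d sites used)\n",
              x$value, x$genome_length, x$n_sites_used))
  invisible(x)
}

#' Fixation index between two samples
#'
#' \deqn{F_{ST}(S_1,S_2,G) = 1 - \frac{\pi(S_1,G) + \pi(S_2,G)}
#'   {2\,\pi(S_1,S_2,G)}}
#' Undefined (NA, with a warning) when the between-sample diversity is zero;
#' small negative values can occur and are estimator noise.
#'
#' @inheritParams pi_inter
#' @return object of class \code{fst_result}: \code{value},
#'   \code{pi_within}, \code{pi_between} and the component \code{pi_result}s.
#' @export
fst <- function(m, sample1, sample2, genome_length) {
  p1 <- pi_intra(m, sample1, genome_length)
  p2 <- pi_intra(m, sample2, genome_length)
  p12 <- pi_inter(m, sample1, sample2, genome_length)
  pw <- p1$value + p2$value
  pb <- 2 * p12$value
  value <- if (pb == 0) {
    warning("pi_between is zero; F_ST undefined for (", sample1, ", ",
            sample2, ")")
    NA_real_
  } else 1 - pw / pb
  structure(list(value = value, pi_within = pw, pi_between = pb,
                 pi1 = p1, pi2 = p2, pi12 = p12,
                 samples = c(sample1, sample2)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST(%s, %s) = %.4g  (pi_within %.4g, pi_between %.4g)\n",
              x$samples[1], x$samples[2], x$value, x$pi_within, x$pi_between))
  invisible(x)
}

# Enumerate, for one codon, its 9 single-nucleotide mutants and count how
# many are synonymous. Changes to or from a stop codon count as
# nonsynonymous (they are not silent); stop-to-stop likewise.
codon_ns_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    res <- t(vapply(codons, function(cd) {
      aa <- gc[[cd]]
      n_syn <- 0L
      for (p in 1:3) for (b in setdiff(NUCS, substr(cd, p, p))) {
        mut <- cd
        substr(mut, p, p) <- b
        aa2 <- gc[[mut]]
        if (aa == aa2 && aa != "*") n_syn <- n_syn + 1L
      }
      c(N = 9L - n_syn, S = n_syn)
    }, c(N = 0L, S = 0L)))
    tab <<- res
    tab
  }
})

#' Expected nonsynonymous and synonymous mutation counts of a gene
#'
#' Enumerates, for every codon of an in-frame gene, all nine possible
#' single-nucleotide changes with equal weight and classifies each as
#' synonymous or nonsynonymous under the standard genetic code. Changes
#' involving stop codons are counted as nonsynonymous. This is the
#' mutational-opportunity denominator of pN/pS.
#'
#' @param gene in-frame nucleotide sequence (character or
#'   \code{DNAString}); length divisible by 3.
#' @return named numeric vector \code{c(N, S)} with \code{N + S = 9 *
#'   n_codons} over the codons used.
#' @examples
#' expected_ns_ratio("TTT")  # N 8, S 1
#' @export
expected_ns_ratio <- function(gene) {
  s <- toupper(as.character(gene))
  if (nchar(s) %% 3 != 0) stop_strainpop("gene length must be divisible by 3")
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  bad <- !codons %in% rownames(codon_ns_table())
  if (any(bad)) {
    warning(sum(bad), " codon(s) with non-ACGT bases skipped")
    codons <- codons[!bad]
  }
  if (any(Biostrings::GENETIC_CODE[codons] == "*" &
          seq_along(codons) < length(codons)))
    warning("internal stop codon(s) present")
  colSums(codon_ns_table()[codons, , drop = FALSE])
}

# Classify one observed substitution (gene position pos, ref -> alt) as
# synonymous or nonsynonymous on the reference gene sequence.
classify_site_ns <- function(gene_seq, pos, ref, alt) {
  s <- toupper(as.character(gene_seq))
  ci <- (pos - 1L) %/% 3L
  off <- (pos - 1L) %% 3L + 1L
  codon <- substr(s, ci * 3L + 1L, ci * 3L + 3L)
  if (substr(codon, off, off) != toupper(ref))
    warning("reference allele mismatch at position ", pos)
  mut <- codon
  substr(mut, off, off) <- toupper(alt)
  if (!codon %in% rownames(codon_ns_table()) ||
      !mut %in% rownames(codon_ns_table())) return(NA_character_)
  aa1 <- Biostrings::GENETIC_CODE[[codon]]
  aa2 <- Biostrings::GENETIC_CODE[[mut]]
  if (aa1 == aa2 && aa1 != "*") "S" else "N"
}

#' Observed/expected pN/pS of a gene
#'
#' The observed nonsynonymous-to-synonymous count ratio of the biallelic
#' SNVs on a gene, normalized by the gene's mutational opportunity from
#' \code{\link{expected_ns_ratio}}:
#' \deqn{pN/pS = \frac{obsN / (obsS + c)}{expN / expS}}
#' with pseudocount \eqn{c} added to the observed synonymous count so that
#' per-gene values are defined when no synonymous SNV is seen (default 1,
#' the standard correction). Use \code{\link{pnps_pooled}} with
#' \code{pseudocount_s = 0} for genome-wide estimates.
#'
#' @param snvs data.frame of biallelic SNVs on the gene: columns \code{pos}
#'   (1-based within gene), \code{ref}, \code{alt}. May have zero rows.
#' @param gene_seq in-frame reference sequence of the gene.
#' @param pseudocount_s pseudocount on observed synonymous SNVs (default 1).
#' @return list: \code{pnps}, \code{obs_n}, \code{obs_s}, \code{exp_n},
#'   \code{exp_s}.
#' @export
pnps <- function(snvs, gene_seq, pseudocount_s = 1) {
  ex <- expected_ns_ratio(gene_seq)
  if (ex[["S"]] == 0) {
    warning("expected synonymous count is zero; pN/pS undefined")
    return(list(pnps = NA_real_, obs_n = NA_integer_, obs_s = NA_integer_,
                exp_n = ex[["N"]], exp_s = 0))
  }
  cls <- if (nrow(snvs) > 0)
    vapply(seq_len(nrow(snvs)), function(i)
      classify_site_ns(gene_seq, snvs$pos[i], snvs$ref[i], snvs$alt[i]), "")
  else character(0)
  obs_n <- sum(cls == "N", na.rm = TRUE)
  obs_s <- sum(cls == "S", na.rm = TRUE)
  val <- (obs_n / (obs_s + pseudocount_s)) / (ex[["N"]] / ex[["S"]])
  list(pnps = val, obs_n = obs_n, obs_s = obs_s,
       exp_n = ex[["N"]], exp_s = ex[["S"]])
}

#' Genome-wide pN/pS from pooled counts
#'
#' Pools observed and expected counts over genes; by default no pseudocount
#' is applied (counts are large genome-wide).
#'
#' @param snvs_by_gene named list (gene id -> SNV data.frame as in
#'   \code{\link{pnps}}).
#' @param genes named character vector or \code{DNAStringSet} of in-frame
#'   gene sequences.
#' @param pseudocount_s pseudocount on the pooled observed synonymous count
#'   (default 0).
#' @return list as in \code{\link{pnps}}, pooled.
#' @export
pnps_pooled <- function(snvs_by_gene, genes, pseudocount_s = 0) {
  gene_ids <- names(genes)
  tot <- list(obs_n = 0L, obs_s = 0L, exp_n = 0, exp_s = 0)
  for (g in gene_ids) {
    snvs <- snvs_by_gene[[g]]
    if (is.null(snvs)) snvs <- data.frame(pos = integer(), ref = character(),
                                          alt = character())
    r <- pnps(snvs, as.character(genes[[g]]), pseudocount_s = 0)
    if (is.na(r$pnps) && r$exp_s == 0) next
    tot$obs_n <- tot$obs_n + r$obs_n
    tot$obs_s <- tot$obs_s + r$obs_s
    tot$exp_n <- tot$exp_n + r$exp_n
    tot$exp_s <- tot$exp_s + r$exp_s
  }
  if (tot$exp_s == 0 || tot$obs_s + pseudocount_s == 0) {
    warning("pooled pN/pS undefined")
    return(c(tot, list(pnps = NA_real_)))
  }
  c(tot, list(pnps = (tot$obs_n / (tot$obs_s + pseudocount_s)) /
                (tot$exp_n / tot$exp_s)))
}

#' Classify SNVs as divergent or polymorphic from strain haplotypes
#'
#' At the strain level, a SNV is divergent when it distinguishes at least
#' two strains and polymorphic when it is invariant in the strain alignment
#' (an unassigned, population-wide variant). At the clade level, divergent
#' SNVs must additionally be uniform within every clade -- SNVs still
#' segregating inside a clade are treated as (possibly transient)
#' polymorphism.
#'
#' @param h a \code{strain_haplotypes}; constant rows are the invariant
#'   SNVs.
#' @param level \code{"strain"} or \code{"clade"}.
#' @param clade_map named strain -> clade vector; defaults to
#'   \code{h$clade_map}. Required at \code{level = "clade"}.
#' @return character vector (\code{"divergent"} / \code{"polymorphic"}),
#'   one per site of \code{h}.
#' @export
classify_divergence <- function(h, level = c("strain", "clade"),
                                clade_map = NULL) {
  stopifnot(inherits(h, "strain_haplotypes"))
  level <- match.arg(level)
  varies <- rowSums(h$states) > 0 & rowSums(h$states) < ncol(h$states)
  if (level == "strain")
    return(ifelse(varies, "divergent", "polymorphic"))
  if (is.null(clade_map)) clade_map <- h$clade_map
  if (is.null(clade_map) || !all(colnames(h$states) %in% names(clade_map)))
    stop_strainpop("clade-level classification needs a complete clade_map")
  clades <- unique(clade_map[colnames(h$states)])
  uniform_within <- rep(TRUE, nrow(h$states))
  for (cl in clades) {
    mem <- colnames(h$states)[clade_map[colnames(h$states)] == cl]
    sub <- h$states[, mem, drop = FALSE]
    uniform_within <- uniform_within &
      (rowSums(sub) == 0 | rowSums(sub) == length(mem))
  }
  ifelse(varies & uniform_within, "divergent", "polymorphic")
}

#' Neutrality Index from divergent/polymorphic SNV class counts
#'
#' \deqn{NI = \frac{pN/pS}{dN/dS}}
#' where dN, dS count nonsynonymous and synonymous divergent SNVs and pN,
#' pS the polymorphic ones. NI > 1 indicates purifying selection acting on
#' divergence (synonymous-enriched divergent SNVs); NI < 1 an excess of
#' nonsynonymous divergence (positive selection or demography).
#'
#' @param dn,ds,pn,ps nonnegative counts.
#' @return list: \code{ni}, \code{pn_ps}, \code{dn_ds} and the input
#'   counts. All three values NA (with a reason) when a denominator is
#'   zero.
#' @examples
#' neutrality_index(5004, 10577, 990, 1450)$ni  # 1.44 at 2 dp
#' @export
neutrality_index <- function(dn, ds, pn, ps) {
  counts <- list(dn = dn, ds = ds, pn = pn, ps = ps)
  if (any(unlist(counts) < 0)) stop_strainpop("counts must be nonnegative")
  if (ds == 0 || ps == 0 || dn == 0) {
    reason <- if (ds == 0) "dS = 0" else if (ps == 0) "pS = 0" else "dN = 0"
    warning("Neutrality Index undefined: ", reason)
    return(c(counts, list(dn_ds = if (ds > 0) dn / ds else NA_real_,
                          pn_ps = if (ps > 0) pn / ps else NA_real_,
                          ni = NA_real_, reason = reason)))
  }
  dn_ds <- dn / ds
  pn_ps <- pn / ps
  c(counts, list(dn_ds = dn_ds, pn_ps = pn_ps, ni = pn_ps / dn_ds))
}
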