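#' GATK-style hard-filter thresholds for SNV annotations
#'
#' Thresholds and keep-directions follow GATK best-practice hard filtering:
#' a record is kept when quality-by-depth and the rank-sum statistics are
#' high enough and the strand-bias Phred score is low enough. Every
#' threshold is configurable; the base-quality direction (keep >= 30) is
#' the convention adopted here.
#'
#' @param qd_min minimum quality by depth (QD).
#' @param fs_max maximum Phred-scaled Fisher strand bias (FS).
#' @param mq_min minimum RMS mapping quality (MQ).
#' @param baseq_min minimum RMS base quality.
#' @param mqrs_min minimum mapping-quality rank-sum.
#' @param rprs_min minimum read-position rank-sum.
#' @return named list of class \code{hard_filter_thresholds}.
#' @export
hard_filter_thresholds <- function(qd_min = 2, fs_max = 60, mq_min = 40,
                                   baseq_min = 30, mqrs_min = -12.5,
                                   rprs_min = -8) {
  t <- list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
            baseq_min = baseq_min, mqrs_min = mqrs_min, rprs_min = rprs_min)
  if (!all(is.finite(unlist(t)))) stop_strainpop("thresholds must be finite")
  structure(t, class = "hard_filter_thresholds")
}

#' Hard-filter SNV records on their quality annotations
#'
#' A record is kept iff QD >= qd_min, FS <= fs_max, MQ >= mq_min,
#' BaseQRMS >= baseq_min, MQRankSum >= mqrs_min and ReadPosRankSum >=
#' rprs_min. A missing (NA or absent) annotation passes vacuously; a
#' message reports how many records relied on that. Idempotent and
#' order-independent.
#'
#' @param records data.frame of SNV records; annotation columns \code{QD},
#'   \code{FS}, \code{MQ}, \code{BaseQRMS}, \code{MQRankSum},
#'   \code{ReadPosRankSum} are each optional.
#' @param thresholds a \code{\link{hard_filter_thresholds}}.
#' @return the kept subset of \code{records}.
#' @export
hard_filter <- function(records, thresholds = hard_filter_thresholds()) {
  stopifnot(inherits(thresholds, "hard_filter_thresholds"))
  n <- nrow(records)
  get <- function(col) if (col %in% names(records)) records[[col]]
         else rep(NA_real_, n)
  pass_ge <- function(x, cut) is.na(x) | x >= cut
  pass_le <- function(x, cut) is.na(x) | x <= cut
  ann <- list(QD = get("QD"), FS = get("FS"), MQ = get("MQ"),
              BaseQRMS = get("BaseQRMS"), MQRankSum = get("MQRankSum"),
              ReadPosRankSum = get("ReadPosRankSum"))
  n_missing <- sum(vapply(ann, function(x) any(is.na(x)), logical(1)))
  if (n_missing > 0)
    message(n_missing, " annotation field(s) contain missing values; ",
            "missing annotations pass the filter")
  keep <- pass_ge(ann$QD, thresholds$qd_min) &
    pass_le(ann$FS, thresholds$fs_max) &
    pass_ge(ann$MQ, thresholds$mq_min) &
    pass_ge(ann$BaseQRMS, thresholds$baseq_min) &
    pass_ge(ann$MQRankSum, thresholds$mqrs_min) &
    pass_ge(ann$ReadPosRankSum, thresholds$rprs_min)
  records[keep, , drop = FALSE]
}

#' Normalize sample coverages by binomial read thinning
#'
#' Computes each sample's median site coverage, takes the smallest as the
#' target, and thins every allele count of deeper samples by independent
#' binomial sampling with retention probability target/median. Thinning
#' keeps counts integral and leaves expected allele frequencies unchanged;
#' samples already at the minimum are untouched.
#'
#' @param m an \code{\link{allele_counts}}.
#' @param seed integer seed (thinning is stochastic).
#' @return a thinned \code{allele_counts}; attribute \code{target} records
#'   the target median coverage.
#' @export
normalize_coverage <- function(m, seed = 1L) {
  stopifnot(inherits(m, "allele_counts"))
  if (nrow(m$sites) == 0) stop_strainpop("empty allele count matrix")
  cov <- coverage(m)
  med <- apply(cov, 2, stats::median)
  if (any(med <= 0))
    stop_strainpop("every sample must have positive median coverage")
  target <- min(med)
  set.seed(substream_seed(seed, 4L))
  cnt <- m$counts
  for (j in seq_along(m$samples)) {
    if (med[j] <= target) next
    p <- target / med[j]
    x <- cnt[, j, ]
    cnt[, j, ] <- stats::rbinom(length(x), as.integer(x), p)
  }
  out <- allele_counts(cnt, m$sites, m$samples)
  attr(out, "target") <- target
  out
}

#' Classify SNV frequencies as polymorphic, fixed or absent
#'
#' A SNV is polymorphic in a sample when its (alternative-allele) frequency
#' lies in [\code{lo}, \code{hi}] (bounds inclusive), fixed above \code{hi}
#' and absent below \code{lo}. Frequencies undefined because of zero
#' coverage yield \code{NA} with a warning.
#'
#' @param f numeric vector of allele frequencies in [0, 1] (NA allowed).
#' @param lo,hi polymorphic bounds (defaults 0.05 and 0.95).
#' @return character vector in \{"polymorphic", "fixed", "absent", NA\}.
#' @export
classify_polymorphic <- function(f, lo = 0.05, hi = 0.95) {
  if (any(is.na(f)))
    warning(sum(is.na(f)), " site(s) with undefined frequency (zero ",
            "coverage) excluded from classification")
  ifelse(is.na(f), NA_character_,
         ifelse(f < lo, "absent", ifelse(f > hi, "fixed", "polymorphic")))
}

#' Read SNV allele counts and annotations from a VCF
#'
#' Expects biallelic SNV records with per-sample AD (allele depth) fields;
#' INFO keys QD, FS, MQ, BaseQRMS (or BaseQualityRankSum alternatives),
#' MQRankSum and ReadPosRankSum are picked up when present. CHROM is
#' interpreted as the gene id and POS as the 1-based position within the
#' gene.
#'
#' @param path VCF file path.
#' @return list: \code{counts} (an \code{allele_counts}), \code{records}
#'   (data.frame with gene_id, pos, ref, alt and annotation columns).
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  ns <- nrow(fix)
  cnt <- array(0L, c(ns, length(samples), 4L))
  ref_i <- match(fix$REF, NUCS)
  alt_i <- match(fix$ALT, NUCS)
  for (j in seq_along(samples)) {
    parts <- strsplit(ad[, j], ",", fixed = TRUE)
    refc <- as.integer(vapply(parts, `[`, "", 1))
    altc <- as.integer(vapply(parts, function(p) if (length(p) > 1) p[2]
                              else "0", ""))
    cnt[cbind(seq_len(ns), j, ref_i)] <- refc
    cnt[cbind(seq_len(ns), j, alt_i)] <- altc
  }
  sites <- data.frame(gene_id = fix$CHROM, pos = as.integer(fix$POS))
  info_num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  records <- data.frame(gene_id = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        QD = info_num("QD"), FS = info_num("FS"),
                        MQ = info_num("MQ"), BaseQRMS = info_num("BaseQRMS"),
                        MQRankSum = info_num("MQRankSum"),
                        ReadPosRankSum = info_num("ReadPosRankSum"))
  list(counts = allele_counts(cnt, sites, samples), records = records)
}

#' Write biallelic SNV counts as a minimal VCF
#'
#' Emits VCF 4.2 with CHROM = gene id, POS = within-gene position and
#' per-sample AD/DP genotype fields -- exactly the fields the pipeline
#' consumes, so read/write/read round-trips are information-preserving.
#'
#' @param m an \code{allele_counts}.
#' @param ref,alt character vectors of reference and alternative alleles
#'   per site.
#' @param path output path.
#' @param records optional data.frame carrying annotation columns (QD, FS,
#'   MQ, BaseQRMS, MQRankSum, ReadPosRankSum) written into INFO.
#' @return invisibly, \code{path}.
#' @export
write_snv_vcf <- function(m, ref, alt, path, records = NULL) {
  stopifnot(inherits(m, "allele_counts"))
  ns <- nrow(m$sites)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste0("##INFO=<ID=", c("QD", "FS", "MQ", "BaseQRMS", "MQRankSum",
                                   "ReadPosRankSum"),
                  ",Number=1,Type=Float,Description=\"", c("Quality by depth",
                  "Phred strand bias", "RMS mapping quality",
                  "RMS base quality", "MQ rank sum", "Read position rank sum"),
                  "\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", m$samples), collapse = "\t"))
  info <- rep(".", ns)
  if (!is.null(records)) {
    keys <- intersect(c("QD", "FS", "MQ", "BaseQRMS", "MQRankSum",
                        "ReadPosRankSum"), names(records))
    if (length(keys) > 0)
      info <- vapply(seq_len(ns), function(i) {
        kv <- vapply(keys, function(k) {
          x <- records[[k]][i]
          if (is.na(x)) NA_character_ else paste0(k, "=", format(x))
        }, "")
        kv <- kv[!is.na(kv)]
        if (length(kv) == 0) "." else paste(kv, collapse = ";")
      }, "")
  }
  ri <- match(ref, NUCS); ai <- match(alt, NUCS)
  gt <- vapply(seq_along(m$samples), function(j) {
    x <- m$counts[, j, ]
    dim(x) <- c(ns, 4L)
    refc <- x[cbind(seq_len(ns), ri)]
    altc <- x[cbind(seq_len(ns), ai)]
    sprintf("%d,%d:%d", refc, altc, refc + altc)
  }, character(ns))
  dim(gt) <- c(ns, length(m$samples))
  body <- cbind(m$sites$gene_id, m$sites$pos, ".", ref, alt, ".", "PASS",
                info, "AD:DP", gt)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
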