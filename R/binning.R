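#' Canopy co-abundance clustering of gene coverage profiles
#'
#' Clusters genes whose coverages covary across samples, the step that
#' separates symbiont core genomes (metagenomic species) from accessory
#' genes. In seeded random order, each unclaimed gene seeds a canopy; the
#' canopy collects all genes with Pearson correlation above
#' \code{pcc_member} to its profile and iterates profile (per-sample median
#' of members) and membership to a fixed point (at most \code{max_iter}
#' rounds). Canopies with median-profile Pearson correlation above
#' \code{pcc_merge} are then merged; canopies whose coverage signal comes
#' from fewer than \code{min_signal_samples} samples (profile > 0) are
#' removed; members whose Spearman correlation to the bin median profile is
#' below \code{spearman_min} are pruned; genes landing in several bins are
#' kept only in the largest (ties by bin id), so the result is a partition;
#' bins smaller than 3 genes are dropped.
#'
#' @param m genes x samples coverage matrix (rownames = gene ids) or a
#'   \code{gene_abundance_sim}.
#' @param pcc_member Pearson membership threshold (default 0.9, exclusive).
#' @param pcc_merge Pearson merge threshold on median profiles (default
#'   0.97, exclusive).
#' @param spearman_min minimum member Spearman correlation (default 0.7).
#' @param min_signal_samples minimum samples with nonzero profile (default
#'   3).
#' @param max_iter maximum profile/membership iterations per canopy.
#' @param seed integer seed (controls the canopy seeding order).
#' @return object of class \code{canopy_bins}: list of bins, each with
#'   \code{members}, \code{profile} and \code{size}.
#' @export
canopy_cluster <- function(m, pcc_member = 0.9, pcc_merge = 0.97,
                           spearman_min = 0.7, min_signal_samples = 3L,
                           max_iter = 100L, seed = 1L) {
  if (inherits(m, "gene_abundance_sim")) m <- m$coverage
  m <- as.matrix(m)
  if (ncol(m) < 3) stop_strainpop("at least 3 samples are required")
  if (any(is.na(m))) stop_strainpop("coverage matrix has missing cells")
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%05d", seq_len(nrow(m)))
  sdv <- apply(m, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance gene(s) excluded from clustering")
    m <- m[sdv > 0, , drop = FALSE]
  }
  genes <- rownames(m)
  tm <- t(m)
  set.seed(substream_seed(seed, 6L))
  order_idx <- sample.int(nrow(m))
  claimed <- logical(nrow(m))
  canopies <- list()
  for (gi in order_idx) {
    if (claimed[gi]) next
    profile <- m[gi, ]
    members <- integer(0)
    for (it in seq_len(max_iter)) {
      if (stats::sd(profile) == 0) break
      pcc <- suppressWarnings(stats::cor(tm, profile))
      new_members <- which(!is.na(pcc) & pcc > pcc_member)
      if (length(new_members) == 0) break
      if (identical(new_members, members)) break
      members <- new_members
      profile <- apply(m[members, , drop = FALSE], 2, stats::median)
    }
    if (length(members) == 0) members <- gi
    claimed[members] <- TRUE
    canopies[[length(canopies) + 1L]] <-
      list(members = members,
           profile = apply(m[members, , drop = FALSE], 2, stats::median))
  }

  # merge canopies with highly correlated median profiles
  repeat {
    k <- length(canopies)
    if (k < 2) break
    prof <- vapply(canopies, `[[`, numeric(ncol(m)), "profile")
    pc <- suppressWarnings(stats::cor(prof))
    pc[!is.finite(pc)] <- -1
    diag(pc) <- -1
    if (max(pc) <= pcc_merge) break
    ij <- which(pc == max(pc), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    mem <- sort(union(canopies[[i]]$members, canopies[[j]]$members))
    canopies[[i]] <- list(members = mem,
                          profile = apply(m[mem, , drop = FALSE], 2,
                                          stats::median))
    canopies[[j]] <- NULL
  }

  # drop canopies whose signal originates from too few samples
  canopies <- Filter(function(cp) sum(cp$profile > 0) >= min_signal_samples,
                     canopies)

  # prune members weakly rank-correlated with the bin profile
  canopies <- lapply(canopies, function(cp) {
    rho <- suppressWarnings(
      apply(m[cp$members, , drop = FALSE], 1, stats::cor, y = cp$profile,
            method = "spearman"))
    mem <- cp$members[!is.na(rho) & rho >= spearman_min]
    if (length(mem) == 0) return(NULL)
    list(members = mem,
         profile = apply(m[mem, , drop = FALSE], 2, stats::median))
  })
  canopies <- Filter(Negate(is.null), canopies)

  # overlap removal: a gene stays in the largest bin (ties: first bin)
  if (length(canopies) > 0) {
    sizes <- vapply(canopies, function(cp) length(cp$members), 0L)
    ord <- order(-sizes, seq_along(canopies))
    seen <- integer(0)
    for (b in ord) {
      mem <- setdiff(canopies[[b]]$members, seen)
      canopies[[b]]$members <- mem
      seen <- c(seen, mem)
    }
    canopies <- Filter(function(cp) length(cp$members) >= 3, canopies)
    canopies <- lapply(canopies, function(cp)
      list(members = genes[sort(cp$members)],
           profile = apply(m[cp$members, , drop = FALSE], 2, stats::median),
           size = length(cp$members)))
  }
  structure(canopies, class = "canopy_bins",
            params = list(pcc_member = pcc_member, pcc_merge = pcc_merge,
                          spearman_min = spearman_min,
                          min_signal_samples = min_signal_samples,
                          seed = seed))
}

#' @export
print.canopy_bins <- function(x, ...) {
  sizes <- vapply(x, `[[`, 0L, "size")
  cat("canopy_bins:", length(x), "bins; sizes:",
      paste(sort(sizes, decreasing = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' Classify bins into MGS and CAG size classes
#'
#' A metagenomic species (MGS) has at least 700 member genes -- large
#' enough to be a bacterial core genome. Co-abundant gene groups (CAGs)
#' have 3 to 699 genes; anything smaller is discarded.
#'
#' @param bins a \code{canopy_bins}.
#' @return the bins with a \code{size_class} element ("MGS"/"CAG"), groups
#'   below 3 genes removed.
#' @export
classify_bins <- function(bins) {
  stopifnot(inherits(bins, "canopy_bins"))
  out <- lapply(bins, function(b) {
    if (b$size < 3) return(NULL)
    b$size_class <- if (b$size >= 700) "MGS" else "CAG"
    b
  })
  out <- Filter(Negate(is.null), out)
  structure(out, class = "canopy_bins", params = attr(bins, "params"))
}

#' MAD outlier filter defining a bin's core genome
#'
#' Removes bin members whose coverage lies at least \code{k} unscaled
#' median absolute deviations from the member median in at least one
#' sample; the survivors constitute the core genome. When a sample's MAD
#' is zero, only exact-median genes satisfy that sample's criterion
#' (deviating genes are removed) and a warning is raised.
#'
#' @param bin one bin (list with \code{members}) from
#'   \code{\link{canopy_cluster}}, or a character vector of gene ids.
#' @param m genes x samples coverage matrix containing the members.
#' @param k MAD multiplier (default 24).
#' @return list: \code{core} and \code{removed} gene id vectors, plus
#'   \code{median} and \code{mad} per-sample vectors.
#' @export
mad_core_filter <- function(bin, m, k = 24) {
  members <- if (is.list(bin)) bin$members else as.character(bin)
  if (inherits(m, "gene_abundance_sim")) m <- m$coverage
  m <- as.matrix(m)
  if (!all(members %in% rownames(m)))
    stop_strainpop("bin members missing from the coverage matrix")
  x <- m[members, , drop = FALSE]
  med <- apply(x, 2, stats::median)
  madu <- apply(x, 2, function(col) stats::median(abs(col - stats::median(col))))
  if (any(madu == 0))
    warning(sum(madu == 0), " sample(s) with zero MAD; only exact-median ",
            "genes pass there")
  dev <- abs(sweep(x, 2, med))
  flag <- sweep(dev, 2, k * madu, `>=`) & dev > 0
  removed <- members[rowSums(flag) > 0]
  list(core = setdiff(members, removed), removed = removed,
       median = med, mad = madu)
}

#' Read / write gene x sample coverage TSV
#'
#' First column \code{gene_id}, one column per sample.
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_abundance_tsv <- function(path) {
  df <- read_tsv_header(path)
  if (names(df)[1] != "gene_id")
    stop_strainpop("abundance TSV must start with a 'gene_id' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_abundance_tsv
#' @param m genes x samples matrix.
#' @param header provenance comment lines.
#' @export
write_abundance_tsv <- function(m, path, header = character()) {
  df <- data.frame(gene_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write_tsv_header(df, path, c("gene mean coverage across samples", header))
}
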