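#' Build a gene index from sequences
#'
#' @param seqs \code{DNAStringSet} (or named character vector) of gene
#'   nucleotide sequences; FASTA headers may carry a \code{partial=TRUE} /
#'   \code{partial=FALSE} token.
#' @return data.frame: \code{gene_id}, \code{length}, \code{is_partial}.
#' @export
gene_index <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  hdr <- names(seqs)
  if (is.null(hdr)) stop_strainpop("gene sequences must be named")
  gene_id <- sub("\\s.*$", "", hdr)
  is_partial <- grepl("partial=TRUE", hdr, fixed = TRUE)
  data.frame(gene_id = gene_id, length = Biostrings::width(seqs),
             is_partial = is_partial)
}

#' Read genes with partial flags from FASTA
#'
#' @param path FASTA path.
#' @return list: \code{seqs} (\code{DNAStringSet}, names reduced to gene
#'   ids) and \code{index} (from \code{\link{gene_index}}).
#' @export
read_gene_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  idx <- gene_index(seqs)
  names(seqs) <- idx$gene_id
  list(seqs = seqs, index = idx)
}

#' Read a BLAST outfmt-6-like similarity hit table
#'
#' Tab-separated with at least the standard first 12 columns; only query,
#' subject, percent identity, alignment length and e-value are used.
#'
#' @param path file path.
#' @return data.frame: \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{aln_len}, \code{evalue}.
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 11) stop_strainpop("hit table needs >= 11 columns (outfmt 6)")
  data.frame(query_id = df[[1]], subject_id = df[[2]],
             pct_identity = as.numeric(df[[3]]),
             aln_len = as.integer(df[[4]]), evalue = as.numeric(df[[11]]))
}

#' Filter similarity hits into accepted clustering edges
#'
#' A hit becomes an undirected edge iff identity >= \code{id_min}, the
#' alignment covers at least \code{cov_min} of the shorter sequence, the
#' e-value passes, the longer/shorter length ratio is at most
#' \code{len_ratio_max} (guards against shared-domain artifacts), and both
#' genes have the same partial status (partial-vs-complete hits are
#' spurious links). Self-hits are dropped; directed duplicates are
#' deduplicated to one undirected edge.
#'
#' @param hits data.frame with \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{aln_len}, \code{evalue}.
#' @param genes gene index (from \code{\link{gene_index}}).
#' @param id_min minimum percent identity (default 95).
#' @param cov_min minimum fraction of the shorter gene covered (default
#'   0.9).
#' @param evalue_max maximum e-value (default 1e-6).
#' @param len_ratio_max maximum long/short length ratio (default 4).
#' @return data.frame of accepted edges (\code{a}, \code{b}) with
#'   \code{a < b} lexicographically.
#' @export
filter_hits <- function(hits, genes, id_min = 95, cov_min = 0.9,
                        evalue_max = 1e-6, len_ratio_max = 4) {
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), genes$gene_id)
  if (length(unknown) > 0)
    stop_strainpop("unknown gene id(s) in hit table: ",
                   paste(utils::head(unknown, 5), collapse = ", "))
  lq <- genes$length[match(hits$query_id, genes$gene_id)]
  ls <- genes$length[match(hits$subject_id, genes$gene_id)]
  pq <- genes$is_partial[match(hits$query_id, genes$gene_id)]
  ps <- genes$is_partial[match(hits$subject_id, genes$gene_id)]
  keep <- hits$query_id != hits$subject_id &
    hits$pct_identity >= id_min &
    hits$aln_len >= cov_min * pmin(lq, ls) &
    hits$evalue <= evalue_max &
    pmax(lq, ls) / pmin(lq, ls) <= len_ratio_max &
    pq == ps
  a <- pmin(hits$query_id[keep], hits$subject_id[keep])
  b <- pmax(hits$query_id[keep], hits$subject_id[keep])
  unique(data.frame(a = a, b = b))
}

#' Single-linkage clustering of genes over accepted edges
#'
#' Connected components of the accepted-edge graph; genes without any edge
#' are singletons. Cluster ids are the lexicographically smallest member,
#' so the partition is independent of input order.
#'
#' @param edges data.frame from \code{\link{filter_hits}}.
#' @param gene_ids character vector of all gene ids (defines singleton
#'   membership).
#' @return data.frame: \code{gene_id}, \code{cluster_id}.
#' @export
single_linkage_cluster <- function(edges, gene_ids) {
  gene_ids <- as.character(gene_ids)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = gene_ids))
  comp <- igraph::components(g)$membership
  cid <- tapply(names(comp), comp, min)[as.character(comp)]
  out <- data.frame(gene_id = names(comp), cluster_id = as.character(cid))
  out[match(gene_ids, out$gene_id), , drop = FALSE]
}

#' Majority-consensus representative of a cluster
#'
#' Votes are taken per position among the members sharing the modal length
#' (the table does not embed an aligner; members of other lengths are
#' excluded from the vote and counted in the \code{n_excluded} attribute).
#' At each position the modal nucleotide wins; ties are broken by a seeded
#' uniform choice among the tied states.
#'
#' @param seqs character vector of member sequences (non-empty).
#' @param seed integer seed for tie breaking.
#' @return consensus sequence string with attributes \code{n_voters} and
#'   \code{n_excluded}.
#' @export
consensus_sequence <- function(seqs, seed = 1L) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) == 0) stop_strainpop("empty cluster")
  lens <- nchar(seqs)
  tl <- table(lens)
  modal_len <- as.integer(names(tl)[tl == max(tl)])
  modal_len <- min(modal_len)  # deterministic on length-mode ties
  voters <- seqs[lens == modal_len]
  set.seed(substream_seed(seed, 5L))
  chars <- do.call(rbind, strsplit(voters, "", fixed = TRUE))
  cons <- vapply(seq_len(modal_len), function(p) {
    tab <- table(chars[, p])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) top else sample(top, 1)
  }, "")
  structure(paste(cons, collapse = ""), n_voters = length(voters),
            n_excluded = length(seqs) - length(voters))
}

#' Two-stage catalog clustering (per-sample, then across samples)
#'
#' Mirrors the production procedure: intra-sample clustering builds
#' sample-specific catalogs, then cross-sample edges join them. Because
#' single linkage is transitive, on inputs without borderline hits this
#' yields the same partition as one-stage clustering of all accepted
#' edges; the function exists to make that equivalence checkable.
#'
#' @param edges accepted edges (data.frame \code{a}, \code{b}).
#' @param genes gene index with a \code{sample_id} column.
#' @return data.frame as \code{\link{single_linkage_cluster}}.
#' @export
two_stage_cluster <- function(edges, genes) {
  if (!"sample_id" %in% names(genes))
    stop_strainpop("two-stage clustering needs genes$sample_id")
  sa <- genes$sample_id[match(edges$a, genes$gene_id)]
  sb <- genes$sample_id[match(edges$b, genes$gene_id)]
  intra <- edges[sa == sb, , drop = FALSE]
  stage1 <- single_linkage_cluster(intra, genes$gene_id)
  # lift cross-sample edges onto stage-1 representatives, then merge
  rep_of <- stats::setNames(stage1$cluster_id, stage1$gene_id)
  cross <- edges[sa != sb, , drop = FALSE]
  lifted <- unique(data.frame(a = pmin(rep_of[cross$a], rep_of[cross$b]),
                              b = pmax(rep_of[cross$a], rep_of[cross$b])))
  stage2 <- single_linkage_cluster(lifted, unique(stage1$cluster_id))
  final <- stats::setNames(stage2$cluster_id, stage2$gene_id)
  data.frame(gene_id = stage1$gene_id,
             cluster_id = as.character(final[stage1$cluster_id]))
}
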