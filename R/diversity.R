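#' Phylogenetic correlation matrix of a strain tree
#'
#' Shared root-to-tip branch length between every pair of tips,
#' standardized to unit diagonal. Encodes how phylogenetically redundant
#' two strains are (1 = identical position, 0 = share no branch).
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return tips x tips correlation matrix.
#' @export
phylo_correlation <- function(tree) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0)
    stop_strainpop("tree must have positive branch lengths")
  V <- ape::vcv(tree)
  stats::cov2cor(V)
}

#' Phylogenetic species evenness (PSE)
#'
#' Abundance-weighted phylogenetic alpha-diversity. Over the strains
#' present (abundance > 0), with abundance vector m, total N, mean
#' abundance \eqn{\bar m} and phylogenetic correlation matrix C:
#' \deqn{PSE = \frac{N\,\mathrm{diag}(C)^\top m - m^\top C m}
#'   {N^2 - N\bar m}}
#' Equals 1 for a star phylogeny with equal abundances and decreases with
#' abundance skew or phylogenetic clustering; reduces to PSV when
#' abundances are equal. Undefined (NA, with warning) when a single strain
#' carries all abundance.
#'
#' @param tree strain tree (\code{phylo}).
#' @param abundances nonnegative per-strain abundances or frequencies,
#'   named by tip label (unnamed vectors are matched by tip order).
#' @return PSE value.
#' @export
pse <- function(tree, abundances) {
  C <- phylo_correlation(tree)
  tips <- rownames(C)
  m <- if (!is.null(names(abundances))) {
    if (!all(tips %in% names(abundances)))
      stop_strainpop("abundances must cover every tip")
    abundances[tips]
  } else {
    if (length(abundances) != length(tips))
      stop_strainpop("abundance length must match number of tips")
    stats::setNames(abundances, tips)
  }
  if (any(m < 0) || sum(m) <= 0)
    stop_strainpop("abundances must be nonnegative with a positive total")
  present <- m > 0
  if (sum(present) < 2) {
    warning("single strain present; PSE undefined")
    return(NA_real_)
  }
  m <- m[present]
  C <- C[present, present]
  N <- sum(m)
  den <- N^2 - N * mean(m)
  num <- N * sum(diag(C) * m) - drop(t(m) %*% C %*% m)
  num / den
}

#' Normalized weighted UniFrac distance between two communities
#'
#' \deqn{d_{WU}(a,b) = \frac{\sum_e l_e\,|p_a(e) - p_b(e)|}
#'   {\sum_e l_e\,(p_a(e) + p_b(e))}}
#' where \eqn{p_x(e)} is the fraction of community x descending from branch
#' e. Zero for identical communities; one when the communities occupy
#' disjoint subtrees.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param a,b per-strain frequency vectors (each summing to 1), named by
#'   tip label or in tip order.
#' @return distance in [0, 1].
#' @export
weighted_unifrac <- function(tree, a, b) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0)
    stop_strainpop("tree must have positive branch lengths")
  tips <- tree$tip.label
  align <- function(v, what) {
    v <- if (!is.null(names(v))) {
      if (!all(tips %in% names(v)))
        stop_strainpop(what, " must cover every tip")
      v[tips]
    } else {
      if (length(v) != length(tips))
        stop_strainpop(what, " length must match number of tips")
      v
    }
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
      stop_strainpop(what, " must be a frequency vector summing to 1")
    as.numeric(v)
  }
  pa <- align(a, "a"); pb <- align(b, "b")
  n_tip <- length(tips)
  n_node <- max(tree$edge)
  wa <- wb <- numeric(n_node)
  wa[seq_len(n_tip)] <- pa
  wb[seq_len(n_tip)] <- pb
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    wa[par] <- wa[par] + wa[child]
    wb[par] <- wb[par] + wb[child]
  }
  l <- tr$edge.length
  pa_e <- wa[tr$edge[, 2]]
  pb_e <- wb[tr$edge[, 2]]
  den <- sum(l * (pa_e + pb_e))
  if (den == 0) return(0)
  sum(l * abs(pa_e - pb_e)) / den
}

#' Spearman rank association between two paired vectors
#'
#' Reports rho, rho-squared (as correlations between diversity measures are
#' conventionally quoted) and the p-value of \code{stats::cor.test}.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list: \code{rho}, \code{rho2}, \code{p}, \code{n}.
#' @export
rank_association <- function(x, y) {
  if (length(x) != length(y)) stop_strainpop("x and y must be paired")
  if (length(x) < 4) stop_strainpop("need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; rank association undefined")
    return(list(rho = NA_real_, rho2 = NA_real_, p = NA_real_,
                n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  list(rho = rho, rho2 = rho^2, p = ct$p.value, n = length(x))
}

#' Mantel-style permutation association between two distance matrices
#'
#' Spearman correlation of the off-diagonal entries, with significance from
#' row/column permutations of one matrix:
#' p = (1 + #\{permuted statistic >= observed\}) / (1 + n_perm). Used, for
#' instance, to test whether host genetic differentiation predicts symbiont
#' F_ST.
#'
#' @param d1,d2 symmetric distance matrices over the same samples (or
#'   \code{dist} objects).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list: \code{statistic} (Spearman rho), \code{p}, \code{n_perm}.
#' @export
matrix_association <- function(d1, d2, n_perm = 9999L, seed = 1L) {
  d1 <- stats::as.dist(d1)
  d2 <- stats::as.dist(d2)
  n <- attr(d1, "Size")
  if (attr(d2, "Size") != n)
    stop_strainpop("distance matrices must be over the same sample set")
  if (n < 4) stop_strainpop("need at least 4 samples")
  set.seed(substream_seed(seed, 7L))
  mt <- vegan::mantel(d1, d2, method = "spearman", permutations = n_perm)
  list(statistic = unname(mt$statistic), p = mt$signif, n_perm = n_perm)
}
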