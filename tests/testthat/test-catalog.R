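make_genes <- function() {
  data.frame(gene_id = c("a", "b", "c", "p1", "q1", "short", "long"),
             length = c(300L, 300L, 300L, 300L, 300L, 100L, 500L),
             is_partial = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
}

hit <- function(q, s, id = 100, aln = 300, ev = 1e-30)
  data.frame(query_id = q, subject_id = s, pct_identity = id, aln_len = aln,
             evalue = ev)

test_that("hit filtering enforces identity, coverage, ratio and partial rules", {
  g <- make_genes()
  expect_equal(nrow(filter_hits(hit("a", "b"), g)), 1)
  # self hits dropped
  expect_equal(nrow(filter_hits(hit("a", "a"), g)), 0)
  # identity below 95
  expect_equal(nrow(filter_hits(hit("a", "b", id = 94.9), g)), 0)
  # coverage below 90% of the shorter gene
  expect_equal(nrow(filter_hits(hit("a", "b", aln = 269), g)), 0)
  expect_equal(nrow(filter_hits(hit("a", "b", aln = 270), g)), 1)
  # e-value
  expect_equal(nrow(filter_hits(hit("a", "b", ev = 1e-5), g)), 0)
  # length ratio 5 rejected even at high identity
  expect_equal(nrow(filter_hits(hit("short", "long", id = 99, aln = 95), g)), 0)
  # partial vs nonpartial discarded
  expect_equal(nrow(filter_hits(hit("p1", "q1"), g)), 0)
  expect_error(filter_hits(hit("a", "zz"), g), "zz")
})

test_that("directed duplicate hits collapse to one undirected edge", {
  g <- make_genes()
  hits <- rbind(hit("a", "b"), hit("b", "a"))
  e <- filter_hits(hits, g)
  expect_equal(nrow(e), 1)
  expect_equal(e$a, "a")
  expect_equal(e$b, "b")
})

test_that("single linkage forms connected components with stable ids", {
  ids <- c("a", "b", "c", "d", "e")
  edges <- data.frame(a = c("a", "b"), b = c("b", "c"))
  cl <- single_linkage_cluster(edges, ids)
  expect_equal(cl$cluster_id[cl$gene_id %in% c("a", "b", "c")],
               rep("a", 3))
  expect_equal(cl$cluster_id[cl$gene_id == "d"], "d")
  expect_equal(cl$cluster_id[cl$gene_id == "e"], "e")
  # no edges: all singletons
  none <- single_linkage_cluster(data.frame(a = character(), b = character()),
                                 c("x", "y", "z"))
  expect_equal(none$cluster_id, c("x", "y", "z"))
  # order independence
  cl2 <- single_linkage_cluster(edges[2:1, ], rev(ids))
  m <- merge(cl, cl2, by = "gene_id")
  expect_identical(m$cluster_id.x, m$cluster_id.y)
})

test_that("planted gene families are recovered exactly", {
  set.seed(9)
  base1 <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  base2 <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sapply(ch[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1))
    paste(ch, collapse = "")
  }
  fam1 <- c(f1a = base1, f1b = mutate(base1, 2), f1c = mutate(base1, 3))
  fam2 <- c(f2a = base2, f2b = mutate(base2, 2))
  genes <- gene_index(c(fam1, fam2))
  # hits within families at high identity, none across
  pairs <- rbind(t(combn(names(fam1), 2)), t(combn(names(fam2), 2)))
  hits <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    hit(pairs[i, 1], pairs[i, 2], id = 98, aln = 118)))
  cl <- single_linkage_cluster(filter_hits(hits, genes), genes$gene_id)
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_equal(unique(cl$cluster_id[cl$gene_id %in% names(fam1)]), "f1a")
})

test_that("consensus takes positionwise majority with seeded ties", {
  expect_equal(as.character(consensus_sequence(c("ACGT", "ACGT", "ACGA"))),
               "ACGT")
  # tie: reproducible under the same seed, only the tied position may differ
  c1 <- as.character(consensus_sequence(c("AC", "AG"), seed = 4))
  c2 <- as.character(consensus_sequence(c("AC", "AG"), seed = 4))
  expect_identical(c1, c2)
  expect_true(c1 %in% c("AC", "AG"))
  # members off the modal length are excluded from the vote
  cons <- consensus_sequence(c("AAAA", "AAAT", "AAAA", "TT"), seed = 1)
  expect_equal(as.character(cons), "AAAA")
  expect_equal(attr(cons, "n_excluded"), 1)
  expect_error(consensus_sequence(character(0)), "empty")
})

test_that("consensus agrees with a positionwise argmax oracle", {
  set.seed(77)
  for (i in 1:200) {
    trio <- vapply(1:3, function(.)
      paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = ""), "")
    cons <- strsplit(as.character(consensus_sequence(trio, seed = i)), "")[[1]]
    chars <- do.call(rbind, strsplit(trio, ""))
    for (p in 1:12) {
      tab <- table(chars[, p])
      if (sum(tab == max(tab)) == 1)
        expect_identical(cons[p], names(which.max(tab)))
      else
        expect_true(cons[p] %in% names(tab)[tab == max(tab)])
    }
  }
})

test_that("clustering is invariant to hit order and to staging", {
  set.seed(12)
  ids <- sprintf("s%d_g%d", rep(1:3, each = 4), rep(1:4, 3))
  genes <- data.frame(gene_id = ids, length = 300L, is_partial = FALSE,
                      sample_id = rep(sprintf("s%d", 1:3), each = 4))
  # three cross-sample families of size 3 plus three singletons
  fams <- list(c("s1_g1", "s2_g1", "s3_g1"),
               c("s1_g2", "s2_g2", "s3_g2"),
               c("s1_g3", "s2_g3", "s3_g3"))
  hits <- do.call(rbind, lapply(fams, function(f) {
    p <- t(combn(f, 2))
    do.call(rbind, lapply(seq_len(nrow(p)), function(i) hit(p[i, 1], p[i, 2])))
  }))
  e <- filter_hits(hits, genes)
  one <- single_linkage_cluster(e, genes$gene_id)
  shuf <- filter_hits(hits[sample(nrow(hits)), ], genes)
  expect_identical(single_linkage_cluster(shuf, genes$gene_id), one)
  two <- two_stage_cluster(e, genes)
  m <- merge(one, two, by = "gene_id")
  expect_identical(m$cluster_id.x, m$cluster_id.y)
})
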