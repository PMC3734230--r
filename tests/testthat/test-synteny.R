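# Circular gene orders, shared adjacencies, cluster status and panels.

test_that("gene order excludes tRNA/pseudogene/remnant and keeps trans-spliced blocks apart", {
  f <- dplyr::bind_rows(
    feature_table("cox1", "protein", "+", 10, 100),
    feature_table("trnW", "tRNA", "+", 150, 220),
    feature_table("nad1", "protein", "+", 300, 360, trans_block = "nad1e"),
    feature_table("nad1", "protein", "-", 500, 560, trans_block = "nad1d"),
    feature_table("rps19_frag", "remnant", "+", 600, 653),
    feature_table("rrn18", "rRNA", "+", 700, 900),
    feature_table("cox1", "protein", "+", 950, 1040, copy_index = 2L)
  )
  ag <- annotated_genome(mt_genome(strrep("A", 1200)), f)
  ord <- extract_gene_order(ag)
  expect_equal(ord$label, c("cox1", "nad1e", "nad1d", "rrn18", "cox1"))
  expect_equal(sum(ord$label == "cox1"), 2L)  # duplicate copies, same label
})

test_that("identical circular orders share n adjacencies and one run", {
  o <- toy_order_genome(paste0("g", 1:6), rep("+", 6))
  ord <- extract_gene_order(o)
  expect_equal(nrow(shared_adjacencies(ord, ord)), 6L)
  expect_equal(count_synteny_clusters(ord, ord, mode = "pair"), 6L)
  expect_equal(count_synteny_clusters(ord, ord, mode = "run"), 1L)
})

test_that("disjoint gene sets share nothing", {
  o1 <- extract_gene_order(toy_order_genome(paste0("a", 1:5), rep("+", 5)))
  o2 <- extract_gene_order(toy_order_genome(paste0("b", 1:5), rep("+", 5)))
  expect_equal(count_synteny_clusters(o1, o2), 0L)
})

test_that("a single internal block inversion yields n - 2 shared adjacencies", {
  for (n in 5:12) {
    for (k in 2:(n - 2)) {
      labels <- paste0("g", 1:n)
      strands <- rep("+", n)
      inv_idx <- 2:(k + 1)
      lab2 <- labels
      str2 <- strands
      lab2[inv_idx] <- rev(labels[inv_idx])
      str2[inv_idx] <- "-"
      o1 <- extract_gene_order(toy_order_genome(labels, strands))
      o2 <- extract_gene_order(toy_order_genome(lab2, str2))
      expect_equal(count_synteny_clusters(o1, o2), n - 2L,
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("pair-mode counts match the brute-force oracle on random permutation pairs", {
  set.seed(101)
  for (trial in 1:200) {
    n <- sample(4:12, 1)
    o1 <- random_order(n)
    o2 <- random_order(n)
    g1 <- toy_order_genome(o1$label, o1$strand)
    g2 <- toy_order_genome(o2$label, o2$strand)
    e1 <- extract_gene_order(g1)
    e2 <- extract_gene_order(g2)
    expect_equal(count_synteny_clusters(e1, e2), oracle_adjacency_count(e1, e2))
    # upper bounds
    expect_lte(count_synteny_clusters(e1, e2), n)
    expect_lte(count_synteny_clusters(e1, e2, mode = "run"),
               max(1L, count_synteny_clusters(e1, e2)))
  }
})

test_that("synteny matrix is symmetric with self-comparison diagonal", {
  gs <- list(toy_order_genome(paste0("g", 1:6), rep("+", 6), species = "s1"),
             toy_order_genome(paste0("g", c(1, 3, 2, 4, 5, 6)), rep("+", 6),
                              species = "s2"),
             toy_order_genome(paste0("g", 6:1), rep("-", 6), species = "s3"))
  m <- synteny_matrix(gs)
  expect_true(isSymmetric(unname(m)))
  expect_equal(diag(m), setNames(rep(6L, 3), c("s1", "s2", "s3")))
  expect_equal(m["s1", "s3"], 6L)  # full reversal preserves all adjacencies
})

test_that("cluster status distinguishes present, broken and member-missing", {
  present <- toy_order_genome(c("cob", "rps14", "x1", "x2"), rep("+", 4))
  expect_equal(cluster_status(c("cob", "rps14"), present), "present")
  # split cluster: a gene transposed in between
  broken <- toy_order_genome(c("cob", "x1", "rps14", "x2"), rep("+", 4))
  expect_equal(cluster_status(c("cob", "rps14"), broken), "broken")
  # strand flip of one member breaks co-transcription
  flipped <- toy_order_genome(c("cob", "rps14", "x1", "x2"),
                              c("+", "-", "+", "+"))
  expect_equal(cluster_status(c("cob", "rps14"), flipped), "broken")
  # whole-block inversion keeps the cluster
  inverted <- toy_order_genome(c("rps14", "cob", "x1", "x2"),
                               c("-", "-", "+", "+"))
  expect_equal(cluster_status(c("cob", "rps14"), inverted), "present")
  missing <- toy_order_genome(c("cob", "x1", "x2", "x3"), rep("+", 4))
  expect_equal(cluster_status(c("cob", "rps14"), missing), "member_missing")
  expect_error(cluster_status("cob", present), "at least two")
})

test_that("member_missing takes precedence and the grid renders +/-/# symbols", {
  gs <- list(toy_order_genome(c("a", "b", "c", "d"), rep("+", 4), species = "s1"),
             toy_order_genome(c("a", "c", "b", "d"), rep("+", 4), species = "s2"),
             toy_order_genome(c("a", "c", "d", "e"), rep("+", 4), species = "s3"))
  grid <- cluster_presence_grid(list(ab = c("a", "b")), gs)
  expect_equal(grid$ab, c("+", "-", "#"))
})

test_that("conserved clusters separate universal from group-specific", {
  mk <- function(labels, strands, sp, grp) {
    toy_order_genome(labels, strands, species = sp, group = grp)
  }
  base <- c("u1", "u2", "m1", "m2", "d1", "d2", "f1", "f2")
  # u1-u2 adjacent everywhere; m1-m2 adjacent only in monocots; d1-d2 only
  # in dicots
  mono1 <- mk(c("u1", "u2", "m1", "m2", "f1", "d1", "f2", "d2"), rep("+", 8),
              "mono1", "monocot")
  mono2 <- mk(c("m1", "m2", "f2", "u1", "u2", "d1", "f1", "d2"), rep("+", 8),
              "mono2", "monocot")
  dic1 <- mk(c("u1", "u2", "f1", "d1", "d2", "m1", "f2", "m2"), rep("+", 8),
             "dic1", "dicot")
  dic2 <- mk(c("d1", "d2", "m2", "u1", "u2", "f2", "m1", "f1"), rep("+", 8),
             "dic2", "dicot")
  cc <- conserved_clusters(list(mono1, mono2, dic1, dic2))
  key <- paste(cc$a, cc$b, cc$scope)
  expect_true("u1 u2 universal" %in% key)
  expect_true("m1 m2 monocot" %in% key)
  expect_true("d1 d2 dicot" %in% key)
})

test_that("generated rearranged pairs agree with their truth tables", {
  for (sd in c(3, 5, 9)) {
    pr <- generate_related_pair(sim_config(seed = sd), n_inversions = 1)
    o1 <- extract_gene_order(pr$a)
    o2 <- extract_gene_order(pr$b)
    expect_equal(count_synteny_clusters(o1, o2),
                 pr$truth$shared_adjacency_count)
    expect_equal(pr$truth$shared_adjacency_count, nrow(o1) - 2L)
  }
  pr0 <- generate_related_pair(sim_config(seed = 4), n_inversions = 0)
  o1 <- extract_gene_order(pr0$a)
  expect_equal(count_synteny_clusters(o1, extract_gene_order(pr0$b)), nrow(o1))
})
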