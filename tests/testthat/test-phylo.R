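# Concatenation, p-distances, neighbor joining, Robinson-Foulds.

toy_loci <- function() {
  tibble::tribble(
    ~locus, ~species, ~seq,
    "cob", "A", "ACGT",
    "cob", "B", "ACGA",
    "cob", "C", "TCGA",
    "cox1", "A", "AAACCC",
    "cox1", "B", "AAACCG",
    "cox1", "C", "AAACGG"
  )
}

test_that("concatenation joins head-to-tail with partition bookkeeping", {
  ca <- concatenate_loci(toy_loci(), c("cob", "cox1"))
  expect_equal(unname(nchar(ca$sequences)), rep(10L, 3))
  expect_equal(ca$partitions$end, c(4L, 10L))
  expect_equal(substr(ca$sequences[["A"]], 1, 4), "ACGT")
  # round-trip split recovers the inputs
  back <- split_concat(ca)
  expect_equal(dplyr::arrange(back, locus, species),
               dplyr::arrange(toy_loci(), locus, species))
  # named gene sets restrict the loci
  expect_error(concatenate_loci(toy_loci(), "ccm"), "absent")
  expect_error(concatenate_loci(toy_loci()[-1, ], c("cob", "cox1")),
               "lacks species")
})

test_that("the conserved gene sets carry the published rosters", {
  all21 <- conserved_gene_set("all21")
  expect_length(all21, 21L)
  expect_setequal(conserved_gene_set("ccm"),
                  c("ccmB", "ccmC", "ccmFC", "ccmFN"))
  expect_equal(conserved_gene_set("complexIII"), "cob")
  expect_length(conserved_gene_set("complexI"), 9L)
  expect_true(all(conserved_gene_set("complexV") %in% all21))
})

test_that("p-distance uses pairwise deletion", {
  d <- p_distance_matrix(c(A = "ACGT", B = "ACGA"))
  expect_equal(d["A", "B"], 0.25)
  expect_equal(p_distance_matrix(c(A = "ACGT", B = "ACGT"))["A", "B"], 0)
  d2 <- p_distance_matrix(c(A = "AC-T", B = "ACGT"))
  expect_equal(d2["A", "B"], 0)  # 3 comparable columns, all equal
  d3 <- p_distance_matrix(c(A = "ACNT", B = "ACGA"))
  expect_equal(d3["A", "B"], 1 / 3)
  expect_error(p_distance_matrix(c(A = "----", B = "ACGT")), "comparable")
})

test_that("three-taxon NJ solves the closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj <- nj_tree(d)
  td <- tidy(nj)
  bl <- setNames(td$branch_length, td$label)
  expect_equal(bl[["a"]], 1)
  expect_equal(bl[["b"]], 1)
  expect_equal(bl[["c"]], 2)
  g <- glance(nj)
  expect_equal(g$n_tips, 3L)
  expect_equal(g$total_branch_length, 4)
})

test_that("NJ recovers topology and branch lengths from additive matrices", {
  set.seed(131)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5))
    d <- stats::cophenetic(tr)
    ord <- sort(rownames(d))
    nj <- nj_tree(d[ord, ord])
    expect_equal(rf_distance(nj, tr), 0L)
    expect_lt(abs(sum(nj$tree$edge.length) - sum(tr$edge.length)), 1e-6)
    # cross-check against the reference NJ implementation
    expect_equal(as.integer(phangorn::RF.dist(ape::unroot(nj$tree),
                                              ape::unroot(ape::nj(d)))), 0L)
  }
})

test_that("NJ input validation and clamping", {
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(bad), "symmetric|three")
  # non-additive matrix that forces a negative estimate: lengths clamped
  d <- matrix(c(0, 0.1, 0.4, 0.5,
                0.1, 0, 0.45, 0.55,
                0.4, 0.45, 0, 0.05,
                0.5, 0.55, 0.05, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  nj <- nj_tree(d)
  expect_true(all(nj$tree$edge.length >= 0))
})

test_that("ultrametric four-taxon matrices give the correct topology", {
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 4,
                6, 6, 4, 0), 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  nj <- nj_tree(d)
  ref <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(rf_distance(nj, ref), 0L)
})

test_that("concatenation order changes neither distances nor topology", {
  set.seed(17)
  loci <- tidyr::crossing(locus = c("cob", "cox1", "atp1"),
                          species = c("A", "B", "C", "D")) %>%
    dplyr::mutate(seq = vapply(seq_len(dplyr::n()),
                               function(i) random_dna(60), character(1)))
  d1 <- p_distance_matrix(concatenate_loci(loci, c("cob", "cox1", "atp1")))
  d2 <- p_distance_matrix(concatenate_loci(loci, c("atp1", "cob", "cox1")))
  expect_equal(d1, d2)
})

test_that("RF distance equals a brute-force bipartition comparison", {
  bipartitions <- function(tr) {
    tr <- ape::unroot(tr)
    tips <- sort(tr$tip.label)
    ntip <- length(tips)
    out <- character(0)
    for (nd in setdiff(unique(tr$edge[, 2]), seq_len(ntip))) {
      below <- ape::extract.clade(tr, nd)$tip.label
      side <- sort(below)
      other <- sort(setdiff(tips, below))
      key <- paste(c(paste(side, collapse = ","), "|",
                     paste(other, collapse = ",")), collapse = "")
      key2 <- paste(c(paste(other, collapse = ","), "|",
                      paste(side, collapse = ",")), collapse = "")
      out <- c(out, min(key, key2))
    }
    unique(out)
  }
  set.seed(19)
  for (i in 1:25) {
    t1 <- ape::rtree(8)
    t2 <- ape::rtree(8, tip.label = t1$tip.label)
    b1 <- bipartitions(t1)
    b2 <- bipartitions(t2)
    brute <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
    expect_equal(rf_distance(t1, t2), brute)
  }
  t1 <- ape::rtree(6)
  expect_equal(rf_distance(t1, t1), 0L)
  expect_error(rf_distance(t1, ape::rtree(5)), "differ")
  t4a <- ape::read.tree(text = "((a,b),(c,d));")
  t4b <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t4a, t4b), 2L)
})

test_that("panels evolved down a tree give an RF-0 concatenated NJ tree", {
  tree <- ape::read.tree(
    text = "((A:0.02,B:0.03):0.02,(C:0.04,(D:0.03,E:0.02):0.02):0.01);")
  cfg <- sim_config(length = 50000, seed = 921,
                    genes = default_gene_roster()[1:20, ],
                    repeat_plan = default_repeat_plan()[0, ],
                    mtpt_plan = default_mtpt_plan(0, 0, 0))
  panel <- generate_species_set(tree, cfg)
  loci <- mtcompare:::panel_locus_alignments(panel$genomes)
  ca <- concatenate_loci(loci, intersect(conserved_gene_set("all21"),
                                         unique(loci$locus)))
  nj <- nj_tree(p_distance_matrix(ca))
  expect_equal(rf_distance(nj, tree), 0L)
})
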