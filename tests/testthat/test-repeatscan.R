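# Repeat detection, family classification and the size-class landscape.

test_that("family classification follows copy orientations", {
  expect_equal(classify_family(c("forward", "forward")), "DR")
  expect_equal(classify_family(c("forward", "reverse")), "IR")
  expect_equal(classify_family(c("forward", "forward", "reverse")), "IR/DR")
  expect_equal(classify_family(rep("forward", 3)), "DR")
  expect_error(classify_family("forward"), "two copies")
})

test_that("published repeat rows classify to their printed DR/IR types", {
  tab <- utils::read.delim(extdata("gh_repeats_gt100bp.tsv"))
  for (i in seq_len(nrow(tab))) {
    starts <- unlist(tab[i, paste0("copy", 1:4, "_start")])
    ends <- unlist(tab[i, paste0("copy", 1:4, "_end")])
    ok <- !is.na(starts)
    # inverted copies are printed with start > end relative to copy 1
    ori <- ifelse(starts[ok] > ends[ok], "reverse", "forward")
    expect_equal(classify_family(ori), tab$type[i], info = tab$no[i])
  }
})

test_that("planted exact families are recovered with correct type and length", {
  sim <- generate_mt_genome(repeat_only_cfg(seed = 201, divergence = 0))
  fams <- find_repeats(sim$mt)
  tr <- sim$truth$repeats
  expect_equal(family_recall(tr, fams), 1)
  # each planted family maps to a reported family of matching type/length
  cp <- repeat_copies(fams)
  for (f in split(tr, tr$family)) {
    hit <- cp[cp$start <= f$end[1] & cp$end >= f$start[1], ]
    expect_gt(nrow(hit), 0)
    expect_lte(abs(hit$rep_length[1] - f$rep_length[1]), 6)
    fam <- fams[fams$family_id == hit$family_id[1], ]
    expect_equal(fam$type, f$type[1])
    expect_gte(fam$identity, 99.5)
  }
})

test_that("a sequence without repeated seeds yields no families", {
  set.seed(77)
  repeat {
    s <- random_dna(600)
    kmers <- substring(s, 1:(600 - 14), 15:600)
    if (!anyDuplicated(kmers)) break
  }
  g <- mt_genome(s, circular = FALSE)
  expect_equal(nrow(find_repeats(g)), 0L)
})

test_that("reported copy pairs realign at or above the identity floor", {
  sim <- generate_mt_genome(repeat_only_cfg(seed = 303, divergence = 0.02))
  fams <- find_repeats(sim$mt, min_identity = 90)
  seqv <- sim$mt$genome$seq
  for (i in seq_len(nrow(fams))) {
    cps <- fams$copies[[i]]
    s1 <- substr(seqv, cps$start[1], cps$end[1])
    s2 <- substr(seqv, cps$start[2], cps$end[2])
    if (cps$orientation[2] == "reverse") s2 <- revcomp(s2)
    pa <- Biostrings::pairwiseAlignment(s1, s2, type = "local")
    expect_gte(Biostrings::pid(pa), 90 - 1e-6)
  }
})

test_that("scan is strand-invariant up to coordinate reflection", {
  sim <- generate_mt_genome(repeat_only_cfg(seed = 404, divergence = 0))
  fwd <- find_repeats(sim$mt)
  rc <- mt_genome(revcomp(sim$mt$genome$seq), circular = TRUE)
  rev <- find_repeats(rc)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$rep_length), sort(rev$rep_length))
  expect_equal(table(fwd$type), table(rev$type))
})

test_that("circular scanning reports an origin-spanning repeat once", {
  set.seed(55)
  bg <- random_dna(6000)
  unit <- random_dna(400)
  # one copy crosses the origin: last 200 bp + first 200 bp
  s <- paste0(substr(unit, 201, 400), substr(bg, 201, 3000), unit,
              substr(bg, 3401, 5800), substr(unit, 1, 200))
  g <- mt_genome(s, circular = TRUE)
  fams <- find_repeats(g)
  expect_equal(nrow(fams), 1L)
  expect_gte(fams$rep_length[1], 395)
  cps <- fams$copies[[1]]
  expect_true(any(cps$start > cps$end))  # wrap representation
})

test_that("landscape tabulation reproduces the published coverage row", {
  tab <- utils::read.delim(extdata("gh_repeat_landscape.tsv"))
  # synthetic family table carrying the printed class counts and totals
  fams <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(i) {
    n <- tab$n_families[i]
    lo <- c(20, 40, 60, 80, 100, 1000)[i]
    per <- tab$total_bp[i] %/% n
    extra <- tab$total_bp[i] - per * n
    tibble::tibble(rep_length = rep(lo, n),
                   copy_total_bp = per + c(extra, rep(0, n - 1)))
  }))
  land <- tabulate_landscape(fams, 621884)
  expect_equal(land$n_families, tab$n_families)
  expect_equal(sum(land$n_families), 343L)
  expect_equal(land$total_bp, tab$total_bp)
  expect_equal(land$coverage_pct, c(1.7, 1.6, 1.5, 1.3, 3.0, 18.9))
})

test_that("landscape arithmetic and union coverage behave", {
  fams <- tibble::tibble(
    family_id = "R01", rep_length = 10000L, identity = 100, type = "DR",
    n_copies = 2L,
    copies = list(tibble::tibble(start = c(1000L, 50000L),
                                 end = c(10999L, 59999L),
                                 orientation = c("forward", "forward"))))
  land <- tabulate_landscape(fams, 621884)
  expect_equal(land$n_families[land$size_class == ">=1000"], 1L)
  expect_equal(land$total_bp[land$size_class == ">=1000"], 20000)
  expect_equal(land$coverage_pct[land$size_class == ">=1000"], 3.2)
  expect_equal(attr(land, "union_coverage_pct"), 3.2)
  empty <- tabulate_landscape(mtcompare:::empty_repeat_families(), 621884)
  expect_true(all(empty$n_families == 0))
  expect_true(all(empty$coverage_pct == 0))
  expect_error(tabulate_landscape(fams, 621884, bounds = c(40, 20)),
               "increasing")
})

test_that("class totals sum to the family-copy total and union is bounded", {
  sim <- generate_mt_genome(repeat_only_cfg(seed = 505))
  fams <- find_repeats(sim$mt)
  land <- tabulate_landscape(fams, sim$mt$genome$length)
  cp <- repeat_copies(fams)
  expect_equal(sum(land$total_bp), sum(cp$end - cp$start + 1L))
  # per-class values are rounded to one decimal, so allow the
  # worst-case rounding slack across six classes plus the union
  expect_lte(attr(land, "union_coverage_pct"), sum(land$coverage_pct) + 0.35)
})
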