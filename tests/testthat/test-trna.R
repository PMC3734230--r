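# tRNA origin classification, distribution grid, and gain/loss parsimony.

test_that("origin classification matches the generator truth", {
  sim <- generate_mt_genome(small_cfg(seed = 701))
  tc <- classify_trna_origin(sim$mt, sim$cp)
  tt <- sim$truth$trna
  m <- merge(tc[, c("locus", "origin")], tt, by = "locus",
             suffixes = c("_pred", "_true"))
  expect_true(all(m$origin_pred == m$origin_true))
  expect_error(classify_trna_origin(sim$mt, NULL), "chloroplast")
})

test_that("the 85% identity boundary is inclusive", {
  # build a cp with one tRNA and an mt tRNA at exactly 85% identity to it
  set.seed(31)
  trna <- random_dna(80)
  cp <- annotated_genome(
    mt_genome(paste0(random_dna(200), trna, random_dna(200)), id = "cp"),
    feature_table("trnW", "tRNA", "+", 201, 280))
  # mutate exactly 12 interior positions: (80-12)/80 = 85%
  mut <- mutate_dna(substr(trna, 2, 79), count = 12L)
  mt_seq <- paste0(substr(trna, 1, 1), mut, substr(trna, 80, 80))
  mt <- annotated_genome(
    mt_genome(paste0(random_dna(100), mt_seq, random_dna(100)), id = "mt"),
    feature_table("trnW", "tRNA", "+", 101, 180))
  cl <- classify_trna_origin(mt, cp)
  expect_gte(cl$best_identity, 85 - 1e-6)
  expect_equal(cl$origin, "cp_like")
  # a tRNA with no real similarity classifies native
  mt2 <- annotated_genome(
    mt_genome(paste0(random_dna(100), random_dna(80), random_dna(100)),
              id = "mt2"),
    feature_table("trnW", "tRNA", "+", 101, 180))
  expect_equal(classify_trna_origin(mt2, cp)$origin, "native")
})

test_that("distribution grids cover the label union with absent cells", {
  panel <- list(
    sp1 = tibble::tibble(locus = c("trnA", "trnW"), copy_index = 1L,
                         isotype = c("trnA", "trnW"),
                         origin = c("native", "cp_like"),
                         best_identity = c(40, 98),
                         best_cp_gene = c(NA, "trnW")),
    sp2 = tibble::tibble(locus = "trnH", copy_index = 1L, isotype = "trnH",
                         origin = "cp_like", best_identity = 97,
                         best_cp_gene = "trnH")
  )
  grid <- build_trna_distribution(panel)
  expect_equal(nrow(grid), 6L)  # 2 species x 3 labels
  expect_equal(grid$state[grid$species == "sp1" & grid$trna == "trnH"],
               "absent")
  expect_equal(grid$state[grid$species == "sp2" & grid$trna == "trnH"],
               "cp_like")
  # duplicates collapse to one cell
  dup <- list(sp = tibble::tibble(locus = c("trnW", "trnW"),
                                  copy_index = 1:2, isotype = "trnW",
                                  origin = c("cp_like", "cp_like"),
                                  best_identity = 98, best_cp_gene = "trnW"))
  expect_equal(nrow(build_trna_distribution(dup)), 1L)
})

test_that("simple characters place as expected on the tree", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  # present at all tips: one gain at the root, no losses
  dist <- tidyr::crossing(species = c("A", "B", "C", "D"), trna = "trnH") %>%
    dplyr::mutate(state = "cp_like")
  ev <- infer_gain_loss(dist, tree)
  expect_equal(sum(ev$event == "gain"), 1L)
  expect_equal(ev$node[ev$event == "gain"], 5L)  # root
  expect_equal(sum(ev$event == "loss"), 0L)
  # present in one tip only: gain on that terminal branch
  dist2 <- dist %>% dplyr::mutate(state = ifelse(species == "C",
                                                 "cp_like", "absent"))
  ev2 <- infer_gain_loss(dist2, tree)
  expect_equal(sum(ev2$event == "gain"), 1L)
  expect_equal(ev2$branch_label[ev2$event == "gain"], "C")
  expect_error(infer_gain_loss(dist, ape::read.tree(text = "((A,B),(C,E));")),
               "differ")
})

test_that("event totals match exhaustive minima on random 6-taxon grids", {
  set.seed(811)
  for (trial in 1:150) {
    tree <- ape::rtree(6)
    present <- stats::runif(6) < 0.5
    if (!any(present)) next
    for (model in c("dollo", "loss_only")) {
      ev <- mtcompare:::place_events_one_character(tree, present, model)
      total <- sum(ev$event %in% c("gain", "loss"))
      expect_equal(total, brute_min_events(tree, present, model),
                   info = paste(model, trial))
    }
  }
})

test_that("replaying inferred events reproduces the tip grid exactly", {
  set.seed(57)
  tree <- ape::rtree(8)
  species <- tree$tip.label
  labels <- paste0("t", 1:6)
  dist <- tidyr::crossing(species = species, trna = labels) %>%
    dplyr::mutate(state = sample(c("native", "cp_like", "absent"),
                                 dplyr::n(), replace = TRUE))
  ev <- infer_gain_loss(dist, tree)
  back <- replay_events(ev, tree, labels)
  cmp <- dplyr::left_join(dist, back, by = c("species", "trna"),
                          suffix = c("_obs", "_replay"))
  expect_true(all(cmp$state_obs == cmp$state_replay))
})

test_that("event totals are invariant under tip order permutation", {
  set.seed(21)
  tree <- ape::rtree(7)
  dist <- tidyr::crossing(species = tree$tip.label, trna = paste0("t", 1:4)) %>%
    dplyr::mutate(state = sample(c("native", "cp_like", "absent"),
                                 dplyr::n(), replace = TRUE))
  ev1 <- infer_gain_loss(dist, tree)
  ev2 <- infer_gain_loss(dist[sample.int(nrow(dist)), ], tree)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_equal(dplyr::arrange(ev1, trna, character, event, node),
               dplyr::arrange(ev2, trna, character, event, node))
})

test_that("scripted gains on a species panel are recovered by parsimony", {
  tree <- ape::read.tree(text = "((A:0.002,B:0.002):0.002,(C:0.002,D:0.002):0.002);")
  tree <- ape::makeNodeLabel(tree)
  # internal node 7 is the (C,D) ancestor; script one cp-like uptake there
  script <- tibble::tibble(node = 7L, event = "gain_cp", trna = "trnC")
  cfg <- small_cfg(seed = 713)
  panel <- generate_species_set(tree, cfg, script = script)
  cls <- purrr::map(panel$genomes, classify_trna_origin, cp = panel$cp)
  dist <- build_trna_distribution(cls)
  expect_equal(sort(dist$species[dist$trna == "trnC" & dist$state == "cp_like"]),
               c("C", "D"))
  ev <- infer_gain_loss(dist, tree)
  g <- ev[ev$trna == "trnC" & ev$event == "gain", ]
  expect_equal(nrow(g), 1L)
  expect_equal(g$node, 7L)
})
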