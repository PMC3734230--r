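# Shared fixtures: compact simulation configurations and small hand-built
# genomes. Everything is generated in code under fixed seeds.

extdata <- function(f) system.file("extdata", f, package = "mtcompare")

# a compact repeat plan covering every published size class; planted
# lengths keep a margin inside each class so that a few bp of chance
# flanking matches picked up by extension cannot shift a family across a
# class boundary
small_repeat_plan <- function(divergence = 0) {
  tibble::tibble(
    len_min = c(25L, 46L, 66L, 86L, 150L, 1100L),
    len_max = c(33L, 53L, 73L, 93L, 400L, 1500L),
    n_copies = c(2L, 2L, 2L, 2L, 3L, 2L),
    type = c("DR", "IR", "DR", "IR", "IR/DR", "DR"),
    divergence = divergence
  )
}

# repeats-only genome: no genes, no MTPT, fast to scan
repeat_only_cfg <- function(seed, divergence = 0, length = 15000) {
  sim_config(length = length, seed = seed,
             genes = default_gene_roster()[0, ],
             repeat_plan = small_repeat_plan(divergence),
             mtpt_plan = default_mtpt_plan(0, 0, 0),
             trna_native = character(0), trna_cp_like = character(0))
}

# MTPT-focused genome: no repeats, thin gene roster
mtpt_cfg <- function(seed, length = 40000) {
  sim_config(length = length, seed = seed,
             genes = default_gene_roster()[1:14, ],
             repeat_plan = default_repeat_plan()[0, ],
             mtpt_plan = default_mtpt_plan())
}

# small full-featured genome
small_cfg <- function(seed, length = 60000) {
  sim_config(length = length, seed = seed,
             genes = default_gene_roster()[1:24, ],
             repeat_plan = small_repeat_plan(),
             mtpt_plan = default_mtpt_plan(2, 1, 2))
}

# hand-built annotated genome from a label/strand/start layout
toy_order_genome <- function(labels, strands, species = "toy",
                             group = "dicot", gene_len = 50, gap = 30) {
  n <- length(labels)
  L <- n * (gene_len + gap) + gap
  starts <- gap + (seq_len(n) - 1L) * (gene_len + gap) + 1L
  f <- feature_table(labels, "protein", strands, starts,
                     starts + gene_len - 1L)
  annotated_genome(mt_genome(strrep("A", L), id = species), f,
                   species = species, group = group)
}

# random circular (label, strand) order over n genes
random_order <- function(n) {
  tibble::tibble(label = sample(paste0("g", seq_len(n))),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 start = seq_len(n))
}

# O(n^2)-style independent oracle for shared adjacency counting
oracle_adjacency_count <- function(o1, o2) {
  pairs_of <- function(o) {
    n <- nrow(o)
    nxt <- c(seq_len(n)[-1], 1L)
    unique(paste(pmin(o$label, o$label[nxt]), pmax(o$label, o$label[nxt]),
                 ifelse(o$strand == o$strand[nxt], "same", "opposite")))
  }
  length(intersect(pairs_of(o1), pairs_of(o2)))
}

# exhaustive minimum of gain+loss events for one presence character
brute_min_events <- function(tree, present, model) {
  nt <- length(tree$tip.label)
  nint <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    st <- c(present, as.logical(bitwAnd(bitwShiftR(mask, 0:(nint - 1)), 1)))
    gains <- 0L
    losses <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- st[tree$edge[e, 1]]
      ch <- st[tree$edge[e, 2]]
      if (!p && ch) gains <- gains + 1L
      if (p && !ch) losses <- losses + 1L
    }
    root_present <- st[nt + 1L]
    ev <- if (model == "dollo") {
      total_gains <- gains + as.integer(root_present)  # stem uptake counts
      if (total_gains > 1L) next
      total_gains + losses
    } else {
      if (gains > 0L || root_present != any(present)) next
      losses
    }
    best <- min(best, ev)
  }
  best
}

# planted-element recovery helpers
family_recall <- function(truth_repeats, families) {
  cp <- repeat_copies(families)
  per_family <- vapply(split(truth_repeats, truth_repeats$family), function(f) {
    all(vapply(seq_len(nrow(f)), function(i) {
      any(cp$start <= f$end[i] & cp$end >= f$start[i])
    }, logical(1)))
  }, logical(1))
  mean(per_family)
}

# an insert counts as recovered when reported homologs cover the clear
# majority of it: boundary runs whose last bases are mutated are trimmed
# back to the outermost exact match, so a diverged insert loses some bp at
# each end without being any less detected
mtpt_recall <- function(truth_mtpt, homologs) {
  vapply(seq_len(nrow(truth_mtpt)), function(i) {
    ov <- homologs$mt_start <= truth_mtpt$mt_end[i] &
      homologs$mt_end >= truth_mtpt$mt_start[i]
    if (!any(ov)) return(FALSE)
    covered <- sum(pmin(homologs$mt_end[ov], truth_mtpt$mt_end[i]) -
                     pmax(homologs$mt_start[ov], truth_mtpt$mt_start[i]) + 1L)
    len <- truth_mtpt$mt_end[i] - truth_mtpt$mt_start[i] + 1L
    covered >= pmax(0.6 * len, pmin(25, len - 5))
  }, logical(1))
}
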