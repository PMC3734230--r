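# tRNA origin census: native vs chloroplast-like classification, the
# species x tRNA distribution grid, and parsimony placement of uptakes and
# losses on a fixed species tree (Dollo for cp-like characters, loss-only
# for native ones).

#' Classify the origin of annotated mitochondrial tRNAs
#'
#' A tRNA is chloroplast-like when its best local alignment to any
#' chloroplast tRNA gene of the same isotype reaches the identity floor over
#' at least the coverage floor of its own length; otherwise it is native.
#' Isotype is taken as the locus label stripped of the anticodon suffix
#' (trnS(GCT) and trnS match).
#'
#' @param mt An [annotated_genome()] (mitochondrial).
#' @param cp An [annotated_genome()] (chloroplast) with tRNA annotations.
#' @param min_identity Percent identity floor (default 85; inclusive).
#' @param min_cov Fraction of the mt tRNA length that must align
#'   (default 0.9).
#' @return A tibble with one row per mt tRNA feature: `locus`, `copy_index`,
#'   `isotype`, `origin` ("native"/"cp_like"), `best_identity`,
#'   `best_cp_gene`.
#' @export
classify_trna_origin <- function(mt, cp, min_identity = 85, min_cov = 0.9) {
  stopifnot(inherits(mt, "annotated_genome"))
  if (!inherits(cp, "annotated_genome")) stop("a chloroplast genome is required")
  isotype_of <- function(x) sub("\\(.*\\)$", "", x)
  mt_fb <- feature_blocks(mt$features) %>% filter(.data$category == "tRNA")
  cp_fb <- feature_blocks(cp$features) %>% filter(.data$category == "tRNA")
  if (nrow(mt_fb) == 0L) {
    return(tibble(locus = character(0), copy_index = integer(0),
                  isotype = character(0), origin = character(0),
                  best_identity = numeric(0), best_cp_gene = character(0)))
  }
  cp_seqs <- purrr::map_chr(seq_len(nrow(cp_fb)), function(i) {
    extract_subsequence(cp$genome, cp_fb$start[i], cp_fb$end[i], cp_fb$strand[i])
  })
  cp_iso <- isotype_of(cp_fb$locus)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  purrr::map_dfr(seq_len(nrow(mt_fb)), function(i) {
    s <- extract_subsequence(mt$genome, mt_fb$start[i], mt_fb$end[i],
                             mt_fb$strand[i])
    iso <- isotype_of(mt_fb$locus[i])
    cand <- which(cp_iso == iso)
    best_id <- 0; best_gene <- NA_character_; best_cov <- 0
    for (j in cand) {
      pa <- Biostrings::pairwiseAlignment(s, cp_seqs[j], type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 4, gapExtension = 2)
      alen <- Biostrings::nchar(pa)
      if (alen == 0L) next
      idp <- Biostrings::pid(pa, type = "PID1")
      cov <- Biostrings::width(Biostrings::pattern(pa)) / nchar(s)
      if (cov >= min_cov && idp > best_id) {
        best_id <- idp; best_gene <- cp_fb$locus[j]; best_cov <- cov
      }
    }
    tibble(locus = mt_fb$locus[i], copy_index = mt_fb$copy_index[i],
           isotype = iso,
           origin = if (best_id >= min_identity) "cp_like" else "native",
           best_identity = best_id, best_cp_gene = best_gene)
  })
}

#' Build the species x tRNA distribution grid
#'
#' @param panel Named list (by species) of classified tRNA tibbles from
#'   [classify_trna_origin()].
#' @return A tibble in long form: `species`, `trna` (locus label), `state`
#'   in {native, cp_like, absent}, covering the union of labels; duplicate
#'   copies collapse to one presence cell (cp_like wins if copies disagree,
#'   recording the acquired state).
#' @export
build_trna_distribution <- function(panel) {
  labels <- sort(unique(unlist(purrr::map(panel, "locus"))))
  purrr::imap_dfr(panel, function(tb, sp) {
    state <- setNames(rep("absent", length(labels)), labels)
    for (lab in unique(tb$locus)) {
      orig <- tb$origin[tb$locus == lab]
      state[lab] <- if (any(orig == "cp_like")) "cp_like" else "native"
    }
    tibble(species = sp, trna = labels, state = unname(state))
  })
}

#' Infer tRNA gains and losses on a species tree by parsimony
#'
#' Chloroplast-like presence is modeled by Dollo parsimony (a single uptake,
#' unlimited subsequent losses); native presence by a loss-only model (the
#' ancestral mitochondrial set is primitively present, so gains below the
#' root are forbidden). Event placement minimizes the event total; among
#' minimal placements events are delayed toward the tips.
#'
#' @param dist Long-form distribution tibble from
#'   [build_trna_distribution()].
#' @param tree A rooted `phylo` tree whose tip labels equal the grid
#'   species.
#' @return A tibble of events: `trna`, `character` ("cp_like"/"native"),
#'   `event` ("gain"/"loss"), `node` (child node of the branch carrying the
#'   event), `branch_label` (tip label or internal node number).
#' @export
infer_gain_loss <- function(dist, tree) {
  stopifnot(inherits(tree, "phylo"))
  sp <- unique(dist$species)
  if (!setequal(sp, tree$tip.label)) {
    stop("tree tips and distribution species differ")
  }
  events <- list()
  for (lab in unique(dist$trna)) {
    d <- dist[dist$trna == lab, ]
    st <- setNames(d$state, d$species)[tree$tip.label]
    for (ch in c("cp_like", "native")) {
      present <- st == ch
      if (!any(present)) next
      ev <- place_events_one_character(tree, present,
                                       model = if (ch == "cp_like") "dollo" else "loss_only")
      if (nrow(ev)) {
        ev$trna <- lab; ev$character <- ch
        events[[length(events) + 1L]] <- ev
      }
    }
  }
  if (!length(events)) {
    return(tibble(trna = character(0), character = character(0),
                  event = character(0), node = integer(0),
                  branch_label = character(0)))
  }
  bind_rows(events) %>%
    select("trna", "character", "event", "node", "branch_label") %>%
    arrange(.data$trna, .data$character, .data$event, .data$node)
}

# Minimal event placement for one presence/absence character.
# dollo: root absent, at most one gain (at the MRCA of the present tips),
#   then one loss on the root edge of each maximal all-absent subtree below
#   the gain. loss_only: state present at the root, losses likewise.
place_events_one_character <- function(tree, present, model) {
  ntip <- length(tree$tip.label)
  node_label <- function(v) {
    unname(ifelse(v <= ntip, tree$tip.label[v], as.character(v)))
  }
  present_tips <- which(present)
  events <- tibble(event = character(0), node = integer(0),
                   branch_label = character(0))
  top <- if (model == "dollo") {
    g <- if (length(present_tips) == 1L) present_tips else
      ape::getMRCA(tree, present_tips)
    events <- tibble(event = "gain", node = as.integer(g),
                     branch_label = node_label(g))
    g
  } else {
    # primitively present: recorded so replay knows the root state, but a
    # root presence is not an evolutionary event
    events <- tibble(event = "root_presence", node = ntip + 1L,
                     branch_label = node_label(ntip + 1L))
    ntip + 1L  # root
  }
  # losses: maximal subtrees below `top` whose tips are all absent
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids(v), tips_below))
  }
  walk <- function(v) {
    tb <- tips_below(v)
    if (all(!present[tb])) {
      events <<- bind_rows(events, tibble(event = "loss", node = as.integer(v),
                                          branch_label = node_label(v)))
      return(invisible())
    }
    if (v > ntip) lapply(kids(v), walk)
    invisible()
  }
  if (top <= ntip) return(events)  # single-tip gain, nothing below
  lapply(kids(top), walk)
  events
}

#' Replay inferred events down the tree
#'
#' Reconstructs the tip state of each character from an event table; used to
#' verify that inferred placements explain the observed grid exactly.
#'
#' @param events Event tibble from [infer_gain_loss()].
#' @param tree The same rooted `phylo` tree.
#' @param trnas Character vector of all tRNA labels in the grid.
#' @return Long tibble `species`, `trna`, `state` composed from the replay
#'   (a tip that carries neither character is "absent").
#' @export
replay_events <- function(events, tree, trnas) {
  ntip <- length(tree$tip.label)
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  tips_below <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids(v), tips_below))
  }
  out <- list()
  for (lab in trnas) {
    for (ch in c("cp_like", "native")) {
      ev <- events[events$trna == lab & events$character == ch, ]
      state <- rep(FALSE, ntip)
      if (ch == "native" && any(ev$event == "root_presence")) state[] <- TRUE
      if (ch == "cp_like") {
        g <- ev$node[ev$event == "gain"]
        if (length(g)) state[tips_below(g)] <- TRUE
      }
      for (v in ev$node[ev$event == "loss"]) state[tips_below(v)] <- FALSE
      out[[length(out) + 1L]] <- tibble(species = tree$tip.label,
                                        trna = lab, character = ch,
                                        present = state)
    }
  }
  bind_rows(out) %>%
    group_by(.data$species, .data$trna) %>%
    summarise(state = if (any(.data$present & .data$character == "cp_like")) {
      "cp_like"
    } else if (any(.data$present & .data$character == "native")) {
      "native"
    } else "absent", .groups = "drop")
}
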