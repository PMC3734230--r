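# Repeat landscape: genome self-comparison, family clustering, DR/IR
# classification, and the size-class frequency table.

#' Detect repeat families in a genome
#'
#' Scans the genome against itself (both strands, doubled sequence when
#' circular), clusters mutually matching copies into families by single
#' linkage, classifies each family as direct (DR), inverted (IR) or mixed
#' (IR/DR), and numbers families R01, R02, ... by decreasing alignment
#' length (ties by first start coordinate).
#'
#' @param g An [mt_genome()] or [annotated_genome()].
#' @param min_len Minimum repeat length in bp (default 20, the conventional
#'   floor for plant mtDNA repeat surveys).
#' @param min_identity Minimum percent identity between copies (default 80).
#' @param seed_k Exact seed word size (must be <= `min_len`; default 15).
#' @param ... Passed to [find_local_matches()].
#' @return A tibble with one row per family: `family_id`, `rep_length`,
#'   `identity` (minimum pairwise percent identity among copies), `type`
#'   (DR/IR/IR/DR), `n_copies`, and a `copies` list-column of tibbles with
#'   `start`, `end`, `orientation` (relative to the first copy).
#' @export
find_repeats <- function(g, min_len = 20, min_identity = 80, seed_k = 15, ...) {
  if (inherits(g, "annotated_genome")) g <- g$genome
  stopifnot(inherits(g, "mt_genome"))
  if (min_len < seed_k) stop("min_len must be >= seed_k")
  if (g$length <= 2 * min_len) stop("genome too short for repeat scanning")
  L <- g$length
  hits <- find_local_matches(g$seq, NULL, k = seed_k, min_len = min_len,
                             min_identity = min_identity,
                             circular = g$circular, ...)
  if (nrow(hits) == 0L) return(empty_repeat_families())

  # linearize wrap intervals for interval algebra
  lin <- function(s, e) ifelse(e < s, e + L, e)
  iv <- tibble(
    start = c(hits$start1, hits$start2),
    end = c(lin(hits$start1, hits$end1), lin(hits$start2, hits$end2)),
    hit = rep(seq_len(nrow(hits)), 2L),
    side = rep(c(1L, 2L), each = nrow(hits))
  )

  # merge copy intervals that overlap reciprocally >= 50%
  ir <- IRanges::IRanges(iv$start, iv$end)
  ov <- IRanges::findOverlaps(ir, ir)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(ir[qi], ir[si]))
  rec <- w >= 0.5 * IRanges::width(ir[qi]) & w >= 0.5 * IRanges::width(ir[si])
  parent <- seq_len(length(ir))
  find_root <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  link <- function(a, b) { ra <- find_root(a); rb <- find_root(b); if (ra != rb) parent[rb] <<- ra }
  for (j in which(rec & qi < si)) link(qi[j], si[j])
  copy_of <- vapply(seq_along(parent), find_root, integer(1))
  copy_id <- match(copy_of, unique(copy_of))
  iv$copy <- copy_id

  # copy node spans (union of member intervals)
  nodes <- iv %>%
    group_by(.data$copy) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")

  # family = connected component of copy nodes linked by hits
  e1 <- iv$copy[iv$side == 1L][order(iv$hit[iv$side == 1L])]
  e2 <- iv$copy[iv$side == 2L][order(iv$hit[iv$side == 2L])]
  fparent <- seq_len(nrow(nodes))
  ffind <- function(x) { while (fparent[x] != x) { fparent[x] <<- fparent[fparent[x]]; x <- fparent[x] }; x }
  for (j in seq_along(e1)) {
    ra <- ffind(e1[j]); rb <- ffind(e2[j]); if (ra != rb) fparent[rb] <- ra
  }
  fam_of <- vapply(seq_len(nrow(nodes)), ffind, integer(1))

  fams <- list()
  for (f in unique(fam_of)) {
    members <- which(fam_of == f)
    if (length(members) < 2L) next
    hidx <- which(e1 %in% members | e2 %in% members)
    # orientation parity by BFS over hit edges from the lowest-start copy
    rep_node <- members[which.min(nodes$start[members])]
    par <- setNames(rep(NA_integer_, length(members)), members)
    par[as.character(rep_node)] <- 0L
    queue <- rep_node
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in hidx) {
        other <- if (e1[j] == cur) e2[j] else if (e2[j] == cur) e1[j] else next
        p <- (par[as.character(cur)] +
                as.integer(hits$orientation[j] == "reverse")) %% 2L
        if (is.na(par[as.character(other)])) {
          par[as.character(other)] <- p
          queue <- c(queue, other)
        }
      }
    }
    par[is.na(par)] <- 0L
    ori <- ifelse(par[as.character(members)] == 0L, "forward", "reverse")
    copies <- tibble(
      start = ((nodes$start[members] - 1L) %% L) + 1L,
      end = ((nodes$end[members] - 1L) %% L) + 1L,
      orientation = ori
    ) %>% arrange(.data$start)
    fams[[length(fams) + 1L]] <- tibble(
      rep_length = max(hits$length[hidx]),
      identity = min(hits$identity[hidx]),
      type = classify_family(copies$orientation),
      n_copies = nrow(copies),
      first_start = min(copies$start),
      copies = list(copies)
    )
  }
  if (!length(fams)) return(empty_repeat_families())
  out <- bind_rows(fams) %>%
    arrange(dplyr::desc(.data$rep_length), .data$first_start)
  if (g$circular && nrow(out) > 1L) out <- drop_shadow_families(out, L)
  out %>%
    mutate(family_id = sprintf("R%02d", row_number())) %>%
    select("family_id", "rep_length", "identity", "type", "n_copies", "copies")
}

# On a circular genome, scanning the doubled sequence can report fragments of
# an origin-spanning family a second time with shifted coordinates. A family
# is a shadow when each of its copies lies (modulo the genome length) within
# a copy of a longer family.
drop_shadow_families <- function(out, L) {
  contains_mod <- function(s1, e1, s2, e2) {
    # does circular interval 1 contain circular interval 2?
    lin <- function(s, e) c(s, ifelse(e < s, e + L, e))
    a <- lin(s1, e1); b <- lin(s2, e2)
    for (sh in c(-L, 0L, L)) {
      if (b[1] + sh >= a[1] && b[2] + sh <= a[2]) return(TRUE)
    }
    FALSE
  }
  keep <- rep(TRUE, nrow(out))
  for (j in seq_len(nrow(out))) {
    for (i in seq_len(nrow(out))) {
      if (i == j || !keep[i] || out$rep_length[i] < out$rep_length[j]) next
      ci <- out$copies[[i]]; cj <- out$copies[[j]]
      covered <- vapply(seq_len(nrow(cj)), function(r) {
        any(vapply(seq_len(nrow(ci)), function(q) {
          contains_mod(ci$start[q], ci$end[q], cj$start[r], cj$end[r])
        }, logical(1)))
      }, logical(1))
      if (all(covered)) { keep[j] <- FALSE; break }
    }
  }
  out[keep, , drop = FALSE]
}

empty_repeat_families <- function() {
  tibble(family_id = character(0), rep_length = integer(0),
         identity = numeric(0), type = character(0), n_copies = integer(0),
         copies = list())
}

#' Classify a repeat family by copy orientations
#'
#' All copies in the same orientation give a direct repeat (DR); two copies
#' in opposite orientation an inverted repeat (IR); three or more copies in
#' mixed orientations both (IR/DR).
#'
#' @param orientations Character vector of "forward"/"reverse" per copy.
#' @return One of `"DR"`, `"IR"`, `"IR/DR"`.
#' @export
classify_family <- function(orientations) {
  n <- length(orientations)
  if (n < 2L) stop("a repeat family needs at least two copies")
  mixed <- length(unique(orientations)) > 1L
  if (!mixed) "DR" else if (n == 2L) "IR" else "IR/DR"
}

#' Unnest repeat copies to one row per copy
#' @param families Output of [find_repeats()].
#' @return A tibble with one row per copy.
#' @export
repeat_copies <- function(families) {
  families %>%
    select("family_id", "rep_length", "identity", "type", "copies") %>%
    tidyr::unnest("copies")
}

#' Tabulate the repeat landscape by size class
#'
#' Size classes are closed-open on the published boundaries
#' (20-39, 40-59, 60-79, 80-99, 100-999, >=1000 by default). Per class the
#' table reports the family count (classified by `rep_length`), total copy
#' length in bp, and coverage as a percent of the genome (one decimal, half
#' away from zero). Overall union coverage merges all copy intervals, so it
#' can be well below the class sum when copies overlap.
#'
#' @param families A family tibble from [find_repeats()], or any tibble with
#'   `rep_length` plus either a `copies` list-column or a `copy_total_bp`
#'   column.
#' @param genome_length Genome length in bp.
#' @param bounds Increasing lower bounds of the size classes.
#' @return A tibble with one row per class (`size_class`, `n_families`,
#'   `total_bp`, `coverage_pct`) carrying the overall union coverage percent
#'   as attribute `union_coverage_pct` (NA when copy intervals are absent).
#' @export
tabulate_landscape <- function(families, genome_length,
                               bounds = c(20, 40, 60, 80, 100, 1000)) {
  if (is.unsorted(bounds, strictly = TRUE)) stop("bounds must be strictly increasing")
  lo <- as.integer(bounds)
  hi <- c(lo[-1] - 1L, NA_integer_)
  labels <- ifelse(!is.na(hi), sprintf("%d-%d", lo, hi), sprintf(">=%d", lo))
  copy_total <- if ("copy_total_bp" %in% names(families)) {
    families$copy_total_bp
  } else if ("copies" %in% names(families)) {
    vapply(families$copies, function(cp) {
      sum(interval_length(cp$start, cp$end, genome_length))
    }, numeric(1))
  } else if (nrow(families) == 0L) {
    numeric(0)
  } else {
    stop("families must carry a `copies` list-column or `copy_total_bp`")
  }
  cls <- findInterval(families$rep_length, bounds)
  out <- tibble(size_class = labels,
                n_families = vapply(seq_along(bounds), function(i) sum(cls == i), integer(1)),
                total_bp = vapply(seq_along(bounds), function(i) sum(copy_total[cls == i]), numeric(1)))
  out$coverage_pct <- pct_of(out$total_bp, genome_length)
  union_cov <- NA_real_
  if ("copies" %in% names(families) && nrow(families) > 0L) {
    allcp <- repeat_copies(families)
    lin_end <- ifelse(allcp$end < allcp$start, allcp$end + genome_length, allcp$end)
    union_cov <- pct_of(union_length(allcp$start, lin_end), genome_length)
  }
  attr(out, "union_coverage_pct") <- union_cov
  out
}
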