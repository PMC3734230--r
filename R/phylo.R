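# Concatenation of conserved respiratory-chain genes, p-distances and
# neighbor-joining trees.

#' Gene sets used for concatenated phylogenies
#'
#' The 21 respiratory-chain related loci conserved across higher plants
#' (17 respiratory complex genes plus the four cytochrome c biogenesis
#' genes) and their five functional subsets.
#'
#' @param set One of "all21", "complexI", "complexIII", "complexIV",
#'   "complexV", "ccm".
#' @return Character vector of locus names.
#' @export
conserved_gene_set <- function(set = c("all21", "complexI", "complexIII",
                                       "complexIV", "complexV", "ccm")) {
  set <- match.arg(set)
  sets <- list(
    complexI = c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                 "nad7", "nad9"),
    complexIII = "cob",
    complexIV = c("cox1", "cox3"),
    complexV = c("atp1", "atp4", "atp6", "atp8", "atp9"),
    ccm = c("ccmB", "ccmC", "ccmFC", "ccmFN")
  )
  if (set == "all21") unlist(sets, use.names = FALSE) else sets[[set]]
}

#' Concatenate per-locus alignments head-to-tail
#'
#' @param loci A tibble with columns `locus`, `species`, `seq` (aligned
#'   sequences over A,C,G,T,N,-; equal length within a locus).
#' @param gene_set Name of a [conserved_gene_set()], or a character vector
#'   of loci to join in the given order.
#' @return An object of class `concat_alignment`: named character vector
#'   `sequences` (one per species) and a `partitions` tibble (`locus`,
#'   `start`, `end`).
#' @export
concatenate_loci <- function(loci, gene_set = "all21") {
  wanted <- if (length(gene_set) == 1L &&
                gene_set %in% c("all21", "complexI", "complexIII", "complexIV",
                                "complexV", "ccm")) {
    conserved_gene_set(gene_set)
  } else {
    gene_set
  }
  missing_loci <- setdiff(wanted, unique(loci$locus))
  if (length(missing_loci)) {
    stop("loci absent from the alignment table: ",
         paste(missing_loci, collapse = ", "))
  }
  species <- sort(unique(loci$species))
  parts <- list()
  seqs <- setNames(rep("", length(species)), species)
  pos <- 0L
  for (loc in wanted) {
    sub <- loci[loci$locus == loc, ]
    miss <- setdiff(species, sub$species)
    if (length(miss)) {
      stop(sprintf("locus %s lacks species: %s", loc, paste(miss, collapse = ", ")))
    }
    len <- unique(nchar(sub$seq))
    if (length(len) != 1L) {
      stop(sprintf("locus %s has unequal sequence lengths", loc))
    }
    s <- setNames(toupper(sub$seq), sub$species)[species]
    seqs <- paste0(seqs, s)
    parts[[loc]] <- tibble(locus = loc, start = pos + 1L, end = pos + len)
    pos <- pos + len
  }
  structure(list(sequences = setNames(seqs, species),
                 partitions = bind_rows(parts)),
            class = "concat_alignment")
}

#' Split a concatenated alignment back into its loci
#' @param ca A `concat_alignment`.
#' @return A tibble `locus`, `species`, `seq`.
#' @export
split_concat <- function(ca) {
  purrr::pmap_dfr(ca$partitions, function(locus, start, end) {
    tibble(locus = locus, species = names(ca$sequences),
           seq = unname(substr(ca$sequences, start, end)))
  })
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' The proportion of mismatched sites over the columns where neither
#' sequence carries a gap or N.
#'
#' @param ca A `concat_alignment`, or a named character vector of aligned
#'   sequences.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(ca) {
  seqs <- if (inherits(ca, "concat_alignment")) ca$sequences else ca
  if (length(seqs) < 2L) stop("need at least two species")
  chm <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  ok <- chm != "-" & chm != "N"
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        stop(sprintf("no comparable columns between %s and %s",
                     names(seqs)[i], names(seqs)[j]))
      }
      d[i, j] <- d[j, i] <- mean(chm[i, comp] != chm[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining with two refinements for reproducibility:
#' negative branch lengths are clamped to zero with the deficit moved to the
#' sister branch, and ties in the Q criterion break deterministically by
#' taxon-name order.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @return An object of class `nj_tree` wrapping an ape `phylo` (unrooted,
#'   with branch lengths).
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least three taxa")
  labels <- rownames(d)
  # working copy; node "newick" strings carry subtrees
  nodes <- as.list(labels)
  D <- d
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    # deterministic tie-break: smallest pair of subtree labels
    key <- apply(best, 1, function(ij) {
      paste(sort(c(nodes[[active[ij[1]]]], nodes[[active[ij[2]]]])),
            collapse = "\r")
    })
    pick <- best[order(key)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    ii <- pick[1]; jj <- pick[2]
    vi <- 0.5 * Dm[ii, jj] + (r[ii] - r[jj]) / (2 * (m - 2))
    vj <- Dm[ii, jj] - vi
    # clamp negatives, moving the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_label <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], vi, nodes[[j]], vj)
    # distances from the new node
    newd <- 0.5 * (D[i, active] + D[j, active] - D[i, j])
    D[i, active] <- newd
    D[active, i] <- newd
    D[i, i] <- 0
    nodes[[i]] <- new_label
    active <- setdiff(active, j)
  }
  a <- active
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  vs <- c(v1, v2, v3)
  for (k in 1:3) {
    if (vs[k] < 0) {
      others <- setdiff(1:3, k)
      vs[others] <- vs[others] + vs[k] / 2
      vs[k] <- 0
    }
  }
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[[a[1]]], vs[1], nodes[[a[2]]], vs[2], nodes[[a[3]]], vs[3])
  tr <- ape::read.tree(text = nwk)
  structure(list(tree = tr, newick = nwk), class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("<nj_tree>", length(x$tree$tip.label), "tips\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Tidy an NJ tree into an edge table
#' @param x An `nj_tree`.
#' @param ... Unused.
#' @return A tibble with `parent`, `node`, `label`, `branch_length`.
#' @export
tidy.nj_tree <- function(x, ...) {
  tr <- x$tree
  ntip <- length(tr$tip.label)
  tibble(parent = tr$edge[, 1], node = tr$edge[, 2],
         label = ifelse(tr$edge[, 2] <= ntip, tr$tip.label[tr$edge[, 2]],
                        NA_character_),
         branch_length = tr$edge.length)
}

#' One-row summary of an NJ tree
#' @param x An `nj_tree`.
#' @param ... Unused.
#' @return A tibble with `n_tips`, `n_internal`, `total_branch_length`,
#'   `min_branch_length`.
#' @export
glance.nj_tree <- function(x, ...) {
  tr <- x$tree
  tibble(n_tips = length(tr$tip.label), n_internal = tr$Nnode,
         total_branch_length = sum(tr$edge.length),
         min_branch_length = min(tr$edge.length))
}

#' Generic tidy (broom-style)
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic glance (broom-style)
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the internal bipartitions of two unrooted trees
#' on the same tip set.
#'
#' @param t1,t2 `phylo` or `nj_tree` objects.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (inherits(t1, "nj_tree")) t1 <- t1$tree
  if (inherits(t2, "nj_tree")) t2 <- t2$tree
  if (!setequal(t1$tip.label, t2$tip.label)) stop("tip sets differ")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}
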