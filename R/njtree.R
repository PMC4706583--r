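#' @importFrom ape nj read.tree write.tree
NULL

clamp_negative_branches <- function(phy) {
  # standard NJ post-processing: a negative branch is set to zero and its
  # deficit moved to the sister branch so path lengths through the parent
  # are preserved as far as possible
  el <- phy$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1]
    sisters <- setdiff(which(phy$edge[, 1] == parent), e)
    if (length(sisters)) {
      el[sisters[1]] <- el[sisters[1]] + el[e]
    }
    el[e] <- 0
  }
  phy$edge.length <- pmax(el, 0)
  phy
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Saitou-Nei neighbor joining on a pairwise distance matrix. The result is
#' an unrooted `ape::phylo` tree; negative branch lengths (possible when the
#' matrix is non-additive) are clamped to zero with the deficit shifted to
#' the sister branch. On an additive matrix NJ recovers the generating tree
#' exactly.
#'
#' @param M A `p_dist_matrix`, a `dist`, or a square symmetric numeric
#'   matrix with dimnames. All pairs must be defined.
#' @return An `ape::phylo` object.
#' @export
nj_tree <- function(M) {
  D <- if (inherits(M, "p_dist_matrix")) M$p else as.matrix(M)
  if (anyNA(D)) {
    und <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distance for pair(s): ",
         paste(rownames(D)[und[, 1]], colnames(D)[und[, 2]],
               sep = "~", collapse = ", "))
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    phy <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
                edge.length = rep(D[1, 2] / 2, 2),
                tip.label = rownames(D), Nnode = 1L)
    class(phy) <- "phylo"
    return(phy)
  }
  clamp_negative_branches(ape::nj(stats::as.dist(D)))
}

tree_bipartitions <- function(phy) {
  # canonical string per internal edge: the side of the split not containing
  # the alphabetically first taxon, tips sorted and joined
  tips <- sort(phy$tip.label)
  anchor <- tips[1]
  ntip <- length(phy$tip.label)
  internal <- which(phy$edge[, 2] > ntip)
  desc <- function(node) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, function(k) if (k <= ntip) phy$tip.label[k]
                  else desc(k)))
  }
  out <- character(0)
  for (e in internal) {
    side <- desc(phy$edge[e, 2])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next  # trivial
    if (anchor %in% side) side <- setdiff(phy$tip.label, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate with the same gap policy, and records for every internal
#' edge of the full-data tree the fraction of successful replicates whose
#' tree contains the same bipartition. Replicates in which some pair has no
#' comparable site are dropped and counted.
#'
#' @param aln Named character vector of aligned residues (>= 3 sequences).
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param policy Gap policy passed to [distance_matrix()].
#' @return List: `tree` (the full-data `phylo` with supports as internal
#'   node labels, in `[0,1]`), `supports` (named by bipartition),
#'   `replicates_used`, `replicates_dropped`.
#' @export
bootstrap_supports <- function(aln, B = 1000L, seed = 1L,
                               policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  stopifnot(B >= 1L, length(aln) >= 3L)
  set.seed(as.integer(seed))
  X <- aln_char_matrix(aln)
  main <- nj_tree(suppressWarnings(distance_matrix(aln, policy)))
  bip_main <- tree_bipartitions(main)
  counts <- stats::setNames(numeric(length(bip_main)), bip_main)
  used <- 0L; dropped <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(X), ncol(X), replace = TRUE)
    rep_aln <- apply(X[, cols, drop = FALSE], 1L, paste, collapse = "")
    Mb <- try(suppressWarnings(distance_matrix(rep_aln, policy)),
              silent = TRUE)
    if (inherits(Mb, "try-error") || anyNA(Mb$p)) { dropped <- dropped + 1L
      next }
    tb <- tree_bipartitions(nj_tree(Mb))
    hit <- bip_main %in% tb
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  supports <- if (used > 0L) counts / used else counts * NA_real_
  # attach as internal node labels: map each non-root internal node's
  # subtree bipartition to its support
  ntip <- length(main$tip.label)
  labs <- rep("", main$Nnode)
  for (e in which(main$edge[, 2] > ntip)) {
    node <- main$edge[e, 2]
    side <- ape::extract.clade(main, node)$tip.label
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (sort(main$tip.label)[1] %in% side) {
      side <- setdiff(main$tip.label, side)
    }
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports)) {
      labs[node - ntip] <- formatC(supports[key], format = "f", digits = 3)
    }
  }
  main$node.label <- labs
  list(tree = main, supports = supports,
       replicates_used = used, replicates_dropped = dropped)
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept; bootstrap supports, when present, are written as
#' internal node labels.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("malformed Newick in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed Newick in ", path)
  phy
}

#' Path-length (patristic) distance matrix of a tree
#'
#' Sums branch lengths along the path between every pair of leaves; on a tree
#' reconstructed from an additive matrix this reproduces the input exactly.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return Square numeric matrix, leaves in `tip.label` order.
#' @export
tree_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}
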