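AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

aln_char_matrix <- function(aln) {
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("alignment has unequal lengths")
  m <- matrix(unlist(strsplit(toupper(aln), ""), use.names = FALSE),
              nrow = length(aln), ncol = L, byrow = TRUE,
              dimnames = list(names(aln), NULL))
  m
}

#' Pairwise p-distance between two aligned sequences
#'
#' The p-distance is the proportion of comparable amino-acid sites at which
#' two aligned sequences differ. Under pairwise deletion a site is comparable
#' when both positions hold one of the 20 standard amino acids (gaps `-` and
#' undetermined `X` are excluded); under complete deletion only sites
#' comparable in the whole alignment are used, which for a single pair
#' coincides with pairwise deletion.
#'
#' @param a,b Aligned residue strings of equal length.
#' @param policy Gap policy, `"pairwise"` (default) or `"complete"`.
#' @return List with `p` (proportion in `[0,1]`, `NA` when no site is
#'   comparable) and `m` (number of comparable sites).
#' @export
p_distance <- function(a, b, policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  if (nchar(a) != nchar(b)) stop("sequences have unequal aligned lengths")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ok <- ca %in% AA20 & cb %in% AA20
  m <- sum(ok)
  p <- if (m == 0L) NA_real_ else sum(ca[ok] != cb[ok]) / m
  list(p = p, m = m)
}

#' All-pairs p-distance matrix
#'
#' Computes the symmetric matrix of pairwise p-distances for an alignment,
#' together with the per-pair comparable-site counts. Pairs with no comparable
#' sites get `NA` and are listed in `flagged`.
#'
#' @param aln Named character vector of aligned residues (>= 2 sequences).
#' @param policy Gap policy: `"pairwise"` deletion (per-pair comparable
#'   sites, the default) or `"complete"` deletion (only columns with a
#'   standard residue in every sequence are used at all).
#' @return Object of class `p_dist_matrix`: list with `ids`, `p` (square
#'   proportion matrix, zero diagonal), `m` (comparable-site counts),
#'   `flagged` (data.frame of undefined pairs), `policy`.
#' @export
distance_matrix <- function(aln, policy = c("pairwise", "complete")) {
  policy <- match.arg(policy)
  if (length(aln) < 2L) stop("need at least 2 sequences")
  X <- aln_char_matrix(aln)
  ok <- matrix(X %in% AA20, nrow = nrow(X))
  if (policy == "complete") {
    keep <- colSums(ok) == nrow(X)
    X <- X[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  okn <- ok * 1
  m <- okn %*% t(okn)                       # comparable sites per pair
  same <- matrix(0, nrow(X), nrow(X))
  for (a in AA20) {
    ia <- (X == a & ok) * 1
    same <- same + ia %*% t(ia)             # identical comparable sites
  }
  p <- ifelse(m > 0, (m - same) / pmax(m, 1), NA_real_)
  diag(p) <- ifelse(diag(m) > 0, 0, NA_real_)
  dimnames(p) <- dimnames(m) <- list(names(aln), names(aln))
  und <- which(upper.tri(m) & m == 0, arr.ind = TRUE)
  flagged <- data.frame(i = names(aln)[und[, 1]], j = names(aln)[und[, 2]],
                        stringsAsFactors = FALSE)
  if (nrow(flagged)) {
    warning(nrow(flagged), " sequence pair(s) share no comparable sites; ",
            "their p-distance is undefined")
  }
  structure(list(ids = names(aln), p = p, m = m,
                 flagged = flagged, policy = policy),
            class = "p_dist_matrix")
}

#' @export
print.p_dist_matrix <- function(x, ...) {
  cat("<p_dist_matrix> ", length(x$ids), " sequences, policy=", x$policy,
      ", ", nrow(x$flagged), " undefined pair(s)\n", sep = "")
  invisible(x)
}

#' Per-sequence average p-distance within a group
#'
#' For each member of a group, the mean p-distance to every other member:
#' the per-sequence diversity value underlying the rank heatmaps and the
#' variance partition. Undefined pairs are dropped from the mean with a
#' warning.
#'
#' @param M A `p_dist_matrix` from [distance_matrix()].
#' @param members Accessions (subset of `M$ids`), at least 2; with fewer an
#'   empty result is returned with a warning (the "blank cell" case).
#' @return Named numeric vector: accession -> average p-distance.
#' @export
per_sequence_average <- function(M, members) {
  stopifnot(inherits(M, "p_dist_matrix"))
  members <- as.character(members)
  if (!all(members %in% M$ids)) {
    stop("unknown accession(s): ",
         paste(setdiff(members, M$ids), collapse = ", "))
  }
  if (length(members) < 2L) {
    warning("fewer than 2 members; average p-distance not available")
    return(stats::setNames(numeric(0), character(0)))
  }
  sub <- M$p[members, members, drop = FALSE]
  diag(sub) <- NA_real_
  if (anyNA(sub[upper.tri(sub)])) {
    warning("undefined pair(s) excluded from per-sequence averages")
  }
  rowMeans(sub, na.rm = TRUE)
}

#' Diversity summary for one taxon
#'
#' Mean and sample SD (n-1 denominator) of the per-sequence average
#' p-distances among a clan's members; statistics are `NA` for singletons.
#'
#' @param M A `p_dist_matrix`.
#' @param node A `taxonomy_node`, or a character vector of accessions.
#' @param rank,taxon Labels used when `node` is a plain accession vector.
#' @return One-row `data.frame`: `rank`, `taxon`, `n`, `mean_p`, `sd_p`.
#' @export
group_summary <- function(M, node, rank = NA_character_,
                          taxon = NA_character_) {
  if (inherits(node, "taxonomy_node")) {
    members <- node$members; rank <- node$rank; taxon <- node$name
  } else members <- as.character(node)
  n <- length(members)
  if (n < 2L) {
    return(data.frame(rank = rank, taxon = taxon, n = n,
                      mean_p = NA_real_, sd_p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  d <- per_sequence_average(M, members)
  data.frame(rank = rank, taxon = taxon, n = n,
             mean_p = mean(d), sd_p = stats::sd(d),
             stringsAsFactors = FALSE)
}

#' Diversity summaries for every taxon at a rank
#'
#' One row per clan at the requested rank; clans with fewer than 2 members
#' appear with blank statistics, mirroring blank heatmap cells.
#'
#' @param M A `p_dist_matrix`.
#' @param taxonomy A `taxonomy_node` from [build_taxonomy()].
#' @param rank One of [lineage_ranks()].
#' @return `data.frame` of [group_summary()] rows.
#' @export
rank_table <- function(M, taxonomy, rank) {
  nodes <- taxonomy_at_rank(taxonomy, rank)
  rows <- lapply(nodes, function(nd) suppressWarnings(group_summary(M, nd)))
  do.call(rbind, rows)
}

#' Two-group comparison of diversity summaries
#'
#' Two-sample t test computed from summary statistics (mean, SD, n) of the
#' per-sequence average p-distances in two clans. Welch's unequal-variance
#' form with Satterthwaite degrees of freedom is the default; the pooled
#' equal-variance form is available for comparison.
#'
#' @param s1,s2 One-row summaries from [group_summary()], each with
#'   `n >= 2` and defined `sd_p`.
#' @param method `"welch"` (default) or `"pooled"`.
#' @return List: `t`, `df` (possibly fractional), `p_value` (two-sided),
#'   `method`.
#' @export
compare_groups <- function(s1, s2, method = c("welch", "pooled")) {
  method <- match.arg(method)
  stopifnot(s1$n >= 2, s2$n >= 2, !is.na(s1$sd_p), !is.na(s2$sd_p))
  v1 <- s1$sd_p^2; v2 <- s2$sd_p^2; n1 <- s1$n; n2 <- s2$n
  delta <- s1$mean_p - s2$mean_p
  if (v1 + v2 == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    df <- n1 + n2 - 2
  } else if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t <- delta / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_value = p, method = method)
}

#' Write a p-distance matrix as a PHYLIP-style distance file
#'
#' @param M A `p_dist_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_phylip <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(M$ids)), con)
  for (i in seq_along(M$ids)) {
    writeLines(paste(c(M$ids[i], formatC(M$p[i, ], format = "f",
                                         digits = 6)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
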