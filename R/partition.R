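#' Inter-/intra-clan variance partition (unequal-size model II ANOVA)
#'
#' Partitions the variance of a set of per-sequence diversity values into an
#' among-clan (inter-clan) and a within-clan (intra-clan) component using the
#' one-way random-effects (model II) ANOVA for unequal group sizes. With
#' clans of sizes \eqn{n_i} (total \eqn{N}, \eqn{k} clans):
#' \deqn{SS_{among} = \sum_i n_i (\bar y_i - \bar y)^2, \quad
#'       SS_{within} = \sum_i \sum_j (y_{ij} - \bar y_i)^2}
#' \deqn{n_0 = \frac{N - \sum_i n_i^2 / N}{k - 1}, \quad
#'       \hat\sigma^2_A = \max\!\left(0,
#'         \frac{MS_{among} - MS_{within}}{n_0}\right)}
#' The inter-clan percentage is
#' \eqn{100\,\hat\sigma^2_A / (\hat\sigma^2_A + MS_{within})}; a negative
#' among-clan component is truncated to zero.
#'
#' Preconditions: at least 2 clans, \eqn{N > k}, and at least one clan with
#' \eqn{n_i \ge 2} (so the within mean square has degrees of freedom).
#' Violations yield a row with `status = "not_available"` rather than an
#' error, mirroring taxa for which the statistic cannot be computed.
#'
#' @param values Named numeric vector of observations (e.g. per-sequence
#'   average p-distances).
#' @param clans Clan label per observation: either a vector parallel to
#'   `values` or named by the same accessions.
#' @param node,child_rank Optional labels recorded in the result.
#' @return One-row `data.frame` of class `variance_partition`: `node`,
#'   `child_rank`, `k`, `sizes` (comma string), `N`, `ss_among`, `ss_within`,
#'   `ms_among`, `ms_within`, `n0`, `sigma2_among`, `sigma2_within`,
#'   `pct_inter`, `pct_intra`, `status`.
#' @export
partition <- function(values, clans, node = NA_character_,
                      child_rank = NA_character_) {
  if (!is.null(names(clans)) && !is.null(names(values))) {
    clans <- clans[names(values)]
  }
  stopifnot(length(values) == length(clans))
  keep <- !is.na(values) & !is.na(clans)
  values <- values[keep]; clans <- as.character(clans)[keep]
  ni <- table(clans)
  k <- length(ni); N <- length(values)
  na_row <- function(reason) {
    structure(data.frame(node = node, child_rank = child_rank, k = k,
                         sizes = paste(as.integer(ni), collapse = ","),
                         N = N, ss_among = NA_real_, ss_within = NA_real_,
                         ms_among = NA_real_, ms_within = NA_real_,
                         n0 = NA_real_, sigma2_among = NA_real_,
                         sigma2_within = NA_real_, pct_inter = NA_real_,
                         pct_intra = NA_real_, status = reason,
                         stringsAsFactors = FALSE),
              class = c("variance_partition", "data.frame"))
  }
  if (k < 2L) return(na_row("not_available: fewer than 2 clans"))
  if (N <= k) return(na_row("not_available: no within-clan df"))
  if (max(ni) < 2L) return(na_row("not_available: all clans singleton"))
  gm <- mean(values)
  mi <- tapply(values, clans, mean)
  ss_among <- sum(as.integer(ni) * (mi - gm)^2)
  ss_within <- sum((values - mi[clans])^2)
  ms_among <- ss_among / (k - 1)
  ms_within <- ss_within / (N - k)
  n0 <- (N - sum(as.integer(ni)^2) / N) / (k - 1)
  s2a <- max(0, (ms_among - ms_within) / n0)
  denom <- s2a + ms_within
  pct_inter <- if (denom > 0) 100 * s2a / denom else 0
  structure(data.frame(node = node, child_rank = child_rank, k = k,
                       sizes = paste(as.integer(ni), collapse = ","), N = N,
                       ss_among = ss_among, ss_within = ss_within,
                       ms_among = ms_among, ms_within = ms_within, n0 = n0,
                       sigma2_among = s2a, sigma2_within = ms_within,
                       pct_inter = pct_inter, pct_intra = 100 - pct_inter,
                       status = "ok", stringsAsFactors = FALSE),
            class = c("variance_partition", "data.frame"))
}

#' Variance partition at every taxonomy bifurcation
#'
#' Walks the taxonomy from the superkingdom down to the family level and, at
#' every node with at least two child clans, partitions the per-sequence
#' average p-distances (computed within that node's member set) into
#' inter-clan and intra-clan components with [partition()]. Ineligible nodes
#' are reported with their reason rather than dropped.
#'
#' @param M A `p_dist_matrix` from [distance_matrix()].
#' @param taxonomy A `taxonomy_node` from [build_taxonomy()].
#' @param observations `"node_local"` (default): the observation for each
#'   sequence is its average p-distance to the other members of the node
#'   under test. `"pairwise"`: the raw within-node pairwise distances are the
#'   observations, each assigned to the clan when both endpoints share it and
#'   discarded otherwise; pairwise distances are not independent, so this
#'   variant is offered for comparison only.
#' @param ranks Ranks of the parent nodes to partition (default
#'   superkingdom through family).
#' @return `data.frame` with one [partition()] row per visited node.
#' @export
partition_lineage <- function(M, taxonomy,
                              observations = c("node_local", "pairwise"),
                              ranks = lineage_ranks()[1:6]) {
  observations <- match.arg(observations)
  rows <- list()
  for (rk in ranks) {
    for (nd in taxonomy_at_rank(taxonomy, rk)) {
      label <- paste0(rk, ":", nd$name)
      crank <- if (length(nd$children)) nd$children[[1]]$rank else NA
      if (length(nd$children) < 2L) {
        row <- partition(numeric(0), character(0), node = label,
                         child_rank = crank)
        row$k <- length(nd$children); row$N <- length(nd$members)
        row$sizes <- paste(vapply(nd$children,
                                  function(ch) length(ch$members), 1L),
                           collapse = ",")
        rows[[length(rows) + 1L]] <- row
        next
      }
      clan_of <- stats::setNames(
        rep(vapply(nd$children, `[[`, "", "name"),
            vapply(nd$children, function(ch) length(ch$members), 1L)),
        unlist(lapply(nd$children, `[[`, "members")))
      if (observations == "node_local") {
        vals <- suppressWarnings(per_sequence_average(M, nd$members))
        rows[[length(rows) + 1L]] <-
          partition(vals, clan_of, node = label, child_rank = crank)
      } else {
        mem <- nd$members
        sub <- M$p[mem, mem, drop = FALSE]
        ut <- which(upper.tri(sub), arr.ind = TRUE)
        ci <- clan_of[mem[ut[, 1]]]; cj <- clan_of[mem[ut[, 2]]]
        same <- !is.na(ci) & ci == cj
        rows[[length(rows) + 1L]] <-
          partition(sub[ut][same], ci[same], node = label,
                    child_rank = crank)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
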