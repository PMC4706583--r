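#' Expected p-distance under the 20-state equal-rates model
#'
#' For a Poisson substitution process over 20 equally exchangeable amino
#' acids, the expected proportion of differing sites after `d` substitutions
#' per site is
#' \deqn{p(d) = \frac{19}{20}\left(1 - e^{-\frac{20}{19} d}\right)}
#' strictly increasing in `d` with asymptote 0.95. Used to calibrate the
#' simulator and to convert branch lengths to per-site change probabilities.
#'
#' @param d Expected substitutions per site, `>= 0` (vectorized).
#' @return Expected p-distance(s) in `[0, 0.95)`.
#' @export
expected_p <- function(d) {
  if (any(d < 0)) stop("d must be non-negative")
  (19 / 20) * (1 - exp(-(20 / 19) * d))
}

#' Simulation configuration for a synthetic protein family
#'
#' Defines the taxonomy shape, per-rank divergence and optional horizontal
#' transfer events for [simulate_family()]. Defaults emulate an uneven
#' multi-rank taxonomy whose group-mean p-distances fall in the 0.3-0.8
#' range typical of deep protein-family comparisons: divergence is
#' concentrated on the phylum branches and on the terminal (organism)
#' branches.
#'
#' @param n_per_rank Named list giving, for each rank below superkingdom,
#'   the number of child clans per parent: a single count or a `c(min, max)`
#'   range sampled per parent (uneven clan sizes).
#' @param seq_length Alignment length L in sites.
#' @param rate_per_rank Named numeric: expected substitutions per site `d`
#'   accumulated on the branch leading into each node of that rank.
#' @param hgt_events Number of cross-clan horizontal transfer events: a
#'   recipient leaf's sequence is replaced by a copy of a donor leaf from a
#'   different family, then diverged by `hgt_divergence`.
#' @param hgt_divergence Post-transfer divergence of the transferred copy.
#' @param superkingdom Name of the (single) superkingdom simulated.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_per_rank = list(kingdom = 1, phylum = 2,
                                         class = 2, order = 2,
                                         family = 2, genus = 2,
                                         organism = c(1, 4)),
                       seq_length = 500L,
                       rate_per_rank = c(kingdom = 0.15, phylum = 0.30,
                                         class = 0.15, order = 0.10,
                                         family = 0.10, genus = 0.08,
                                         organism = 0.18),
                       hgt_events = 0L, hgt_divergence = 0.05,
                       superkingdom = "Synthkingdom", seed = 1L) {
  ranks <- lineage_ranks()[-1]
  if (!all(ranks %in% names(n_per_rank))) {
    stop("n_per_rank must name every rank below superkingdom")
  }
  if (!all(ranks %in% names(rate_per_rank))) {
    stop("rate_per_rank must name every rank below superkingdom")
  }
  if (seq_length < 1L) stop("seq_length must be >= 1")
  if (any(rate_per_rank < 0)) stop("rates must be non-negative")
  if (hgt_events < 0L) stop("hgt_events must be non-negative")
  structure(list(n_per_rank = n_per_rank, seq_length = as.integer(seq_length),
                 rate_per_rank = rate_per_rank,
                 hgt_events = as.integer(hgt_events),
                 hgt_divergence = hgt_divergence,
                 superkingdom = superkingdom, seed = as.integer(seed)),
            class = "sim_config")
}

mutate_seq <- function(chars, d) {
  # per-site substitution under the 20-state equal-rates model: a site
  # changes with probability p(d) and then takes one of the 19 other
  # residues uniformly (transition probability of the compound process,
  # so branches compose additively in d)
  hit <- stats::runif(length(chars)) < expected_p(d)
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(AA20[AA20 != a], 1L)
    }, "")
  }
  chars
}

#' Simulate an aligned protein family over a known taxonomy
#'
#' Draws a uniform random root sequence, grows a taxonomy according to the
#' configuration, and evolves the sequence down every branch under the
#' 20-state equal-rates model (no indels; gap handling is exercised
#' separately with [mask_gaps()]). Optional horizontal transfer events then
#' replace recipient leaves with diverged copies of cross-family donors.
#' Everything is reproducible from `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return List: `alignment` (named character vector), `lineages`
#'   (`data.frame` as from [read_lineages()]), `truth` (list with the taxon
#'   names per rank, per-rank branch rates, counts, and the HGT event table).
#' @export
simulate_family <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ranks <- lineage_ranks()[-1]
  L <- cfg$seq_length
  root <- sample(AA20, L, replace = TRUE)
  counters <- stats::setNames(rep(0L, length(ranks)), ranks)
  rows <- list(); seqs <- list()
  n_children <- function(rank) {
    spec <- cfg$n_per_rank[[rank]]
    if (length(spec) == 1L) as.integer(spec)
    else sample(seq.int(spec[1], spec[2]), 1L)
  }
  grow <- function(chars, depth, path) {
    rank <- ranks[depth]
    for (i in seq_len(n_children(rank))) {
      counters[rank] <<- counters[rank] + 1L
      name <- sprintf("%s_%02d", rank, counters[rank])
      child <- mutate_seq(chars, cfg$rate_per_rank[[rank]])
      path2 <- c(path, stats::setNames(name, rank))
      if (rank == "organism") {
        acc <- sprintf("SYN%04d", length(seqs) + 1L)
        seqs[[acc]] <<- paste(child, collapse = "")
        rows[[length(rows) + 1L]] <<- c(accession = acc,
                                        superkingdom = cfg$superkingdom,
                                        path2)
      } else {
        grow(child, depth + 1L, path2)
      }
    }
  }
  grow(root, 1L, character(0))
  aln <- unlist(seqs)
  lineages <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  lineages <- lineages[, c("accession", lineage_ranks())]
  hgt <- data.frame(recipient = character(0), donor = character(0),
                    stringsAsFactors = FALSE)
  if (cfg$hgt_events > 0L) {
    for (e in seq_len(cfg$hgt_events)) {
      rec <- sample(names(aln), 1L)
      fam_rec <- lineages$family[lineages$accession == rec]
      donors <- lineages$accession[lineages$family != fam_rec]
      if (!length(donors)) break
      don <- sample(donors, 1L)
      copied <- mutate_seq(strsplit(aln[[don]], "")[[1]],
                           cfg$hgt_divergence)
      aln[[rec]] <- paste(copied, collapse = "")
      hgt <- rbind(hgt, data.frame(recipient = rec, donor = don,
                                   stringsAsFactors = FALSE))
    }
  }
  truth <- list(seed = cfg$seed, seq_length = L,
                rate_per_rank = as.list(cfg$rate_per_rank),
                counts_per_rank = as.list(counters),
                n_sequences = length(aln), hgt = hgt)
  list(alignment = aln, lineages = lineages, truth = truth)
}

#' Mask random residues with gaps
#'
#' Replaces a seeded random subset of residues with `-` so the pairwise
#' deletion policy can be exercised on gap-free simulated alignments. Each
#' residue is masked independently with probability `fraction`, so the
#' expected comparable-site count per pair is `L * (1 - fraction)^2`.
#'
#' @param aln Named character vector of aligned residues.
#' @param fraction Masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The masked alignment.
#' @export
mask_gaps <- function(aln, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(aln)
  set.seed(as.integer(seed))
  X <- aln_char_matrix(aln)
  X[matrix(stats::runif(length(X)) < fraction, nrow(X))] <- "-"
  out <- apply(X, 1L, paste, collapse = "")
  names(out) <- names(aln)
  out
}
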