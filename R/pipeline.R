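#' Pipeline run configuration
#'
#' @param alignment Path to an aligned FASTA file.
#' @param lineages Path to a lineage TSV ([read_lineages()]).
#' @param out_dir Output directory (created; must be empty or absent).
#' @param gap_policy `"pairwise"` or `"complete"` deletion.
#' @param ranks Ranks to summarize in the diversity tables.
#' @param bootstrap Bootstrap replicate count B (0 disables supports).
#' @param seed Integer seed for the bootstrap.
#' @param strict_kingdom Completeness rule flag
#'   (see [filter_complete_lineage()]).
#' @param plots Write heatmap/pie PDFs? (Requires ggplot2; TSVs are always
#'   the authoritative output.)
#' @return List of class `run_config`.
#' @export
run_config <- function(alignment, lineages, out_dir,
                       gap_policy = c("pairwise", "complete"),
                       ranks = lineage_ranks()[3:7],
                       bootstrap = 0L, seed = 1L,
                       strict_kingdom = FALSE, plots = FALSE) {
  gap_policy <- match.arg(gap_policy)
  structure(list(alignment = alignment, lineages = lineages,
                 out_dir = out_dir, gap_policy = gap_policy, ranks = ranks,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 strict_kingdom = strict_kingdom, plots = plots),
            class = "run_config")
}

#' Run the full diversity/partition/tree pipeline
#'
#' Executes, in order: deduplication of identical sequences, the
#' complete-lineage filter, taxonomy construction, the p-distance matrix,
#' per-rank diversity tables, inter-/intra-clan variance partitions along
#' the lineage, and the NJ tree (with bootstrap supports when
#' `cfg$bootstrap > 0`). Writes all tabular outputs plus a JSON manifest of
#' stage counts to `cfg$out_dir`; any stage error aborts with the stage
#' name and removes partial outputs.
#'
#' @param cfg A `run_config`.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (dir.exists(cfg$out_dir) && length(list.files(cfg$out_dir))) {
    stop("output directory not empty: ", cfg$out_dir)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, e) {
    unlink(cfg$out_dir, recursive = TRUE)
    stop("pipeline aborted at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  manifest <- list(seed = cfg$seed, gap_policy = cfg$gap_policy,
                   package_version = as.character(
                     utils::packageVersion("clanova")))

  aln <- stage("read_alignment", read_alignment(cfg$alignment))
  manifest$n_input <- length(aln)
  aln <- stage("dedup_identical", dedup_identical(aln))
  manifest$n_after_dedup <- length(aln)
  lin <- stage("read_lineages", read_lineages(cfg$lineages))
  flt <- stage("filter_complete_lineage",
               suppressMessages(filter_complete_lineage(
                 aln, lin, cfg$strict_kingdom)))
  if (length(flt$kept) < 2L) {
    fail("filter_complete_lineage",
         simpleError("fewer than 2 sequences with complete lineage"))
  }
  manifest$n_complete <- length(flt$kept)
  manifest$counts_per_superkingdom <- as.list(flt$counts)
  message("pipeline: ", manifest$n_input, " -> dedup ",
          manifest$n_after_dedup, " -> complete lineage ",
          manifest$n_complete)

  taxonomy <- stage("build_taxonomy", build_taxonomy(flt$lineages))
  M <- stage("distance_matrix",
             suppressWarnings(distance_matrix(flt$kept, cfg$gap_policy)))
  manifest$n_undefined_pairs <- nrow(M$flagged)
  write_dist_phylip(M, file.path(cfg$out_dir, "pdistance.phylip.tsv"))

  summaries <- stage("rank_table", {
    do.call(rbind, lapply(cfg$ranks, function(rk)
      rank_table(M, taxonomy, rk)))
  })
  utils::write.table(summaries, file.path(cfg$out_dir, "rank_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  parts <- stage("partition_lineage", partition_lineage(M, taxonomy))
  utils::write.table(parts, file.path(cfg$out_dir, "variance_partitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  manifest$n_partitions_ok <- sum(parts$status == "ok")
  manifest$skipped_nodes <- parts$node[parts$status != "ok"]

  stage("nj_tree", {
    if (cfg$bootstrap > 0L && length(flt$kept) >= 3L) {
      bs <- bootstrap_supports(flt$kept, cfg$bootstrap, cfg$seed,
                               cfg$gap_policy)
      manifest$bootstrap_replicates_used <- bs$replicates_used
      manifest$bootstrap_replicates_dropped <- bs$replicates_dropped
      write_newick(bs$tree, file.path(cfg$out_dir, "njtree.nwk"))
    } else {
      write_newick(nj_tree(M), file.path(cfg$out_dir, "njtree.nwk"))
    }
  })

  if (isTRUE(cfg$plots) && requireNamespace("ggplot2", quietly = TRUE)) {
    p <- plot_rank_heatmap(summaries)
    ggplot2::ggsave(file.path(cfg$out_dir, "rank_heatmap.pdf"), p,
                    width = 7, height = 7)
  }

  cfg_echo <- unclass(cfg)
  jsonlite::write_json(cfg_echo, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Heatmap of per-taxon average p-distances
#'
#' One tile per taxon, one column per rank, fill = mean p-distance; blank
#' tiles are clans whose average is not available (n < 2).
#'
#' @param summaries `data.frame` of [rank_table()] rows (several ranks
#'   may be stacked).
#' @return A ggplot object.
#' @export
plot_rank_heatmap <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rank_heatmap requires ggplot2")
  }
  summaries$rank <- factor(summaries$rank,
                           levels = intersect(lineage_ranks(),
                                              unique(summaries$rank)))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$rank, y = .data$taxon,
                               fill = .data$mean_p)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white",
                                  name = "mean p") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
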