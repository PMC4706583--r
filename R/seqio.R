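#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet width
NULL

#' Taxonomic rank names, root to tip
#'
#' The eight ranks used throughout the package, ordered from superkingdom to
#' organism.
#'
#' @return Character vector of the eight rank names.
#' @export
lineage_ranks <- function() {
  c("superkingdom", "kingdom", "phylum", "class", "order",
    "family", "genus", "organism")
}

#' Read an aligned protein FASTA
#'
#' Reads a multiple sequence alignment in FASTA format. All records must have
#' the same aligned length; the gap character is `-` and `X` marks an
#' undetermined residue. Residues are uppercased on input.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector: accession -> aligned residue string.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty alignment file: ", path)
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1L) {
    stop("alignment records have unequal lengths (",
         paste(sort(unique(w)), collapse = ", "), "); input is not aligned")
  }
  acc <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in alignment: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  res <- toupper(as.character(aa))
  names(res) <- acc
  res
}

#' Write an aligned protein FASTA
#'
#' Inverse of [read_alignment()]; records are written unwrapped (one line per
#' sequence) so write-then-read is byte-stable for normalized input.
#'
#' @param aln Named character vector of aligned residues.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(is.character(aln), !is.null(names(aln)))
  aa <- Biostrings::AAStringSet(aln)
  Biostrings::writeXStringSet(aa, path, width = 20001L)
  invisible(path)
}

#' Read a taxonomic lineage table
#'
#' Parses a UTF-8 tab-separated table with a header row naming an `accession`
#' column plus any of the eight ranks ([lineage_ranks()]). Empty cells and the
#' literal `NA` denote an absent rank. Unknown columns are dropped with a
#' warning; missing rank columns are filled with `NA`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `accession` and the eight ranks, one row
#'   per input row (zero rows for an empty body).
#' @export
read_lineages <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c("", "NA"),
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (!"accession" %in% names(tab)) {
    stop("lineage table lacks an 'accession' column: ", path)
  }
  ranks <- lineage_ranks()
  unknown <- setdiff(names(tab), c("accession", ranks))
  if (length(unknown)) {
    warning("ignoring unknown lineage column(s): ",
            paste(unknown, collapse = ", "))
  }
  for (r in setdiff(ranks, names(tab))) tab[[r]] <- NA_character_
  out <- tab[, c("accession", ranks), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a lineage table
#'
#' @param lineages Lineage `data.frame` as returned by [read_lineages()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  utils::write.table(lineages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Remove identical sequences
#'
#' Drops every sequence whose full residue string (gaps included, case
#' insensitive) duplicates an earlier one; the first occurrence is kept and
#' input order is preserved.
#'
#' @param aln Named character vector of aligned residues.
#' @return The deduplicated alignment.
#' @export
dedup_identical <- function(aln) {
  aln[!duplicated(toupper(aln))]
}

#' Filter sequences to complete taxonomic lineages
#'
#' A lineage is complete when all eight ranks are present. Because prokaryote
#' records carry no kingdom, the kingdom rank is by default required only when
#' the superkingdom is Eukaryota; `strict_kingdom = TRUE` requires it for all.
#'
#' @param aln Named character vector of aligned residues.
#' @param lineages Lineage `data.frame` ([read_lineages()]).
#' @param strict_kingdom Require the kingdom rank for every superkingdom?
#' @return List with `kept` and `dropped` alignments, the matching `lineages`
#'   rows (kingdom back-filled with the superkingdom name where it was waived),
#'   and `counts`, a table of kept sequences per superkingdom.
#' @export
filter_complete_lineage <- function(aln, lineages, strict_kingdom = FALSE) {
  acc <- names(aln)
  idx <- match(acc, lineages$accession)
  ranks <- lineage_ranks()
  lin <- lineages[idx, , drop = FALSE]
  present <- !is.na(as.matrix(lin[, ranks, drop = FALSE])) &
    nzchar(as.matrix(lin[, ranks, drop = FALSE]))
  need <- matrix(TRUE, nrow(lin), length(ranks),
                 dimnames = list(NULL, ranks))
  if (!strict_kingdom) {
    euk <- !is.na(lin$superkingdom) &
      tolower(lin$superkingdom) == "eukaryota"
    need[, "kingdom"] <- euk
  }
  complete <- !is.na(idx) & apply(present | !need, 1L, all)
  lin_kept <- lin[complete, , drop = FALSE]
  # waived kingdoms become a pass-through clan named after the superkingdom,
  # so the taxonomy stays an eight-rank tree
  fill <- is.na(lin_kept$kingdom) | !nzchar(lin_kept$kingdom)
  lin_kept$kingdom[fill] <- lin_kept$superkingdom[fill]
  lin_kept$accession <- acc[complete]
  rownames(lin_kept) <- NULL
  counts <- table(lin_kept$superkingdom)
  message("complete-lineage filter: kept ", sum(complete), "/", length(aln),
          " (", paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  list(kept = aln[complete], dropped = aln[!complete],
       lineages = lin_kept, counts = counts)
}

#' Build a taxonomy tree from complete lineages
#'
#' Builds the nested clan structure used by [rank_table()] and
#' [partition_lineage()]. Each node records its rank, name, member accessions
#' and child nodes; leaves are organisms. A forest (one root per superkingdom)
#' is returned under a synthetic `"root"` node.
#'
#' @param lineages Lineage `data.frame` with complete lineages
#'   (see [filter_complete_lineage()]).
#' @return A `taxonomy_node`: `list(rank, name, members, children)`.
#' @export
build_taxonomy <- function(lineages) {
  ranks <- lineage_ranks()
  m <- as.matrix(lineages[, ranks, drop = FALSE])
  if (any(is.na(m) | !nzchar(m))) {
    stop("build_taxonomy requires complete lineages; run ",
         "filter_complete_lineage() first")
  }
  # same organism must not sit under two distinct parent paths
  paths <- apply(m, 1L, paste, collapse = "\r")
  by_org <- split(paths, m[, "organism"])
  bad <- names(by_org)[vapply(by_org, function(p) length(unique(p)) > 1L,
                              logical(1))]
  if (length(bad)) {
    accs <- lineages$accession[m[, "organism"] %in% bad]
    stop("conflicting lineages for organism(s) ",
         paste(bad, collapse = ", "), " (accessions: ",
         paste(accs, collapse = ", "), ")")
  }
  build <- function(rows, depth) {
    if (depth > length(ranks)) return(list())
    nm <- m[rows, ranks[depth]]
    lapply(split(rows, factor(nm, levels = unique(nm))), function(rr) {
      node <- list(rank = ranks[depth], name = m[rr[1L], ranks[depth]],
                   members = lineages$accession[rr],
                   children = build(rr, depth + 1L))
      class(node) <- "taxonomy_node"
      node
    })
  }
  root <- list(rank = "root", name = "root",
               members = lineages$accession,
               children = build(seq_len(nrow(lineages)), 1L))
  class(root) <- "taxonomy_node"
  root
}

#' @export
print.taxonomy_node <- function(x, ...) {
  cat("<taxonomy_node> ", x$rank, " '", x$name, "': ",
      length(x$members), " member(s), ",
      length(x$children), " child clan(s)\n", sep = "")
  invisible(x)
}

#' Collect taxonomy nodes at a rank
#'
#' Depth-first list of all nodes whose rank equals `rank`.
#'
#' @param taxonomy A `taxonomy_node` from [build_taxonomy()].
#' @param rank One of [lineage_ranks()].
#' @return List of `taxonomy_node`s.
#' @export
taxonomy_at_rank <- function(taxonomy, rank) {
  rank <- match.arg(rank, lineage_ranks())
  out <- list()
  walk <- function(node) {
    if (identical(node$rank, rank)) out[[length(out) + 1L]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(taxonomy)
  out
}
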