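# Independent brute-force oracles and fixture builders used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# character-by-character p-distance, independent of the package's
# matrix-algebra implementation
brute_p <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca %in% AA & cb %in% AA
  m <- sum(ok)
  list(p = if (m == 0) NA_real_ else sum(ca[ok] != cb[ok]) / m, m = m)
}

# naive double-loop one-way random-effects ANOVA
brute_partition <- function(values, clans) {
  clans <- as.character(clans)
  labs <- unique(clans)
  k <- length(labs); N <- length(values)
  gm <- sum(values) / N
  ss_a <- 0; ss_w <- 0; sum_ni2 <- 0
  for (g in labs) {
    y <- values[clans == g]
    m <- sum(y) / length(y)
    ss_a <- ss_a + length(y) * (m - gm)^2
    for (v in y) ss_w <- ss_w + (v - m)^2
    sum_ni2 <- sum_ni2 + length(y)^2
  }
  ms_a <- ss_a / (k - 1); ms_w <- ss_w / (N - k)
  n0 <- (N - sum_ni2 / N) / (k - 1)
  s2a <- max(0, (ms_a - ms_w) / n0)
  list(ms_among = ms_a, ms_within = ms_w, n0 = n0, sigma2_among = s2a,
       pct_inter = 100 * s2a / (s2a + ms_w))
}

random_alignment <- function(n, L, gap_frac = 0, x_frac = 0) {
  pool <- AA
  aln <- vapply(seq_len(n), function(i) {
    ch <- sample(pool, L, replace = TRUE)
    mask <- runif(L) < gap_frac
    ch[mask] <- "-"
    xm <- runif(L) < x_frac
    ch[xm & !mask] <- "X"
    paste(ch, collapse = "")
  }, "")
  names(aln) <- sprintf("S%02d", seq_len(n))
  aln
}

# additive distance matrix from a random tree with positive branch lengths
random_additive_matrix <- function(n) {
  phy <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(phy)
  D[sort(rownames(D)), sort(colnames(D))]
}

# minimal complete-lineage table for toy datasets: one genus per family etc.
toy_lineages <- function(acc, phylum, genus = phylum, organism = acc,
                         superkingdom = "Bacteria") {
  data.frame(accession = acc, superkingdom = superkingdom,
             kingdom = NA_character_, phylum = phylum,
             class = paste0("c_", phylum), order = paste0("o_", phylum),
             family = paste0("f_", genus), genus = genus,
             organism = organism, stringsAsFactors = FALSE)
}

# synthetic lineage table mirroring the published per-superkingdom
# bookkeeping (a stand-in built in code; the real supplementary accession
# tables are not redistributed here)
synthetic_supplementary_lineages <- function() {
  mk <- function(n, superkingdom, kingdom, phylum, cls, prefix) {
    if (n == 0) return(NULL)
    i <- seq_len(n)
    data.frame(accession = sprintf("%s%04d", prefix, i),
               superkingdom = superkingdom, kingdom = kingdom,
               phylum = phylum, class = cls,
               order = paste0(cls, "_ord", (i %% 2) + 1),
               family = paste0(cls, "_fam", (i %% 3) + 1),
               genus = paste0(cls, "_gen", (i %% 5) + 1),
               organism = sprintf("%s organism %04d", cls, i),
               stringsAsFactors = FALSE)
  }
  # archaea: 2 phyla (33 + 55), 7 classes, printed breakdown
  arch <- rbind(
    mk(33, "Archaea", NA, "Crenarchaeota", "Thermoprotei", "ARCR"),
    mk(1,  "Archaea", NA, "Euryarchaeota", "Archaeoglobi", "AREA"),
    mk(14, "Archaea", NA, "Euryarchaeota", "Halobacteria", "AREB"),
    mk(14, "Archaea", NA, "Euryarchaeota", "Methanococci", "AREC"),
    mk(12, "Archaea", NA, "Euryarchaeota", "Methanomicrobia", "ARED"),
    mk(13, "Archaea", NA, "Euryarchaeota", "Thermococci", "AREE"),
    mk(1,  "Archaea", NA, "Euryarchaeota", "Thermoplasmata", "AREF"))
  # bacteria: 2586 spread over 9 phyla / 18 classes
  bac <- do.call(rbind, lapply(seq_len(18), function(j) {
    n <- 2586 %/% 18 + (j <= 2586 %% 18)
    mk(n, "Bacteria", NA, paste0("Bphylum", (j - 1) %/% 2 + 1),
       paste0("Bclass", j), sprintf("BA%02d", j))
  }))
  # eukaryota: 53 Fungi + 397 Metazoa + 274 Viridiplantae = 724
  euk <- rbind(
    mk(53,  "Eukaryota", "Fungi", "Ephylum1", "Eclass1", "EUF"),
    mk(397, "Eukaryota", "Metazoa", "Ephylum2", "Eclass2", "EUM"),
    mk(274, "Eukaryota", "Viridiplantae", "Ephylum3", "Eclass3", "EUV"))
  rbind(arch, bac, euk)
}
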