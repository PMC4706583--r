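test_that("p_distance counts comparable and differing sites correctly", {
  expect_equal(p_distance("ACDE", "ACDE"), list(p = 0, m = 4L))
  expect_equal(p_distance("ACDE", "ACDF"), list(p = 0.25, m = 4L))
  expect_equal(p_distance("AC-E", "ACDE"), list(p = 0, m = 3L))
  expect_equal(p_distance("AAAA", "CCCC"), list(p = 1, m = 4L))
  # X is excluded like a gap
  expect_equal(p_distance("AXDE", "ACDE"), list(p = 0, m = 3L))
  r <- p_distance("----", "ACDE")
  expect_true(is.na(r$p))
  expect_equal(r$m, 0L)
  expect_error(p_distance("AC", "ACD"), "unequal")
})

test_that("distance_matrix matches per-pair brute force, with gaps and X", {
  set.seed(11)
  for (rep in 1:25) {
    aln <- random_alignment(sample(3:6, 1), sample(8:20, 1),
                            gap_frac = 0.15, x_frac = 0.05)
    M <- suppressWarnings(distance_matrix(aln))
    for (i in seq_along(aln)) for (j in seq_along(aln)) {
      o <- brute_p(aln[[i]], aln[[j]])
      expect_equal(M$p[i, j], o$p, tolerance = 1e-12)
      expect_equal(unname(M$m[i, j]), o$m)
    }
    expect_true(isSymmetric(M$p) || anyNA(M$p))
  }
})

test_that("identical sequences give a zero matrix and permutation is consistent", {
  aln <- setNames(rep("ACDEFG", 4), paste0("S", 1:4))
  M <- distance_matrix(aln)
  expect_true(all(M$p == 0))

  set.seed(3)
  aln2 <- random_alignment(5, 15)
  M1 <- distance_matrix(aln2)
  perm <- sample(5)
  M2 <- distance_matrix(aln2[perm])
  expect_equal(M2$p, M1$p[perm, perm])
})

test_that("complete deletion drops columns with any gap before comparing", {
  aln <- c(a = "ACDE", b = "AC-E", c = "GCDE")
  M <- distance_matrix(aln, policy = "complete")
  # column 3 removed everywhere: a~b compare ACE vs ACE
  expect_equal(unname(M$m["a", "b"]), 3)
  expect_equal(M$p["a", "b"], 0)
  expect_equal(M$p["a", "c"], 1 / 3)
})

test_that("pairs with no comparable sites are flagged, not fatal", {
  aln <- c(a = "AC--", b = "--DE", c = "ACDE")
  expect_warning(M <- distance_matrix(aln), "no comparable sites")
  expect_true(is.na(M$p["a", "b"]))
  expect_equal(nrow(M$flagged), 1L)
})

test_that("per-sequence averages reproduce hand arithmetic", {
  p <- matrix(0, 3, 3, dimnames = list(c("s1", "s2", "s3"),
                                       c("s1", "s2", "s3")))
  p["s1", "s2"] <- p["s2", "s1"] <- 0.2
  p["s1", "s3"] <- p["s3", "s1"] <- 0.4
  p["s2", "s3"] <- p["s3", "s2"] <- 0.6
  M <- structure(list(ids = rownames(p), p = p, m = p * 0 + 10,
                      flagged = data.frame(), policy = "pairwise"),
                 class = "p_dist_matrix")
  d <- per_sequence_average(M, rownames(p))
  expect_equal(unname(d), c(0.3, 0.4, 0.5))

  g <- group_summary(M, rownames(p), rank = "genus", taxon = "g1")
  expect_equal(g$mean_p, 0.4)
  expect_equal(g$sd_p, 0.1)
  # mean of per-sequence averages equals the mean of all pairwise values
  expect_equal(g$mean_p, mean(c(0.2, 0.4, 0.6)))

  expect_warning(empty <- per_sequence_average(M, "s1"), "fewer than 2")
  expect_length(empty, 0)
  s <- group_summary(M, "s1")
  expect_equal(s$n, 1L)
  expect_true(is.na(s$mean_p) && is.na(s$sd_p))
})

test_that("group mean identity holds on random alignments", {
  set.seed(21)
  for (rep in 1:10) {
    aln <- random_alignment(sample(4:8, 1), 30)
    M <- distance_matrix(aln)
    d <- per_sequence_average(M, names(aln))
    pair_mean <- mean(M$p[upper.tri(M$p)])
    expect_equal(mean(d), pair_mean, tolerance = 1e-12)
  }
})

test_that("single-residue mutation shifts an average distance by at most 1/m", {
  set.seed(5)
  aln <- random_alignment(5, 40)
  M0 <- distance_matrix(aln)
  d0 <- per_sequence_average(M0, names(aln))[1]
  for (rep in 1:20) {
    mut <- aln
    pos <- sample(40, 1)
    ch <- strsplit(mut[[1]], "")[[1]]
    ch[pos] <- sample(setdiff(AA, ch[pos]), 1)
    mut[[1]] <- paste(ch, collapse = "")
    d1 <- per_sequence_average(distance_matrix(mut), names(aln))[1]
    expect_gte(d1 - d0, -1 / 40 - 1e-12)
  }
})

test_that("rank tables partition the dataset and match per-group brute force", {
  sim <- simulate_family(sim_config(seq_length = 120, seed = 19))
  flt <- suppressMessages(filter_complete_lineage(sim$alignment,
                                                  sim$lineages))
  tax <- build_taxonomy(flt$lineages)
  M <- distance_matrix(flt$kept)
  for (rk in c("phylum", "genus")) {
    tab <- rank_table(M, tax, rk)
    expect_equal(sum(tab$n), length(flt$kept))
    for (r in seq_len(nrow(tab))) {
      members <- flt$lineages$accession[flt$lineages[[rk]] == tab$taxon[r]]
      expect_equal(tab$n[r], length(members))
      if (length(members) >= 2) {
        sub <- M$p[members, members]
        diag(sub) <- NA
        d <- rowMeans(sub, na.rm = TRUE)
        expect_equal(tab$mean_p[r], mean(d), tolerance = 1e-12)
        expect_equal(tab$sd_p[r], sd(d), tolerance = 1e-12)
      } else {
        expect_true(is.na(tab$mean_p[r]))
      }
    }
  }
})

test_that("two-group comparison reproduces the textbook t forms", {
  s1 <- data.frame(n = 3, mean_p = 2, sd_p = 1)
  s2 <- data.frame(n = 3, mean_p = 4, sd_p = 1)
  w <- compare_groups(s1, s2, "welch")
  expect_equal(w$t, -2 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(w$df, 4)
  expect_equal(w$p_value, 2 * pt(-abs(w$t), 4), tolerance = 1e-10)
  expect_equal(round(w$p_value, 4), 0.0705)
  p <- compare_groups(s1, s2, "pooled")
  expect_equal(p$t, w$t)
  expect_equal(p$df, 4)

  eq <- compare_groups(s1, s1)
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  z1 <- data.frame(n = 4, mean_p = 0.5, sd_p = 0)
  expect_equal(compare_groups(z1, z1)$p_value, 1)
})

test_that("welch t agrees with t.test on raw data", {
  set.seed(8)
  x <- rnorm(12, 0.4, 0.1); y <- rnorm(20, 0.6, 0.2)
  s1 <- data.frame(n = 12, mean_p = mean(x), sd_p = sd(x))
  s2 <- data.frame(n = 20, mean_p = mean(y), sd_p = sd(y))
  w <- compare_groups(s1, s2)
  ref <- t.test(x, y)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  pl <- compare_groups(s1, s2, "pooled")
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(pl$t, unname(refp$statistic), tolerance = 1e-10)
  expect_equal(pl$p_value, refp$p.value, tolerance = 1e-10)
})
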