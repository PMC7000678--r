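test_that("collapse_haplotypes groups identical sequences over surviving columns", {
  a3 <- sequence_set(c(x = "ACGT", y = "ACGT", z = "ACGT"), is_alignment = TRUE)
  t3 <- collapse_haplotypes(a3)
  expect_equal(nrow(t3$haplotypes), 1L)
  expect_equal(t3$haplotypes$count, 3L)

  a2 <- sequence_set(c(x = "ACGT", y = "ACGA", z = "ACGT"), is_alignment = TRUE)
  t2 <- collapse_haplotypes(a2)
  expect_equal(t2$haplotypes$count, c(2L, 1L))
  expect_identical(t2$members$H1, c("x", "z"))

  # a difference at a column that carries a gap in a third subset member is
  # erased by complete deletion: x/y differ only at site 4, z has a gap there
  ag <- sequence_set(c(x = "ACGT", y = "ACGA", z = "ACG-"), is_alignment = TRUE)
  tg <- collapse_haplotypes(ag)
  expect_equal(nrow(tg$haplotypes), 1L)
  expect_equal(tg$analyzed_sites, 3L)
  # ... but the same subset without z keeps the difference
  expect_equal(nrow(collapse_haplotypes(ag, c("x", "y"))$haplotypes), 2L)
})

test_that("haplotype diversity follows the unbiased n/(n-1) estimator", {
  # all-distinct sample scores exactly 1 for every n
  for (n in c(2, 3, 7, 25)) {
    strs <- vapply(seq_len(n), function(i)
      paste(c(rep("A", i - 1), "T", rep("A", n - i)), collapse = ""),
      character(1))
    names(strs) <- paste0("s", seq_len(n))
    tab <- collapse_haplotypes(sequence_set(strs, is_alignment = TRUE))
    expect_identical(haplotype_diversity(tab), 1)
  }

  # single haplotype scores 0
  mono <- sequence_set(c(a = "ACGT", b = "ACGT"), is_alignment = TRUE)
  expect_identical(haplotype_diversity(collapse_haplotypes(mono)), 0)

  # counts (2,1,1), n = 4: (4/3)(1 - (1/4 + 1/16 + 1/16)) = 5/6
  x <- sequence_set(c(a = "AAA", b = "AAA", c = "AAT", d = "ATA"),
                    is_alignment = TRUE)
  expect_equal(haplotype_diversity(collapse_haplotypes(x)), 5 / 6)

  expect_error(haplotype_diversity(collapse_haplotypes(
    sequence_set(c(a = "ACGT"), is_alignment = TRUE))),
    class = "neustonet_insufficient_sample")
})

test_that("Hd and K are invariant to input order", {
  set.seed(23)
  strs <- vapply(1:12, function(i) random_dna(60), character(1))
  names(strs) <- paste0("s", 1:12)
  aln <- sequence_set(strs, is_alignment = TRUE)
  perm <- sample(names(strs))
  hd1 <- haplotype_diversity(collapse_haplotypes(aln))
  hd2 <- haplotype_diversity(collapse_haplotypes(aln, perm))
  expect_equal(hd1, hd2)
  expect_equal(mean_pairwise_differences(aln),
               mean_pairwise_differences(aln, perm))
})

test_that("K equals the naive all-pairs oracle and the haplotype-weighted route", {
  two <- sequence_set(c(a = "AAAAA", b = "ATTTA"), is_alignment = TRUE)
  expect_equal(mean_pairwise_differences(two), 3)

  same <- sequence_set(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                       is_alignment = TRUE)
  expect_equal(mean_pairwise_differences(same), 0)

  set.seed(29)
  for (i in 1:5) {
    strs <- vapply(1:10, function(j) random_dna(100), character(1))
    # duplicate a few sequences so haplotype weighting is non-trivial
    strs[8:10] <- strs[1:3]
    names(strs) <- paste0("s", 1:10)
    aln <- sequence_set(strs, is_alignment = TRUE)
    k <- mean_pairwise_differences(aln)
    expect_equal(k, naive_mean_pairwise(strs))
    expect_equal(k, hapweighted_K(collapse_haplotypes(aln)))
  }
})

test_that("K agrees with ape's pairwise difference counts on clean alignments", {
  skip_if_not_installed("ape")
  set.seed(31)
  strs <- vapply(1:8, function(j) random_dna(200), character(1))
  names(strs) <- paste0("s", 1:8)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(strs), "")))
  d <- ape::dist.dna(bin, model = "N")
  expect_equal(mean_pairwise_differences(sequence_set(strs, is_alignment = TRUE)),
               mean(d))
})

test_that("pooled Kt recomputes site exclusion on the union", {
  aln <- sequence_set(c(a = "AAAAA", b = "AAAAT", c = "TTTTT", d = "TTTTA"),
                      is_alignment = TRUE)
  # degenerate pooling equals K of the non-empty subset
  expect_equal(pooled_mean_differences(aln, c("a", "b"), character(0)),
               mean_pairwise_differences(aln, c("a", "b")))
  # two singletons differing at 5 sites
  expect_equal(pooled_mean_differences(aln, "a", "c"), 5)
  expect_error(pooled_mean_differences(aln, c("a", "b"), c("b", "c")),
               class = "neustonet_disjointness")
  # brute-force pooled pair average on simulated two-clade data
  cfg <- sim_config(n_clades = 2, seqs_per_clade = 6, seq_length = 300,
                    habitat_assignment = c(A = "planktonic", B = "planktonic"),
                    seed = 5)
  sim <- simulate_dataset(cfg)
  ids_a <- sim$groups$id[sim$groups$clade == "A"]
  ids_b <- sim$groups$id[sim$groups$clade == "B"]
  kt <- pooled_mean_differences(sim$sequences, ids_a, ids_b)
  expect_equal(kt, naive_mean_pairwise(sim$sequences$seq[c(ids_a, ids_b)]))
})

test_that("p-distances use pairwise deletion, stay symmetric with zero diagonal", {
  same <- sequence_set(c(a = "ACGT", b = "ACGT"), is_alignment = TRUE)
  expect_equal(p_distance_matrix(same)$distance["a", "b"], 0)

  quarter <- sequence_set(c(a = "AAAA", b = "AAAT"), is_alignment = TRUE)
  expect_equal(p_distance_matrix(quarter)$distance["a", "b"], 0.25)

  # pairwise deletion: the N column is excluded for the pair that carries it
  amb <- sequence_set(c(a = "AANA", b = "AAGT", c = "AAGA"),
                      is_alignment = TRUE)
  pd <- p_distance_matrix(amb)
  expect_equal(pd$comparable["a", "b"], 3L)
  expect_equal(pd$distance["a", "b"], 1 / 3)
  expect_equal(pd$comparable["b", "c"], 4L)

  set.seed(37)
  strs <- vapply(1:6, function(j) random_dna(150, p_n = 0.05), character(1))
  names(strs) <- paste0("s", 1:6)
  pdm <- p_distance_matrix(sequence_set(strs, is_alignment = TRUE))
  expect_identical(pdm$distance, t(pdm$distance))
  expect_true(all(diag(pdm$distance) == 0))
  expect_true(all(pdm$distance >= 0 & pdm$distance <= 1, na.rm = TRUE))
})

test_that("p-distance agrees with ape under pairwise deletion", {
  skip_if_not_installed("ape")
  set.seed(41)
  strs <- vapply(1:7, function(j) random_dna(180, p_n = 0.04), character(1))
  names(strs) <- paste0("s", 1:7)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(strs), "")))
  d <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  pdm <- p_distance_matrix(sequence_set(strs, is_alignment = TRUE))
  expect_equal(unname(pdm$distance), unname(d), tolerance = 1e-12)
})

test_that("a pair with no comparable sites is flagged missing", {
  x <- sequence_set(c(a = "AANN", b = "NNAA", c = "AAAA"), is_alignment = TRUE)
  expect_warning(pd <- p_distance_matrix(x),
                 class = "neustonet_incomparable_pair")
  expect_true(is.na(pd$distance["a", "b"]))
  expect_false(is.na(pd$distance["a", "c"]))
})

test_that("composition chi-square is zero under exact homogeneity", {
  same <- sequence_set(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                       is_alignment = TRUE)
  r <- composition_chisq(same)
  expect_true(all(r$chisq == 0))
  expect_false(any(r$flagged))
  expect_true(all(r$df == 3L))

  # each sequence matches the pooled composition although sequences differ
  mix <- sequence_set(c(a = "AACCGGTT", b = "ACGTACGT"), is_alignment = TRUE)
  r2 <- composition_chisq(mix)
  expect_true(all(r2$chisq == 0))
})

test_that("composition test reduces df when a base is absent from the pool", {
  x <- sequence_set(c(a = "AATT", b = "ATAT"), is_alignment = TRUE)
  expect_warning(r <- composition_chisq(x),
                 class = "neustonet_zero_expectation")
  expect_true(all(r$df == 1L))
  expect_error(composition_chisq(sequence_set(c(a = "ACGT"),
                                              is_alignment = TRUE)),
               class = "neustonet_insufficient_sample")
})

test_that("diversity_by_clade assembles per-clade Hd/K rows", {
  cfg <- sim_config(n_clades = 3, seqs_per_clade = 5, seq_length = 400,
                    seed = 71)
  sim <- simulate_dataset(cfg)
  div <- diversity_by_clade(sim$sequences, sim$groups)
  expect_equal(nrow(div), 3L)
  expect_true(all(div$Hd >= 0 & div$Hd <= 1))
  expect_true(all(div$K >= 0))
  expect_equal(div$pi, div$K / div$analyzed_sites)
})
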