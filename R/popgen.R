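#' Collapse aligned sequences into haplotypes
#'
#' Applies [complete_deletion()] to the requested subset (so only columns
#' unambiguous across that subset are compared), then groups sequences that
#' are identical over the surviving columns. Haplotypes are numbered by
#' first occurrence in input order (`H1`, `H2`, ...).
#'
#' @param aln a [sequence_set()] alignment.
#' @param subset sequence ids to analyze; defaults to all.
#' @return an object of class `haplotype_table`: a list with elements
#'   `haplotypes` (data.frame `haplotype`, `count`), `representative`
#'   (named character of haplotype residue strings over analyzed sites),
#'   `members` (named list of member ids), `n` and `analyzed_sites`.
#' @export
collapse_haplotypes <- function(aln, subset = NULL) {
  stopifnot(inherits(aln, "sequence_set"))
  if (!aln$is_alignment)
    ns_stop("neustonet_value", "haplotype collapsing requires an alignment")
  if (is.null(subset)) subset <- seq_ids(aln)
  if (length(subset) == 0L)
    ns_stop("neustonet_empty_input", "empty subset")
  sub <- complete_deletion(seq_subset(aln, subset))
  key <- sub$seq
  first <- !duplicated(key)
  reps <- key[first]
  hap_id <- paste0("H", seq_along(reps))
  names(reps) <- hap_id
  idx <- match(key, key[first])
  members <- split(names(key), hap_id[idx])
  members <- members[hap_id]  # restore first-occurrence order
  structure(list(
    haplotypes = data.frame(haplotype = hap_id,
                            count = as.integer(lengths(members)),
                            stringsAsFactors = FALSE),
    representative = reps,
    members = members,
    n = length(subset),
    analyzed_sites = nchar(reps[[1L]])),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d sequence(s), %d haplotype(s), %d analyzed site(s)\n",
              x$n, nrow(x$haplotypes), x$analyzed_sites))
  print(utils::head(x$haplotypes, 10L))
  invisible(x)
}

#' Haplotype diversity (Hd)
#'
#' Nei's unbiased haplotype (gene) diversity,
#' `Hd = n/(n-1) * (1 - sum(p_i^2))`, where `p_i` are haplotype relative
#' frequencies. The small-sample `n/(n-1)` correction makes an all-distinct
#' sample score exactly 1.
#'
#' @param table a `haplotype_table` from [collapse_haplotypes()].
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  n <- table$n
  if (n < 2L)
    ns_stop("neustonet_insufficient_sample",
            "haplotype diversity needs at least 2 sequences")
  cts <- table$haplotypes$count
  # integer-count form of n/(n-1) * (1 - sum(p^2)): exact at the endpoints
  hd <- (n^2 - sum(cts^2)) / (n * (n - 1))
  min(max(hd, 0), 1)
}

# pairwise difference-count matrix over an aligned character matrix
diff_count_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  for (i in 1L:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

#' Mean number of pairwise differences (K)
#'
#' `K = sum_{i<j} d(i,j) / choose(n, 2)` where `d` counts differing sites
#' between a sequence pair. Differences are raw counts (no multiple-hit
#' correction). Under the default complete-deletion convention all pairs are
#' compared over the same site set; under pairwise deletion each pair is
#' compared over the sites where both carry a plain base.
#'
#' @param aln a [sequence_set()] alignment.
#' @param subset ids to analyze (>= 2); defaults to all.
#' @param deletion `"complete"` (default) or `"pairwise"` site exclusion.
#' @return K, a non-negative number.
#' @export
mean_pairwise_differences <- function(aln, subset = NULL,
                                      deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "sequence_set"))
  if (is.null(subset)) subset <- seq_ids(aln)
  if (length(subset) < 2L)
    ns_stop("neustonet_insufficient_sample", "K needs at least 2 sequences")
  sub <- seq_subset(aln, subset)
  if (deletion == "complete") {
    m <- seq_matrix(complete_deletion(sub))
    d <- diff_count_matrix(m)
  } else {
    m <- seq_matrix(sub)
    ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
    n <- nrow(m)
    d <- matrix(0L, n, n)
    for (i in 1L:(n - 1L)) for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both])
    }
  }
  n <- nrow(d)
  sum(d[upper.tri(d)]) / choose(n, 2)
}

#' Mean pairwise differences of two clades pooled (Kt)
#'
#' Pools two disjoint clade subsets and recomputes K over the union, with
#' site exclusion recomputed on the pooled subset.
#'
#' @inheritParams mean_pairwise_differences
#' @param subset_a,subset_b disjoint id vectors; `subset_b` may be empty, in
#'   which case Kt equals K of `subset_a`.
#' @return Kt, a non-negative number.
#' @export
pooled_mean_differences <- function(aln, subset_a, subset_b,
                                    deletion = c("complete", "pairwise")) {
  if (length(intersect(subset_a, subset_b)))
    ns_stop("neustonet_disjointness", "clade subsets overlap: %s",
            paste(intersect(subset_a, subset_b), collapse = ", "))
  mean_pairwise_differences(aln, c(subset_a, subset_b), deletion = deletion)
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites among sites comparable per pair (pairwise
#' deletion: both sequences carry a plain `A`/`C`/`G`/`T`). A pair with zero
#' comparable sites gets `NA` with a warning.
#'
#' @param aln a [sequence_set()] alignment.
#' @param subset ids to analyze; defaults to all.
#' @param mode `"proportion"` (p-distance, default) or `"count"` (raw
#'   difference counts).
#' @return an object of class `p_distance_matrix`: list with `ids`,
#'   `distance` (symmetric matrix, zero diagonal), `comparable` (sites per
#'   pair), `mode`, and `min` (minimum off-diagonal distance).
#' @export
p_distance_matrix <- function(aln, subset = NULL,
                              mode = c("proportion", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "sequence_set"))
  if (!aln$is_alignment)
    ns_stop("neustonet_value", "p-distance requires an alignment")
  if (is.null(subset)) subset <- seq_ids(aln)
  m <- seq_matrix(seq_subset(aln, subset))
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  dist <- matrix(0, n, n, dimnames = list(subset, subset))
  comp <- matrix(ncol(m), n, n, dimnames = list(subset, subset))
  if (n >= 2L) for (i in 1L:(n - 1L)) for (j in (i + 1L):n) {
    both <- ok[i, ] & ok[j, ]
    nc <- sum(both)
    comp[i, j] <- comp[j, i] <- nc
    if (nc == 0L) {
      dist[i, j] <- dist[j, i] <- NA_real_
      ns_warn("neustonet_incomparable_pair",
              "no comparable sites for pair %s / %s", subset[i], subset[j])
    } else {
      nd <- sum(m[i, both] != m[j, both])
      dist[i, j] <- dist[j, i] <- if (mode == "proportion") nd / nc else nd
    }
  }
  off <- dist[upper.tri(dist)]
  structure(list(ids = subset, distance = dist, comparable = comp,
                 mode = mode,
                 min = if (length(off)) suppressWarnings(min(off, na.rm = TRUE)) else NA_real_),
            class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  cat(sprintf("p_distance_matrix: %d sequences (%s mode), minimum off-diagonal = %s\n",
              length(x$ids), x$mode, format(x$min, digits = 6)))
  invisible(x)
}

#' Per-sequence base-composition heterogeneity chi-square test
#'
#' Screens each sequence for non-stationary base composition: observed
#' `A`/`C`/`G`/`T` counts (gaps and ambiguity codes excluded) are compared
#' against expectations under the frequencies pooled over all sequences,
#' with `X^2 = sum_b (o_b - e_b)^2 / e_b` on 3 degrees of freedom. Sequences
#' with `p < 0.05` are flagged; a Bonferroni-adjusted p-value column is also
#' emitted, but flagging follows the uncorrected per-sequence screen.
#'
#' @param x a [sequence_set()] with at least 2 sequences.
#' @return a data.frame of class `composition_test` with columns `id`, `A`,
#'   `C`, `G`, `T`, `chisq`, `df`, `p_value`, `flagged`, `p_bonferroni`.
#' @export
composition_chisq <- function(x) {
  stopifnot(inherits(x, "sequence_set"))
  if (length(x) < 2L)
    ns_stop("neustonet_insufficient_sample",
            "composition test needs at least 2 sequences")
  bases <- c("A", "C", "G", "T")
  obs <- t(vapply(x$seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    vapply(bases, function(b) sum(ch == b), numeric(1))
  }, numeric(4)))
  pooled <- colSums(obs)
  f <- pooled / sum(pooled)
  use <- f > 0
  if (!all(use))
    ns_warn("neustonet_zero_expectation",
            "base(s) absent from pooled composition: %s (df reduced)",
            paste(bases[!use], collapse = ", "))
  L <- rowSums(obs)
  stat <- numeric(nrow(obs)); df <- integer(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    if (L[i] == 0L) { stat[i] <- NA_real_; df[i] <- 0L; next }
    e <- f[use] * L[i]
    stat[i] <- sum((obs[i, use] - e)^2 / e)
    df[i] <- sum(use) - 1L
  }
  if (anyNA(stat))
    ns_warn("neustonet_empty_sequence",
            "zero-length sequence(s) skipped in composition test")
  p <- ifelse(df > 0, stats::pchisq(stat, df, lower.tail = FALSE), NA_real_)
  out <- data.frame(id = seq_ids(x), obs, chisq = stat, df = df, p_value = p,
                    flagged = !is.na(p) & p < 0.05,
                    p_bonferroni = pmin(1, p * nrow(obs)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("composition_test", "data.frame")
  out
}

#' Clade-level diversity summary
#'
#' Convenience wrapper computing, per clade of a group map, the haplotype
#' count `h`, haplotype diversity `Hd`, mean pairwise differences `K`,
#' per-site `pi` (`K / analyzed_sites`) and the analyzed site count.
#'
#' @param aln a [sequence_set()] alignment.
#' @param groups a `group_map` covering the alignment.
#' @param clades clade labels to analyze; defaults to all in the map.
#' @param deletion site-exclusion convention for K.
#' @return a data.frame of class `diversity_summary`.
#' @export
diversity_by_clade <- function(aln, groups, clades = NULL,
                               deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (is.null(clades)) clades <- unique(groups$clade)
  rows <- lapply(clades, function(cl) {
    ids <- intersect(seq_ids(aln), groups$id[groups$clade == cl])
    if (length(ids) < 2L)
      ns_stop("neustonet_insufficient_sample",
              "clade %s has fewer than 2 sequences", cl)
    tab <- collapse_haplotypes(aln, ids)
    k <- mean_pairwise_differences(aln, ids, deletion = deletion)
    data.frame(clade = cl, n = tab$n, h = nrow(tab$haplotypes),
               Hd = haplotype_diversity(tab), K = k,
               pi = k / tab$analyzed_sites,
               analyzed_sites = tab$analyzed_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", "data.frame")
  out
}
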