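# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive results by the most naive route available
# (position-by-position scans, all-pairs loops, exhaustive enumeration)
# and never call the code paths they check.

# naive position-by-position motif scan (overlapping; N never matches
# because substr comparison is literal)
naive_count <- function(seq, motif) {
  n <- nchar(seq)
  if (n < 3L) return(0L)
  hits <- 0L
  for (i in 1:(n - 2L)) if (substr(seq, i, i + 2L) == motif) hits <- hits + 1L
  hits
}

naive_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
  paste(map[ch], collapse = "")
}

# all-pairs mean difference count over a named character vector of equal
# length strings (assumes site exclusion already applied)
naive_mean_pairwise <- function(strings) {
  n <- length(strings)
  tot <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    a <- strsplit(strings[[i]], "", fixed = TRUE)[[1L]]
    b <- strsplit(strings[[j]], "", fixed = TRUE)[[1L]]
    tot <- tot + sum(a != b)
  }
  tot / choose(n, 2)
}

# K via haplotype-table weighting: sum_{i<j} p_i p_j d_ij * n/(n-1) ... the
# unweighted all-pairs mean equals sum over haplotype pairs of
# count_i*count_j*d_ij / C(n,2) (within-haplotype pairs contribute 0)
hapweighted_K <- function(tab) {
  reps <- tab$representative
  counts <- tab$haplotypes$count
  h <- length(reps)
  tot <- 0
  if (h >= 2L) for (i in 1:(h - 1L)) for (j in (i + 1L):h) {
    a <- strsplit(reps[[i]], "", fixed = TRUE)[[1L]]
    b <- strsplit(reps[[j]], "", fixed = TRUE)[[1L]]
    tot <- tot + counts[i] * counts[j] * sum(a != b)
  }
  tot / choose(tab$n, 2)
}

random_dna <- function(n, freqs = c(A = .35, C = .15, G = .20, T = .30),
                       p_n = 0) {
  pool <- names(freqs)
  s <- sample(pool, n, replace = TRUE, prob = freqs)
  if (p_n > 0) {
    k <- stats::rbinom(1L, n, p_n)
    if (k > 0) s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

# Prim MST total length over a distance matrix
mst_length <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  total <- 0
  for (step in seq_len(n - 1L)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    total <- total + min(dd)
    j <- which(!in_tree)[which(dd == min(dd), arr.ind = TRUE)[1L, 2L]]
    in_tree[j] <- TRUE
  }
  total
}

ham_mat_strings <- function(strings) {
  m <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0, n, n)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# exhaustive Steiner minimal length for binary (two-state) haplotypes in
# Hamming space: minimum over all subsets (size <= n-2) of unobserved state
# vectors of the MST length over observed + subset
steiner_opt_binary <- function(obs, states = c("A", "T")) {
  L <- nchar(obs[1L])
  all_vec <- apply(expand.grid(rep(list(states), L)), 1L, paste, collapse = "")
  cand <- setdiff(all_vec, obs)
  best <- mst_length(ham_mat_strings(obs))
  kmax <- max(0L, length(obs) - 2L)
  for (k in seq_len(kmax)) {
    if (k > length(cand)) break
    combos <- utils::combn(cand, k, simplify = FALSE)
    for (s in combos) {
      len <- mst_length(ham_mat_strings(c(obs, s)))
      if (len < best) best <- len
    }
  }
  best
}

# Steiner length achieved *within* a haplotype network: minimum over
# subsets of its median nodes of the MST length over observed + subset
network_steiner_length <- function(net) {
  obs <- unname(net$seqs[net$nodes$kind == "observed"])
  med <- unname(net$seqs[net$nodes$kind == "median"])
  best <- mst_length(ham_mat_strings(obs))
  for (k in seq_along(med)) {
    combos <- utils::combn(med, k, simplify = FALSE)
    for (s in combos) {
      len <- mst_length(ham_mat_strings(c(obs, s)))
      if (len < best) best <- len
    }
  }
  best
}

# small helpers for building fixtures in code
write_tmp_fasta <- function(records, desc = NULL) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (i in seq_along(records)) {
    hdr <- names(records)[i]
    if (!is.null(desc) && nzchar(desc[i])) hdr <- paste(hdr, desc[i])
    cat(">", hdr, "\n", records[[i]], "\n", sep = "", file = con)
  }
  close(con)
  path
}

write_tmp_groups <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
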