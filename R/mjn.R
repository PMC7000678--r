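#' Hamming distance between two residue strings
#'
#' @param a,b residue strings (or character vectors of single residues) of
#'   equal length.
#' @return number of positions at which the states differ.
#' @export
hamming <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(a, "", fixed = TRUE)[[1L]] else a
  bv <- if (length(b) == 1L) strsplit(b, "", fixed = TRUE)[[1L]] else b
  if (length(av) != length(bv))
    ns_stop("neustonet_value", "hamming: length mismatch (%d vs %d)",
            length(av), length(bv))
  sum(av != bv)
}

# Hamming distance matrix over rows of a character matrix
hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n >= 2L) for (i in 1L:(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

# --- minimum spanning network backbone ------------------------------------
#
# The MSN is the union of all minimum spanning trees: edge (u,v) belongs to
# some MST iff its weight equals the minimax path weight between u and v,
# i.e. the smallest distance class at which u and v become connected using
# edges of weight <= that class. epsilon relaxes the rule: edges whose
# weight exceeds that connection threshold by <= epsilon also enter.
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L)
    return(data.frame(from = integer(), to = integer(), weight = integer()))
  thresh <- matrix(Inf, n, n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (w in sort(unique(d[upper.tri(d)]))) {
    idx <- which(d == w & upper.tri(d), arr.ind = TRUE)
    # union all edges of this class, then record newly-connected pairs
    for (r in seq_len(nrow(idx))) {
      ri <- find(idx[r, 1L]); rj <- find(idx[r, 2L])
      if (ri != rj) parent[rj] <- ri
    }
    roots <- vapply(seq_len(n), find, integer(1))
    newly <- outer(roots, roots, "==") & !is.finite(thresh)
    thresh[newly] <- w
    if (all(roots == roots[1L])) {
      take <- d <= thresh + epsilon & upper.tri(d)
      idx2 <- which(take, arr.ind = TRUE)
      return(data.frame(from = idx2[, 1L], to = idx2[, 2L],
                        weight = d[take]))
    }
  }
  # disconnected only if duplicate vectors collapsed distances weirdly;
  # with a genuine distance matrix we always exit inside the loop
  take <- d <= thresh + epsilon & upper.tri(d)
  idx2 <- which(take, arr.ind = TRUE)
  data.frame(from = idx2[, 1L], to = idx2[, 2L], weight = d[take])
}

make_network <- function(node_id, seqs, kind, freq, edges, epsilon) {
  nodes <- data.frame(node_id = node_id, kind = kind,
                      frequency = as.integer(freq),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = node_id[edges$from], to = node_id[edges$to],
                      weight = as.integer(edges$weight),
                      stringsAsFactors = FALSE)
  names(seqs) <- node_id
  structure(list(nodes = nodes, seqs = seqs, edges = edges,
                 epsilon = as.integer(epsilon)),
            class = "haplotype_network")
}

#' Minimum spanning network of a haplotype table
#'
#' Builds the union of all minimum spanning trees over the observed
#' haplotypes (Hamming distances), optionally relaxed by `epsilon`: an edge
#' is included iff its weight is at most `epsilon` above the distance class
#' at which its endpoints first become connected. With `epsilon` at least
#' the maximum pairwise distance the network is the complete graph.
#'
#' @param table a `haplotype_table` from [collapse_haplotypes()].
#' @param epsilon non-negative integer relaxation parameter.
#' @return a `haplotype_network` (all nodes observed).
#' @export
minimum_spanning_network <- function(table, epsilon = 0L) {
  stopifnot(inherits(table, "haplotype_table"))
  reps <- table$representative
  m <- do.call(rbind, strsplit(reps, "", fixed = TRUE))
  e <- msn_edges(hamming_matrix(m), epsilon)
  make_network(names(reps), unname(reps), rep("observed", length(reps)),
               table$haplotypes$count, e, epsilon)
}

# per-site median (majority) of three residue vectors; ties (three distinct
# states) take the state of the lexicographically first sequence of the
# triplet, making candidate generation deterministic
median_vector <- function(a, b, c, tie) {
  m <- tie
  ab <- a == b; ac <- a == c; bc <- b == c
  m[ab | ac] <- a[ab | ac]
  m[bc] <- b[bc]
  m
}

#' Median-joining haplotype network
#'
#' Iterates the median-joining heuristic: (1) for every triplet of current
#' nodes, form the per-site majority-consensus (median) vector; (2) add
#' unseen median vectors whose star connection cost to the triplet is
#' strictly smaller than the triplet's spanning cost (perimeter minus its
#' largest side) — i.e. medians that genuinely shorten the local network;
#' (3) purge median nodes of degree < 3 in the rebuilt
#' [minimum_spanning_network()] and repeat until no additions; a candidate
#' purged once is never re-proposed, which guarantees termination. The
#' final network is the MSN over surviving nodes with observed haplotype
#' frequencies attached; median (inferred) nodes carry frequency 0.
#'
#' @param table a `haplotype_table`.
#' @param epsilon non-negative integer passed to the MSN backbone.
#' @param max_growth node-count ceiling as a multiple of the observed
#'   haplotype count; exceeding it raises a non-convergence error carrying
#'   the partial network in its `partial` field.
#' @return a `haplotype_network` with `kind` `"observed"` or `"median"`.
#' @export
median_joining <- function(table, epsilon = 0L, max_growth = 10) {
  stopifnot(inherits(table, "haplotype_table"))
  if (table$analyzed_sites < 1L)
    ns_stop("neustonet_value", "no analyzed sites")
  obs <- unname(table$representative)
  n_obs <- length(obs)
  mat <- do.call(rbind, strsplit(obs, "", fixed = TRUE))
  kind <- rep("observed", n_obs)
  tried <- character(0)  # candidates ever inserted; never re-tried (termination)
  repeat {
    d <- hamming_matrix(mat)
    n <- nrow(mat)
    existing <- apply(mat, 1L, paste, collapse = "")
    cand <- character(0); gains <- numeric(0)
    if (n >= 3L) {
      for (i in 1L:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
        for (k in (j + 1L):n) {
          # spanning cost of the triplet: perimeter minus largest side;
          # a median can only help when it strictly undercuts it
          per <- d[i, j] + d[i, k] + d[j, k]
          span <- per - max(d[i, j], d[i, k], d[j, k])
          if ((per + 1L) %/% 2L >= span) next  # star >= ceil(per/2): cannot win
          tie <- mat[c(i, j, k)[order(existing[c(i, j, k)])[1L]], ]
          mv <- median_vector(mat[i, ], mat[j, ], mat[k, ], tie)
          star <- sum(mv != mat[i, ]) + sum(mv != mat[j, ]) + sum(mv != mat[k, ])
          if (star >= span) next
          med <- paste(mv, collapse = "")
          if (med %in% existing || med %in% tried) next
          gain <- span - star
          if (is.na(match(med, cand))) {
            cand <- c(cand, med); gains <- c(gains, gain)
          } else if (gain > gains[match(med, cand)]) {
            gains[match(med, cand)] <- gain
          }
        }
      }
    }
    if (!length(cand)) break
    # throttle each pass to the best-improving candidates (ties included),
    # in deterministic lexicographic order
    best <- max(gains)
    cand <- sort(cand[gains == best])
    tried <- c(tried, cand)
    mat <- rbind(mat, do.call(rbind, strsplit(cand, "", fixed = TRUE)))
    kind <- c(kind, rep("median", length(cand)))
    # purge medians of degree < 3 (iteratively, on the augmented MSN)
    repeat {
      d <- hamming_matrix(mat)
      e <- msn_edges(d, epsilon)
      deg <- tabulate(c(e$from, e$to), nbins = nrow(mat))
      drop <- which(kind == "median" & deg < 3L)
      if (!length(drop)) break
      mat <- mat[-drop, , drop = FALSE]
      kind <- kind[-drop]
    }
    if (nrow(mat) > max_growth * n_obs) {
      partial <- finalize_mjn(mat, kind, table, epsilon)
      cond <- errorCondition(
        sprintf("median-joining did not converge below %d nodes",
                as.integer(max_growth * n_obs)),
        class = c("neustonet_nonconvergence", "neustonet_error"))
      cond$partial <- partial
      stop(cond)
    }
  }
  finalize_mjn(mat, kind, table, epsilon)
}

finalize_mjn <- function(mat, kind, table, epsilon) {
  seqs <- apply(mat, 1L, paste, collapse = "")
  obs_idx <- which(kind == "observed")
  med_idx <- which(kind == "median")
  # median node numbering: lexicographic over residues, deterministic
  med_ord <- med_idx[order(seqs[med_idx])]
  ord <- c(obs_idx, med_ord)
  mat <- mat[ord, , drop = FALSE]
  kind <- kind[ord]
  seqs <- seqs[ord]
  ids <- c(names(table$representative),
           if (length(med_idx)) paste0("MV", seq_along(med_idx)))
  freq <- c(table$haplotypes$count, rep(0L, length(med_idx)))
  e <- msn_edges(hamming_matrix(mat), epsilon)
  make_network(ids, unname(seqs), kind, freq, e, epsilon)
}

#' @export
print.haplotype_network <- function(x, ...) {
  nm <- sum(x$nodes$kind == "median")
  cat(sprintf("haplotype_network: %d observed + %d median node(s), %d edge(s), epsilon = %d\n",
              nrow(x$nodes) - nm, nm, nrow(x$edges), x$epsilon))
  cat(sprintf("  total edge length: %d substitution(s)\n", sum(x$edges$weight)))
  invisible(x)
}

#' @export
summary.haplotype_network <- function(object, ...) {
  list(n_observed = sum(object$nodes$kind == "observed"),
       n_median = sum(object$nodes$kind == "median"),
       n_edges = nrow(object$edges),
       total_length = sum(object$edges$weight),
       epsilon = object$epsilon)
}

#' Plot a haplotype network
#'
#' Observed nodes are drawn as filled circles scaled by haplotype frequency
#' (pie-diameter convention); inferred median nodes are small hollow
#' squares. Edge labels give substitution counts.
#'
#' @param x a `haplotype_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.haplotype_network <- function(x, ...) {
  g <- as_igraph(x)
  med <- igraph::V(g)$kind == "median"
  igraph::plot.igraph(
    g,
    vertex.shape = ifelse(med, "square", "circle"),
    vertex.size = ifelse(med, 4, 6 + 3 * sqrt(igraph::V(g)$frequency)),
    vertex.color = ifelse(med, "white", "steelblue"),
    vertex.label = ifelse(med, NA, igraph::V(g)$name),
    edge.label = igraph::E(g)$weight, ...)
  invisible(x)
}

as_igraph <- function(net) {
  v <- net$nodes
  v$seq <- unname(net$seqs[v$node_id])
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = v)
}

#' Write a haplotype network to disk
#'
#' @param net a `haplotype_network`.
#' @param path output path.
#' @param format `"graphml"`, `"gml"`, or `"tsv"` (edge list; a companion
#'   `<path>.nodes.tsv` carries the node attributes).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "gml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "haplotype_network"))
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nodes <- net$nodes
    nodes$seq <- unname(net$seqs[nodes$node_id])
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = format)
  }
  invisible(path)
}

#' Read a haplotype network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"gml"`.
#' @return a `haplotype_network`.
#' @export
read_network <- function(path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- igraph::read_graph(path, format = format)
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  id <- if ("name" %in% names(v)) v$name else as.character(seq_len(nrow(v)))
  seqs <- v$seq
  names(seqs) <- id
  structure(list(
    nodes = data.frame(node_id = id, kind = v$kind,
                       frequency = as.integer(v$frequency),
                       stringsAsFactors = FALSE),
    seqs = seqs,
    edges = data.frame(from = e$from, to = e$to,
                       weight = as.integer(e$weight),
                       stringsAsFactors = FALSE),
    epsilon = NA_integer_),
    class = "haplotype_network")
}
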