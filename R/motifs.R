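#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement (IUPAC ambiguity codes included, `N` maps
#' to `N`), then reversal. Gap characters are rejected: motif counting is
#' defined on dealigned sequences only.
#'
#' @param x character vector of residue strings (canonical alphabet).
#' @return character vector of reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  if (any(grepl("-", x, fixed = TRUE)))
    ns_stop("neustonet_gap", "gap character in sequence; dealign first")
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Count overlapping occurrences of a trinucleotide motif
#'
#' Counts every start position whose 3-residue window equals the motif, so
#' occurrences may overlap: `"TTTT"` contains two `"TTT"` motifs. Windows
#' containing `N` (or any non-ACGT code) never match.
#'
#' @param seq a residue string (dealigned).
#' @param motif a 3-residue word over `A`,`C`,`G`,`T`.
#' @return non-negative integer count.
#' @export
count_overlapping <- function(seq, motif) {
  if (nchar(motif) != 3L || grepl("[^ACGT]", motif))
    ns_stop("neustonet_value", "motif must be a 3-residue word over ACGT")
  n <- nchar(seq)
  if (n < 3L) return(0L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mm <- strsplit(motif, "", fixed = TRUE)[[1L]]
  sum(ch[1:(n - 2L)] == mm[1L] &
      ch[2:(n - 1L)] == mm[2L] &
      ch[3:n]        == mm[3L])
}

SALIENT_MOTIFS <- c("TTA", "TTT", "TTC", "TTG")

#' Both-strand counts of UVR-salient trinucleotides
#'
#' For each of the four salient motifs — the photolesion *promoters* `TTA`
#' and `TTT` and the photolesion *inhibitors* `TTC` and `TTG` — counts
#' overlapping occurrences on the plus strand and on the reverse complement,
#' and sums the two strands. `promoter_sum = TTA + TTT`,
#' `inhibitor_sum = TTC + TTG`.
#'
#' @param x a [sequence_set()] (dealigned) or a named character vector of
#'   residue strings.
#' @return a data.frame of class `motif_counts` with columns `id`, `TTA`,
#'   `TTT`, `TTC`, `TTG`, `promoter_sum`, `inhibitor_sum`,
#'   `effective_length`, and per-kilobase normalized sums
#'   (`promoter_per_kb`, `inhibitor_per_kb`) for sets of unequal length.
#' @export
count_salient <- function(x) {
  seqs <- if (inherits(x, "sequence_set")) x$seq else x
  if (is.null(names(seqs)))
    ns_stop("neustonet_invalid_id", "sequences must be named")
  if (any(grepl("-", seqs, fixed = TRUE)))
    ns_stop("neustonet_gap", "gap character present; dealign before counting")
  rc <- reverse_complement(seqs)
  counts <- vapply(seq_along(seqs), function(i) {
    vapply(SALIENT_MOTIFS, function(m)
      count_overlapping(seqs[[i]], m) + count_overlapping(rc[[i]], m),
      numeric(1))
  }, numeric(length(SALIENT_MOTIFS)))
  counts <- t(counts)
  len <- nchar(seqs)
  out <- data.frame(id = names(seqs), counts,
                    promoter_sum = counts[, "TTA"] + counts[, "TTT"],
                    inhibitor_sum = counts[, "TTC"] + counts[, "TTG"],
                    effective_length = len,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$promoter_per_kb <- ifelse(len > 0, 1000 * out$promoter_sum / len, 0)
  out$inhibitor_per_kb <- ifelse(len > 0, 1000 * out$inhibitor_sum / len, 0)
  class(out) <- c("motif_counts", "data.frame")
  out
}

#' Five-number summary of motif counts by habitat group
#'
#' Summarizes `promoter_sum` (TTA+TTT) and `inhibitor_sum` (TTC+TTG) per
#' habitat class with the five-number summary underlying a box-and-whisker
#' plot. Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param records a `motif_counts` data.frame from [count_salient()].
#' @param groups a `group_map`.
#' @return a data.frame of class `motif_group_summary` with columns
#'   `habitat`, `motif_class`, `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_by_group <- function(records, groups) {
  missing <- setdiff(records$id, groups$id)
  if (length(missing))
    ns_stop("neustonet_missing_group", "record id(s) absent from group map: %s",
            paste(missing, collapse = ", "))
  habitat <- groups$habitat[match(records$id, groups$id)]
  present <- unique(groups$habitat)
  empty <- setdiff(present, habitat)
  if (length(empty))
    ns_warn("neustonet_empty_group", "habitat group(s) with no records omitted: %s",
            paste(empty, collapse = ", "))
  rows <- list()
  for (h in intersect(c("neustonic", "planktonic"), unique(habitat))) {
    for (cls in c("promoter", "inhibitor")) {
      v <- records[habitat == h, paste0(cls, "_sum")]
      q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        habitat = h, motif_class = cls, n = length(v),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("motif_group_summary", "data.frame")
  out
}

#' Box-and-whisker plot of salient motif counts by habitat
#'
#' @param records a `motif_counts` data.frame.
#' @param groups a `group_map`.
#' @param ... passed to [graphics::boxplot()].
#' @export
motif_boxplot <- function(records, groups, ...) {
  habitat <- groups$habitat[match(records$id, groups$id)]
  long <- data.frame(
    count = c(records$promoter_sum, records$inhibitor_sum),
    group = factor(rep(c("TTA/TTT", "TTC/TTG"), each = nrow(records))),
    habitat = factor(rep(habitat, 2L), levels = c("neustonic", "planktonic")))
  graphics::boxplot(count ~ habitat + group, data = long,
                    col = c("lightpink", "lightblue"),
                    ylab = "both-strand motif count", ...)
  invisible(long)
}
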