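#' Read a FASTA file into a sequence set
#'
#' Parsing is delegated to [seqinr::read.fasta()]; this wrapper enforces the
#' package contracts: unique ids (the header token before the first
#' whitespace; the remainder is kept as a description for round-tripping),
#' the canonical alphabet (upper-case, `U` folded to `T`), and the
#' alignment flag.
#'
#' @param path path to a FASTA file (multi-line records allowed).
#' @param alignment `NA` (default) to auto-detect — the set is flagged as an
#'   alignment iff all sequences have equal length *and* at least one gap
#'   character is present — or `TRUE`/`FALSE` to assert.
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path, alignment = NA) {
  if (!file.exists(path))
    ns_stop("neustonet_io", "no such file: %s", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE, whole.header = TRUE),
    error = function(e) ns_stop("neustonet_empty_input",
                                "no FASTA records in %s", path))
  if (length(recs) == 0L)
    ns_stop("neustonet_empty_input", "no FASTA records in %s", path)
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    ns_stop("neustonet_duplicate_id", "duplicate FASTA id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  residues <- vapply(recs, as.character, character(1))
  names(residues) <- ids
  lens <- nchar(residues)
  if (is.na(alignment))
    alignment <- length(unique(lens)) == 1L && any(grepl("-", residues, fixed = TRUE))
  sequence_set(residues, desc, is_alignment = alignment)
}

#' Write a sequence set to FASTA
#'
#' @param x a [sequence_set()].
#' @param path output file path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "sequence_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(x$seq)) {
    hdr <- if (nzchar(x$desc[[id]])) paste(id, x$desc[[id]]) else id
    cat(">", hdr, "\n", sep = "", file = con)
    s <- x$seq[[id]]
    n <- nchar(s)
    if (n == 0L) { cat("\n", file = con); next }
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a clade/habitat group map
#'
#' The group map is a tab-separated table with header columns `id`, `clade`
#' and `habitat` assigning each sequence to a geographic clade and to one of
#' the two habitat classes contrasted in the UVR motif analysis.
#'
#' @param path path to the TSV file.
#' @param sequences optional [sequence_set()]; when given, every sequence id
#'   must be present in the map.
#' @return a `data.frame` of class `group_map` with columns `id`, `clade`,
#'   `habitat`.
#' @export
read_group_map <- function(path, sequences = NULL) {
  if (!file.exists(path))
    ns_stop("neustonet_io", "no such file: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  group_map(df, sequences = sequences)
}

#' @rdname read_group_map
#' @param df a data.frame with columns `id`, `clade`, `habitat`.
#' @export
group_map <- function(df, sequences = NULL) {
  need <- c("id", "clade", "habitat")
  if (!all(need %in% names(df)))
    ns_stop("neustonet_value", "group map needs columns: %s",
            paste(need, collapse = ", "))
  df <- df[need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$id))
    ns_stop("neustonet_duplicate_id", "duplicate id(s) in group map")
  bad <- setdiff(unique(df$habitat), c("neustonic", "planktonic"))
  if (length(bad))
    ns_stop("neustonet_value", "unknown habitat value(s): %s (must be neustonic|planktonic)",
            paste(bad, collapse = ", "))
  if (length(unique(df$clade)) == 0L || nrow(df) == 0L)
    ns_stop("neustonet_value", "group map is empty")
  if (!is.null(sequences)) {
    missing <- setdiff(seq_ids(sequences), df$id)
    if (length(missing))
      ns_stop("neustonet_missing_group", "sequence id(s) missing from group map: %s",
              paste(missing, collapse = ", "))
  }
  class(df) <- c("group_map", "data.frame")
  df
}

#' Write a group map to TSV
#' @param x a `group_map`.
#' @param path output path.
#' @export
write_group_map <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Remove alignment gaps from every sequence
#'
#' Strips every `-` character, mirroring the "dealign" preprocessing applied
#' before motif counting so that motif windows never span gap characters.
#' Ids and order are preserved and the alignment flag is cleared. Sequences
#' reduced to length zero are retained with a warning; they contribute zero
#' counts downstream.
#'
#' @param x a [sequence_set()].
#' @return a gap-free [sequence_set()] with `is_alignment = FALSE`.
#' @export
dealign <- function(x) {
  stopifnot(inherits(x, "sequence_set"))
  res <- gsub("-", "", x$seq, fixed = TRUE)
  if (any(nchar(res) == 0L))
    ns_warn("neustonet_empty_sequence",
            "sequence(s) empty after gap removal: %s",
            paste(names(res)[nchar(res) == 0L], collapse = ", "))
  sequence_set(res, x$desc, is_alignment = FALSE)
}

#' Restrict an alignment to unambiguous columns (complete deletion)
#'
#' Keeps only the columns in which every sequence carries a plain `A`, `C`,
#' `G` or `T`; any column containing a gap, `N` or other ambiguity code in
#' any analyzed sequence is dropped. This is the site-exclusion convention
#' used (per clade subset) before haplotype collapsing and the Hd/K/Kt
#' statistics.
#'
#' @param x a [sequence_set()] with `is_alignment = TRUE`.
#' @return a [sequence_set()] over the surviving columns (relative order
#'   preserved), still flagged as an alignment.
#' @export
complete_deletion <- function(x) {
  stopifnot(inherits(x, "sequence_set"))
  if (!x$is_alignment)
    ns_stop("neustonet_value", "complete_deletion requires an alignment")
  m <- seq_matrix(x)
  keep <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))) == nrow(m)
  if (!any(keep))
    ns_stop("neustonet_degenerate_alignment",
            "no columns survive complete deletion")
  res <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(res) <- rownames(m)
  sequence_set(res, x$desc, is_alignment = TRUE)
}

#' Write a tabular result to TSV or JSON
#'
#' Numeric fields keep full precision (at least 6 significant digits), so
#' diversity statistics printed to 5 decimals round-trip exactly.
#'
#' @param records a non-empty data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    ns_stop("neustonet_empty_input", "refusing to write an empty report")
  if (format == "tsv") {
    out <- records
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) format(v, digits = 15L, trim = TRUE,
                                                   scientific = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}
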