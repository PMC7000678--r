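#' Construct a sequence set
#'
#' A `sequence_set` is the package's currency for nucleotide data: a named
#' character vector of upper-case residue strings (ids as names), optional
#' descriptions, and a flag saying whether the set is a site-homologous
#' alignment. Residues are restricted to `A C G T N -` plus IUPAC ambiguity
#' codes; `U` is normalized to `T` and case is folded at construction so
#' every downstream operation can assume the canonical alphabet.
#'
#' @param residues named character vector of residue strings; names are the
#'   sequence ids and must be unique and non-empty.
#' @param desc optional character vector of FASTA descriptions (recycled to
#'   `""` when absent); kept only for round-tripping headers.
#' @param is_alignment logical flag; if `TRUE` all strings must be of equal
#'   length.
#' @return an object of class `sequence_set`.
#' @export
sequence_set <- function(residues, desc = NULL, is_alignment = FALSE) {
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids)))
    ns_stop("neustonet_invalid_id", "every sequence needs a non-empty id")
  if (anyDuplicated(ids))
    ns_stop("neustonet_duplicate_id", "duplicate sequence id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  residues <- normalize_residues(residues)
  if (is.null(desc)) desc <- rep("", length(residues))
  names(desc) <- ids
  if (isTRUE(is_alignment) && length(unique(nchar(residues))) > 1L)
    ns_stop("neustonet_ragged_alignment",
            "alignment flag set but sequence lengths differ")
  structure(list(seq = residues, desc = desc,
                 is_alignment = isTRUE(is_alignment)),
            class = "sequence_set")
}

# upper-case, U->T, and alphabet validation (A/C/G/T/N/-/IUPAC)
normalize_residues <- function(x) {
  out <- chartr("u", "T", toupper(x))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTNRYSWKMBDHV-]", out)
  if (any(bad)) {
    offending <- gsub("[ACGTNRYSWKMBDHV-]", "", out[bad][1L])
    ns_stop("neustonet_alphabet",
            "illegal residue character(s) '%s' in sequence '%s'",
            substr(offending, 1L, 5L), names(x)[bad][1L])
  }
  names(out) <- names(x)
  out
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d sequence(s)%s\n", length(x$seq),
              if (x$is_alignment)
                sprintf(", alignment of %d columns", nchar(x$seq[1L]))
              else ""))
  show <- utils::head(x$seq, 5L)
  for (id in names(show))
    cat(sprintf("  %s  [%d nt] %s%s\n", id, nchar(show[[id]]),
                substr(show[[id]], 1L, 40L),
                if (nchar(show[[id]]) > 40L) "..." else ""))
  if (length(x$seq) > 5L) cat(sprintf("  ... and %d more\n", length(x$seq) - 5L))
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$seq)

seq_ids <- function(x) names(x$seq)

# character matrix view (rows = sequences); requires an alignment
seq_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seq, "", fixed = TRUE))
  rownames(m) <- names(x$seq)
  m
}

# restrict a sequence_set to a subset of ids, preserving order of `ids`
seq_subset <- function(x, ids) {
  missing <- setdiff(ids, names(x$seq))
  if (length(missing))
    ns_stop("neustonet_unknown_id", "id(s) not in sequence set: %s",
            paste(missing, collapse = ", "))
  sequence_set(x$seq[ids], x$desc[ids], is_alignment = x$is_alignment)
}
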