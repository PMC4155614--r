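#' Alignment groups
#'
#' An `alignment_group` is one sample of a comparative diagram: a set of
#' aligned, equal-length sequences with a label and a display color. Residues
#' are stored uppercased; the gap symbol is `"-"`.
#'
#' @param sequences Character vector of aligned sequences (equal length >= 2
#'   columns), optionally named by record id.
#' @param label Sample label used in legends and table exports.
#' @param color Display color (`"#RRGGBB"` or `"#RRGGBBAA"`), or `NULL` to be
#'   assigned from the default palette when the diagram is built.
#' @return An object of class `alignment_group` with fields `label`, `color`,
#'   `sequences`, `n_sequences`, `n_columns`.
#' @export
alignment_group <- function(sequences, label, color = NULL) {
  ids <- names(sequences)
  sequences <- stats::setNames(toupper(as.character(sequences)), ids)
  if (length(sequences) == 0) {
    sdd_error("no sequences", "sdd_invalid_alignment")
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    ids <- names(sequences) %||% as.character(seq_along(sequences))
    bad <- ids[lens != lens[1]]
    sdd_error(sprintf("not aligned: sequence lengths differ (offending records: %s)",
                      paste(bad, collapse = ", ")), "sdd_invalid_alignment")
  }
  if (lens[1] < 2) {
    sdd_error("alignment must have at least 2 columns", "sdd_invalid_alignment")
  }
  structure(
    list(label = as.character(label), color = color, sequences = sequences,
         n_sequences = length(sequences), n_columns = unname(lens[1])),
    class = "alignment_group"
  )
}

#' @export
print.alignment_group <- function(x, ...) {
  cat(sprintf("<alignment_group '%s': %d sequences x %d columns>\n",
              x$label, x$n_sequences, x$n_columns))
  invisible(x)
}

# Character matrix view (n_sequences x n_columns), used by all counting code.
group_matrix <- function(group) {
  m <- matrix(unlist(strsplit(group$sequences, ""), use.names = FALSE),
              nrow = group$n_sequences, ncol = group$n_columns, byrow = TRUE)
  rownames(m) <- names(group$sequences)
  m
}

#' Read an aligned FASTA file into an alignment group
#'
#' Parses a multi-record FASTA file of pre-aligned sequences and validates it
#' against a residue scheme: all records equal length (>= 2 columns), every
#' character in the scheme alphabet, a declared ambiguity code, or the gap
#' symbol `"-"`. Lowercase residues are uppercased; record order is preserved.
#' Duplicate record ids raise a warning, not an error.
#'
#' @param path Path to an aligned FASTA file.
#' @param scheme The [alphabet_scheme()] the alignment must conform to.
#'   Default: [default_protein_scheme()].
#' @param label Sample label; defaults to the file name without extension.
#' @param color Optional display color.
#' @param dot_as_gap Map `"."` to `"-"` on input (default `FALSE`: a dot is an
#'   unknown residue).
#' @return An [alignment_group()].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "PA", ">b", "PA", ">c", "LP", ">d", "PA"), f)
#' g <- read_alignment_fasta(f)
#' g$n_sequences  # 4
#' @export
read_alignment_fasta <- function(path, scheme = default_protein_scheme(),
                                 label = NULL, color = NULL,
                                 dot_as_gap = FALSE) {
  if (!file.exists(path)) {
    sdd_error(sprintf("file not found: %s", path), "sdd_missing_file")
  }
  recs <- tryCatch(Biostrings::readBStringSet(path), error = function(e) {
    sdd_error(sprintf("cannot parse FASTA file %s: %s", path,
                      conditionMessage(e)), "sdd_invalid_alignment")
  })
  if (length(recs) == 0) {
    sdd_error(sprintf("no sequences in %s", path), "sdd_invalid_alignment")
  }
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    warning(sprintf("duplicate record id(s) in %s: %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            call. = FALSE)
  }
  seqs <- stats::setNames(toupper(as.character(recs)), ids)
  if (dot_as_gap) seqs <- gsub(".", "-", seqs, fixed = TRUE)

  group <- alignment_group(seqs, label = label %||%
                             tools::file_path_sans_ext(basename(path)),
                           color = color)
  validate_group_alphabet(group, scheme)
  group
}

# Every character must be a legal scheme character; report the first offender
# with record id, 1-based column and the character itself.
validate_group_alphabet <- function(group, scheme) {
  legal <- scheme_legal_chars(scheme)
  m <- group_matrix(group)
  bad <- !(m %in% legal)
  if (any(bad)) {
    idx <- which(bad)[1]
    row <- (idx - 1L) %% group$n_sequences + 1L
    col <- (idx - 1L) %/% group$n_sequences + 1L
    id <- names(group$sequences)[row] %||% as.character(row)
    sdd_error(sprintf("unknown residue '%s' in record '%s' at column %d",
                      m[idx], id, col), "sdd_invalid_alignment")
  }
  invisible(TRUE)
}

#' Write an alignment group to FASTA
#'
#' Round-trip companion of [read_alignment_fasta()]: writing a group and
#' re-reading it yields identical sequences in identical order.
#'
#' @param group An [alignment_group()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(group, path) {
  stopifnot(inherits(group, "alignment_group"))
  ids <- names(group$sequences) %||% paste0("seq", seq_len(group$n_sequences))
  writeLines(paste0(">", ids, "\n", group$sequences), path)
  invisible(path)
}

#' Validate a set of alignment groups for overlay
#'
#' Overlaying samples in one diagram requires a common x-axis, i.e. identical
#' column counts across groups. Labels must be distinct (they key the tables);
#' duplicate colors only warn.
#'
#' @param groups List of [alignment_group()] objects (length >= 1; a
#'   single-sample diagram is legal).
#' @return A validation report: list with `ok`, `n_groups`, `n_columns`,
#'   `labels`, `n_sequences` (named vector).
#' @export
validate_group_set <- function(groups) {
  if (!is.list(groups) || length(groups) == 0 ||
      !all(vapply(groups, inherits, logical(1), "alignment_group"))) {
    sdd_error("'groups' must be a non-empty list of alignment_group objects",
              "sdd_invalid_alignment")
  }
  ncols <- unname(vapply(groups, `[[`, integer(1), "n_columns"))
  if (length(unique(ncols)) != 1) {
    labs <- vapply(groups, `[[`, character(1), "label")
    sdd_error(sprintf("incompatible alignments: column counts differ (%s)",
                      paste(sprintf("%s=%d", labs, ncols), collapse = ", ")),
              "sdd_incompatible_alignments")
  }
  labels <- unname(vapply(groups, `[[`, character(1), "label"))
  if (anyDuplicated(labels)) {
    sdd_error(sprintf("duplicate group label(s): %s",
                      paste(unique(labels[duplicated(labels)]), collapse = ", ")),
              "sdd_invalid_alignment")
  }
  colors <- unlist(lapply(groups, `[[`, "color"))
  if (length(colors) > 1 && anyDuplicated(colors)) {
    warning("two groups share a display color; overlay will be ambiguous",
            call. = FALSE)
  }
  list(
    ok = TRUE,
    n_groups = length(groups),
    n_columns = ncols[1],
    labels = labels,
    n_sequences = stats::setNames(
      vapply(groups, `[[`, integer(1), "n_sequences"), labels)
  )
}
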