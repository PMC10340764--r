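# FASTA and tabular I/O.

#' Construct a protein record
#'
#' @param id Identifier (non-empty string).
#' @param sequence Amino-acid sequence over the 20 canonical one-letter codes;
#'   uppercased and validated.
#' @param description Optional free-text description.
#' @return A \code{protein_record} object (list with \code{id},
#'   \code{description}, \code{sequence}).
#' @examples
#' protein_record("p1", "PAL")
#' @export
protein_record <- function(id, sequence, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  structure(
    list(id = id, description = description,
         sequence = validate_sequence(sequence, paste0("sequence of '", id, "'"))),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased on read; any character outside the 20-letter
#' canonical alphabet (including B/J/O/U/X/Z) is an error naming its position.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    if (is.null(header) || !nzchar(trimws(header)))
      stop("malformed FASTA header for record ", i, " in ", path)
    parts <- strsplit(trimws(header), "[ \t]+")[[1]]
    desc <- if (length(parts) > 1L)
      sub("^[^ \t]+[ \t]+", "", trimws(header)) else ""
    protein_record(parts[1], as.character(set[[i]]), desc)
  })
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: \code{read_fasta(write_fasta(x, path))}
#' reproduces \code{x}.
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(length(records) >= 1L)
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Stable column order shared by the peptide-table writer and reader.
PEPTIDE_TABLE_COLUMNS <- c(
  "sequence", "length", "mono_mass", "avg_mass", "hydrophobic_fraction",
  "n_term_hydrophobic", "pro_n_terminal", "pro_penultimate", "pro_c_terminal",
  "bioactivity", "dppiv_probability"
)

#' Write a peptide table to CSV
#'
#' Writes one row per peptide with a stable column order (sequence, length,
#' masses, motif flags, then any ingested predictor scores). The file
#' round-trips losslessly through [read_peptide_table()].
#'
#' @param peptides A data.frame of peptide records, e.g. from
#'   [peptide_records()] or [screen_peptides()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  stopifnot(is.data.frame(peptides))
  cols <- intersect(PEPTIDE_TABLE_COLUMNS, names(peptides))
  cols <- c(cols, setdiff(names(peptides), cols))
  out <- peptides[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write peptide table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a peptide table written by [write_peptide_table()]
#'
#' @param path CSV path.
#' @return A data.frame with the same columns and types.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
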