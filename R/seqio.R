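# Sequence and table IO with strict validation.
#
# Sequences are carried as a `seq_set`: a data.frame with columns
# id, residues, read_class and trimmed_length. Residues are stored uppercase
# and restricted to IUPAC nucleotide codes. All inputs are assumed
# plus-strand; coordinates in reports are 1-based inclusive.

IUPAC_NT <- c("A", "C", "G", "T", "U", "M", "R", "W", "S", "Y", "K",
              "V", "H", "D", "B", "N")

PRIMER_CLASSES <- c("universal_1525R", "universal_1492R",
                    "spiro_selective", "bact_selective")

#' Construct a validated sequence set
#'
#' @param id character vector of unique record identifiers.
#' @param residues character vector of IUPAC nucleotide strings.
#' @param read_class `"full"` or `"partial"`, recycled.
#' @return a `seq_set` data.frame with columns `id`, `residues`,
#'   `read_class`, `trimmed_length`.
#' @export
seq_set <- function(id, residues, read_class = "full") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(residues))) {
    bad <- id[!nzchar(residues)]
    stop("empty sequence record: ", paste(bad, collapse = ", "))
  }
  ok <- !grepl(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"), residues)
  if (any(!ok)) {
    i <- which(!ok)[1]
    ch <- regmatches(residues[i],
                     regexpr(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"),
                             residues[i]))
    stop(sprintf("non-IUPAC character '%s' in record '%s' (record %d)",
                 ch, id[i], i))
  }
  read_class <- rep_len(match.arg(read_class, c("full", "partial")), length(id))
  out <- data.frame(id = id, residues = residues, read_class = read_class,
                    trimmed_length = trimmed_len(residues),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

# number of unambiguous (ACGT) residues after terminal-N trimming
trimmed_len <- function(residues) {
  trimmed <- sub("^N+", "", sub("N+$", "", residues))
  nchar(gsub("[^ACGT]", "", trimmed))
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d sequence(s), lengths %d-%d\n",
              nrow(x),
              if (nrow(x)) min(nchar(x$residues)) else 0L,
              if (nrow(x)) max(nchar(x$residues)) else 0L))
  invisible(x)
}

#' Read a FASTA file into a sequence set
#'
#' Order-preserving; duplicate ids, empty records and non-IUPAC characters
#' are rejected with the offending record named.
#'
#' @param path path to a FASTA file.
#' @param read_class read class to tag records with (`"full"` or `"partial"`).
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, read_class = "full") {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(ss))
  seq_set(ids, as.character(ss), read_class = read_class)
}

#' Write a sequence set as FASTA
#'
#' Records are written in order, sequence lines wrapped at 70 columns,
#' newline-terminated.
#'
#' @param seqs a [seq_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Trim terminal ambiguity runs
#'
#' Removes leading and trailing runs of `N`; internal residues are left
#' untouched. `trimmed_length` counts the unambiguous residues that remain
#' and is what the 350-base validation filter tests.
#'
#' @param seqs a [seq_set()].
#' @return the sequence set with terminal Ns removed and `trimmed_length`
#'   updated.
#' @export
trim_terminal_ambiguity <- function(seqs) {
  seqs$residues <- sub("^N+", "", sub("N+$", "", seqs$residues))
  seqs$trimmed_length <- trimmed_len(seqs$residues)
  seqs
}

#' Read a clone metadata table
#'
#' Expects tab-separated columns `clone_id`, `library_id`, `dog_id`,
#' `primer_class`; clone ids must be unique and primer classes must come
#' from the four-value vocabulary
#' (`r paste(PRIMER_CLASSES, collapse = ", ")`).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_clone_table <- function(path) {
  df <- read_tsv(path)
  need <- c("clone_id", "library_id", "primer_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clone table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$clone_id))
    stop("duplicate clone_id in clone table: ",
         paste(unique(df$clone_id[duplicated(df$clone_id)]), collapse = ", "))
  bad <- setdiff(unique(df$primer_class), PRIMER_CLASSES)
  if (length(bad)) stop("unknown primer_class value(s): ",
                        paste(bad, collapse = ", "))
  df
}
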