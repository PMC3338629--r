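# Greedy, incremental, dual-threshold phylotype (COT) assignment with a
# growing reference set.
#
# Each validated clone is first screened over its 5' partial window against
# every reference (pairwise deletion, fewest mismatches wins, ties to the
# lowest COT number). A clone within the mismatch budget joins that taxon.
# Otherwise its full-length sequence is compared to all references: identity
# strictly above the cutoff joins the best-matching taxon AND adds the clone
# as an additional reference of that taxon (taxa are single-linkage chains
# of references); anything else founds a new taxon with the next COT number.
# The scheme is order-dependent by construction; input order is
# authoritative and preserved in the output.

#' Create a reference set
#'
#' @param seqs optional [seq_set()] of full-length reference sequences.
#' @param cot optional integer vector of COT numbers, one per sequence;
#'   defaults to `1:nrow(seqs)`.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(seqs = NULL, cot = NULL) {
  rs <- structure(list(ref_id = character(), ref_seq = character(),
                       ref_cot = integer(), next_cot = 1L,
                       anchor_seq = NULL, proj = NULL),
                  class = "reference_set")
  if (!is.null(seqs) && nrow(seqs)) {
    cot <- if (is.null(cot)) seq_len(nrow(seqs)) else as.integer(cot)
    stopifnot(length(cot) == nrow(seqs))
    for (i in seq_len(nrow(seqs)))
      rs <- add_reference(rs, seqs$id[i], seqs$residues[i], cot[i])
    rs$next_cot <- max(cot) + 1L
  }
  rs
}

add_reference <- function(rs, id, seq, cot) {
  if (id %in% rs$ref_id) stop("duplicate reference id: ", id)
  if (is.null(rs$anchor_seq)) {
    rs$anchor_seq <- seq
    rs$proj <- matrix(encode_seq(seq), nrow = 1, dimnames = list(id, NULL))
  } else {
    row <- project_to_anchor(seq_set(id, seq), rs$anchor_seq)
    rs$proj <- rbind(rs$proj, row)
  }
  rs$ref_id <- c(rs$ref_id, id)
  rs$ref_seq <- c(rs$ref_seq, seq)
  rs$ref_cot <- c(rs$ref_cot, as.integer(cot))
  rs$next_cot <- max(rs$next_cot, as.integer(cot) + 1L)
  rs
}

n_taxa <- function(rs) length(unique(rs$ref_cot))

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d reference sequence(s) in %d taxa; next %s\n",
              length(x$ref_id), n_taxa(x), cot_label(x$next_cot)))
  invisible(x)
}

#' Partial-sequence screen against the reference set
#'
#' Compares the first `window` aligned bases of a clone's 5' region to every
#' reference under pairwise deletion; the best reference is the one with the
#' fewest mismatches, ties broken by lowest COT number. The clone matches
#' when mismatches are within `budget`.
#'
#' @param clone_seq clone residues (partial read), or single-row [seq_set()].
#' @param refs a `reference_set`.
#' @param budget mismatch budget (default 7).
#' @param window 5' window in bases (default 500).
#' @return list: `best_ref`, `cot`, `mismatches`, `compared`,
#'   `identity_percent`, `matched`, `unassignable`.
#' @export
screen_partial <- function(clone_seq, refs, budget = 7L, window = 500L) {
  clone_seq <- as_residues(clone_seq)
  if (length(refs$ref_id) == 0L) stop("reference set is empty")
  v <- project_to_anchor(seq_set("q", clone_seq), refs$anchor_seq)[1L, ]
  covered <- which(v > 0L)
  cols <- utils::head(covered, window)
  if (length(cols) == 0L)
    return(list(best_ref = NA_character_, cot = NA_integer_,
                mismatches = NA_integer_, compared = 0L,
                identity_percent = NA_real_, matched = FALSE,
                unassignable = TRUE))
  rc <- row_vs_matrix(v, refs$proj, cols)
  if (max(rc$compared) < ceiling(0.7 * window))
    return(list(best_ref = NA_character_, cot = NA_integer_,
                mismatches = NA_integer_, compared = max(rc$compared),
                identity_percent = NA_real_, matched = FALSE,
                unassignable = TRUE))
  ord <- order(rc$mismatches, refs$ref_cot, seq_along(refs$ref_id))
  b <- ord[1L]
  list(best_ref = refs$ref_id[b], cot = refs$ref_cot[b],
       mismatches = as.integer(rc$mismatches[b]),
       compared = as.integer(rc$compared[b]),
       identity_percent = 100 * (1 - rc$mismatches[b] / rc$compared[b]),
       matched = rc$mismatches[b] <= budget,
       unassignable = FALSE)
}

#' Full-length resolution of an escalated clone
#'
#' Full-length identity (pairwise deletion) against every reference:
#' strictly above `cutoff` joins the best taxon and appends the clone as an
#' additional reference of that taxon; otherwise a new taxon is created with
#' the next COT number and the clone as its founding reference.
#'
#' @param clone_id clone identifier (becomes the reference id on append).
#' @param full_seq full-length residues.
#' @param refs a `reference_set`.
#' @param cutoff identity cutoff in percent (default 98.5, strict).
#' @return list: `assignment` (one-row data.frame) and updated `refs`.
#' @export
resolve_full <- function(clone_id, full_seq, refs, cutoff = 98.5) {
  full_seq <- as_residues(full_seq)
  if (length(refs$ref_id) == 0L) {
    refs <- add_reference(refs, clone_id, full_seq, refs$next_cot)
    return(list(assignment = assignment_row(clone_id, refs$ref_cot[1L],
                                            clone_id, NA_real_, NA_real_,
                                            "new_taxon"),
                refs = refs))
  }
  v <- project_to_anchor(seq_set("q", full_seq), refs$anchor_seq)[1L, ]
  rc <- row_vs_matrix(v, refs$proj)
  ident <- 100 * (1 - rc$mismatches / rc$compared)
  ident[rc$compared == 0L] <- NA_real_
  ord <- order(-ident, refs$ref_cot, seq_along(refs$ref_id), na.last = TRUE)
  b <- ord[1L]
  best <- ident[b]
  if (!is.na(best) && best > cutoff) {
    cot <- refs$ref_cot[b]
    refs <- add_reference(refs, clone_id, full_seq, cot)
    list(assignment = assignment_row(clone_id, cot, refs$ref_id[b],
                                     NA_real_, best,
                                     "full_match_new_reference"),
         refs = refs)
  } else {
    cot <- refs$next_cot
    refs <- add_reference(refs, clone_id, full_seq, cot)
    list(assignment = assignment_row(clone_id, cot, clone_id,
                                     NA_real_, best, "new_taxon"),
         refs = refs)
  }
}

assignment_row <- function(clone_id, cot, best_ref, partial_identity,
                           full_identity, decision) {
  data.frame(clone_id = clone_id, cot = as.integer(cot),
             cot_label = cot_label(cot), best_ref = best_ref,
             partial_identity = partial_identity,
             full_identity = full_identity, decision = decision,
             stringsAsFactors = FALSE)
}

#' Assign all clones to COTs
#'
#' Processes clones in input order through the greedy dual-threshold scheme,
#' growing the reference set as novel taxa and additional within-taxon
#' references are encountered.
#'
#' @param partials [seq_set()] of validated partial (5') clone reads.
#' @param refs starting `reference_set` (default empty).
#' @param fulls optional [seq_set()] of full-length clone sequences, looked
#'   up by clone id when a clone escalates past the partial screen; a clone
#'   needing escalation without a full-length sequence is unassignable.
#' @param budget partial mismatch budget (default 7).
#' @param window partial 5' window (default 500).
#' @param cutoff full-length identity cutoff in percent (default 98.5).
#' @return object of class `cot_assignments`: list with `assignments`
#'   (data.frame in input order), `unassigned` (data.frame of clone_id +
#'   reason) and the final `refs`.
#' @export
assign_all <- function(partials, refs = reference_set(), fulls = NULL,
                       budget = 7L, window = 500L, cutoff = 98.5) {
  stopifnot(inherits(partials, "seq_set"))
  full_lookup <- if (!is.null(fulls))
    stats::setNames(fulls$residues, fulls$id) else character()
  rows <- vector("list", nrow(partials))
  un <- list()
  for (i in seq_len(nrow(partials))) {
    cid <- partials$id[i]
    pseq <- partials$residues[i]
    if (length(refs$ref_id)) {
      sp <- screen_partial(pseq, refs, budget = budget, window = window)
      if (sp$unassignable) {
        un[[length(un) + 1L]] <- data.frame(clone_id = cid,
                                            reason = "too_few_compared_sites",
                                            stringsAsFactors = FALSE)
        next
      }
      if (sp$matched) {
        rows[[i]] <- assignment_row(cid, sp$cot, sp$best_ref,
                                    sp$identity_percent, NA_real_,
                                    "partial_match")
        next
      }
    }
    fseq <- if (cid %in% names(full_lookup)) full_lookup[[cid]]
      else if (identical(partials$read_class[i], "full")) pseq
      else NULL
    if (is.null(fseq)) {
      un[[length(un) + 1L]] <- data.frame(clone_id = cid,
                                          reason = "no_full_length_sequence",
                                          stringsAsFactors = FALSE)
      next
    }
    rf <- resolve_full(cid, fseq, refs, cutoff = cutoff)
    refs <- rf$refs
    rows[[i]] <- rf$assignment
  }
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(assignments)) assignments <- assignment_row(character(), integer(),
                                                          character(), numeric(),
                                                          numeric(), character())
  unassigned <- if (length(un)) do.call(rbind, un) else
    data.frame(clone_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(assignments = assignments, unassigned = unassigned,
                 refs = refs),
            class = "cot_assignments")
}

#' @export
print.cot_assignments <- function(x, ...) {
  cat(sprintf("<cot_assignments> %d clone(s) assigned to %d taxa; %d unassignable\n",
              nrow(x$assignments), n_taxa(x$refs), nrow(x$unassigned)))
  invisible(x)
}

#' @export
summary.cot_assignments <- function(object, ...) {
  a <- object$assignments
  cat(sprintf("Clones assigned:   %d\n", nrow(a)))
  cat(sprintf("Taxa (COTs):       %d\n", n_taxa(object$refs)))
  cat(sprintf("Reference seqs:    %d\n", length(object$refs$ref_id)))
  cat(sprintf("Unassignable:      %d\n", nrow(object$unassigned)))
  print(table(a$decision))
  invisible(object)
}

#' Serialize a reference set
#'
#' Writes the reference sequences as FASTA and a taxon table
#' (`ref_id`, `cot`, `cot_label`) as TSV.
#'
#' @param refs a `reference_set`.
#' @param fasta_path,tsv_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_reference_set <- function(refs, fasta_path, tsv_path) {
  write_fasta(seq_set(refs$ref_id, refs$ref_seq), fasta_path)
  write_tsv(data.frame(ref_id = refs$ref_id, cot = refs$ref_cot,
                       cot_label = cot_label(refs$ref_cot),
                       stringsAsFactors = FALSE), tsv_path)
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}

#' Read a serialized reference set
#'
#' @param fasta_path,tsv_path paths written by [write_reference_set()].
#' @return a `reference_set`.
#' @export
read_reference_set <- function(fasta_path, tsv_path) {
  seqs <- read_fasta(fasta_path)
  tab <- read_tsv(tsv_path)
  cot <- tab$cot[match(seqs$id, tab$ref_id)]
  if (anyNA(cot)) stop("reference FASTA and taxon table disagree on ids")
  reference_set(seqs, cot)
}
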