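# Clone validation: trimmed-length filter and the end-divergence chimera
# test.
#
# The chimera rule: find, independently for the first and last `end_len`
# bases of a clone, the best-identity reference (excluding the clone's own
# reference if named), then flag the clone when the Jukes-Cantor distance
# between those two references exceeds `threshold` (strictly). A chimera
# whose parents are closer than the threshold is undetectable by this rule
# by design.

#' Length filter verdict
#'
#' A record is `too_short` when its trimmed length (unambiguous residues
#' after terminal-N trimming) is strictly below `min_len`.
#'
#' @param seqs a [seq_set()] (trimmed).
#' @param min_len minimum trimmed length in bases (default 350).
#' @return logical vector, `TRUE` where too short.
#' @export
length_filter <- function(seqs, min_len = 350L) {
  seqs$trimmed_length < min_len
}

#' Screen a clone library
#'
#' Applies the trimmed-length filter and the end-divergence chimera test to
#' every clone; verdicts are independent of clone order.
#'
#' @param clones a [seq_set()] of clone sequences.
#' @param refs a [seq_set()] of full-length reference sequences.
#' @param min_len minimum trimmed length (default 350).
#' @param end_len end window in bases (default 300); the chimera test is
#'   skipped (pass, with a note) for clones not longer than `2 * end_len`.
#' @param threshold JC distance between the two end matches above which a
#'   clone is called chimeric (default 0.05, strict).
#' @param floor_identity minimum percent identity for an end match to count
#'   (default 70); if either end finds no match above the floor the verdict
#'   is `unresolved` and the clone passes with a warning note.
#' @param self_ref optional named character vector mapping clone id to the
#'   id of its own reference, excluded from its end matches.
#' @return list with `verdicts` (a `screen_verdicts` data.frame: clone_id,
#'   passed, reasons, end5_best_ref, end3_best_ref, end_divergence, note)
#'   and `validated` (the passing subset of `clones`).
#' @export
screen_library <- function(clones, refs, min_len = 350L, end_len = 300L,
                           threshold = 0.05, floor_identity = 70,
                           self_ref = NULL) {
  stopifnot(inherits(clones, "seq_set"))
  if (nrow(refs) < 1L) stop("reference set is empty")
  clones <- trim_terminal_ambiguity(clones)
  short <- length_filter(clones, min_len)

  anchor_seq <- refs$residues[1L]
  ref_proj <- project_to_anchor(refs, anchor_seq)
  ref_dm <- if (nrow(refs) >= 2L) build_distance_matrix(refs) else NULL
  proj <- project_to_anchor(clones, anchor_seq)

  n <- nrow(clones)
  end5 <- end3 <- rep(NA_character_, n)
  div <- rep(NA_real_, n)
  chim <- rep(FALSE, n)
  note <- rep("", n)

  for (i in seq_len(n)) {
    len_i <- nchar(clones$residues[i])
    if (len_i <= 2L * end_len) {
      note[i] <- "end_test_skipped_short"
      next
    }
    covered <- which(proj[i, ] > 0L)
    if (length(covered) < 2L * end_len * 0.5) {
      note[i] <- "unresolved"
      next
    }
    excl <- if (!is.null(self_ref)) self_ref[[clones$id[i]]] else NULL
    keep <- if (is.null(excl)) seq_len(nrow(refs)) else which(refs$id != excl)
    b5 <- best_end_match(proj[i, ], ref_proj[keep, , drop = FALSE],
                         utils::head(covered, end_len), floor_identity)
    b3 <- best_end_match(proj[i, ], ref_proj[keep, , drop = FALSE],
                         utils::tail(covered, end_len), floor_identity)
    if (is.na(b5) || is.na(b3)) {
      note[i] <- "unresolved"
      next
    }
    end5[i] <- refs$id[keep][b5]
    end3[i] <- refs$id[keep][b3]
    div[i] <- if (end5[i] == end3[i]) 0 else ref_dm$d[end5[i], end3[i]]
    if (is.na(div[i])) {
      note[i] <- "unresolved"
      div[i] <- NA_real_
      next
    }
    chim[i] <- div[i] > threshold
  }

  reasons <- character(n)
  reasons[short] <- "too_short"
  reasons[chim] <- ifelse(nzchar(reasons[chim]),
                          paste0(reasons[chim], ",chimeric"), "chimeric")
  verdicts <- data.frame(clone_id = clones$id,
                         passed = !nzchar(reasons),
                         reasons = reasons,
                         end5_best_ref = end5,
                         end3_best_ref = end3,
                         end_divergence = div,
                         note = note,
                         stringsAsFactors = FALSE)
  class(verdicts) <- c("screen_verdicts", "data.frame")
  list(verdicts = verdicts, validated = clones[verdicts$passed, , drop = FALSE])
}

# index (into rows of ref_proj) of the best-identity reference over `cols`,
# or NA if none reaches the identity floor
best_end_match <- function(v, ref_proj, cols, floor_identity) {
  rc <- row_vs_matrix(v, ref_proj, cols)
  ident <- 100 * (1 - rc$mismatches / rc$compared)
  ident[rc$compared < length(cols) * 0.5] <- NA_real_
  if (all(is.na(ident)) || max(ident, na.rm = TRUE) < floor_identity)
    return(NA_integer_)
  which.max(ident)
}

#' @export
print.screen_verdicts <- function(x, ...) {
  cat(sprintf(
    "<screen_verdicts> %d clone(s): %d passed, %d too_short, %d chimeric\n",
    nrow(x), sum(x$passed), sum(grepl("too_short", x$reasons)),
    sum(grepl("chimeric", x$reasons))))
  invisible(x)
}

#' Chimera check for a single record
#'
#' Single-record convenience wrapper around [screen_library()]; see there
#' for the decision rule.
#'
#' @param rec a single-row [seq_set()].
#' @inheritParams screen_library
#' @return one-row `screen_verdicts` data.frame.
#' @export
chimera_check <- function(rec, refs, end_len = 300L, threshold = 0.05,
                          floor_identity = 70, self_ref = NULL) {
  screen_library(rec, refs, min_len = 0L, end_len = end_len,
                 threshold = threshold, floor_identity = floor_identity,
                 self_ref = self_ref)$verdicts
}
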