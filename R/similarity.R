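# Pairwise alignment, percent identity and Jukes-Cantor distances with
# pairwise deletion -- the numeric core every other stage calls.
#
# Alignment columns containing a gap or an ambiguity code in either sequence
# are excluded from every comparison ("comparisons with missing data are
# eliminated pairwise"); ambiguity codes are missing data, never partial
# matches. Percent identity is reported to one decimal, but every threshold
# comparison is made on the unrounded value with strict inequalities.

ALIGN_MATCH <- 1
ALIGN_MISMATCH <- -1
ALIGN_GAP_OPEN <- 4
ALIGN_GAP_EXTEND <- 1

.subst_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = ALIGN_MATCH, mismatch = ALIGN_MISMATCH, baseOnly = FALSE,
        type = "DNA")
    cache
  }
})

#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (match +1, mismatch -1, gap open -4, gap extend -1); deterministic.
#'
#' @param a,b nucleotide strings (or single-row [seq_set()]s).
#' @return list with aligned rows `a` and `b` (equal-length strings with
#'   `-` for gaps) and the alignment `score`.
#' @export
align_pair <- function(a, b) {
  a <- as_residues(a)
  b <- as_residues(b)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .subst_matrix(),
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

as_residues <- function(x) {
  if (inherits(x, "seq_set")) {
    stopifnot(nrow(x) == 1L)
    x$residues
  } else {
    toupper(as.character(x))
  }
}

#' Compare two aligned rows under pairwise deletion
#'
#' @param a_row,b_row equal-length aligned strings (gaps as `-`).
#' @return list of class `pairwise_comparison`: `compared_sites`,
#'   `mismatches`, `p_distance`, `identity_percent`.
#' @export
compare_aligned <- function(a_row, b_row) {
  av <- strsplit(toupper(a_row), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b_row), "", fixed = TRUE)[[1]]
  if (length(av) != length(bv))
    stop("aligned rows differ in length (", length(av), " vs ", length(bv), ")")
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  compared <- sum(ok)
  if (compared == 0L)
    stop("undefined comparison: no unambiguous site shared by both sequences")
  mism <- sum(av[ok] != bv[ok])
  structure(list(compared_sites = compared,
                 mismatches = mism,
                 p_distance = mism / compared,
                 identity_percent = 100 * (1 - mism / compared)),
            class = "pairwise_comparison")
}

#' Percent identity between two unaligned sequences
#'
#' Convenience wrapper: [align_pair()] then [compare_aligned()].
#'
#' @inheritParams align_pair
#' @return a `pairwise_comparison`.
#' @export
percent_identity <- function(a, b) {
  al <- align_pair(a, b)
  compare_aligned(al$a, al$b)
}

#' Jukes-Cantor distance
#'
#' Corrects an observed mismatch fraction for multiple substitutions at a
#' site: d = -(3/4) ln(1 - 4p/3). Undefined at saturation (p >= 0.75).
#'
#' @param p observed mismatch fraction(s), each in `[0, 0.75)`.
#' @param on_saturation `"error"` (default) or `"na"`: how to treat
#'   `p >= 0.75`.
#' @return numeric vector of distances.
#' @export
jukes_cantor <- function(p, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  if (any(p < 0, na.rm = TRUE)) stop("p must be non-negative")
  sat <- !is.na(p) & p >= 0.75
  if (any(sat) && on_saturation == "error")
    stop("Jukes-Cantor distance undefined at p >= 0.75 (saturation); p = ",
         paste(signif(p[sat], 4), collapse = ", "))
  d <- -0.75 * log(1 - 4 * p / 3)
  d[sat] <- NA_real_
  d
}

#' Mismatch budget for an identity cutoff
#'
#' Number of base differences allowed at an identity cutoff over a given
#' sequence length, rounded half away from zero: at the 98.5% phylotype
#' cutoff over 1530 bases this is 23 differences.
#'
#' @param length_bases sequence length in bases.
#' @param cutoff_percent identity cutoff in percent (default 98.5).
#' @return integer mismatch budget.
#' @export
#' @examples
#' mismatch_budget(1530)  # 23
mismatch_budget <- function(length_bases, cutoff_percent = 98.5) {
  as.integer(round_half_up((1 - cutoff_percent / 100) * length_bases))
}

# ---- integer encoding and bulk identity machinery -------------------------

# A=1 C=2 G=3 T=4; gaps, ambiguity codes and uncovered positions are 0 and
# are pairwise-deleted by construction.
encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  as.integer(v)
}

encode_rows <- function(rows) {
  m <- t(vapply(rows, encode_seq, integer(nchar(rows[[1]]))))
  rownames(m) <- names(rows)
  m
}

# Pairwise match/compared-site counts over the rows of one (or two) encoded
# matrices, via one-hot cross products.
pair_counts <- function(E1, E2 = NULL) {
  same <- is.null(E2)
  if (same) E2 <- E1
  C1 <- (E1 > 0) * 1
  C2 <- (E2 > 0) * 1
  compared <- tcrossprod(C1, C2)
  matches <- matrix(0, nrow(E1), nrow(E2))
  for (b in 1:4)
    matches <- matches + tcrossprod((E1 == b) * 1, (E2 == b) * 1)
  dimnames(compared) <- dimnames(matches) <-
    list(rownames(E1), rownames(E2))
  list(compared = compared, mismatches = compared - matches)
}

# Mismatch/compared counts of one encoded row against each row of an encoded
# matrix, restricted to columns `cols`.
row_vs_matrix <- function(v, M, cols = seq_along(v)) {
  vv <- v[cols]
  sub <- M[, cols, drop = FALSE]
  cov <- rep(vv > 0, each = nrow(sub))
  both <- sub > 0 & cov
  mism <- both & sub != rep(vv, each = nrow(sub))
  list(compared = rowSums(both), mismatches = rowSums(mism))
}

# ---- star alignment -------------------------------------------------------

#' Star alignment of a sequence set to an anchor
#'
#' Builds a multiple alignment by aligning every sequence to one designated
#' anchor with [align_pair()] and merging gaps: insertion slots relative to
#' the anchor are unioned across sequences (max length per slot). Adequate
#' for the <5%-divergent 16S sequences this pipeline handles; not a general
#' progressive aligner.
#'
#' @param seqs a [seq_set()] (>= 1 row).
#' @param anchor row index of the anchor sequence (default 1).
#' @return character matrix of aligned rows (rownames = ids).
#' @export
star_align <- function(seqs, anchor = 1L) {
  n <- nrow(seqs)
  stopifnot(n >= 1L, anchor >= 1L, anchor <= n)
  A <- seqs$residues[anchor]
  La <- nchar(A)
  per_anchor_char <- vector("list", n)  # char at each anchor position, "-" if deleted
  per_ins <- vector("list", n)          # named list: anchor pos (0..La) -> inserted chars
  for (i in seq_len(n)) {
    if (i == anchor) {
      per_anchor_char[[i]] <- strsplit(A, "", fixed = TRUE)[[1]]
      per_ins[[i]] <- list()
      next
    }
    al <- align_pair(A, seqs$residues[i])
    ar <- strsplit(al$a, "", fixed = TRUE)[[1]]
    br <- strsplit(al$b, "", fixed = TRUE)[[1]]
    at <- ar != "-"
    pos <- cumsum(at)                  # anchor position of each column (0 = before first)
    chars <- rep("-", La)
    chars[pos[at]] <- br[at]
    per_anchor_char[[i]] <- chars
    insidx <- which(!at)
    per_ins[[i]] <- if (length(insidx)) split(br[insidx], pos[insidx]) else list()
  }
  # merged insertion width after each anchor position 0..La
  ins_width <- integer(La + 1L)
  for (i in seq_len(n)) {
    for (nm in names(per_ins[[i]])) {
      p <- as.integer(nm) + 1L
      ins_width[p] <- max(ins_width[p], length(per_ins[[i]][[nm]]))
    }
  }
  width <- La + sum(ins_width)
  out <- matrix("-", n, width, dimnames = list(seqs$id, NULL))
  # column layout: [ins-slot after pos 0][pos 1][ins-slot after pos 1][pos 2]...
  pos_col <- integer(La)
  ins_col_start <- integer(La + 1L)
  cursor <- 0L
  for (p in 0:La) {
    ins_col_start[p + 1L] <- cursor + 1L
    cursor <- cursor + ins_width[p + 1L]
    if (p < La) {
      pos_col[p + 1L] <- cursor + 1L
      cursor <- cursor + 1L
    }
  }
  for (i in seq_len(n)) {
    out[i, pos_col] <- per_anchor_char[[i]]
    for (nm in names(per_ins[[i]])) {
      p <- as.integer(nm)
      chars <- per_ins[[i]][[nm]]
      cols <- ins_col_start[p + 1L] + seq_along(chars) - 1L
      out[i, cols] <- chars
    }
  }
  attr(out, "anchor_columns") <- pos_col
  out
}

#' JC distance matrix over a sequence set
#'
#' All pairs are compared under pairwise deletion on a common alignment
#' (a [star_align()] to the anchor unless `aligned_rows` is supplied), and
#' observed mismatch fractions are Jukes-Cantor corrected. Saturated or
#' empty comparisons are stored as `NA` and rejected later by tree building.
#'
#' @param seqs a [seq_set()] of at least 2 sequences (>= 3 for tree use).
#' @param anchor anchor row for the star alignment.
#' @param aligned_rows optional pre-aligned character matrix (rows = ids);
#'   when given, `seqs` may be `NULL`.
#' @return object of class `jc_dist`: list with `ids`, JC matrix `d`,
#'   `p` (mismatch fractions) and `compared` (per-cell compared sites).
#' @export
build_distance_matrix <- function(seqs, anchor = 1L, aligned_rows = NULL) {
  if (is.null(aligned_rows)) {
    stopifnot(nrow(seqs) >= 2L)
    aligned_rows <- star_align(seqs, anchor)
  }
  rows <- apply(aligned_rows, 1L, paste, collapse = "")
  E <- encode_rows(as.list(rows))
  pc <- pair_counts(E)
  p <- pc$mismatches / pc$compared
  p[pc$compared == 0] <- NA_real_
  diag(p) <- 0
  d <- jukes_cantor(p, on_saturation = "na")
  structure(list(ids = rownames(E), d = d, p = p, compared = pc$compared),
            class = "jc_dist")
}

#' @export
print.jc_dist <- function(x, ...) {
  cat(sprintf("<jc_dist> %d sequences; %d undefined cell(s)\n",
              length(x$ids), sum(is.na(x$d))))
  invisible(x)
}

#' @export
as.matrix.jc_dist <- function(x, ...) x$d

#' @export
as.dist.jc_dist <- function(m, ...) stats::as.dist(m$d)

#' Write a distance matrix as square TSV
#'
#' @param dm a `jc_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
  colnames(df) <- c("id", dm$ids)
  write_tsv(df, path)
}

# ---- fast projection onto an anchor ---------------------------------------

# Project sequences into ungapped anchor coordinates. Fast path: seeded
# ungapped offset search (clone reads are 5'-anchored, indel-free to within
# sequencing error); DP fallback via align_pair when ungapped identity over
# the overlap is below `min_identity`. Insertions relative to the anchor are
# dropped from the projection (they can never align to an anchor column).
project_to_anchor <- function(seqs, anchor_seq, max_offset = 64L,
                              min_identity = 0.7) {
  av <- encode_seq(anchor_seq)
  La <- length(av)
  n <- nrow(seqs)
  out <- matrix(0L, n, La, dimnames = list(seqs$id, NULL))
  for (i in seq_len(n)) {
    sv <- encode_seq(seqs$residues[i])
    Lc <- length(sv)
    placed <- FALSE
    if (Lc <= La) {
      offs <- 0:min(max_offset, La - Lc)
      m <- min(200L, Lc)
      best_off <- 0L
      best_ident <- -1
      head_v <- sv[seq_len(m)]
      for (off in offs) {
        aw <- av[off + seq_len(m)]
        both <- aw > 0L & head_v > 0L
        nb <- sum(both)
        ident <- if (nb) sum(aw[both] == head_v[both]) / nb else 0
        if (ident > best_ident) {
          best_ident <- ident
          best_off <- off
        }
        if (ident >= 0.95) break  # unambiguous seed hit
      }
      if (best_ident >= min_identity) {
        aw <- av[best_off + seq_len(Lc)]
        both <- aw > 0L & sv > 0L
        full_ident <- if (sum(both)) sum(aw[both] == sv[both]) / sum(both) else 0
        if (full_ident >= min_identity) {
          out[i, best_off + seq_len(Lc)] <- sv
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      al <- align_pair(anchor_seq, seqs$residues[i])
      ar <- strsplit(al$a, "", fixed = TRUE)[[1]]
      br <- strsplit(al$b, "", fixed = TRUE)[[1]]
      at <- ar != "-"
      pos <- cumsum(at)
      keep <- at & br != "-"
      out[i, pos[keep]] <- encode_seq(paste(br[keep], collapse = ""))
    }
  }
  out
}
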