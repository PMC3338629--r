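# Tabular results: phylum x primer-class counts, rank abundance,
# singleton statistics, coverage curves and the shared-taxa headline
# statistic. All printed percentages use round-half-away-from-zero at the
# printed precision; threshold logic stays unrounded.

#' Phylum-by-primer-class clone count table
#'
#' Counts clones per phylum and primer class, with per-phylum phylotype
#' counts, row totals and a Total row; rows ordered by total clones
#' descending.
#'
#' @param clone_table data.frame with `clone_id` and `primer_class`.
#' @param assignments `cot_assignments` or its `assignments` data.frame
#'   (`clone_id`, `cot`).
#' @param taxonomy `cot_taxonomy` (or data.frame with `cot`, `phylum`).
#' @return data.frame of class `phylum_primer_table`: `phylum`,
#'   `phylotypes`, one column per primer class, `total`.
#' @export
build_phylum_primer_table <- function(clone_table, assignments, taxonomy) {
  if (inherits(assignments, "cot_assignments"))
    assignments <- assignments$assignments
  df <- merge(clone_table[, c("clone_id", "primer_class")],
              assignments[, c("clone_id", "cot")], by = "clone_id")
  df$phylum <- taxonomy$phylum[match(df$cot, taxonomy$cot)]
  if (anyNA(df$phylum))
    stop("clone(s) assigned to a taxon with no phylum: ",
         paste(utils::head(unique(df$cot[is.na(df$phylum)])), collapse = ", "))
  phyla <- unique(taxonomy$phylum[taxonomy$cot %in% df$cot])
  out <- data.frame(phylum = phyla, stringsAsFactors = FALSE)
  out$phylotypes <- vapply(phyla, function(ph)
    length(unique(df$cot[df$phylum == ph])), integer(1))
  for (pc in PRIMER_CLASSES)
    out[[pc]] <- vapply(phyla, function(ph)
      sum(df$phylum == ph & df$primer_class == pc), integer(1))
  out$total <- rowSums(out[, PRIMER_CLASSES, drop = FALSE])
  out <- out[order(-out$total, out$phylum), ]
  total_row <- data.frame(phylum = "Total",
                          phylotypes = sum(out$phylotypes),
                          stringsAsFactors = FALSE)
  for (pc in PRIMER_CLASSES) total_row[[pc]] <- sum(out[[pc]])
  total_row$total <- sum(out$total)
  out <- rbind(out, total_row)
  rownames(out) <- NULL
  class(out) <- c("phylum_primer_table", "data.frame")
  out
}

#' Rank abundance of taxa
#'
#' Taxa sorted by clone count descending (ties broken by COT number), with
#' relative abundance percent, singleton count, and a major-taxon flag for
#' taxa with 30 or more clones.
#'
#' @param assignments `cot_assignments` or its `assignments` data.frame.
#' @return data.frame of class `rank_abundance`: `rank`, `cot`,
#'   `cot_label`, `clones`, `relative_percent`, `major`; attributes
#'   `total_clones`, `n_singletons`, `singleton_percent` (share of one
#'   clone, printed precision 3 d.p.).
#' @export
rank_abundance <- function(assignments) {
  if (inherits(assignments, "cot_assignments"))
    assignments <- assignments$assignments
  stopifnot(nrow(assignments) >= 1L)
  counts <- table(assignments$cot)
  cot <- as.integer(names(counts))
  clones <- as.integer(counts)
  ord <- order(-clones, cot)
  cot <- cot[ord]
  clones <- clones[ord]
  total <- sum(clones)
  out <- data.frame(rank = seq_along(cot), cot = cot,
                    cot_label = cot_label(cot), clones = clones,
                    relative_percent = 100 * clones / total,
                    major = clones >= 30L,
                    stringsAsFactors = FALSE)
  attr(out, "total_clones") <- total
  attr(out, "n_singletons") <- sum(clones == 1L)
  attr(out, "singleton_percent") <- round_half_up(100 / total, 3)
  class(out) <- c("rank_abundance", "data.frame")
  out
}

#' Coverage of clones by the top-k taxa
#'
#' Cumulative percent of clones accounted for by the k most abundant taxa;
#' non-decreasing in k and exactly 100% at k = number of taxa.
#'
#' @param ra a [rank_abundance()] table.
#' @param k number of top taxa (vectorized; each `k <=` number of taxa).
#' @return numeric vector of coverage percentages.
#' @export
coverage_curve <- function(ra, k) {
  stopifnot(all(k >= 0), all(k <= nrow(ra)))
  cum <- cumsum(ra$relative_percent)
  cum[nrow(ra)] <- 100  # exact by construction
  ifelse(k == 0, 0, cum[k])
}

#' Fraction of taxa shared with the other microbiome
#'
#' @param taxonomy a `cot_taxonomy` with `shared_with_human` filled in by
#'   [flag_shared()].
#' @return shared percentage, rounded half-away-from-zero to 1 d.p.
#' @export
shared_fraction <- function(taxonomy) {
  if (anyNA(taxonomy$shared_with_human))
    stop("shared flags not computed; run flag_shared() first")
  round_half_up(100 * sum(taxonomy$shared_with_human) / nrow(taxonomy), 1)
}

#' Fraction of taxa called as named species
#'
#' @param taxonomy a `cot_taxonomy`.
#' @return named percentage, rounded to 1 d.p.
#' @export
named_fraction <- function(taxonomy) {
  round_half_up(100 * sum(taxonomy$name_status == "named") /
                  nrow(taxonomy), 1)
}
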