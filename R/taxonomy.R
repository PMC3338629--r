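# Provisional six-rank taxonomy: named-species calls against type strains,
# genus placement with novel-genus placeholders, and cross-microbiome
# shared-taxon flags.
#
# A taxon is called a named species when a type strain matches one of its
# references at >98.5% identity (strict). A taxon at >=90% identity to a
# named genus is placed in that genus as "<Genus> sp."; below 90% it gets a
# novel-genus placeholder "[G-k]" under the deepest higher rank supported by
# its best named match (identity floors: family 85, order 80, class 78,
# phylum 75; below all floors the placeholder hangs off the domain). The
# floors are a deterministic proxy for the manual tree inspection such
# curation is normally done by.

RANKS <- c("phylum", "class", "order", "family", "genus", "species")
RANK_FLOORS <- c(family = 85, order = 80, class = 78, phylum = 75)

#' Construct a named reference set (type strains with lineages)
#'
#' @param seqs a [seq_set()] of type-strain 16S sequences.
#' @param lineage data.frame with columns `id`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`, one row per sequence id.
#' @return object of class `named_refs`.
#' @export
named_refs <- function(seqs, lineage) {
  need <- c("id", RANKS)
  miss <- setdiff(need, names(lineage))
  if (length(miss)) stop("lineage missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!setequal(seqs$id, lineage$id))
    stop("lineage ids do not match sequence ids")
  lineage <- lineage[match(seqs$id, lineage$id), ]
  structure(list(seqs = seqs, lineage = lineage), class = "named_refs")
}

# identity matrix (percent) between two sequence sets, computed on the
# coordinate system of the first set's first sequence
cross_identity <- function(seqs_a, seqs_b, anchor_seq = NULL) {
  anchor_seq <- anchor_seq %||% seqs_a$residues[1L]
  Ea <- project_to_anchor(seqs_a, anchor_seq)
  Eb <- project_to_anchor(seqs_b, anchor_seq)
  pc <- pair_counts(Ea, Eb)
  ident <- 100 * (1 - pc$mismatches / pc$compared)
  ident[pc$compared == 0] <- NA_real_
  dimnames(ident) <- list(seqs_a$id, seqs_b$id)
  ident
}

#' Named-species call for each taxon
#'
#' @param refs a `reference_set`.
#' @param named a [named_refs()] set of type strains, or `NULL` (all taxa
#'   unnamed).
#' @param cutoff identity in percent above which (strictly) the binomial of
#'   the best type strain is adopted (default 98.5).
#' @return data.frame per taxon: `cot`, `named` flag, `best_named_ref`,
#'   `best_named_identity`, `genus`, `species` (NA when not named).
#' @export
call_named_species <- function(refs, named = NULL, cutoff = 98.5) {
  cots <- sort(unique(refs$ref_cot))
  out <- data.frame(cot = cots, named = FALSE,
                    best_named_ref = NA_character_,
                    best_named_identity = NA_real_,
                    genus = NA_character_, species = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.null(named) || nrow(named$seqs) == 0L) return(out)
  ident <- cross_identity(seq_set(refs$ref_id, refs$ref_seq), named$seqs,
                          anchor_seq = refs$anchor_seq)
  for (k in seq_along(cots)) {
    rows <- which(refs$ref_cot == cots[k])
    sub <- ident[rows, , drop = FALSE]
    if (all(is.na(sub))) next
    best <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    out$best_named_ref[k] <- colnames(sub)[best[2L]]
    out$best_named_identity[k] <- sub[best[1L], best[2L]]
    if (out$best_named_identity[k] > cutoff) {
      out$named[k] <- TRUE
      j <- match(out$best_named_ref[k], named$lineage$id)
      out$genus[k] <- named$lineage$genus[j]
      out$species[k] <- named$lineage$species[j]
    }
  }
  out
}

#' Genus placement and full lineage assignment
#'
#' Builds the complete provisional taxonomy for every taxon in a reference
#' set: named-species calls, genus placement or novel-genus placeholders,
#' and lineage inheritance from the best named match.
#'
#' @param refs a `reference_set`.
#' @param named a [named_refs()] set carrying six-rank lineages.
#' @param genus_cutoff identity in percent at or above which a taxon is
#'   placed in the best-matching named genus (default 90).
#' @param species_cutoff named-species cutoff (default 98.5, strict).
#' @param clone_counts optional named integer vector (names = COT numbers as
#'   character) of clone counts per taxon.
#' @return object of class `cot_taxonomy`: data.frame per taxon with `cot`,
#'   `cot_label`, the six ranks, `name_status`
#'   (named / unnamed_in_genus / novel_genus), `novel_genus_label`,
#'   `shared_with_human` (NA until [flag_shared()]), `clone_count`,
#'   `reference_ids`.
#' @export
assign_taxonomy <- function(refs, named, genus_cutoff = 90,
                            species_cutoff = 98.5, clone_counts = NULL) {
  if (length(refs$ref_id) == 0L) stop("reference set is empty")
  cots <- sort(unique(refs$ref_cot))
  nsc <- call_named_species(refs, named, cutoff = species_cutoff)
  ident <- if (!is.null(named) && nrow(named$seqs))
    cross_identity(seq_set(refs$ref_id, refs$ref_seq), named$seqs,
                   anchor_seq = refs$anchor_seq) else NULL
  out <- data.frame(cot = cots, cot_label = cot_label(cots),
                    phylum = NA_character_, class = NA_character_,
                    order = NA_character_, family = NA_character_,
                    genus = NA_character_, species = NA_character_,
                    name_status = NA_character_,
                    novel_genus_label = NA_character_,
                    shared_with_human = NA,
                    clone_count = 0L, reference_ids = NA_character_,
                    stringsAsFactors = FALSE)
  novel_counter <- new.env(parent = emptyenv())
  for (k in seq_along(cots)) {
    rows <- which(refs$ref_cot == cots[k])
    out$reference_ids[k] <- paste(refs$ref_id[rows], collapse = ",")
    if (!is.null(clone_counts)) {
      cc <- clone_counts[as.character(cots[k])]
      out$clone_count[k] <- if (is.na(cc)) 0L else as.integer(cc)
    }
    if (is.null(ident) || all(is.na(ident[rows, ]))) {
      out$name_status[k] <- "novel_genus"
      out$novel_genus_label[k] <- next_novel_label(novel_counter, "Bacteria")
      out[k, RANKS] <- c(rep("Bacteria_incertae_sedis", 4),
                         paste("Bacteria", out$novel_genus_label[k]), "sp.")
      next
    }
    sub <- ident[rows, , drop = FALSE]
    best <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    best_id <- colnames(sub)[best[2L]]
    best_ident <- sub[best[1L], best[2L]]
    lin <- named$lineage[match(best_id, named$lineage$id), ]
    if (nsc$named[k]) {
      out$name_status[k] <- "named"
      out[k, RANKS] <- lin[, RANKS]
      out$species[k] <- nsc$species[k]
      out$genus[k] <- nsc$genus[k]
    } else if (best_ident >= genus_cutoff) {
      out$name_status[k] <- "unnamed_in_genus"
      out[k, RANKS] <- lin[, RANKS]
      out$species[k] <- "sp."
    } else {
      # novel genus: anchor to the deepest rank whose floor the best
      # identity clears
      anchor_rank <- names(RANK_FLOORS)[which(best_ident >= RANK_FLOORS)[1L]]
      out$name_status[k] <- "novel_genus"
      if (is.na(anchor_rank) || length(anchor_rank) == 0L) {
        parent <- "Bacteria"
        out[k, c("phylum", "class", "order", "family")] <-
          "Bacteria_incertae_sedis"
      } else {
        parent <- lin[[anchor_rank]]
        keep <- RANKS[seq_len(match(anchor_rank, RANKS))]
        out[k, keep] <- lin[, keep]
        for (r in setdiff(RANKS[seq_len(5L)], keep)) out[k, r] <- NA_character_
      }
      lbl <- next_novel_label(novel_counter, parent)
      out$novel_genus_label[k] <- lbl
      out$genus[k] <- paste(parent, lbl)
      out$species[k] <- "sp."
      # placeholder propagated through unset intermediate ranks
      for (r in c("class", "order", "family"))
        if (is.na(out[k, r])) out[k, r] <- out$genus[k]
    }
  }
  class(out) <- c("cot_taxonomy", "data.frame")
  out
}

next_novel_label <- function(env, parent) {
  key <- gsub("\\s", "_", parent)
  k <- (get0(key, envir = env) %||% 0L) + 1L
  assign(key, k, envir = env)
  sprintf("[G-%d]", k)
}

#' Genus placement for one taxon
#'
#' Single-taxon view of the placement rule; see [assign_taxonomy()] for the
#' full table builder.
#'
#' @param taxon_seqs [seq_set()] of the taxon's reference sequence(s).
#' @param named a [named_refs()].
#' @param genus_cutoff identity floor for placement into a named genus
#'   (default 90; at or above places, strictly below goes novel).
#' @return list: `genus`, `species`, `name_status`, `best_identity`,
#'   `best_named_ref`.
#' @export
place_genus <- function(taxon_seqs, named, genus_cutoff = 90) {
  rs <- reference_set(taxon_seqs, rep(1L, nrow(taxon_seqs)))
  tab <- assign_taxonomy(rs, named, genus_cutoff = genus_cutoff)
  nsc <- call_named_species(rs, named)
  list(genus = tab$genus[1L], species = tab$species[1L],
       name_status = tab$name_status[1L],
       best_identity = nsc$best_named_identity[1L],
       best_named_ref = nsc$best_named_ref[1L])
}

#' Flag taxa shared with another microbiome's reference set
#'
#' A taxon is shared when any of its reference sequences matches any
#' sequence of the other set at identity strictly above `cutoff`.
#'
#' @param taxonomy a `cot_taxonomy` (or data.frame with `cot`).
#' @param refs the `reference_set` the taxonomy was built from.
#' @param other_seqs [seq_set()] of the other microbiome's reference
#'   sequences (e.g. a human oral reference set).
#' @param cutoff identity cutoff in percent (default 98.5, strict).
#' @return the taxonomy with `shared_with_human` filled in.
#' @export
flag_shared <- function(taxonomy, refs, other_seqs, cutoff = 98.5) {
  ident <- cross_identity(seq_set(refs$ref_id, refs$ref_seq), other_seqs,
                          anchor_seq = refs$anchor_seq)
  best_by_ref <- apply(ident, 1L, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  shared <- vapply(taxonomy$cot, function(ct) {
    b <- best_by_ref[refs$ref_cot == ct]
    any(!is.na(b) & b > cutoff)
  }, logical(1))
  taxonomy$shared_with_human <- shared
  taxonomy
}

#' Distinct-name counts per rank
#'
#' Counts distinct lineages at each rank, where a name at rank r is the full
#' lineage prefix down to r (so identically-named genera in different
#' families count separately, and novel placeholders are distinct within
#' their parent). Guaranteed monotone non-increasing from species to phylum.
#'
#' @param taxonomy a `cot_taxonomy` or any data.frame with the six rank
#'   columns.
#' @return named integer vector: phyla, classes, orders, families, genera,
#'   taxa.
#' @export
summarize_ranks <- function(taxonomy) {
  prefix <- ""
  counts <- integer(0)
  for (r in RANKS[1:5]) {
    prefix <- paste(prefix, taxonomy[[r]], sep = "|")
    counts <- c(counts, length(unique(prefix)))
  }
  c(phyla = counts[1], classes = counts[2], orders = counts[3],
    families = counts[4], genera = counts[5], taxa = nrow(taxonomy))
}

#' Write a taxonomy table as TSV
#'
#' @param taxonomy a `cot_taxonomy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_tsv(as.data.frame(taxonomy), path)
}
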