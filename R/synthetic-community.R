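# Ground-truthed synthetic 16S community generator.
#
# The generator emulates the statistical structure a clone-library phylotype
# analysis assumes: taxa separable at the 98.5% cutoff (inter-taxon
# divergence strictly above intra-taxon variation), geometric heavy-tailed
# rank abundance, primer-class-dependent phylum sampling, constructed
# chimeras (5' of one parent joined to 3' of another at a breakpoint in the
# middle third), per-base substitution error, and short failed reads
# truncated below the 350-base filter. Sequences evolve by i.i.d. per-site
# substitution from a random ancestor with no indels, so the true alignment
# is the identity mapping and every truth value is exact.

CANONICAL_PHYLA <- c("Firmicutes", "Proteobacteria", "Bacteroidetes",
                     "Spirochaetes", "Synergistetes", "Actinobacteria",
                     "Fusobacteria", "TM7", "Tenericutes", "GN02", "SR1",
                     "Chlorobi", "Chloroflexi", "WPS-2")

default_phylum_weights <- function() {
  w <- c(Firmicutes = 162, Proteobacteria = 52, Bacteroidetes = 43,
         Spirochaetes = 37, Synergistetes = 13, Actinobacteria = 12,
         Fusobacteria = 10, TM7 = 7, Tenericutes = 6, GN02 = 4, SR1 = 3,
         Chlorobi = 2, Chloroflexi = 1, `WPS-2` = 1)
  w / sum(w)
}

#' Per-phylum sampling weights of a primer class
#'
#' Encodes the qualitative primer selectivity of the four library chemistries:
#' the spirochete-selective pair amplifies only Spirochaetes and
#' Synergistetes; the Bacteroidetes-selective pair strongly favours
#' Bacteroidetes (with partial recovery of Chlorobi/TM7/SR1); the first
#' universal pair depletes Actinobacteria and misses Fusobacteria entirely;
#' the revised universal pair is unbiased.
#'
#' @param primer_class one of `universal_1525R`, `universal_1492R`,
#'   `spiro_selective`, `bact_selective`.
#' @param phyla phylum names to return weights for.
#' @return named numeric weight vector.
#' @export
primer_phylum_weights <- function(primer_class, phyla = CANONICAL_PHYLA) {
  primer_class <- match.arg(primer_class, PRIMER_CLASSES)
  w <- switch(primer_class,
    spiro_selective = ifelse(phyla %in% c("Spirochaetes", "Synergistetes"),
                             1.0, 0.0),
    bact_selective = ifelse(phyla == "Bacteroidetes", 1.0,
                            ifelse(phyla %in% c("Chlorobi", "TM7", "SR1"),
                                   0.3, 0.05)),
    universal_1525R = ifelse(phyla == "Actinobacteria", 0.01,
                             ifelse(phyla == "Fusobacteria", 0, 1.0)),
    universal_1492R = rep(1.0, length(phyla)))
  stats::setNames(w, phyla)
}

#' Specify a synthetic community
#'
#' @param n_taxa number of taxa.
#' @param phylum_weights named probability vector over phyla (must sum to 1
#'   within 1e-9); default reflects a subgingival-plaque-like phylotype
#'   composition.
#' @param rank_abundance_shape geometric decay parameter s in (0,1): taxon
#'   ranked i has abundance weight proportional to s^i (default 0.95).
#' @param inter_taxon_min_divergence minimum pairwise divergence between
#'   taxa (default 0.03); must exceed `intra_taxon_max_divergence`,
#'   otherwise taxa are not resolvable at the 98.5% cutoff and
#'   specification fails.
#' @param intra_taxon_max_divergence maximum divergence of a within-taxon
#'   sequence variant from its reference (default 0.012).
#' @param seq_length full sequence length in bases (default 1530).
#' @param partial_length 5' partial read length (default 500).
#' @param seed master integer seed; per-library streams are derived from it
#'   by stable hashing of the library id.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(n_taxa, phylum_weights = default_phylum_weights(),
                           rank_abundance_shape = 0.95,
                           inter_taxon_min_divergence = 0.03,
                           intra_taxon_max_divergence = 0.012,
                           seq_length = 1530L, partial_length = 500L,
                           seed = 1L) {
  stopifnot(n_taxa >= 1, seq_length > 0, partial_length > 0,
            rank_abundance_shape > 0)
  if (abs(sum(phylum_weights) - 1) > 1e-9)
    stop("phylum_weights must sum to 1 (got ", sum(phylum_weights), ")")
  if (!(inter_taxon_min_divergence > intra_taxon_max_divergence))
    stop("inter_taxon_min_divergence must exceed intra_taxon_max_divergence;",
         " taxa would not be resolvable at the 98.5% cutoff")
  structure(list(n_taxa = as.integer(n_taxa),
                 phylum_weights = phylum_weights,
                 rank_abundance_shape = rank_abundance_shape,
                 inter_taxon_min_divergence = inter_taxon_min_divergence,
                 intra_taxon_max_divergence = intra_taxon_max_divergence,
                 seq_length = as.integer(seq_length),
                 partial_length = as.integer(partial_length),
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Specify a clone library
#'
#' @param library_id identifier; also seeds the library's RNG stream.
#' @param primer_class one of the four primer classes.
#' @param n_clones clones picked (default 90).
#' @param chimera_rate per-clone chimera probability (default 0).
#' @param error_rate per-base substitution probability (default 0).
#' @param short_rate per-clone probability of truncation below 350 bases
#'   (default 0). `chimera_rate + short_rate` must not exceed 1.
#' @param n_chimera,n_short optional exact counts overriding the binomial
#'   draws, for constructed fixtures.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(library_id, primer_class, n_clones = 90L,
                         chimera_rate = 0, error_rate = 0, short_rate = 0,
                         n_chimera = NULL, n_short = NULL) {
  primer_class <- match.arg(primer_class, PRIMER_CLASSES)
  if (chimera_rate + short_rate > 1)
    stop("chimera_rate + short_rate must not exceed 1")
  structure(list(library_id = as.character(library_id),
                 primer_class = primer_class, n_clones = as.integer(n_clones),
                 chimera_rate = chimera_rate, error_rate = error_rate,
                 short_rate = short_rate,
                 n_chimera = if (is.null(n_chimera)) NULL else as.integer(n_chimera),
                 n_short = if (is.null(n_short)) NULL else as.integer(n_short)),
            class = "library_spec")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_at <- function(seq_chars, sites) {
  for (s in sites)
    seq_chars[s] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[s]), 1L)
  seq_chars
}

#' Generate the reference taxa of a synthetic community
#'
#' Draws a random ancestor and derives each taxon by substituting a random
#' site set sized to place every taxon pair at or beyond the inter-taxon
#' divergence floor; the all-pairs constraint is verified exactly and
#' violating taxa are re-drawn (bounded retries). Each taxon also gets one
#' within-taxon sequence variant within the intra-taxon divergence cap,
#' used as an additional sampling template. Deterministic given the seed.
#'
#' @param spec a [community_spec()].
#' @return object of class `synthetic_community`: list with `refs`
#'   ([seq_set()] of taxon reference sequences, ids `T###`), `taxa`
#'   (truth data.frame: taxon_id, phylum, abundance_weight, variant
#'   divergences), `variants` (list of per-taxon template character
#'   vectors), and the `spec`.
#' @export
generate_reference_taxa <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  L <- spec$seq_length
  n <- spec$n_taxa
  inter <- spec$inter_taxon_min_divergence
  min_diff <- ceiling(inter * L)
  n_mut <- ceiling(0.8 * inter * L)
  if (2 * n_mut >= 0.75 * L)
    stop("inter_taxon_min_divergence too large for seq_length: ",
         "taxa would saturate Jukes-Cantor distances")
  with_seed(spec$seed, {
    anc <- strsplit(random_seq(L), "", fixed = TRUE)[[1]]
    seqs <- vector("list", n)
    for (i in seq_len(n))
      seqs[[i]] <- mutate_at(anc, sample.int(L, n_mut))
    # verify pairwise divergence; re-draw offenders
    for (round in seq_len(50L)) {
      E <- t(vapply(seqs, function(s) match(s, c("A", "C", "G", "T")),
                    integer(L)))
      pc <- pair_counts(E)
      bad <- pc$mismatches < min_diff
      diag(bad) <- FALSE
      if (!any(bad)) break
      if (round == 50L)
        stop("could not satisfy inter_taxon_min_divergence = ", inter,
             " after bounded retries")
      for (i in unique(which(bad, arr.ind = TRUE)[, 1L]))
        seqs[[i]] <- mutate_at(anc, sample.int(L, n_mut))
    }
    phyla <- sample(names(spec$phylum_weights), n, replace = TRUE,
                    prob = spec$phylum_weights)
    w <- spec$rank_abundance_shape^seq_len(n)
    w <- w / sum(w)
    var_div <- integer(n)
    variants <- vector("list", n)
    for (i in seq_len(n)) {
      v <- floor(stats::runif(1, 0.25, 1) * spec$intra_taxon_max_divergence * L)
      var_div[i] <- v
      variants[[i]] <- c(paste(seqs[[i]], collapse = ""),
                         paste(mutate_at(seqs[[i]],
                                         if (v) sample.int(L, v) else integer()),
                               collapse = ""))
    }
    ids <- sprintf("T%03d", seq_len(n))
    structure(list(refs = seq_set(ids, vapply(variants, `[`, "", 1L)),
                   taxa = data.frame(taxon_id = ids, phylum = phyla,
                                     abundance_weight = w,
                                     variant_divergence = var_div,
                                     stringsAsFactors = FALSE),
                   variants = stats::setNames(variants, ids),
                   spec = spec),
              class = "synthetic_community")
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d taxa, %d phyla, seq length %d\n",
              nrow(x$taxa), length(unique(x$taxa$phylum)),
              x$spec$seq_length))
  invisible(x)
}

#' Sample a clone library from a synthetic community
#'
#' Draws clones from the community's taxa with abundance weights reweighted
#' by the primer class's per-phylum selectivity. Chimeras join the 5'
#' segment of one parent template to the 3' segment of another (distinct
#' taxon) at a uniform breakpoint within the middle third; short failures
#' are truncated below 350 bases; per-base substitution errors are applied
#' after chimera construction. Chimera/short/normal states are disjoint.
#'
#' @param lspec a [library_spec()].
#' @param community a `synthetic_community`.
#' @return list: `clones` ([seq_set()] of full insert sequences, ids
#'   `<library>_<serial>`), `partials` (5' reads of `partial_length`
#'   bases), `truth` (data.frame: clone_id, library_id, primer_class,
#'   true_taxon, is_chimera, parent_a, parent_b, breakpoint, is_short).
#' @export
sample_library <- function(lspec, community) {
  stopifnot(inherits(lspec, "library_spec"),
            inherits(community, "synthetic_community"))
  spec <- community$spec
  taxa <- community$taxa
  pw <- primer_phylum_weights(lspec$primer_class,
                              phyla = unique(taxa$phylum))
  w <- taxa$abundance_weight * pw[taxa$phylum]
  if (sum(w) <= 0)
    stop("primer class ", lspec$primer_class,
         " has zero total weight over the phyla present in this community")
  w <- w / sum(w)
  n <- lspec$n_clones
  L <- spec$seq_length
  with_seed(derive_seed(spec$seed, lspec$library_id), {
    n_chim <- lspec$n_chimera %||% stats::rbinom(1L, n, lspec$chimera_rate)
    n_short <- lspec$n_short %||% stats::rbinom(1L, n, lspec$short_rate)
    if (n_chim + n_short > n)
      stop("n_chimera + n_short exceed n_clones")
    status <- rep("normal", n)
    special <- sample.int(n, n_chim + n_short)
    status[special[seq_len(n_chim)]] <- "chimera"
    status[special[seq_len(n_short) + n_chim]] <- "short"

    taxon_idx <- sample.int(nrow(taxa), n, replace = TRUE, prob = w)
    ids <- sprintf("%s_%04d", lspec$library_id, seq_len(n))
    seqs <- character(n)
    parent_a <- parent_b <- rep(NA_character_, n)
    breakpoint <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      ti <- taxon_idx[i]
      template <- community$variants[[ti]][sample.int(2L, 1L)]
      if (status[i] == "chimera") {
        tj <- sample.int(nrow(taxa), 1L, prob = w)
        guard <- 0L
        while (tj == ti && guard < 100L) {
          tj <- sample.int(nrow(taxa), 1L, prob = w)
          guard <- guard + 1L
        }
        if (tj == ti) tj <- if (ti == 1L) 2L else 1L
        other <- community$variants[[tj]][sample.int(2L, 1L)]
        bp <- sample(seq.int(floor(L / 3) + 1L, floor(2 * L / 3)), 1L)
        seqs[i] <- paste0(substr(template, 1L, bp),
                          substr(other, bp + 1L, L))
        parent_a[i] <- taxa$taxon_id[ti]
        parent_b[i] <- taxa$taxon_id[tj]
        breakpoint[i] <- bp
      } else if (status[i] == "short") {
        seqs[i] <- substr(template, 1L, sample(100:349, 1L))
      } else {
        seqs[i] <- template
      }
      if (lspec$error_rate > 0) {
        len <- nchar(seqs[i])
        k <- stats::rbinom(1L, len, lspec$error_rate)
        if (k > 0) {
          ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          seqs[i] <- paste(mutate_at(ch, sample.int(len, k)), collapse = "")
        }
      }
    }
    truth <- data.frame(clone_id = ids, library_id = lspec$library_id,
                        primer_class = lspec$primer_class,
                        true_taxon = taxa$taxon_id[taxon_idx],
                        is_chimera = status == "chimera",
                        parent_a = parent_a, parent_b = parent_b,
                        breakpoint = breakpoint,
                        is_short = status == "short",
                        stringsAsFactors = FALSE)
    list(clones = seq_set(ids, seqs),
         partials = seq_set(ids, substr(seqs, 1L,
                                        pmin(nchar(seqs), spec$partial_length)),
                            read_class = "partial"),
         truth = truth)
  })
}

#' Simulate a full multi-library study
#'
#' @param spec a [community_spec()].
#' @param libraries list of [library_spec()]s.
#' @return list: `community`, pooled `clones` and `partials` [seq_set()]s,
#'   combined `truth` table, `clone_table` (clone_id, library_id,
#'   primer_class).
#' @export
simulate_community <- function(spec, libraries) {
  community <- generate_reference_taxa(spec)
  libs <- lapply(libraries, sample_library, community = community)
  clones <- do.call(rbind, lapply(libs, `[[`, "clones"))
  partials <- do.call(rbind, lapply(libs, `[[`, "partials"))
  truth <- do.call(rbind, lapply(libs, `[[`, "truth"))
  class(clones) <- c("seq_set", "data.frame")
  class(partials) <- c("seq_set", "data.frame")
  rownames(clones) <- rownames(partials) <- rownames(truth) <- NULL
  list(community = community, clones = clones, partials = partials,
       truth = truth,
       clone_table = truth[, c("clone_id", "library_id", "primer_class")])
}

#' Write a simulated study to disk
#'
#' Emits reference FASTA, clone and partial FASTAs, the clone truth TSV and
#' the taxon truth TSV.
#'
#' @param sim result of [simulate_community()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_community <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(refs = file.path(outdir, "reference.fasta"),
             clones = file.path(outdir, "clones.fasta"),
             partials = file.path(outdir, "partials.fasta"),
             truth = file.path(outdir, "clone_truth.tsv"),
             taxa = file.path(outdir, "taxon_truth.tsv"))
  write_fasta(sim$community$refs, paths["refs"])
  write_fasta(sim$clones, paths["clones"])
  write_fasta(sim$partials, paths["partials"])
  write_tsv(sim$truth, paths["truth"])
  write_tsv(sim$community$taxa, paths["taxa"])
  invisible(paths)
}
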