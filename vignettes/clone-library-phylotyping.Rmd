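---
title: "Clone-library phylotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-library phylotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotaxa)
```

## The problem

Culture-independent surveys of a microbial habitat — here, subgingival
plaque from the canine oral cavity — clone and Sanger-sequence 16S rRNA
genes, then reduce thousands of clone reads to a catalogue of species-level
phylotypes. Because most of the organisms are unnamed, the catalogue itself
becomes the reference taxonomy: each phylotype receives a sequential
Canine Oral Taxon (COT) number, a full-length reference sequence, and a
provisional six-rank lineage. `cotaxa` implements that workflow end to end:
clone validation, greedy phylotype assignment, Jukes–Cantor/neighbor-joining
phylogenetics, provisional taxonomy, and the standard summary tables, plus a
ground-truthed synthetic community generator used to validate every stage.

## Clone validation

Two rules decide whether a clone enters the analysis.

**Length.** A read must retain at least 350 unambiguous bases after
terminal-`N` trimming (strictly fewer fails). "Trimmed" here means terminal
ambiguity runs only: quality- and vector-trimming happen upstream of this
package and are not reproducible from sequence alone, so the trimmed length
is defined as the count of unambiguous residues after removing leading and
trailing `N` runs.

**Chimera test.** PCR chimeras splice two parent templates. The detector
finds, independently for the first and last `end_len` bases of a clone (300
by default), the best-identity reference sequence, excluding the clone's own
reference. If the Jukes–Cantor distance between those two best matches
exceeds 0.05 (strictly), the clone is called chimeric. Two design
parameters are not dictated by the decision rule itself and are exposed as
arguments: the end window (300 bases — long enough for a stable best match,
short enough to stay within one parent segment for mid-sequence
breakpoints) and a 70% identity floor below which an end match is deemed
unresolved and the clone passes with a warning rather than being discarded
on weak evidence. The rule has a designed blind spot: a chimera whose
parents are closer than the 5% threshold is undetectable, and the test
suite demonstrates this on a constructed example rather than hiding it.
Clones not longer than twice the end window skip the test (the windows
would overlap by more than half).

## Greedy dual-threshold phylotype assignment

Phylotypes are defined by **>98.5% full-length identity** (strict), i.e. a
mismatch budget of `round(0.015 × L)` bases — 23 for a 1530-base sequence.
Screening uses a coarser, cheaper rule on the 5′ partial read: a clone
within **7 mismatches** over its first 500 aligned bases of some reference
joins that reference's taxon. The two thresholds deliberately disagree
(7/500 = 1.4%, not 1.5%): the mismatch budget is the operative rule and the
percentage its gloss, so both are configurable but the defaults reproduce
the printed values.

Assignment is greedy and incremental, in input order:

1. Screen the partial read against every current reference under pairwise
   deletion; fewest mismatches wins, ties break to the lowest COT number.
2. Within budget → assign to that taxon.
3. Otherwise compare the clone's full-length sequence to all references.
   Identity strictly above 98.5% to some reference → join that taxon *and*
   append the clone as an additional reference of the taxon. This makes
   taxa single-linkage chains of references: two co-members may differ by
   more than the budget from each other provided each is within the cutoff
   of some reference, which is exactly why the partial screen alone is
   insufficient.
4. No reference above the cutoff → the clone founds a new taxon with the
   next COT number (zero-padded three-digit labels; numbering gaps are
   legal).

Order-dependence is inherent to any greedy scheme; the package treats input
order as authoritative and records it in the output so runs are
reproducible. A useful consequence checked by the tests: re-running the
assignment against the final reference set is idempotent (no new taxa, no
moved clones).

## Distances, alignment and trees

All identity and distance computations delete, pairwise, any alignment
column holding a gap or an ambiguity code in either sequence; ambiguity
codes are missing data, never fractional matches. Observed mismatch
fractions are corrected with Jukes–Cantor, d = −(3/4)·ln(1 − 4p/3),
undefined at p ≥ 0.75; undefined cells are carried as `NA` and rejected by
tree construction with the offending pair named.

The original study hand-aligned sequences against rRNA secondary structure.
That is not reproducible algorithmically, so the package uses deterministic
pairwise global alignment with affine gaps (match +1, mismatch −1, open −4,
extend −1) and, for multi-sequence work, a star alignment: every sequence
is aligned to a designated anchor and the gap patterns are merged. For the
<5%-divergent 16S sequences this pipeline handles, the star alignment is an
adequate stand-in for a curated alignment; it is not a general progressive
aligner and is documented as such. At scale (thousands of clones against
one anchor) the implementation first tries a seeded ungapped offset search
— 5′ clone reads are anchored at the gene start, and terminal truncation
preserves the prefix — and falls back to the full dynamic program whenever
ungapped identity over the overlap drops below 70%. The fallback path is
exercised in the tests with an indel-bearing read.

Trees are neighbor joining (Saitou–Nei, via `ape::nj`) on the JC matrix,
with negative branch-length estimates clamped to zero. Bootstrap support
resamples alignment columns with replacement (the conventional reading of
"bootstrap resampling" for sequence data), rebuilds distance matrix and
tree per replicate, and reports for each internal edge of the point
estimate the percentage of replicates containing that bipartition; a
majority-rule consensus of the replicates is emitted alongside, since
either object can be meant by a "consensus" NJ tree. Replicates whose
resampled matrix contains an undefined distance are dropped and counted;
more than 10% dropped is an error. Newick output shows supports strictly
greater than 50 and keeps the full table in a sidecar TSV.

## Provisional taxonomy

* **Named species:** a taxon whose reference matches a type strain at
  >98.5% (strict) adopts that binomial.
* **Genus placement:** best named-reference identity ≥90% places the taxon
  in that genus as "*Genus* sp."; strictly below 90% the taxon gets a
  novel-genus placeholder "[G-k]" (k counts per parent, in COT order)
  hanging off a higher rank.
* **Anchoring novel genera:** the study placed novel lineages by inspecting
  trees. As a deterministic proxy, the placeholder anchors at the deepest
  rank of the best-matching named lineage whose identity floor it clears —
  family 85%, order 80%, class 78%, phylum 75% — and below all floors it
  hangs off the domain. The floors are configurable constants, chosen to
  mirror the identity bands conventionally quoted for those ranks;
  intermediate ranks between the anchor and the genus inherit the
  placeholder label so rank counts stay consistent.
* **Shared taxa:** a taxon is flagged as shared with a second microbiome
  (e.g. a human oral reference set) when any of its references matches any
  sequence of the other set at >98.5% (strict).

Rank summaries count distinct lineage *prefixes* at each rank, which makes
the counts monotone non-increasing from species to phylum by construction
and keeps same-named genera in different families distinct.

## The synthetic community generator

Real inputs for this kind of study live in sequence archives; validation
here runs instead on a generator whose truth is exact by construction.

* **Sequence model:** i.i.d. per-site substitutions from one random
  ancestor, no indels (so the true alignment is the identity mapping);
  indels enter only as terminal truncation of short failed reads. Each
  taxon receives a random mutated site set sized at `0.8 × inter × L`
  sites, the all-pairs divergence floor is verified exactly, and violating
  taxa are redrawn (bounded retries). Each taxon also carries one
  within-taxon variant inside the intra-taxon cap.
* **Separability:** generation refuses specs whose inter-taxon floor does
  not exceed the intra-taxon cap — such communities are unresolvable at
  the 98.5% cutoff and parameter-recovery claims would be meaningless.
  Defaults: 3% between taxa, 1.2% within, matching the divergence bands
  the phylotype definition assumes.
* **Rank abundance:** geometric decay (weight ∝ s^rank, default s = 0.95),
  the simplest heavy-tailed model that reproduces a clone-library-like
  profile without overfitting a particular survey.
* **Primer bias:** each of the four library chemistries reweights phylum
  sampling. The spirochete-selective pair amplifies only Spirochaetes and
  Synergistetes (weight 0 elsewhere — selective columns in phylum tables
  are otherwise zero); the Bacteroidetes-selective pair favours
  Bacteroidetes (1.0) with partial recovery of Chlorobi/TM7/SR1 (0.3) and
  weak recovery elsewhere (0.05); the first universal pair depletes
  Actinobacteria (0.01) and misses Fusobacteria (0); the revised universal
  pair is flat. A primer class with zero total weight over the phyla
  actually present raises an error rather than silently sampling nothing.
* **Artifacts:** chimeras join the 5′ segment of one parent template to
  the 3′ segment of another (distinct taxon) at a uniform breakpoint in
  the middle third; short failures truncate below 350 bases; per-base
  substitution errors apply after chimera construction. Rates are binomial
  per library; constructed fixtures may instead force exact counts.
  Chimera prevalence is not a published quantity (excluded clones pool
  short and chimeric), so the chimera rate is a free parameter defaulting
  to zero.
* **Reproducibility:** one master seed; each library derives its own RNG
  stream by a stable hash of the library id, so adding a library never
  perturbs another's draws.

What the generator does **not** emulate: indel-rich evolution, chromatogram
noise and quality trimming, PCR cycle-level amplification bias, and
non-geometric abundance shapes. Tests passing on this generator therefore
validate the decision logic and its thresholds — not robustness to
alignment ambiguity in indel-rich regions, which real 16S data can present.

## Numerical conventions

* Threshold comparisons ("greater than 98.5%", ">5%", "<90%") are strict
  and always use unrounded values; printed percentages are rounded half
  away from zero at the printed precision (`round_half_up()`).
* Ties in best-match searches break to the lowest COT number, then input
  order; tree-building tie-breaks are those of `ape::nj`, which are
  deterministic, so all runs are bit-reproducible.
* Identity comparisons with zero shared unambiguous sites are errors, not
  silent zeros.

## Problem sizes

The test suite validates the full stack on communities of 15–30 taxa with
libraries of 50–300 clones, and one full-scale validation run of 6,025
clones (40 forced short, 27 forced chimeric, zero sequencing error, 6%
divergence floor so every chimera is detectable) which must validate
exactly 5,958 clones. The shared-taxon and named-fraction checks use a
353-taxon community with 58 constructed cross-set matches (16.4%) and 70
constructed type-strain matches (19.8%). Bootstrap tests use 100–150
replicates on six-taxon alignments; full-size runs (e.g. 1,000 replicates)
use the same code path.

## Worked example

```{r example, eval = FALSE}
cs <- community_spec(n_taxa = 20, seed = 42)
sim <- simulate_community(cs, list(
  library_spec("L01", "universal_1492R", n_clones = 120,
               chimera_rate = 0.05, short_rate = 0.05)))

scr <- screen_library(sim$clones, sim$community$refs)
asg <- assign_all(sim$partials[sim$partials$id %in% scr$validated$id, ],
                  fulls = sim$clones)
summary(asg)

aln <- star_align(seq_set(asg$refs$ref_id, asg$refs$ref_seq))
bs <- bootstrap_support(aln, n_reps = 200, seed = 1)
write_newick(bs, "refs.nwk", sidecar_path = "refs_support.tsv")
```

## Known limitations

* The star alignment presumes low divergence around one anchor; distant
  outgroups should be aligned by a dedicated MSA tool before import.
* Greedy assignment is order-dependent by design; a different clone order
  can found taxa from different representatives (the catalogue is stable,
  the representative choice is not).
* The chimera rule cannot see chimeras of parents closer than its
  threshold, and the novel-genus floors are a heuristic stand-in for
  manual tree curation.
* Reverse-complement rescue is out of scope: all inputs are assumed
  plus-strand, as clone libraries built with directional primers are.
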