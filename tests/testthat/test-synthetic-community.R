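test_that("community specs enforce their invariants", {
  expect_error(community_spec(5, phylum_weights = c(A = 0.6, B = 0.5)),
               "sum to 1")
  expect_error(community_spec(5, inter_taxon_min_divergence = 0.01,
                              intra_taxon_max_divergence = 0.012),
               "resolvable")
  expect_error(library_spec("L", "universal_1492R", chimera_rate = 0.6,
                            short_rate = 0.5), "exceed 1")
})

test_that("reference taxa satisfy the divergence floor and are reproducible", {
  cs <- community_spec(n_taxa = 2, seed = 5)
  com <- generate_reference_taxa(cs)
  diffs <- sum(strsplit(com$refs$residues[1], "")[[1]] !=
                 strsplit(com$refs$residues[2], "")[[1]])
  expect_gte(diffs, 46)  # 0.03 x 1530 rounded up

  # byte-identical FASTA on re-run with the same seed
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(generate_reference_taxa(cs)$refs, f1)
  write_fasta(generate_reference_taxa(cs)$refs, f2)
  expect_identical(readLines(f1), readLines(f2))

  # all-pairs separability holds for a larger community too
  cs2 <- community_spec(n_taxa = 25, seed = 6)
  com2 <- generate_reference_taxa(cs2)
  dm <- build_distance_matrix(com2$refs)
  expect_gte(min(dm$p[upper.tri(dm$p)]), 0.03)
})

test_that("libraries are deterministic per seed and tracked in the truth", {
  fx <- fixture_sim()
  ls1 <- library_spec("DET", "universal_1492R", n_clones = 80,
                      chimera_rate = 0.1)
  a <- sample_library(ls1, fx$community)
  b <- sample_library(ls1, fx$community)
  expect_identical(a$clones$residues, b$clones$residues)
  expect_identical(a$truth, b$truth)
  k <- sum(a$truth$is_chimera)
  expect_true(k >= 0 && k <= 80)  # realized binomial draw, fixed by seed
  expect_identical(sum(b$truth$is_chimera), k)

  # every clone id appears exactly once in the truth table
  expect_identical(sort(a$truth$clone_id), sort(a$clones$id))
  expect_false(anyDuplicated(a$truth$clone_id) > 0)
})

test_that("error-free non-chimeric clones are exact template copies", {
  fx <- fixture_sim()
  clean <- sample_library(library_spec("CLEAN", "universal_1492R",
                                       n_clones = 40), fx$community)
  for (i in seq_len(40)) {
    tid <- clean$truth$true_taxon[i]
    expect_true(clean$clones$residues[i] %in% fx$community$variants[[tid]])
  }
})

test_that("primer classes reweight phyla and error on zero total weight", {
  w <- primer_phylum_weights("spiro_selective")
  expect_equal(unname(w[c("Spirochaetes", "Synergistetes")]), c(1, 1))
  expect_true(all(w[setdiff(names(w), c("Spirochaetes", "Synergistetes"))] == 0))
  expect_equal(unname(primer_phylum_weights("universal_1525R")["Fusobacteria"]),
               0)

  # community with no spirochete-amplifiable phyla cannot be sampled
  cs <- community_spec(n_taxa = 4,
                       phylum_weights = c(Firmicutes = 0.5, Fusobacteria = 0.5),
                       seed = 9)
  com <- generate_reference_taxa(cs)
  expect_error(sample_library(library_spec("S", "spiro_selective"), com),
               "zero total weight")

  # spirochete-selective libraries contain only the selected phyla
  fx <- fixture_sim()
  present <- unique(fx$community$taxa$phylum)
  if (any(present %in% c("Spirochaetes", "Synergistetes"))) {
    lib <- sample_library(library_spec("SP", "spiro_selective", n_clones = 30),
                          fx$community)
    ph <- fx$community$taxa$phylum[match(lib$truth$true_taxon,
                                         fx$community$taxa$taxon_id)]
    expect_true(all(ph %in% c("Spirochaetes", "Synergistetes")))
  }
})

test_that("constructed chimeras have ends matching their recorded parents", {
  fx <- fixture_sim()
  truth <- fx$sim$truth
  refs <- fx$community$refs
  dm <- build_distance_matrix(refs)
  chim <- which(truth$is_chimera)
  expect_gt(length(chim), 0)
  for (i in chim) {
    pa <- truth$parent_a[i]
    pb <- truth$parent_b[i]
    expect_true(dm$d[pa, pb] > 0.05)
    seqr <- fx$sim$clones$residues[match(truth$clone_id[i], fx$sim$clones$id)]
    L <- nchar(seqr)
    expect_true(truth$breakpoint[i] > L / 3 & truth$breakpoint[i] <= 2 * L / 3)
    end5 <- substr(seqr, 1, 300)
    end3 <- substr(seqr, L - 299, L)
    id5 <- vapply(refs$residues, function(r)
      percent_identity(end5, substr(r, 1, 300))$identity_percent, numeric(1))
    id3 <- vapply(refs$residues, function(r)
      percent_identity(end3, substr(r, L - 299, L))$identity_percent,
      numeric(1))
    expect_equal(refs$id[which.max(id5)], pa)
    expect_equal(refs$id[which.max(id3)], pb)
  }
})

test_that("short clones are truncated below the filter and chimera/short are disjoint", {
  fx <- fixture_sim()
  truth <- fx$sim$truth
  lens <- nchar(fx$sim$clones$residues)
  expect_true(all(lens[truth$is_short] < 350))
  expect_true(all(lens[!truth$is_short] == fx$spec$seq_length))
  expect_false(any(truth$is_short & truth$is_chimera))
})

test_that("a simulated study writes a complete, consistent bundle", {
  fx <- fixture_sim()
  outdir <- withr::local_tempdir()
  paths <- write_community(fx$sim, outdir)
  expect_true(all(file.exists(paths)))
  truth <- read.delim(paths["truth"])
  expect_equal(nrow(truth), nrow(fx$sim$clones))
  partials <- read_fasta(paths["partials"], read_class = "partial")
  expect_true(all(nchar(partials$residues) <= fx$spec$partial_length))
})
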