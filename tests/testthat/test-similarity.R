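test_that("global alignment handles the toy gap case deterministically", {
  al <- align_pair("ACGTACGT", "ACGTACGT")
  expect_false(grepl("-", al$a) || grepl("-", al$b))
  expect_equal(compare_aligned(al$a, al$b)$identity_percent, 100)

  al <- align_pair("ACGTACGT", "ACGACGT")
  gaps <- sum(strsplit(al$b, "")[[1]] == "-")
  expect_equal(gaps, 1L)
  cmp <- compare_aligned(al$a, al$b)
  expect_equal(cmp$compared_sites, 7L)
  expect_equal(cmp$mismatches, 0L)

  # score symmetry
  expect_equal(align_pair("ACGTACGT", "ACGACGT")$score,
               align_pair("ACGACGT", "ACGTACGT")$score)
})

test_that("pairwise deletion excludes gap and ambiguity columns", {
  cmp <- compare_aligned("ACGTACGT", "ACGTACGA")
  expect_equal(cmp$compared_sites, 8L)
  expect_equal(cmp$mismatches, 1L)
  expect_equal(cmp$identity_percent, 100 * 7 / 8)

  cmp <- compare_aligned("ACG-ACGT", "ACGTACGT")
  expect_equal(cmp$compared_sites, 7L)
  expect_equal(cmp$identity_percent, 100)

  cmp <- compare_aligned("ACGN", "ACGT")
  expect_equal(cmp$compared_sites, 3L)
  expect_equal(cmp$mismatches, 0L)

  expect_error(compare_aligned("NNN", "ACG"), "undefined comparison")

  # invariant to appending a gap-only column
  a <- "ACGTACGT"; b <- "ACCTACGT"
  expect_equal(compare_aligned(paste0(a, "-"), paste0(b, "-"))$p_distance,
               compare_aligned(a, b)$p_distance)
})

test_that("Jukes-Cantor correction matches its closed form and domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), 0.1073256, tolerance = 1e-6)
  expect_error(jukes_cantor(0.75), "saturation")
  expect_error(jukes_cantor(-0.1), "non-negative")
  # monotone increasing, d >= p, d -> p as p -> 0
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  expect_equal(jukes_cantor(1e-8), 1e-8, tolerance = 1e-6)
})

test_that("mismatch budget reproduces the printed thresholds", {
  expect_identical(mismatch_budget(1530), 23L)
  expect_identical(mismatch_budget(1000), 15L)
})

test_that("distance matrix agrees with a site-by-site recount", {
  set.seed(42)
  anc <- rand_seq(200)
  seqs <- seq_set(paste0("s", 1:5),
                  c(anc, vapply(c(4, 9, 15, 30),
                                function(k) mutate_seq(anc, k), "")))
  dm <- build_distance_matrix(seqs)
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  aln <- star_align(seqs)
  rows <- apply(aln, 1, paste, collapse = "")
  for (i in 1:4) for (j in (i + 1):5) {
    nv <- naive_compare(rows[i], rows[j])
    expect_equal(dm$p[i, j], nv$mismatches / nv$compared)
    expect_equal(dm$compared[i, j], nv$compared)
  }
  # zero matrix for identical sequences
  same <- seq_set(c("x", "y", "z"), rep(anc, 3))
  expect_true(all(build_distance_matrix(same)$d == 0))
})

test_that("JC distances cross-check against an independent implementation", {
  set.seed(11)
  anc <- rand_seq(600)
  seqs <- seq_set(paste0("t", 1:4),
                  c(anc, vapply(c(12, 40, 90),
                                function(k) mutate_seq(anc, k), "")))
  dm <- build_distance_matrix(seqs)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs$residues), ""), identity))
  names(bin) <- seqs$id
  ref <- as.matrix(ape::dist.dna(ape::as.matrix.DNAbin(bin), model = "JC69",
                                 pairwise.deletion = TRUE))
  expect_equal(dm$d, ref[dm$ids, dm$ids], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("star alignment merges insertions without losing residues", {
  anchor <- "ACGTACGTACGTACGT"
  with_ins <- "ACGTACGTTTACGTACGT"   # TT inserted mid-sequence
  with_del <- "ACGTACACGT"
  seqs <- seq_set(c("anc", "ins", "del"), c(anchor, with_ins, with_del))
  aln <- star_align(seqs)
  expect_true(ncol(aln) >= nchar(with_ins))
  degapped <- apply(aln, 1, function(r) paste(r[r != "-"], collapse = ""))
  expect_equal(unname(degapped), seqs$residues)
})

test_that("anchor projection falls back to full alignment for indels", {
  anc <- rand_seq(400, seed = 5)
  # deletion of 30 bases forces the gapped path
  del <- paste0(substr(anc, 1, 150), substr(anc, 181, 400))
  proj <- cotaxa:::project_to_anchor(seq_set(c("d"), del), anc,
                                     min_identity = 0.9)
  covered <- which(proj[1, ] > 0)
  expect_equal(length(covered), 370L)
  anc_enc <- cotaxa:::encode_seq(anc)
  expect_true(all(proj[1, covered] == anc_enc[covered]))
})
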