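test_that("NJ recovers the 4-taxon additive tree exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  # recovered path lengths reproduce the additive matrix exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d)
  # topology is ((A,B),(C,D)): A and B are sisters
  pr <- ape::prop.part(tr)
  splits <- lapply(pr, function(p) sort(tr$tip.label[p]))
  expect_true(list(c("A", "B")) %in% splits ||
                list(c("C", "D")) %in% splits)
})

test_that("3 taxa resolve to the closed-form star and zeros give zeros", {
  d <- matrix(c(0, 2, 3,
                2, 0, 5,
                3, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- nj_tree(d)
  # closed form: x = (ab+ac-bc)/2 etc.
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("a", "b", "c")]), c(0, 2, 3))

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(z)$edge.length == 0))
})

test_that("NJ matches a brute-force least-squares oracle on additive trees", {
  for (seed in 1:4) {
    true <- withr::with_seed(seed, {
      tr <- ape::rtree(5, rooted = FALSE)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
      tr
    })
    d <- as.matrix(ape::cophenetic.phylo(true))
    est <- nj_tree(d)
    oracle <- brute_force_best_tree(d)
    # exactly one topology fits the additive matrix perfectly ...
    expect_lt(oracle$rss, 1e-12)
    expect_gt(oracle$second_rss, 1e-6)
    expect_equal(oracle$fitted, d, tolerance = 1e-8)
    # ... and NJ realizes that same matrix, hence that same topology
    expect_equal(as.matrix(ape::cophenetic.phylo(est))[rownames(d), colnames(d)],
                 d, tolerance = 1e-10)
  }
})

test_that("undefined distance cells are rejected with the pair named", {
  d <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_error(nj_tree(structure(list(d = d), class = "jc_dist")),
               "undefined distance.*'[xz]' and '[xz]'")
})

test_that("bootstrap supports are deterministic and 100% for a clean split", {
  aln <- make_two_clade_alignment()
  bs <- bootstrap_support(aln, n_reps = 150, seed = 5)
  expect_equal(split_support(bs, c("a1", "a2", "a3")), 100)
  bs2 <- bootstrap_support(aln, n_reps = 150, seed = 5)
  expect_identical(bs$supports, bs2$supports)
  expect_true(all(bs$supports$support >= 0 & bs$supports$support <= 100))
  # single replicate can only give 0 or 100
  bs1 <- bootstrap_support(aln, n_reps = 1, seed = 3)
  expect_true(all(bs1$supports$support %in% c(0, 100)))
  # consensus of the replicates contains the clean split too
  cons_splits <- lapply(ape::prop.part(bs$consensus),
                        function(p) sort(bs$consensus$tip.label[p]))
  flat <- vapply(cons_splits, paste, "", collapse = ",")
  expect_true("a1,a2,a3" %in% flat || "b1,b2,b3" %in% flat)
})

test_that("supports are invariant to leaf order of the input alignment", {
  aln <- make_two_clade_alignment()
  bs <- bootstrap_support(aln, n_reps = 100, seed = 7)
  perm <- c(4, 1, 6, 2, 5, 3)
  bsp <- bootstrap_support(aln[perm, , drop = FALSE], n_reps = 100, seed = 7)
  expect_equal(split_support(bsp, c("a1", "a2", "a3")),
               split_support(bs, c("a1", "a2", "a3")))
})

test_that("newick output hides supports at or below 50 and round-trips", {
  aln <- make_two_clade_alignment()
  bs <- bootstrap_support(aln, n_reps = 150, seed = 5)
  path <- withr::local_tempfile(fileext = ".nwk")
  sidecar <- withr::local_tempfile(fileext = ".tsv")
  write_newick(bs, path, sidecar_path = sidecar)
  txt <- readLines(path)
  expect_match(txt, "100")
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(bs$tree)), 0,
               ignore_attr = TRUE)
  expect_equal(nrow(read.delim(sidecar)), bs$tree$Nnode)

  # strictly-greater-than-50 display rule
  toy <- bs$tree
  toy$edge.length <- NULL  # labels only, so digit checks see just supports
  toy$node.label <- as.character(c(NA, 50, 51, 49)[seq_len(toy$Nnode)])
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(toy, p2)
  txt2 <- readLines(p2)
  expect_false(grepl("50", txt2))
  expect_match(txt2, "51")
})
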