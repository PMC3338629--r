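# Assignment/clone-table fixtures are built directly; the summary layer
# only needs ids, counts and lineages.
make_assignments <- function(cots) {
  data.frame(clone_id = sprintf("c%05d", seq_along(cots)),
             cot = cots, stringsAsFactors = FALSE)
}

test_that("phylum-by-primer table reproduces a known row and its totals", {
  # Spirochaetes clone counts per primer class as in a subgingival survey
  spiro_counts <- c(universal_1525R = 17, universal_1492R = 22,
                    spiro_selective = 366, bact_selective = 4)
  other_counts <- c(universal_1525R = 40, universal_1492R = 60,
                    spiro_selective = 0, bact_selective = 30)
  pc <- rep(c(names(spiro_counts), names(other_counts)),
            times = c(spiro_counts, other_counts))
  cots <- c(rep(1L, sum(spiro_counts)), rep(2L, sum(other_counts)))
  clone_table <- data.frame(clone_id = sprintf("c%05d", seq_along(pc)),
                            primer_class = pc, stringsAsFactors = FALSE)
  tax <- data.frame(cot = c(1L, 2L), phylum = c("Spirochaetes", "Firmicutes"),
                    stringsAsFactors = FALSE)
  tab <- build_phylum_primer_table(clone_table, make_assignments(cots), tax)

  spiro <- tab[tab$phylum == "Spirochaetes", ]
  expect_equal(unlist(spiro[, names(spiro_counts)]), spiro_counts,
               ignore_attr = TRUE)
  expect_equal(spiro$total, 409)
  # Total row equals column sums; cells equal an independent recount
  total <- tab[tab$phylum == "Total", ]
  for (p in names(spiro_counts)) {
    expect_equal(total[[p]], sum(tab[[p]][tab$phylum != "Total"]))
    for (ph in c("Spirochaetes", "Firmicutes"))
      expect_equal(tab[[p]][tab$phylum == ph],
                   sum(clone_table$primer_class == p &
                         tax$phylum[cots] == ph))
  }
  expect_equal(total$total, length(pc))
})

test_that("empty input yields an all-zero table", {
  tab <- build_phylum_primer_table(
    data.frame(clone_id = character(), primer_class = character()),
    make_assignments(integer()),
    data.frame(cot = integer(), phylum = character()))
  expect_equal(tab$total, 0)
  expect_equal(tab$phylum, "Total")
})

test_that("rank abundance sorts, flags majors and measures singletons", {
  # 5,958 clones: one singleton, the rest spread over a few taxa
  cots <- c(rep(1L, 3000), rep(2L, 2000), rep(3L, 928), rep(4L, 29), 5L)
  ra <- rank_abundance(make_assignments(cots))
  expect_equal(attr(ra, "total_clones"), 5958L)
  expect_equal(attr(ra, "singleton_percent"), 0.017)
  expect_equal(attr(ra, "n_singletons"), 1L)
  expect_equal(ra$cot, 1:5)  # already in descending order
  expect_equal(ra$major, c(TRUE, TRUE, TRUE, FALSE, FALSE))  # 29 < 30 boundary
  expect_equal(sum(ra$relative_percent), 100, tolerance = 1e-9)

  one <- rank_abundance(make_assignments(rep(9L, 50)))
  expect_equal(one$relative_percent, 100)
  expect_true(one$major)

  # ties broken by COT number
  tie <- rank_abundance(make_assignments(c(7L, 7L, 3L, 3L)))
  expect_equal(tie$cot, c(3L, 7L))
})

test_that("coverage curve is non-decreasing and exact at both ends", {
  ra <- rank_abundance(make_assignments(c(rep(1L, 60), rep(2L, 40))))
  expect_equal(coverage_curve(ra, 1), 60)
  expect_equal(coverage_curve(ra, 2), 100)

  cots <- rep(seq_len(30), times = round(1000 * 0.9^seq_len(30)) + 1)
  ra2 <- rank_abundance(make_assignments(cots))
  cov <- coverage_curve(ra2, seq_len(nrow(ra2)))
  expect_true(all(diff(cov) >= 0))
  expect_equal(cov[length(cov)], 100)

  # geometric community: empirical curve tracks the analytic partial sum
  s <- 0.8; n <- 12
  weights <- s^seq_len(n); weights <- weights / sum(weights)
  counts <- round(weights * 1e5)
  ra3 <- rank_abundance(make_assignments(rep(seq_len(n), times = counts)))
  analytic <- 100 * cumsum(weights)
  expect_equal(coverage_curve(ra3, seq_len(n)), analytic, tolerance = 1e-3)
})

test_that("shared fraction reports the rounded percentage", {
  tax <- data.frame(cot = seq_len(353),
                    shared_with_human = c(rep(TRUE, 58), rep(FALSE, 295)))
  expect_equal(shared_fraction(tax), 16.4)
  tax$shared_with_human <- FALSE
  expect_equal(shared_fraction(tax), 0)
  tax$shared_with_human[1] <- NA
  expect_error(shared_fraction(tax), "flag_shared")
})
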