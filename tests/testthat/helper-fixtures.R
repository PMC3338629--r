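# Fixtures are generated in code; nothing is stored on disk.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(len, seed = NULL) {
  gen <- function() paste(sample(BASES, len, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# substitute exactly k sites (never back to the same base)
mutate_seq <- function(s, k, seed = NULL) {
  gen <- function() {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in sample(length(ch), k))
      ch[i] <- sample(setdiff(BASES, ch[i]), 1)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# site-by-site recount of mismatches/compared sites, independent of the
# package's encoded-matrix machinery
naive_compare <- function(a_row, b_row) {
  av <- strsplit(a_row, "", fixed = TRUE)[[1]]
  bv <- strsplit(b_row, "", fixed = TRUE)[[1]]
  comp <- 0L
  mism <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% BASES && bv[i] %in% BASES) {
      comp <- comp + 1L
      if (av[i] != bv[i]) mism <- mism + 1L
    }
  }
  list(compared = comp, mismatches = mism)
}

# brute-force least-squares tree fit: enumerate all unrooted topologies,
# fit branch lengths by ordinary least squares on path distances, return
# the best topology
brute_force_best_tree <- function(d) {
  n <- nrow(d)
  tips <- rownames(d)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = tips)
  pairs <- t(utils::combn(n, 2))
  best <- NULL
  best_fitted <- NULL
  best_rss <- Inf
  second_rss <- Inf
  # pure-R path finding over the edge matrix, independent of ape internals
  path_edges <- function(edge, from, to) {
    n_nodes <- max(edge)
    parent <- rep(NA_integer_, n_nodes)
    via <- rep(NA_integer_, n_nodes)
    queue <- from
    seen <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == to) break
      inc <- which(edge[, 1] == v | edge[, 2] == v)
      for (e in inc) {
        w <- if (edge[e, 1] == v) edge[e, 2] else edge[e, 1]
        if (!(w %in% seen)) {
          parent[w] <- v; via[w] <- e
          seen <- c(seen, w); queue <- c(queue, w)
        }
      }
    }
    out <- integer(0)
    v <- to
    while (!is.na(via[v])) {
      out <- c(out, via[v])
      v <- parent[v]
    }
    out
  }
  for (k in seq_along(topos)) {
    tr <- topos[[k]]  # [[ restores tip labels from the multiPhylo wrapper
    node_of <- match(tips, tr$tip.label)
    # design matrix: which edges lie on the path between each tip pair
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (r in seq_len(nrow(pairs)))
      X[r, path_edges(tr$edge, node_of[pairs[r, 1]],
                      node_of[pairs[r, 2]])] <- 1
    y <- d[pairs]
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      second_rss <- best_rss
      best_rss <- rss
      best <- tr
      best$edge.length <- fit$coefficients
      best_fitted <- X %*% fit$coefficients
    } else if (rss < second_rss) {
      second_rss <- rss
    }
  }
  fitted_d <- matrix(0, n, n, dimnames = dimnames(d))
  fitted_d[pairs] <- best_fitted
  fitted_d <- fitted_d + t(fitted_d)
  list(tree = best, rss = best_rss, second_rss = second_rss,
       fitted = fitted_d)
}

# two 3-leaf clades separated by k substitutions over ncol sites
make_two_clade_alignment <- function(ncol = 400, k = 40) {
  base <- strsplit(rand_seq(ncol, seed = 101), "")[[1]]
  other <- strsplit(mutate_seq(paste(base, collapse = ""), k, seed = 102),
                    "")[[1]]
  matrix(c(rep(base, 3), rep(other, 3)), nrow = 6, byrow = TRUE,
         dimnames = list(c("a1", "a2", "a3", "b1", "b2", "b3"), NULL))
}

# a small well-separated community plus one library, shared by several tests
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cs <- community_spec(n_taxa = 15, inter_taxon_min_divergence = 0.06,
                           intra_taxon_max_divergence = 0.012, seed = 7)
      cache <<- list(
        spec = cs,
        community = generate_reference_taxa(cs),
        sim = simulate_community(cs, list(
          library_spec("LA", "universal_1492R", n_clones = 250,
                       n_chimera = 20, n_short = 10),
          library_spec("LB", "bact_selective", n_clones = 50))))
    }
    cache
  }
})
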