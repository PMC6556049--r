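test_that("search order honours the three-level tie-break", {
  chain <- make_chain(c("C", "N", "O"), c("1", "2"))
  cc <- compute_candidates(chain, chain)
  expect_equal(search_order(cc, chain), 1:3)  # all singletons: file order

  # one unique atom (a central N among four equivalent carbons) goes
  # first even though it is last in file order
  star <- molecular_graph(
    c(rep("C", 4), "N"),
    rbind(c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 1.5, 0), c(0, -1.5, 0),
          c(0, 0, 0)),
    {
      m <- matrix("", 5, 5)
      m[5, 1:4] <- m[1:4, 5] <- "1"
      m
    })
  ord <- search_order(compute_candidates(star, star), star)
  expect_equal(ord[1], 5)

  # benzene: first atom is file-order-first; every later atom is bonded
  # to the already-placed prefix (connectivity-guided traversal)
  b <- make_benzene()
  ord <- search_order(compute_candidates(b, b), b)
  expect_equal(ord[1], 1)
  for (k in 2:6) {
    placed <- ord[seq_len(k - 1)]
    expect_true(any(b$bonds[ord[k], placed] != ""))
  }
})

test_that("identical poses map by identity at zero cost", {
  for (nm in c("benzene", "chain", "para_ring", "c60")) {
    g <- fixture_registry()[[nm]]()
    fit <- find_optimal_mapping(g, g)
    expect_equal(fit$total_sq, 0, tolerance = 1e-12, info = nm)
    expect_equal(rmsd_of_mapping(g, g, fit$mapping), 0,
                 tolerance = 1e-9, info = nm)
  }
})

test_that("a 60-degree ring rotation of benzene is recognized as a symmetry", {
  b1 <- make_benzene()
  b2 <- transform_pose(b1, axis = c(0, 0, 1), angle = pi / 3)
  fit <- find_optimal_mapping(b1, b2)
  expect_lt(sqrt(fit$total_sq / 6), 1e-6)
  # the optimal mapping is a cyclic shift, not the identity
  expect_false(identical(fit$mapping, 1:6))
})

test_that("search cost equals the brute-force oracle cost on randomized fixtures", {
  mismatches <- 0L
  for (s in 1:60) {
    n <- with_test_seed(s, sample(4:12, 1))
    g <- make_random_tree(n, seed = s)
    p <- make_pose_pair(g, seed = s)
    fit <- find_optimal_mapping(p$query, p$template)
    oracle <- brute_force_oracle(p$query, p$template)
    if (abs(fit$total_sq - oracle$total_sq) > 1e-9) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("disabling DEE never changes the cost, only the node count", {
  for (s in c(2, 9, 23)) {
    g <- make_random_tree(10, seed = s)
    p <- make_pose_pair(g, seed = s)
    cand <- compute_candidates(p$query, p$template)
    with_dee <- find_optimal_mapping(p$query, p$template, cand, use_dee = TRUE)
    without <- find_optimal_mapping(p$query, p$template, cand, use_dee = FALSE)
    expect_equal(with_dee$total_sq, without$total_sq, tolerance = 1e-12)
    expect_lte(with_dee$nodes, without$nodes)
  }
  # symmetric case where pruning actually bites
  b <- make_benzene()
  b2 <- perturb(b, 0.2, seed = 5)
  with_dee <- find_optimal_mapping(b, b2, use_dee = TRUE)
  without <- find_optimal_mapping(b, b2, use_dee = FALSE)
  expect_equal(with_dee$total_sq, without$total_sq, tolerance = 1e-12)
  expect_lt(with_dee$nodes, without$nodes)
})

test_that("returned mappings always satisfy the mapping invariants", {
  for (s in 1:10) {
    g <- make_random_tree(9, seed = s + 100)
    p <- make_pose_pair(g, seed = s)
    fit <- find_optimal_mapping(p$query, p$template)
    m <- fit$mapping
    expect_setequal(m, seq_len(g$n_atoms))
    expect_identical(tolower(p$query$elements),
                     tolower(p$template$elements[m]))
    expect_identical(p$query$bonds, p$template$bonds[m, m])
  }
})

test_that("a C60 self-pair completes in seconds despite a 60^60 state space", {
  c60 <- make_c60()
  elapsed <- system.time(fit <- find_optimal_mapping(c60, c60))[["elapsed"]]
  expect_equal(fit$total_sq, 0, tolerance = 1e-9)
  expect_lt(elapsed, 30)
  # a rotated-and-perturbed pose pair also finishes
  pose2 <- perturb(transform_pose(c60, axis = c(1, 1, 0), angle = 0.7,
                                  translation = c(0.3, 0, -0.2)),
                   0.05, seed = 13)
  elapsed2 <- system.time(
    fit2 <- find_optimal_mapping(c60, pose2))[["elapsed"]]
  expect_lt(elapsed2, 60)
  expect_true(is.finite(fit2$total_sq))
})

test_that("non-isomorphic graphs with matching signatures raise a no-isomorphism error", {
  # a 6-cycle and two disjoint triangles: same composition, same bond
  # counts, and every atom has the identical depth-2 signature, yet no
  # bond-preserving bijection exists
  ring <- make_benzene()
  tri <- molecular_graph(
    rep("C", 6),
    rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.7, 1.2, 0),
          c(5, 0, 0), c(6.4, 0, 0), c(5.7, 1.2, 0)),
    {
      m <- matrix("", 6, 6)
      edge <- function(i, j) m[i, j] <<- m[j, i] <<- "ar"
      edge(1, 2); edge(2, 3); edge(1, 3)
      edge(4, 5); edge(5, 6); edge(4, 6)
      m
    })
  cand <- compute_candidates(ring, tri)
  expect_true(all(lengths(cand) == 6))  # signatures cannot tell them apart
  expect_error(find_optimal_mapping(ring, tri, cand),
               class = "symrmsd_no_isomorphism")
})

test_that("the oracle enumerates exactly the bond-preserving bijections", {
  b <- make_benzene()
  o <- brute_force_oracle(b, b)
  expect_equal(o$n_bijections, 12)  # dihedral symmetries of a 6-cycle
  expect_equal(o$total_sq, 0)

  chain <- make_chain(c("C", "N", "O"), c("1", "2"))
  expect_equal(brute_force_oracle(chain, chain)$n_bijections, 1)

  # oracle cost is never above the identity mapping's cost
  p <- make_pose_pair(make_benzene(), seed = 31, shuffle = FALSE)
  d2 <- sum((p$query$coords - p$template$coords)^2)
  expect_lte(brute_force_oracle(p$query, p$template)$total_sq, d2 + 1e-12)

  # refuses state spaces beyond its cap
  c60 <- make_c60()
  expect_error(brute_force_oracle(c60, c60), class = "symrmsd_oracle_cap")
})

test_that("relabelling recovers the inverse permutation at zero cost", {
  g <- make_random_tree(11, seed = 42)
  perm <- with_test_seed(43, sample(11))
  g2 <- relabel(g, perm)
  fit <- find_optimal_mapping(g, g2)
  expect_equal(fit$total_sq, 0, tolerance = 1e-12)
  expect_equal(fit$mapping, order(perm))
})
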