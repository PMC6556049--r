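test_that("RMSD of a mapping follows the closed form", {
  b <- make_benzene()
  expect_equal(rmsd_of_mapping(b, b, 1:6), 0)

  # one atom displaced by d, others coincident: d / sqrt(N)
  g <- make_chain(rep("C", 4), rep("1", 3))
  g2 <- g
  g2$coords[2, ] <- g2$coords[2, ] + c(0, 0.8, 0)
  expect_equal(rmsd_of_mapping(g, g2, 1:4), 0.8 / sqrt(4))

  # 2 atoms with pair distances 0 and 2: sqrt(2)
  two <- make_chain(c("C", "N"), "1")
  two2 <- two
  two2$coords[2, ] <- two2$coords[2, ] + c(0, 2, 0)
  expect_equal(rmsd_of_mapping(two, two2, 1:2), sqrt(2))

  expect_error(rmsd_of_mapping(b, b, c(1, 1, 2, 3, 4, 5)),
               class = "symrmsd_bad_mapping")
})

test_that("naive RMSD of a 60-degree benzene rotation equals the circumradius", {
  r <- 1.39
  b1 <- make_benzene(circumradius = r)
  b2 <- transform_pose(b1, axis = c(0, 0, 1), angle = pi / 3)
  # every atom moves by one chord = 2 r sin(30 deg) = r
  expect_equal(naive_rmsd(b1, b2), r, tolerance = 1e-9)
  expect_equal(naive_rmsd(b1, b1), 0)
  expect_error(naive_rmsd(b1, make_chain()),
               class = "symrmsd_not_same_molecule")
})

test_that("Hungarian baseline equals brute-force assignment over element-preserving bijections", {
  # independent oracle: minimum summed squared distance over all 6!
  # permutations of benzene's carbons (bonds ignored)
  b <- make_benzene()
  p <- make_pose_pair(b, seed = 8)
  d2 <- outer(rowSums(p$query$coords^2), rowSums(p$template$coords^2), "+") -
    2 * tcrossprod(p$query$coords, p$template$coords)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 6), ]
  costs <- apply(perms, 1, function(x) sum(d2[cbind(1:6, x)]))
  expect_equal(hungarian_rmsd(p$query, p$template),
               sqrt(min(costs) / 6), tolerance = 1e-9)

  # mixed-element case: assignment must stay within elements
  g <- make_random_tree(7, seed = 5)
  pp <- make_pose_pair(g, seed = 5)
  h <- hungarian_rmsd(pp$query, pp$template, details = TRUE)
  expect_identical(tolower(pp$query$elements),
                   tolower(pp$template$elements[h$mapping]))
  expect_error(hungarian_rmsd(make_chain(c("C", "N", "O"), c("1", "1")),
                              make_chain(c("C", "N", "S"), c("1", "1"))),
               class = "symrmsd_not_same_molecule")
})

test_that("Hungarian never exceeds the corrected RMSD; equality for well-separated asymmetric molecules", {
  for (nm in names(fixture_registry())) {
    if (nm == "c60") next
    g <- fixture_registry()[[nm]]()
    p <- make_pose_pair(g, seed = 77)
    h <- hungarian_rmsd(p$query, p$template)
    corr <- dock_rmsd(p$query, p$template)$rmsd
    expect_lte(h, corr + 1e-9, label = nm)
  }
  chain <- make_chain(c("C", "N", "O"), c("1", "2"))
  p <- make_pose_pair(chain, seed = 12, sigma = 0.05)
  expect_equal(hungarian_rmsd(p$query, p$template),
               dock_rmsd(p$query, p$template)$rmsd, tolerance = 1e-9)
})

test_that("the pseudo-mirror pose pair fools the Hungarian baseline", {
  pm <- make_pseudo_mirror()
  mirrored <- pm
  mirrored$coords[, 1] <- -mirrored$coords[, 1]
  h <- hungarian_rmsd(pm, mirrored)
  corr <- dock_rmsd(pm, mirrored)$rmsd
  expect_lt(h, corr - 0.5)  # strictly below: chemically impossible mapping
  # the molecule is chemically asymmetric: the corrected value must use
  # the unique bond-preserving (identity) mapping
  expect_equal(corr, naive_rmsd(pm, mirrored), tolerance = 1e-12)
})

test_that("all three RMSD variants are symmetric in query and template", {
  g <- make_random_tree(9, seed = 19)
  p <- make_pose_pair(g, seed = 19, shuffle = FALSE)
  expect_equal(naive_rmsd(p$query, p$template),
               naive_rmsd(p$template, p$query), tolerance = 1e-9)
  expect_equal(hungarian_rmsd(p$query, p$template),
               hungarian_rmsd(p$template, p$query), tolerance = 1e-9)
  expect_equal(dock_rmsd(p$query, p$template)$rmsd,
               dock_rmsd(p$template, p$query)$rmsd, tolerance = 1e-9)
})

test_that("a common rigid motion of both poses leaves all RMSDs unchanged", {
  g <- make_para_ring()
  p <- make_pose_pair(g, seed = 23, shuffle = FALSE)
  move <- function(x) transform_pose(x, axis = c(2, -1, 0.5), angle = 1.1,
                                     translation = c(3, -4, 2))
  for (f in list(naive_rmsd, hungarian_rmsd,
                 function(a, b) dock_rmsd(a, b)$rmsd)) {
    expect_equal(f(move(p$query), move(p$template)),
                 f(p$query, p$template), tolerance = 1e-6)
  }
})

test_that("scaling both poses by s scales every RMSD by s", {
  g <- make_random_tree(8, seed = 3)
  p <- make_pose_pair(g, seed = 3, shuffle = FALSE)
  s <- 2.5
  scale_g <- function(x) {
    x$coords <- x$coords * s
    x
  }
  for (f in list(naive_rmsd, hungarian_rmsd,
                 function(a, b) dock_rmsd(a, b)$rmsd)) {
    expect_equal(f(scale_g(p$query), scale_g(p$template)),
                 s * f(p$query, p$template), tolerance = 1e-9)
  }
})

test_that("dock_rmsd applies the bond-type-stripping fallback automatically", {
  b1 <- make_benzene()
  b2 <- transform_pose(make_kekule_benzene(), axis = c(0, 0, 1),
                       angle = pi / 3)
  r <- dock_rmsd(b1, b2)
  expect_true(r$bond_types_stripped)
  expect_lt(r$rmsd, 1e-6)
  expect_equal(as.character(r$total_mappings), "46656")

  # forced stripping on an otherwise comparable pair
  r2 <- dock_rmsd(b1, make_benzene(), strip_types = TRUE)
  expect_true(r2$bond_types_stripped)
  expect_equal(r2$rmsd, 0)
})

test_that("rmsd_result invariants hold: rmsd^2 * n equals the mapping's squared sum", {
  g <- make_random_tree(10, seed = 9)
  p <- make_pose_pair(g, seed = 9)
  r <- dock_rmsd(p$query, p$template)
  expect_gte(r$rmsd, 0)
  d2 <- sum((p$query$coords - p$template$coords[r$mapping, ])^2)
  expect_equal(r$rmsd^2 * r$n_atoms, d2, tolerance = 1e-9)
  expect_false(r$symmetric && as.character(r$total_mappings) == "1")
})
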