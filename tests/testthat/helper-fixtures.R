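# Shared test helpers: all fixtures are generated in code, none stored.

# Every element- and bond-preserving bijection between two tiny graphs,
# by plain recursive enumeration in file order. Independent of the
# package's candidate refinement and search; used as the equivalence
# oracle for candidate-set and automorphism properties.
enumerate_isomorphisms <- function(query, template) {
  n <- query$n_atoms
  stopifnot(n <= 12, template$n_atoms == n)
  qe <- tolower(query$elements)
  te <- tolower(template$elements)
  qb <- query$bonds
  tb <- template$bonds
  found <- list()
  m <- integer(n)
  used <- logical(n)
  recurse <- function(i) {
    if (i > n) {
      found[[length(found) + 1L]] <<- m
      return(invisible(NULL))
    }
    for (t in which(te == qe[i])) {
      if (used[t]) next
      prev <- seq_len(i - 1L)
      if (i > 1L && !identical(qb[i, prev], unname(tb[t, m[prev]]))) next
      m[i] <<- t; used[t] <<- TRUE
      recurse(i + 1L)
      used[t] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  found
}

# A pose pair for one molecule: the template is the query relabelled
# (optionally), rigidly moved, and perturbed with seeded noise.
make_pose_pair <- function(g, seed, sigma = 0.15, shuffle = TRUE) {
  t <- g
  if (shuffle) {
    perm <- with_test_seed(seed, sample(g$n_atoms))
    t <- relabel(t, perm)
  }
  t <- transform_pose(t, axis = c(1, 2, 3), angle = 0.4,
                      translation = c(0.5, -0.3, 0.2))
  t <- perturb(t, sigma, seed + 50000L)
  list(query = g, template = t)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Benzene with alternating Kekule single/double bonds instead of "ar".
make_kekule_benzene <- function(circumradius = 1.39) {
  b <- make_benzene(circumradius)
  for (i in 1:6) {
    j <- i %% 6 + 1
    type <- if (i %% 2 == 1) "1" else "2"
    b$bonds[i, j] <- b$bonds[j, i] <- type
  }
  b
}

# Identity (file-order) mapping is bond-preserving between two poses?
identity_feasible <- function(q, t) {
  identical(tolower(q$elements), tolower(t$elements)) &&
    identical(q$bonds, t$bonds)
}
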