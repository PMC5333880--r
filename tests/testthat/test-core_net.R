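test_that("incidence matrix matches arc definitions on hand-built nets", {
  A <- incidence_matrix(chain_net())
  expect_identical(A, matrix(c(-1L, 1L), 2, 1,
                             dimnames = list(c("p1", "p2"), "t1")))

  # oppositely directed weight-1 pair (read arc) cancels to a zero column
  loop <- petri_net("p1", "t1",
                    data.frame(source = c("p1", "t1"), target = c("t1", "p1")))
  expect_identical(unname(incidence_matrix(loop)), matrix(0L, 1, 1))
})

test_that("net validation rejects malformed inputs", {
  expect_error(petri_net("p1", "t1", data.frame(source = "p1", target = "tX")),
               "unknown node")
  expect_error(petri_net(c("p1", "p2"), "t1",
                         data.frame(source = "p1", target = "p2")),
               "bipartite")
  expect_error(petri_net("a", "a", NULL), "disjoint")
  expect_error(petri_net("p1", "t1",
                         data.frame(source = c("p1", "p1"),
                                    target = c("t1", "t1"))),
               "duplicate arc")
  expect_error(petri_net("p1", "t1",
                         data.frame(source = "p1", target = "t1", weight = 0)),
               "positive integers")
  expect_error(petri_net(character(), character(), NULL), "at least one")
})

test_that("firing any enabled transition changes the marking by its incidence column", {
  for (seed in 1:20) {
    net <- random_net(n = 5, m = 6, n_arcs = 14, wmax = 2, seed = seed)
    A <- incidence_matrix(net)
    m0 <- as_marking(net, NULL)
    for (t in enabled_transitions(net, m0)) {
      m1 <- fire_transition(net, m0, t)
      expect_identical(unname(m1 - m0), unname(A[, t]))
    }
  }
})

test_that("enabledness matches the direct per-arc definition on random nets", {
  for (seed in 1:10) {
    net <- random_net(n = 4, m = 5, n_arcs = 12, wmax = 3, seed = seed)
    got <- transition_ids(net) %in% enabled_transitions(net, NULL)
    expect_identical(got, unname(oracle_enabled(net, NULL)))
  }

  # a transition with no pre-places is enabled at every marking
  src <- petri_net("p1", "t1", data.frame(source = "t1", target = "p1"))
  expect_identical(enabled_transitions(src, c(p1 = 0)), "t1")
  # all-zero marking disables any transition with a pre-place
  expect_length(enabled_transitions(chain_net(0L)), 0)
})

test_that("firing is value-semantic and guards against disabled transitions", {
  net <- chain_net(1L)
  m0 <- as_marking(net, NULL)
  m1 <- fire_transition(net, m0, "t1")
  expect_identical(unname(m1), c(0L, 1L))
  expect_identical(unname(m0), c(1L, 0L))   # input untouched
  expect_error(fire_transition(net, m1, "t1"), "not enabled")
})

test_that("a full circuit of firings restores the initial marking", {
  net <- cycle_net(1L)
  m <- as_marking(net, NULL)
  m <- fire_transition(net, m, "t1")
  m <- fire_transition(net, m, "t2")
  expect_identical(m, as_marking(net, NULL))
})

test_that("state equation holds along random firing walks", {
  for (seed in 1:5) {
    net <- generate_covered_net(5, 7, n_circuits = 2, seed = seed)
    A <- incidence_matrix(net)
    set.seed(seed)
    m <- as_marking(net, NULL)
    count <- stats::setNames(integer(ncol(A)), colnames(A))
    for (step in 1:100) {
      en <- enabled_transitions(net, m)
      if (!length(en)) break
      t <- if (length(en) == 1) en else sample(en, 1)
      m <- fire_transition(net, m, t)
      count[t] <- count[t] + 1L
      expect_true(all(m >= 0))
    }
    expect_identical(unname(m), unname(as_marking(net, NULL) + as.integer(A %*% count)))
  }
})

test_that("structural report classifies the toy nets", {
  rep1 <- structural_report(chain_net())
  expect_true(rep1$ordinary && rep1$homogeneous && rep1$pure &&
              rep1$connected && rep1$structurally_conflict_free)
  expect_false(rep1$strongly_connected)

  expect_true(structural_report(cycle_net())$strongly_connected)

  # one place feeding two transitions: a structural conflict
  confl <- petri_net(c("p1", "p2"), c("t1", "t2"),
                     data.frame(source = c("p1", "p1", "t1", "t2"),
                                target = c("t1", "t2", "p2", "p2")))
  expect_false(structural_report(confl)$structurally_conflict_free)

  # read arc breaks purity; weight 2 breaks ordinariness but not homogeneity
  impure <- petri_net("p1", "t1",
                      data.frame(source = c("p1", "t1"), target = c("t1", "p1"),
                                 weight = c(2L, 2L)))
  r <- structural_report(impure)
  expect_false(r$pure); expect_false(r$ordinary); expect_true(r$homogeneous)

  # isolated vertex disconnects the net
  iso <- petri_net(c("p1", "p2"), "t1",
                   data.frame(source = "p1", target = "t1"))
  expect_false(structural_report(iso)$connected)
})

test_that("structural report is invariant under node relabeling", {
  net <- generate_covered_net(5, 7, n_circuits = 2, seed = 3)
  rep1 <- structural_report(net)
  perm <- net
  set.seed(1)
  perm$places <- perm$places[sample(nrow(perm$places)), ]
  perm$transitions <- perm$transitions[sample(nrow(perm$transitions)), ]
  perm$marking <- perm$marking[perm$places$id]
  rep2 <- structural_report(perm)
  expect_identical(unclass(rep1), unclass(rep2))
})

test_that("columns of A sum to zero when transitions conserve tokens", {
  # circuit-union nets: every transition has one input and one output arc
  net <- generate_covered_net(6, 9, n_circuits = 3, seed = 11)
  expect_true(all(colSums(incidence_matrix(net)) == 0))
})
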