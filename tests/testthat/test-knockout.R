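test_that("structural knockout reproduces the published ranking exactly", {
  fx <- load_angiogenesis_fixture()
  mct <- compute_mct_sets(fx$support)
  tab <- structural_knockout_table(fx$support, knock_units(mct))
  expect_identical(nrow(tab), 26L)
  got <- stats::setNames(tab$affected_percent, tab$unit)
  want <- stats::setNames(fx$knockout_expected$affected_percent,
                          fx$knockout_expected$unit)
  expect_setequal(names(got), names(want))
  expect_equal(got[names(want)], want, tolerance = 1e-9)
})

test_that("all members of one MCT set have the same knockout impact", {
  fx <- load_angiogenesis_fixture()
  per_member <- structural_knockout_table(
    fx$support, stats::setNames(as.list(fx$mct_sets$m2), fx$mct_sets$m2))
  expect_true(all(per_member$affected_percent == 79.17))
})

test_that("knockout percentage handles empty hits and rejects unknown transitions", {
  S <- rbind(x1 = c(1, 0, 0), x2 = c(1, 1, 0))
  colnames(S) <- c("t1", "t2", "t3")
  tab <- structural_knockout_table(S, list(u1 = "t3", u2 = "t1"))
  expect_identical(tab$affected_percent[tab$unit == "u1"], 0)
  expect_identical(tab$affected_percent[tab$unit == "u2"], 100)
  expect_identical(tab$unit[1], "u2")          # sorted by impact
  expect_error(structural_knockout_table(S, list(u = "tX")), "unknown transitions")
})

test_that("affected percentage is monotone under unit inclusion", {
  fx <- load_angiogenesis_fixture()
  set.seed(17)
  tl <- colnames(fx$support)
  for (i in 1:10) {
    small <- sample(tl, 3)
    big <- union(small, sample(tl, 5))
    tab <- structural_knockout_table(fx$support, list(small = small, big = big))
    expect_gte(tab$affected_percent[tab$unit == "big"],
               tab$affected_percent[tab$unit == "small"])
  }
})

test_that("disabled transitions are OFFLINE with firing chance exactly zero", {
  net <- cycle_net(1L)
  pkg <- run_simulation(net, simulation_params(steps = 50, repetitions = 5,
                                               seed = 7, disabled = "t1"))
  t1 <- pkg$transitions[pkg$transitions$id == "t1", ]
  expect_identical(t1$status, "OFFLINE")
  expect_identical(t1$mean_firing, 0)
  # with the only source of tokens for p2 blocked, t2 starves after one pass
  t2 <- pkg$transitions[pkg$transitions$id == "t2", ]
  expect_identical(t2$status, "KNOCKOUT")
  expect_identical(t2$mean_firing, 0)
})

test_that("a source transition fires at the willing probability", {
  src <- petri_net("p1", "t1", data.frame(source = "t1", target = "p1"))
  pkg <- run_simulation(src, simulation_params(steps = 400, repetitions = 60,
                                               firing_probability = 0.5, seed = 3))
  tr <- pkg$transitions
  se <- sqrt(0.25 / (400 * 60))
  expect_lt(abs(tr$mean_firing - 0.5), 3 * se)
  # per-repetition firing fraction is Binomial(steps, p)/steps
  expect_equal(tr$sd_firing, sqrt(0.25 / 400), tolerance = 0.2)
  expect_identical(tr$status, "ACTIVE")
})

test_that("disabling the unique source starves every downstream transition", {
  # t0 (source) -> p1 -> t1 -> p2 -> t2 -> p3
  net <- petri_net(paste0("p", 1:3), paste0("t", 0:2),
                   data.frame(source = c("t0", "p1", "t1", "p2", "t2"),
                              target = c("p1", "t1", "p2", "t2", "p3")))
  ref <- run_simulation(net, simulation_params(steps = 100, repetitions = 10, seed = 5))
  expect_true(all(ref$transitions$status == "ACTIVE"))
  ko <- run_simulation(net, simulation_params(steps = 100, repetitions = 10,
                                              seed = 5, disabled = "t0"))
  expect_identical(ko$transitions$status, c("OFFLINE", "KNOCKOUT", "KNOCKOUT"))

  cmp <- compare_simulation_packages(ref, ko)
  expect_identical(cmp$status, ko$transitions$status)
  expect_true(all(is.na(cmp$difference)))       # nothing left ACTIVE
})

test_that("token statistics are conserved on a closed circuit", {
  net <- cycle_net(1L)
  for (mode in c("random-order", "maximal")) {
    pkg <- run_simulation(net, simulation_params(steps = 200, repetitions = 10,
                                                 seed = 11, mode = mode))
    # exactly one token circulates: per-step totals always sum to 1
    expect_equal(sum(pkg$places$mean_tokens), 1, tolerance = 1e-12)
    expect_true(all(pkg$places$mean_tokens >= 0))
    expect_true(all(pkg$transitions$mean_firing >= 0 &
                    pkg$transitions$mean_firing <= 1))
  }
})

test_that("the same seed reproduces a bit-identical package", {
  net <- generate_covered_net(5, 7, n_circuits = 2, seed = 2)
  p <- simulation_params(steps = 60, repetitions = 8, seed = 42)
  a <- run_simulation(net, p)
  b <- run_simulation(net, p)
  expect_identical(a, b)
  c <- run_simulation(net, simulation_params(steps = 60, repetitions = 8, seed = 43))
  expect_false(identical(a$transitions$mean_firing, c$transitions$mean_firing))
})

test_that("comparing a package with itself gives zero differences", {
  net <- cycle_net(1L)
  pkg <- run_simulation(net, simulation_params(steps = 50, repetitions = 4, seed = 1))
  cmp <- compare_simulation_packages(pkg, pkg)
  expect_true(all(cmp$difference[cmp$status == "ACTIVE"] == 0))
  expect_identical(cmp$status, pkg$transitions$status)
})

test_that("packages over different transition sets cannot be compared", {
  a <- run_simulation(cycle_net(), simulation_params(steps = 10, repetitions = 2))
  b <- run_simulation(chain_net(), simulation_params(steps = 10, repetitions = 2))
  expect_error(compare_simulation_packages(a, b), "different transition sets")
})

test_that("simulation parameter validation and unknown transitions are caught", {
  expect_error(simulation_params(steps = 0), "steps")
  expect_error(simulation_params(firing_probability = 0))
  expect_error(run_simulation(cycle_net(),
                              simulation_params(steps = 5, repetitions = 1,
                                                disabled = "tz")),
               "unknown transitions")
})
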