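test_that("running_statistic produces well-formed prefix traces", {
  # constant barriers: all values equal, all changes zero
  tr <- running_statistic(barrier_ensemble(rep(15, 6)), "boltzmann_average")
  expect_equal(tr$points$n, 1:6)
  expect_equal(tr$points$value, rep(15, 6))
  expect_equal(tr$changes$change, rep(0, 5))
  expect_equal(nrow(tr$changes), nrow(tr$points) - 1L)

  # derived two-point trace
  tr2 <- running_statistic(barrier_ensemble(c(10, 20)), "boltzmann_average")
  expect_equal(tr2$points$value, c(10, 10.410679191258), tolerance = 1e-10)

  # DE trace starts at n = 2 and matches per-prefix recomputation
  set.seed(11)
  b <- runif(10, 5, 30)
  trd <- running_statistic(barrier_ensemble(b), "disproportionate_effect")
  expect_equal(trd$points$n, 2:10)
  expect_equal(trd$points$value,
               vapply(2:10, function(k) de_direct(b[1:k]), numeric(1)),
               tolerance = 1e-10)
  expect_equal(nrow(trd$changes), nrow(trd$points) - 1L)

  # reversing record order changes the trace but not the final point
  trr <- running_statistic(barrier_ensemble(rev(b)), "disproportionate_effect")
  expect_equal(tail(trr$points$value, 1), tail(trd$points$value, 1))

  expect_error(running_statistic(barrier_ensemble(18.7),
                                 "disproportionate_effect"), "too few")
})

test_that("converged_after applies the windowed strictly-below rule", {
  rule <- convergence_rule()   # 5% over 5

  # constant trace over >= 7 points converges at the first point
  trc <- running_statistic(barrier_ensemble(rep(15, 8)), "boltzmann_average")
  expect_equal(converged_after(trc, rule), 1L)

  # every change at the threshold or above: never converges
  tr_bad <- trace_from_values(c(100, 110, 121, 133.1, 146.41, 161.05, 177.16))
  expect_identical(converged_after(tr_bad, rule), NA_integer_)

  # 6 points, changes [10%, 1%, 1%, 1%, 1%]: only 5 changes and the first
  # is too large, so no candidate hosts a full quiet window
  v <- c(100, 110)
  for (k in 1:4) v <- c(v, v[length(v)] * 1.01)
  tr6 <- trace_from_values(v)
  expect_equal(round(tr6$changes$change, 6), c(10, 1, 1, 1, 1))
  expect_identical(converged_after(tr6, rule), NA_integer_)

  # one more quiet change and the window after point 2 fits
  v7 <- c(v, v[length(v)] * 1.01)
  expect_equal(converged_after(trace_from_values(v7), rule), 2L)

  # window_end semantics reports the confirming point instead
  rule_end <- convergence_rule(semantics = "window_end")
  expect_equal(converged_after(trc, rule_end), 1L + 5L)
  expect_equal(converged_after(trace_from_values(v7), rule_end), 7L)

  # too-short traces return NA, never a guess
  short <- running_statistic(barrier_ensemble(rep(15, 4)), "boltzmann_average")
  expect_identical(converged_after(short, rule), NA_integer_)
})

test_that("converged_after is monotone in threshold and antitone in window", {
  set.seed(22)
  for (i in 1:30) {
    e <- rand_ensemble(sample(8:25, 1))
    tr <- running_statistic(e, "boltzmann_average")
    as_inf <- function(x) if (is.na(x)) 1e9 else x   # NA ~ "never", ordered last
    thresholds <- c(1, 2, 5, 10, 25)
    counts_t <- vapply(thresholds, function(th)
      as_inf(converged_after(tr, convergence_rule(threshold = th))),
      numeric(1))
    expect_true(all(diff(counts_t) <= 0))  # raising threshold never increases

    windows <- c(1, 2, 3, 5, 7)
    counts_w <- vapply(windows, function(w)
      as_inf(converged_after(tr, convergence_rule(window = w))), numeric(1))
    expect_true(all(diff(counts_w) >= 0))  # longer window never decreases
  }
})

test_that("combined criterion takes the later of the two counts", {
  # constant ensemble: Boltzmann converges at 1, DE trace only starts at 2
  expect_equal(combined_converged_after(barrier_ensemble(rep(12, 8))), 2L)

  # combined is never earlier than either constituent
  set.seed(33)
  for (i in 1:20) {
    e <- rand_ensemble(sample(10:25, 1))
    rule <- convergence_rule()
    cb <- converged_after(running_statistic(e, "boltzmann_average",
                                            rule = rule), rule)
    cd <- converged_after(running_statistic(e, "disproportionate_effect",
                                            rule = rule), rule)
    cc <- combined_converged_after(e, rule)
    if (is.na(cb) || is.na(cd)) {
      expect_identical(cc, NA_integer_)
    } else {
      expect_equal(cc, max(cb, cd))
      expect_gte(cc, cb)
      expect_gte(cc, cd)
    }
  }

  # an ensemble whose DE trace never settles propagates NA
  osc <- barrier_ensemble(rep(c(5, 40), 6) + seq(0, 0.11, by = 0.01))
  rule_tight <- convergence_rule(threshold = 0)
  expect_identical(combined_converged_after(osc, rule_tight), NA_integer_)
})

test_that("ordering_sensitivity is seed-reproducible and leaves the RNG alone", {
  e <- rand_ensemble(12)
  a <- ordering_sensitivity(e, n_permutations = 15, seed = 7)
  b <- ordering_sensitivity(e, n_permutations = 15, seed = 7)
  expect_identical(a, b)
  expect_length(a, 15)

  # constant ensemble: every permutation gives the same count
  const <- barrier_ensemble(rep(11, 9))
  expect_true(all(ordering_sensitivity(const, n_permutations = 8,
                                       seed = 1) == 2L))

  # caller RNG state is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(ordering_sensitivity(e, n_permutations = 5,
                                               seed = 4))
  after <- runif(3)
  expect_identical(before, after)

  expect_error(ordering_sensitivity(e, n_permutations = 0), ">= 1")
  expect_error(ordering_sensitivity(e, n_permutations = 2, seed = 1.5),
               "seed")
})
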