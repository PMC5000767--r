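test_that("rank_by_small sorts ascending with stable ties on sampling order", {
  p <- paired_ensemble(barrier_small = c(20, 18, 19),
                       barrier_big = c(16, 15, 17),
                       conformation_id = c("a", "b", "c"))
  expect_equal(rank_by_small(p), c("b", "c", "a"))

  tie <- paired_ensemble(barrier_small = rep(20, 4),
                         barrier_big = c(15, 16, 17, 18),
                         conformation_id = c("w", "x", "y", "z"))
  expect_equal(rank_by_small(tie), c("w", "x", "y", "z"))

  # the lowest-barrier snapshot (18.7 kcal/mol at 6.5 ns) ranks first
  small <- c(21.4, 19.2, 18.7, 23.0)
  p2 <- paired_ensemble(barrier_small = small,
                        barrier_big = c(16, 15.5, 15.0, 18),
                        conformation_id = c("t2", "t4", "t13", "t17"),
                        sample_time = c(1.0, 2.0, 6.5, 8.5))
  expect_equal(rank_by_small(p2)[1], "t13")
})

test_that("barrier_correlation: rank correlation with documented edge behaviour", {
  set.seed(55)
  s <- runif(10, 10, 30)
  shift <- paired_ensemble(barrier_small = s, barrier_big = s + 1)
  expect_equal(barrier_correlation(shift), 1)

  # invariance under strictly increasing transforms of either side
  mono <- paired_ensemble(barrier_small = s, barrier_big = exp(s / 10))
  expect_equal(barrier_correlation(mono), 1)

  anti <- paired_ensemble(barrier_small = s, barrier_big = 50 - s)
  expect_equal(barrier_correlation(anti), -1)

  # hand-computed: ranks (1,2,3) vs (2,1,3), sum d^2 = 2 -> 1 - 12/24
  tri <- paired_ensemble(barrier_small = c(1, 2, 3),
                         barrier_big = c(2, 1, 3))
  expect_equal(barrier_correlation(tri), 0.5)
  expect_equal(barrier_correlation(tri, method = "pearson"), 0.5)

  expect_error(barrier_correlation(
    paired_ensemble(c(1, 2), c(2, 1))), "at least 3")
  expect_error(barrier_correlation(
    paired_ensemble(rep(5, 4), c(1, 2, 3, 4))), "undefined correlation")
})

test_that("run_protocol consumes big barriers in ranked order and stops on convergence", {
  # constant big barriers: stops as soon as a full window fits after the
  # first defined DE point (n = 2 + window)
  const <- paired_ensemble(barrier_small = seq(20, 27, by = 1),
                           barrier_big = rep(15, 8))
  res <- run_protocol(const)
  expect_equal(res$n_big_evaluated, 7L)
  expect_true(res$converged)
  expect_equal(res$converged_after, 2L)
  expect_equal(res$final_boltzmann_average, 15)

  # evaluation order is the small-QM ranking of all conformations
  set.seed(66)
  p <- generate_paired_ensemble(synthetic_spec(seed = 8))
  r <- run_protocol(p)
  expect_equal(r$evaluation_order, rank_by_small(p))
  expect_lte(r$n_big_evaluated, nrow(p))
})

test_that("a rule that can never fire exhausts the ensemble and reproduces full-set statistics", {
  p <- generate_paired_ensemble(synthetic_spec(seed = 12))
  never <- convergence_rule(threshold = 0)
  res <- run_protocol(p, rule = never)
  expect_false(res$converged)
  expect_equal(res$n_big_evaluated, nrow(p))
  big <- ensemble_side(p, "big")
  expect_equal(res$final_boltzmann_average, boltzmann_average(big),
               tolerance = 1e-12)
  expect_equal(res$final_disproportionate_effect,
               disproportionate_effect(big), tolerance = 1e-12)
})

test_that("cost accounting matches the pre-screening arithmetic", {
  cm <- cost_model(0.1)
  # 20 cheap evaluations at 10% + 8 expensive ones vs 20 expensive ones
  expect_equal(cost_savings(cm, 20, 8, baseline = 20), 50)
  # free pre-screening, full big-QM evaluation: nothing saved
  expect_equal(cost_savings(cost_model(0), 0, 20, baseline = 20), 0)
  # pre-screening at full cost doubles the bill
  expect_equal(cost_savings(cost_model(1), 20, 20, baseline = 20), -100)

  expect_error(cost_savings(cm, 20, 8), "baseline")
  expect_error(cost_model(1.5), "relative_cost")
  expect_error(cost_model(0.1, baseline_big_evaluations = 0), "baseline")

  # savings decrease in relative cost and in big-QM evaluations
  s_by_cost <- vapply(c(0.05, 0.1, 0.5, 1),
                      function(rc) cost_savings(cost_model(rc), 20, 8,
                                                baseline = 20), numeric(1))
  expect_true(all(diff(s_by_cost) < 0))
  s_by_nbig <- vapply(c(5, 8, 12, 20),
                      function(nb) cost_savings(cm, 20, nb, baseline = 20),
                      numeric(1))
  expect_true(all(diff(s_by_nbig) < 0))

  # run_protocol reports the same accounting it performed
  p <- generate_paired_ensemble(synthetic_spec(seed = 21))
  res <- run_protocol(p, cost = cost_model(0.1))
  expect_equal(res$total_cost, nrow(p) * 0.1 + res$n_big_evaluated)
  expect_equal(res$savings,
               cost_savings(cost_model(0.1), nrow(p), res$n_big_evaluated,
                            baseline = nrow(p)))
})

test_that("ranked screening needs no more big-QM evaluations than MD-order screening (correlated batches)", {
  # distributional comparison under perfect small/big correlation:
  # consuming big barriers lowest-first front-loads the conformations that
  # dominate the Boltzmann sum
  set.seed(77)
  wins <- 0L; ties <- 0L; losses <- 0L
  for (i in 1:30) {
    b <- runif(20, 8, 30)
    p <- paired_ensemble(barrier_small = b, barrier_big = b + 2)
    ranked <- run_protocol(p)$n_big_evaluated
    md <- combined_converged_after(ensemble_side(p, "big"))
    md_n <- if (is.na(md)) 20L else {
      # evaluations needed to confirm in MD order: count + window
      min(20L, md + 5L)
    }
    if (ranked < md_n) wins <- wins + 1L
    else if (ranked == md_n) ties <- ties + 1L
    else losses <- losses + 1L
  }
  expect_gte(wins + ties, losses)
})
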