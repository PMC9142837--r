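# Experiments: perturbation compilation, trajectory checking, outcome
# negation.

test_that("experiment validation enforces times, modes and clamp consistency", {
  expect_error(experiment("e", length = 5,
                          constraints = data.frame(time = 5, component = "A",
                                                   value = TRUE, role = "outcome")),
               "time")
  expect_error(experiment("e", perturbations = data.frame(
    component = c("A", "A"), mode = c("KO", "FE"))), "one perturbation mode")
  expect_error(experiment("e", perturbations = data.frame(component = "A",
                                                          mode = "KD")),
               "KO or FE")
  # KO'd component may not be observed active
  expect_error(experiment("e", length = 5,
                          perturbations = data.frame(component = "A", mode = "KO"),
                          constraints = data.frame(time = 2, component = "A",
                                                   value = TRUE,
                                                   role = "intermediate")),
               "opposite")
  expect_error(experiment("e", length = 5,
                          constraints = data.frame(time = c(1, 1),
                                                   component = "A",
                                                   value = c(TRUE, FALSE),
                                                   role = "intermediate")),
               "contradictory")
})

test_that("perturbations compile to all-step clamps", {
  e <- experiment("e", perturbations = data.frame(component = c("G", "H"),
                                                  mode = c("KO", "FE")))
  expect_identical(compile_perturbations(e), c(G = FALSE, H = TRUE))
  expect_length(compile_perturbations(experiment("empty")), 0L)
})

test_that("trajectory_satisfies checks timed observation predicates", {
  net <- chain_net()
  tr <- simulate_trajectory(net, c(A = TRUE, B = FALSE, C = FALSE), 21)
  # the canonical timed pair: active at step 0, inactive at step 20
  e <- experiment("decay", length = 21,
                  constraints = data.frame(time = c(0, 20), component = "A",
                                           value = c(TRUE, FALSE),
                                           role = c("initial", "outcome")))
  expect_false(trajectory_satisfies(tr, e))  # A self-sustains
  tr2 <- simulate_trajectory(net, c(A = FALSE, B = TRUE, C = FALSE), 21)
  expect_false(trajectory_satisfies(tr2, e)) # A never on at 0
  # no self-loop on B: on at 0, decays
  e_b <- experiment("decay_b", length = 21,
                    constraints = data.frame(time = c(0, 20), component = "B",
                                             value = c(TRUE, FALSE),
                                             role = c("initial", "outcome")))
  expect_true(trajectory_satisfies(tr2, e_b))
  expect_true(trajectory_satisfies(tr, experiment("empty", length = 21)))
  expect_error(trajectory_satisfies(tr, experiment("short", length = 5)),
               "length")
})

test_that("negate_outcome flips exactly the outcome constraints and is an involution", {
  cons <- data.frame(time = c(0, 3, 7, 7),
                     component = c("A", "B", "C", "B"),
                     value = c(TRUE, FALSE, TRUE, FALSE),
                     role = c("initial", "intermediate", "outcome", "outcome"))
  e <- experiment("e", length = 8,
                  perturbations = data.frame(component = "A", mode = "FE"),
                  constraints = cons)
  n <- negate_outcome(e)
  expect_identical(n$constraints$value, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(n$constraints$role, cons$role)
  expect_identical(n$perturbations, e$perturbations)
  expect_identical(negate_outcome(n)$constraints, e$constraints)
  expect_error(negate_outcome(experiment("no_out", length = 3)),
               "no outcome")
})

test_that("a deterministic trajectory satisfies at most one of an experiment and its negation", {
  net <- chain_net()
  for (a in c(TRUE, FALSE)) {
    tr <- simulate_trajectory(net, c(A = a, B = FALSE, C = FALSE), 10)
    e <- experiment("e", length = 10,
                    constraints = data.frame(time = 9, component = "C",
                                             value = TRUE, role = "outcome"))
    expect_false(trajectory_satisfies(tr, e) &&
                 trajectory_satisfies(tr, negate_outcome(e)))
  }
})

test_that("suites require unique labels", {
  e <- experiment("dup")
  expect_error(experiment_suite(list(e, e)), "unique")
})
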