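# The synthesis engine against its brute-force oracle, verification, and
# null-hypothesis plumbing.

test_that("an empty suite is satisfiable by any concretization", {
  net <- abn(c("A", "B"),
             interactions = data.frame(source = "A", target = "B",
                                       sign = TRUE, definite = FALSE),
             menus = list(A = 0:1, B = 0:1))
  res <- synthesize(net, experiment_suite(list()), limit = Inf)
  expect_identical(res$status, "SAT")
  expect_equal(length(res$models), 8L)  # 2 optional subsets x 2 x 2 menus
  expect_true(res$exhaustive)
})

test_that("a repressed target with the anchored condition and no activator is unsatisfiable", {
  net <- repressor_abn()
  suite <- experiment_suite(steady_on_experiment())
  res <- synthesize(net, suite)
  expect_identical(res$status, "UNSAT")
  expect_length(res$models, 0L)
  expect_true(res$exhaustive)
  # the independent oracle agrees
  expect_identical(brute_force_synthesize(net, suite)$status, "UNSAT")
})

test_that("solutions are verified models and the limit controls collection, not status", {
  spec <- fixture_spec(11, n_components = 5, n_definite = 5, n_optional = 3,
                       menu_size = 2, n_experiments = 2, length = 8,
                       observed_fraction = 0.6)
  net <- random_abn(spec)
  fix <- plant_and_observe(spec, net)
  all_res <- synthesize(net, fix$suite, limit = Inf)
  expect_identical(all_res$status, "SAT")
  expect_true(all_res$exhaustive)
  for (m in all_res$models) {
    expect_true(verify_model(m$network, fix$suite))
    for (lab in names(fix$suite))
      expect_true(trajectory_satisfies(m$witnesses[[lab]], fix$suite[[lab]]))
  }
  one <- synthesize(net, fix$suite, limit = 1)
  expect_false(one$exhaustive && length(all_res$models) > 1)
  # deterministic: first model identical whatever the limit
  expect_identical(boolsynth:::solution_key(one$models[[1]]$network),
                   boolsynth:::solution_key(all_res$models[[1]]$network))
})

test_that("engine and brute-force oracle agree on status and full solution sets", {
  for (seed in 1:25) {
    spec <- fixture_spec(seed, n_components = 4, n_definite = 4,
                         n_optional = 3, menu_size = 2, n_experiments = 2,
                         length = 6, observed_fraction = 0.5)
    net <- random_abn(spec)
    fix <- plant_and_observe(spec, net)
    fast <- synthesize(net, fix$suite, limit = Inf, witnesses = FALSE,
                       verify = FALSE)
    slow <- brute_force_synthesize(net, fix$suite)
    expect_identical(fast$status, slow$status)
    expect_identical(solution_keys(fast), solution_keys(slow))
  }
})

test_that("a non-solution fails verify_model", {
  net <- repressor_abn()
  suite <- experiment_suite(steady_on_experiment())
  expect_false(verify_model(concrete_network(net), suite))
})

test_that("adding an experiment never turns UNSAT into SAT", {
  for (seed in 1:10) {
    spec <- fixture_spec(100 + seed, n_components = 4, n_definite = 4,
                         n_optional = 2, menu_size = 2, n_experiments = 2,
                         length = 6, observed_fraction = 0.8)
    net <- random_abn(spec)
    fix <- plant_and_observe(spec, net)
    sub <- experiment_suite(list(fix$suite[[1]]))
    full <- fix$suite
    s_sub <- synthesize(net, sub, limit = 1, witnesses = FALSE)$status
    s_full <- synthesize(net, full, limit = 1, witnesses = FALSE)$status
    expect_false(s_sub == "UNSAT" && s_full == "SAT")
  }
})

test_that("null-hypothesis testing replaces one experiment by its negation", {
  # single-concretization chain with a fully determined initial state: the
  # outcome is forced, so exactly one of normal / null is SAT
  net <- chain_abn()
  cons <- data.frame(time = c(0, 0, 0, 5),
                     component = c("A", "B", "C", "C"),
                     value = c(TRUE, FALSE, FALSE, TRUE),
                     role = c(rep("initial", 3), "outcome"))
  e <- experiment("obs", length = 6, constraints = cons)
  suite <- experiment_suite(e)
  normal <- synthesize(net, suite)
  null <- test_null_hypothesis(net, suite, "obs")
  expect_identical(sort(c(normal$status, null$status)), c("SAT", "UNSAT"))
  # isolate mode drops the other experiments
  e2 <- experiment("other", length = 6,
                   constraints = data.frame(time = 0, component = "A",
                                            value = TRUE, role = "initial"))
  iso <- test_null_hypothesis(net, experiment_suite(list(e, e2)), "obs",
                              isolate = TRUE)
  expect_identical(iso$labels, "obs")
  expect_error(test_null_hypothesis(net, suite, "nope"), "unknown experiment")
})
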