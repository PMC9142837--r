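# Synthetic fixtures: random ABNs with a planted hidden concretization and
# observation suites simulated from it, for testing synthesis, verification
# and null-hypothesis machinery without any curated model.

#' Specification of a synthetic fixture
#'
#' @param seed Integer seed; all randomness in [random_abn()] and
#'   [plant_and_observe()] is derived from it.
#' @param n_components Number of components.
#' @param n_definite,n_optional Numbers of definite and optional signed
#'   interactions (together at most `2 * n_components^2`, the number of
#'   distinct signed source-target pairs).
#' @param menu_size Size of each component's random condition menu (1..18).
#' @param n_experiments Number of observation experiments to generate.
#' @param length Trajectory length of each experiment.
#' @param observed_fraction Fraction of (step, component) cells of the true
#'   trajectories emitted as observation constraints, in `(0, 1]`.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_components = 5L, n_definite = 5L,
                         n_optional = 3L, menu_size = 2L,
                         n_experiments = 2L, length = 8L,
                         observed_fraction = 1) {
  k <- as.integer(length)
  spec <- list(seed = as.integer(seed), n_components = as.integer(n_components),
               n_definite = as.integer(n_definite),
               n_optional = as.integer(n_optional),
               menu_size = as.integer(menu_size),
               n_experiments = as.integer(n_experiments), length = k,
               observed_fraction = as.numeric(observed_fraction))
  stopifnot(spec$n_components >= 1L, spec$menu_size >= 1L,
            spec$menu_size <= 18L, spec$n_experiments >= 1L, k >= 2L,
            spec$observed_fraction > 0, spec$observed_fraction <= 1)
  if (spec$n_definite + spec$n_optional > 2L * spec$n_components^2)
    stop("infeasible edge counts: more signed edges requested than exist")
  structure(spec, class = "fixture_spec")
}

# run code under a local RNG state seeded from the fixture seed
.with_fixture_rng <- function(spec, offset, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((spec$seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate a random abstract Boolean network
#'
#' Draws `n_definite + n_optional` distinct signed interactions uniformly
#' from all source-target-sign triples (activation and repression equally
#' likely; self-loops allowed) and gives every component a random condition
#' menu of the requested size. Reproducible: the same spec always yields the
#' identical network.
#'
#' @param spec A [fixture_spec].
#' @return An [abn].
#' @export
random_abn <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_fixture_rng(spec, 0L, {
    n <- spec$n_components
    nm <- sprintf("G%d", seq_len(n))
    all_triples <- expand.grid(source = nm, target = nm, sign = c(TRUE, FALSE),
                               stringsAsFactors = FALSE)
    ne <- spec$n_definite + spec$n_optional
    pick <- sample.int(nrow(all_triples), ne)
    ia <- all_triples[pick, , drop = FALSE]
    ia$definite <- rep(c(TRUE, FALSE), c(spec$n_definite, spec$n_optional))
    menus <- lapply(seq_len(n), function(i) sort(sample(0:17, spec$menu_size)))
    names(menus) <- nm
    abn(nm, interactions = ia, menus = menus)
  })
}

#' Plant a hidden concrete network and observe it
#'
#' Samples one concretization of the ABN (a random optional-edge subset and
#' random menu choices) together with a random full initial state per
#' experiment, simulates each experiment on the hidden network, and emits
#' observation constraints sampled from the true trajectories at the
#' requested fraction. Step-0 cells are tagged `"initial"`, final-step cells
#' `"outcome"` (at least one is always included), the rest
#' `"intermediate"`. By construction the hidden network satisfies the
#' resulting suite.
#'
#' @param spec A [fixture_spec].
#' @param abn The network from [random_abn]`(spec)` (regenerated when
#'   omitted).
#' @return A list with `hidden` (a [concrete_network]), `suite` (an
#'   [experiment_suite]) and `trajectories` (the true trajectories).
#' @export
plant_and_observe <- function(spec, abn = random_abn(spec)) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(abn, "abn"))
  .with_fixture_rng(spec, 1L, {
    nm <- abn$components$name
    n <- length(nm)
    m <- sum(!abn$interactions$definite)
    hidden <- concrete_network(
      abn,
      chosen_optional = sample(c(TRUE, FALSE), m, replace = TRUE),
      conditions = stats::setNames(
        vapply(abn$menus[nm],
               function(mn) mn[sample.int(length(mn), 1L)], 1L), nm))
    k <- spec$length
    exps <- vector("list", spec$n_experiments)
    trajs <- vector("list", spec$n_experiments)
    for (e in seq_len(spec$n_experiments)) {
      init <- stats::setNames(sample(c(TRUE, FALSE), n, replace = TRUE), nm)
      traj <- simulate_trajectory(hidden, init, k)
      cells <- which(matrix(stats::runif(k * n), k, n) <= spec$observed_fraction,
                     arr.ind = TRUE)
      # guarantee at least one outcome observation
      if (!any(cells[, 1] == k))
        cells <- rbind(cells, c(k, sample.int(n, 1L)))
      cons <- data.frame(
        time = cells[, 1] - 1L,
        component = nm[cells[, 2]],
        value = traj[cells],
        role = ifelse(cells[, 1] == 1L, "initial",
                      ifelse(cells[, 1] == k, "outcome", "intermediate")),
        stringsAsFactors = FALSE)
      exps[[e]] <- experiment(sprintf("obs%d", e), length = k,
                              constraints = cons)
      trajs[[e]] <- traj
    }
    suite <- experiment_suite(exps)
    names(trajs) <- names(suite)
    list(hidden = hidden, suite = suite, trajectories = trajs)
  })
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Synthetic fixture spec: seed ", x$seed, ", ", x$n_components,
      " components, ", x$n_definite, "+", x$n_optional,
      " definite+optional edges, menus of ", x$menu_size, ", ",
      x$n_experiments, " experiments of length ", x$length,
      ", observed fraction ", x$observed_fraction, "\n", sep = "")
  invisible(x)
}
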