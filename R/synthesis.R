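# Synthesis: decide whether any concretization of an ABN satisfies every
# experiment in a suite, enumerate the consistent concrete networks, verify
# them by independent simulation, and run null-hypothesis tests.

# Flatten an ABN + suite into the engine's encoding. Optional interactions
# are numbered 0..m-1 in their declaration order.
.encode_problem <- function(abn, suite, length_override = NULL) {
  nm <- abn$components$name
  n <- length(nm)
  ia <- abn$interactions
  opt_rows <- which(!ia$definite)
  m <- length(opt_rows)
  opt_id <- integer(nrow(ia))
  opt_id[opt_rows] <- seq_len(m) - 1L

  comps <- lapply(seq_len(n), function(i) {
    inc <- which(match(ia$target, nm) == i)
    da <- inc[ia$definite[inc] & ia$sign[inc]]
    dr <- inc[ia$definite[inc] & !ia$sign[inc]]
    oa <- inc[!ia$definite[inc] & ia$sign[inc]]
    or <- inc[!ia$definite[inc] & !ia$sign[inc]]
    list(def_act = match(ia$source[da], nm) - 1L,
         def_rep = match(ia$source[dr], nm) - 1L,
         opt_act = match(ia$source[oa], nm) - 1L,
         opt_act_id = opt_id[oa],
         opt_rep = match(ia$source[or], nm) - 1L,
         opt_rep_id = opt_id[or],
         menu = abn$menus[[nm[i]]])
  })

  exps <- lapply(suite, function(e) {
    k <- if (is.null(length_override)) e$length else as.integer(length_override)
    cl <- compile_perturbations(e)
    bad <- setdiff(names(cl), nm)
    if (length(bad))
      stop("perturbation names unknown component: ", paste(bad, collapse = ", "))
    cs <- e$constraints
    bad <- setdiff(cs$component, nm)
    if (length(bad))
      stop("constraint names unknown component: ", paste(bad, collapse = ", "))
    if (any(cs$time >= k)) stop("constraint time beyond overridden length")
    cs <- cs[order(cs$time), , drop = FALSE]
    clamp_idx <- match(names(cl), nm)
    init <- cs[cs$time == 0L & !(cs$component %in% names(cl)), , drop = FALSE]
    free <- setdiff(seq_len(n), c(clamp_idx, match(init$component, nm)))
    list(k = k,
         clamp_idx = clamp_idx - 1L,
         clamp_val = as.integer(cl),
         cons_t = cs$time,
         cons_c = match(cs$component, nm) - 1L,
         cons_v = as.integer(cs$value),
         init_c = match(init$component, nm) - 1L,
         init_v = as.integer(init$value),
         free_c = free - 1L)
  })

  tabs <- unclass(regulation_conditions())
  storage.mode(tabs) <- "integer"
  list(n = n, m = m, tables = tabs, components = comps,
       experiments = unname(exps))
}

.wrap_solution <- function(abn, suite, sol, length_override = NULL) {
  net <- concrete_network(abn, chosen_optional = as.logical(sol$optional),
                          conditions = stats::setNames(as.integer(sol$conditions),
                                                       abn$components$name))
  wit <- NULL
  if (length(sol$witnesses) && !is.null(sol$witnesses[[1L]])) {
    wit <- lapply(seq_along(suite), function(e) {
      w <- sol$witnesses[[e]]
      k <- nrow(w)
      structure(w == 1, class = "abn_trajectory",
                dimnames = list(0:(k - 1L), abn$components$name))
    })
    names(wit) <- names(suite)
  }
  list(network = net, witnesses = wit)
}

#' Synthesize concrete networks consistent with an experiment suite
#'
#' Searches the ABN's concretization space -- one shared choice of optional
#' interactions and regulation conditions across all experiments, with
#' per-experiment existential choice of unconstrained initial values -- for
#' concrete networks whose synchronous dynamics satisfy every observation
#' constraint of every experiment. The search is exhaustive and
#' deterministic; `limit` caps how many solutions are collected (the
#' `exhaustive` flag reports whether the whole space was swept).
#'
#' @param abn An [abn].
#' @param suite An [experiment_suite] (or a single [experiment]).
#' @param limit Maximum number of solutions to collect (`Inf` for all).
#' @param length_override Optional common trajectory length replacing each
#'   experiment's own.
#' @param witnesses Collect one witness trajectory per experiment for each
#'   solution.
#' @param verify Re-check every returned solution with the independent
#'   pure-R simulator ([verify_model()]); an engine/simulator disagreement
#'   is raised as an error.
#' @return An object of class `synthesis_result`: a list with `status`
#'   (`"SAT"`/`"UNSAT"`), `models` (each a list with a `network` and its
#'   `witnesses`), `exhaustive`, `n_space` and `n_checked`.
#' @examples
#' net <- abn(c("A", "B"),
#'            interactions = data.frame(source = "A", target = "B",
#'                                      sign = TRUE, definite = FALSE),
#'            menus = list(A = 0:17, B = 5L))
#' e <- experiment("on", length = 3,
#'                 constraints = data.frame(time = c(0, 2), component = "B",
#'                                          value = c(FALSE, TRUE),
#'                                          role = c("initial", "outcome")))
#' synthesize(net, experiment_suite(e))
#' @export
synthesize <- function(abn, suite, limit = 10, length_override = NULL,
                       witnesses = TRUE, verify = TRUE) {
  stopifnot(inherits(abn, "abn"))
  if (inherits(suite, "abn_experiment")) suite <- experiment_suite(suite)
  stopifnot(inherits(suite, "experiment_suite"))
  if (!is.infinite(limit) && (!is.numeric(limit) || limit < 1))
    stop("limit must be >= 1 or Inf")
  enc <- .encode_problem(abn, suite, length_override)
  res <- .engine_solve(enc, if (is.infinite(limit)) -1 else as.double(limit),
                       isTRUE(witnesses))
  models <- lapply(res$solutions, .wrap_solution, abn = abn, suite = suite,
                   length_override = length_override)
  if (isTRUE(verify)) {
    for (mod in models) {
      if (!verify_model(mod$network, suite, length_override = length_override))
        stop("internal error: engine solution failed independent verification")
      if (!is.null(mod$witnesses)) {
        ok <- mapply(trajectory_satisfies, mod$witnesses, suite)
        if (!all(ok))
          stop("internal error: engine witness violates its experiment")
      }
    }
  }
  structure(list(status = res$status, models = models,
                 exhaustive = res$exhaustive, n_space = res$n_space,
                 n_checked = res$n_checked, labels = names(suite)),
            class = "synthesis_result")
}

#' Enumerate consistent concrete networks
#'
#' Convenience wrapper around [synthesize()] that collects up to `limit`
#' distinct solutions (distinct optional-edge subset or condition
#' assignment).
#'
#' @inheritParams synthesize
#' @return A `synthesis_result`.
#' @export
enumerate_solutions <- function(abn, suite, limit = Inf, ...) {
  synthesize(abn, suite, limit = limit, ...)
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat("Synthesis result: ", x$status, "\n", sep = "")
  cat("  concretization space: ", format(x$n_space, big.mark = ","),
      " (", format(x$n_checked, big.mark = ","), " examined, ",
      if (x$exhaustive) "exhaustive" else "stopped at limit", ")\n", sep = "")
  cat("  solutions collected:  ", length(x$models), "\n", sep = "")
  invisible(x)
}

#' @export
summary.synthesis_result <- function(object, ...) {
  if (object$status == "SAT" && length(object$models)) {
    opt <- vapply(object$models, function(m) sum(m$network$chosen_optional), 1)
    cat("Consistent networks found:", length(object$models),
        if (object$exhaustive) "(exhaustive)" else "(capped)", "\n")
    cat("Optional interactions used per model:",
        paste(range(opt), collapse = "-"), "\n")
  } else {
    cat("No consistent network exists for the encoded experiments.\n")
  }
  invisible(object)
}

#' Verify a concrete network against a suite by simulation
#'
#' Independent, solver-free check: for every experiment, searches
#' exhaustively over the assignments of unconstrained initial values (those
#' neither clamped nor fixed by a step-0 constraint) for a simulated
#' trajectory satisfying all constraints. The pure-R simulator
#' ([simulate_trajectory()]) is used throughout.
#'
#' @param net A [concrete_network] drawn from the suite's ABN.
#' @param suite An [experiment_suite] or single [experiment].
#' @param length_override Optional common trajectory length.
#' @param max_free Error out if an experiment leaves more than this many
#'   initial values free (the search is `2^free`).
#' @param return_witnesses If `TRUE`, return the satisfying trajectories
#'   (or `NULL` on failure) instead of a logical.
#' @return Logical, or a named list of trajectories.
#' @export
verify_model <- function(net, suite, length_override = NULL, max_free = 20L,
                         return_witnesses = FALSE) {
  stopifnot(inherits(net, "concrete_network"))
  if (inherits(suite, "abn_experiment")) suite <- experiment_suite(suite)
  nm <- net$abn$components$name
  wits <- vector("list", length(suite))
  names(wits) <- names(suite)
  for (lab in names(suite)) {
    e <- suite[[lab]]
    k <- if (is.null(length_override)) e$length else as.integer(length_override)
    cl <- compile_perturbations(e)
    cs <- e$constraints
    init <- cs[cs$time == 0L & !(cs$component %in% names(cl)), , drop = FALSE]
    free <- setdiff(nm, c(names(cl), init$component))
    if (length(free) > max_free)
      stop("experiment '", lab, "' leaves ", length(free),
           " initial values free; exhaustive check bounded at ", max_free)
    base_init <- stats::setNames(rep(FALSE, length(nm)), nm)
    base_init[init$component] <- init$value
    found <- NULL
    for (a in 0:(2^length(free) - 1)) {
      q0 <- base_init
      if (length(free))
        q0[free] <- as.logical(bitwAnd(bitwShiftR(a, seq_along(free) - 1L), 1L))
      traj <- simulate_trajectory(net, q0, k, clamps = cl)
      ec <- e
      ec$length <- k
      if (trajectory_satisfies(traj, ec)) { found <- traj; break }
    }
    if (is.null(found)) {
      if (return_witnesses) return(NULL)
      return(FALSE)
    }
    wits[[lab]] <- found
  }
  if (return_witnesses) wits else TRUE
}

#' Brute-force synthesis oracle
#'
#' Exact reference implementation: enumerates every concretization of the
#' ABN (all optional-interaction subsets times all menu assignments) and
#' keeps those that pass [verify_model()]. Independent of the compiled
#' search engine; intended as an oracle for small instances.
#'
#' @inheritParams synthesize
#' @param max_space Error out if the concretization space exceeds this.
#' @return A `synthesis_result` containing every consistent concretization.
#' @export
brute_force_synthesize <- function(abn, suite, length_override = NULL,
                                   max_space = 1e6) {
  stopifnot(inherits(abn, "abn"))
  if (inherits(suite, "abn_experiment")) suite <- experiment_suite(suite)
  s <- network_summary(abn)
  if (s$model_space > max_space)
    stop("concretization space ", s$model_space, " exceeds max_space")
  m <- s$optional
  nm <- abn$components$name
  menus <- abn$menus[nm]
  models <- list()
  n_checked <- 0
  grids <- c(rep(list(c(FALSE, TRUE)), m), menus)
  idx <- rep(1L, length(grids))
  sizes <- vapply(grids, length, 1L)
  repeat {
    n_checked <- n_checked + 1
    sel <- if (m > 0) vapply(seq_len(m), function(j) grids[[j]][idx[j]], TRUE) else logical()
    cond <- vapply(seq_len(length(nm)), function(i) grids[[m + i]][idx[m + i]], 1L)
    net <- concrete_network(abn, chosen_optional = sel,
                            conditions = stats::setNames(cond, nm))
    w <- verify_model(net, suite, length_override = length_override,
                      return_witnesses = TRUE)
    if (!is.null(w)) models[[length(models) + 1L]] <- list(network = net, witnesses = w)
    j <- length(idx)
    while (j >= 1L && idx[j] == sizes[j]) { idx[j] <- 1L; j <- j - 1L }
    if (j < 1L) break
    idx[j] <- idx[j] + 1L
  }
  structure(list(status = if (length(models)) "SAT" else "UNSAT",
                 models = models, exhaustive = TRUE,
                 n_space = s$model_space, n_checked = n_checked,
                 labels = names(suite)),
            class = "synthesis_result")
}

#' Null-hypothesis satisfiability test
#'
#' Replaces one experiment by its outcome-negated copy ([negate_outcome()])
#' and re-runs synthesis. `SAT` means some concretization consistent with
#' all *other* experiments realizes the opposite outcome of the targeted
#' one; `UNSAT` means every consistent network predicts the accepted
#' outcome.
#'
#' @inheritParams synthesize
#' @param label Label of the experiment whose outcome is negated.
#' @param isolate If `TRUE`, drop all other experiments and test the negated
#'   experiment alone; by default the other experiments' constraints are
#'   retained.
#' @return A `synthesis_result` for the modified suite.
#' @export
test_null_hypothesis <- function(abn, suite, label, isolate = FALSE,
                                 limit = 1, length_override = NULL, ...) {
  if (inherits(suite, "abn_experiment")) suite <- experiment_suite(suite)
  if (!label %in% names(suite)) stop("unknown experiment label: ", label)
  neg <- negate_outcome(suite[[label]])
  exps <- if (isolate) list(neg) else {
    out <- unclass(suite)
    out[[label]] <- neg
    out
  }
  synthesize(abn, experiment_suite(exps), limit = limit,
             length_override = length_override, ...)
}
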