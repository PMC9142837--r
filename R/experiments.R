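# Experiments: KO/FE perturbations plus timed Boolean observation
# constraints, trajectory checking, and outcome negation for null-hypothesis
# tests.

#' Construct an experiment
#'
#' An experiment is a bounded scenario: a trajectory length, a set of
#' knockout (KO, clamped inactive) / forced-expression (FE, clamped active)
#' perturbations, and timed observation constraints `(time, component,
#' value)`. Each constraint carries a role: `"initial"` (step-0 conditions),
#' `"intermediate"`, or `"outcome"` (the constraints that a null-hypothesis
#' test negates).
#'
#' @param label Experiment identifier.
#' @param length Number of states (`k`); constraint times must lie in
#'   `0..k-1`.
#' @param perturbations Data frame with columns `component`, `mode`
#'   (`"KO"` or `"FE"`), or `NULL`.
#' @param constraints Data frame with columns `time`, `component`, `value`
#'   (logical), `role`, or `NULL`.
#' @return An object of class `abn_experiment`.
#' @export
experiment <- function(label, length = 21L, perturbations = NULL,
                       constraints = NULL) {
  k <- as.integer(length)
  stopifnot(is.character(label), base::length(label) == 1L, k >= 1L)
  if (is.null(perturbations))
    perturbations <- data.frame(component = character(), mode = character(),
                                stringsAsFactors = FALSE)
  stopifnot(all(c("component", "mode") %in% names(perturbations)))
  perturbations$component <- as.character(perturbations$component)
  perturbations$mode <- as.character(perturbations$mode)
  if (!all(perturbations$mode %in% c("KO", "FE")))
    stop("perturbation mode must be KO or FE")
  if (anyDuplicated(perturbations$component))
    stop("at most one perturbation mode per component (conflicting KO/FE on ",
         perturbations$component[duplicated(perturbations$component)][1L], ")")
  if (is.null(constraints))
    constraints <- data.frame(time = integer(), component = character(),
                              value = logical(), role = character(),
                              stringsAsFactors = FALSE)
  stopifnot(all(c("time", "component", "value", "role") %in% names(constraints)))
  constraints$time <- as.integer(constraints$time)
  constraints$component <- as.character(constraints$component)
  constraints$value <- as.logical(constraints$value)
  constraints$role <- as.character(constraints$role)
  if (!all(constraints$role %in% c("initial", "intermediate", "outcome")))
    stop("constraint role must be initial, intermediate or outcome")
  if (any(constraints$time < 0L | constraints$time >= k))
    stop("constraint time outside 0..", k - 1L)
  ckey <- paste(constraints$time, constraints$component)
  dup <- duplicated(ckey) | duplicated(ckey, fromLast = TRUE)
  if (any(dup)) {
    vals <- tapply(constraints$value, ckey, function(v) length(unique(v)))
    if (any(vals > 1L)) stop("contradictory duplicate observation constraints")
    constraints <- constraints[!duplicated(ckey), , drop = FALSE]
  }
  # a perturbed component may not be observed at the opposite value
  if (nrow(perturbations) && nrow(constraints)) {
    cl <- stats::setNames(perturbations$mode == "FE", perturbations$component)
    hit <- constraints$component %in% names(cl)
    if (any(hit & constraints$value != cl[constraints$component]))
      stop("perturbed component constrained to the opposite of its clamp value")
  }
  rownames(perturbations) <- rownames(constraints) <- NULL
  structure(list(label = label, length = k, perturbations = perturbations,
                 constraints = constraints),
            class = "abn_experiment")
}

#' Bundle experiments into a suite
#'
#' @param experiments List of [experiment] objects with unique labels.
#' @return An object of class `experiment_suite`.
#' @export
experiment_suite <- function(experiments) {
  if (inherits(experiments, "abn_experiment")) experiments <- list(experiments)
  stopifnot(all(vapply(experiments, inherits, TRUE, "abn_experiment")))
  labels <- vapply(experiments, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("experiment labels must be unique")
  structure(stats::setNames(experiments, labels), class = "experiment_suite")
}

#' @export
print.abn_experiment <- function(x, ...) {
  cat("Experiment '", x$label, "': length ", x$length, ", ",
      nrow(x$perturbations), " perturbation(s), ",
      nrow(x$constraints), " constraint(s)\n", sep = "")
  invisible(x)
}

#' @export
print.experiment_suite <- function(x, ...) {
  cat("Experiment suite with", length(x), "experiment(s):\n")
  for (e in x)
    cat("  ", e$label, " (k=", e$length, ", ",
        paste0(e$perturbations$mode, " ", e$perturbations$component,
               collapse = ", "),
        ")\n", sep = "")
  invisible(x)
}

#' Compile an experiment's perturbations into clamps
#'
#' KO clamps the component to `FALSE` and FE to `TRUE`, at every time step
#' including step 0.
#'
#' @param exp An [experiment].
#' @return Named logical vector of clamp values (empty if unperturbed).
#' @export
compile_perturbations <- function(exp) {
  stopifnot(inherits(exp, "abn_experiment"))
  stats::setNames(exp$perturbations$mode == "FE", exp$perturbations$component)
}

#' Check a trajectory against an experiment's constraints
#'
#' @param traj An `abn_trajectory` whose length equals the experiment's.
#' @param exp An [experiment].
#' @return `TRUE` iff every observation constraint holds at its step.
#' @export
trajectory_satisfies <- function(traj, exp) {
  stopifnot(inherits(exp, "abn_experiment"))
  if (nrow(traj) != exp$length)
    stop("trajectory length ", nrow(traj), " does not match experiment length ",
         exp$length)
  cs <- exp$constraints
  if (!nrow(cs)) return(TRUE)
  bad <- setdiff(cs$component, colnames(traj))
  if (length(bad)) stop("constraint on unknown component: ", paste(bad, collapse = ", "))
  all(traj[cbind(cs$time + 1L, match(cs$component, colnames(traj)))] == cs$value)
}

#' Negate an experiment's outcome
#'
#' Returns a copy of the experiment in which every outcome-role constraint
#' has its value flipped; initial and intermediate constraints and
#' perturbations are untouched. Applying it twice restores the original.
#' This is the constraint transformation behind null-hypothesis testing:
#' the same initial conditions and perturbations, with the opposite final
#' observation.
#'
#' @param exp An [experiment] with at least one outcome constraint.
#' @return The negated [experiment].
#' @export
negate_outcome <- function(exp) {
  stopifnot(inherits(exp, "abn_experiment"))
  is_out <- exp$constraints$role == "outcome"
  if (!any(is_out)) stop("experiment '", exp$label, "' has no outcome constraints")
  exp$constraints$value[is_out] <- !exp$constraints$value[is_out]
  experiment(exp$label, exp$length, exp$perturbations, exp$constraints)
}
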