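# Synchronous Boolean semantics: occupancy classification, one-step update,
# trajectory simulation.

# Precompute per-component regulator index lists for a concrete network.
# Returned value is consumed by .step_compiled(); this is the pure-R
# simulation path, independent of the compiled search engine.
compile_network <- function(net) {
  stopifnot(inherits(net, "concrete_network"))
  nm <- net$abn$components$name
  eff <- effective_interactions(net)
  si <- match(eff$source, nm)
  ti <- match(eff$target, nm)
  act <- lapply(seq_along(nm), function(i) si[ti == i & eff$sign])
  rep_ <- lapply(seq_along(nm), function(i) si[ti == i & !eff$sign])
  tabs <- regulation_conditions()
  list(names = nm, act = act, rep = rep_,
       cond_tab = lapply(net$conditions[nm], function(ci) unclass(tabs)[ci + 1L, ]),
       has_in = vapply(seq_along(nm), function(i)
         length(act[[i]]) + length(rep_[[i]]) > 0L, TRUE))
}

.occupancy <- function(active, total) {
  if (total == 0L || active == 0L) 0L else if (active == total) 2L else 1L
}

.step_compiled <- function(cnet, state, clamp_idx = integer(), clamp_val = logical()) {
  n <- length(cnet$names)
  nxt <- logical(n)
  for (i in seq_len(n)) {
    if (!cnet$has_in[i]) next  # no effective regulators: decays to FALSE
    a <- .occupancy(sum(state[cnet$act[[i]]]), length(cnet$act[[i]]))
    r <- .occupancy(sum(state[cnet$rep[[i]]]), length(cnet$rep[[i]]))
    nxt[i] <- cnet$cond_tab[[i]][.rc_cell(a, r)]
  }
  if (length(clamp_idx)) nxt[clamp_idx] <- clamp_val
  nxt
}

.as_state <- function(net, state) {
  nm <- net$abn$components$name
  if (is.null(names(state))) {
    if (length(state) != length(nm)) stop("state must cover every component")
    return(stats::setNames(as.logical(state), nm))
  }
  if (!setequal(names(state), nm)) stop("state must cover exactly the component set")
  as.logical(state[nm])
}

.as_clamps <- function(net, clamps) {
  if (is.null(clamps) || length(clamps) == 0L)
    return(list(idx = integer(), val = logical()))
  nm <- net$abn$components$name
  bad <- setdiff(names(clamps), nm)
  if (length(bad)) stop("clamp names unknown component: ", paste(bad, collapse = ", "))
  list(idx = match(names(clamps), nm), val = as.logical(clamps))
}

#' Classify a component's regulator occupancy in a state
#'
#' Reports whether none, some or all of the component's effective activators
#' (and, symmetrically, repressors) are active. A component with zero
#' regulators of a given sign is reported as `"none"` for that sign, so the
#' `"all"` level is never produced degenerately.
#'
#' @param net A [concrete_network].
#' @param component Component name.
#' @param state Named logical vector over the network's components.
#' @return Named character vector `c(activators = , repressors = )`.
#' @export
classify_regulators <- function(net, component, state) {
  stopifnot(inherits(net, "concrete_network"))
  nm <- net$abn$components$name
  if (!component %in% nm) stop("unknown component: ", component)
  st <- .as_state(net, state)
  cn <- compile_network(net)
  i <- match(component, nm)
  lv <- occupancy_levels()
  c(activators = lv[.occupancy(sum(st[cn$act[[i]]]), length(cn$act[[i]])) + 1L],
    repressors = lv[.occupancy(sum(st[cn$rep[[i]]]), length(cn$rep[[i]])) + 1L])
}

#' One synchronous update step
#'
#' Every non-clamped component is updated simultaneously: its assigned
#' regulation condition is evaluated at its current occupancy levels. Clamped
#' components (knockout/forced expression) take their clamp value. A
#' component with no effective incoming interaction and no clamp decays to
#' `FALSE`.
#'
#' @param net A [concrete_network].
#' @param state Named logical vector over the components.
#' @param clamps Optional named logical vector of clamped values.
#' @return The successor state (named logical vector).
#' @export
synchronous_step <- function(net, state, clamps = NULL) {
  st <- .as_state(net, state)
  cl <- .as_clamps(net, clamps)
  cn <- compile_network(net)
  stats::setNames(.step_compiled(cn, st, cl$idx, cl$val), cn$names)
}

#' Simulate a synchronous trajectory
#'
#' Deterministically unrolls `length` states `q0 .. q(length-1)`, with `q0`
#' the initial state after clamping (clamps override regulation at every
#' step, including step 0) and each successor given by [synchronous_step()].
#'
#' @param net A [concrete_network].
#' @param initial Named logical vector over the components.
#' @param length Number of states (`k >= 1`); state indices run `0..k-1`.
#' @param clamps Optional named logical vector of clamped values.
#' @return An `abn_trajectory`: a `k x n` logical matrix, rows named by step
#'   index, columns by component.
#' @export
simulate_trajectory <- function(net, initial, length, clamps = NULL) {
  stopifnot(inherits(net, "concrete_network"))
  k <- as.integer(length)
  if (is.na(k) || k < 1L) stop("trajectory length must be at least 1")
  st <- .as_state(net, initial)
  cl <- .as_clamps(net, clamps)
  cn <- compile_network(net)
  if (length(cl$idx)) st[cl$idx] <- cl$val
  out <- matrix(NA, nrow = k, ncol = length(cn$names),
                dimnames = list(0:(k - 1L), cn$names))
  out[1L, ] <- st
  if (k > 1L) for (t in 2:k) {
    st <- .step_compiled(cn, st, cl$idx, cl$val)
    out[t, ] <- st
  }
  structure(out == 1, class = "abn_trajectory",
            dimnames = dimnames(out))
}

#' @rdname simulate_trajectory
#' @param object A [concrete_network] (S3 method for [stats::simulate()]).
#' @param nsim Number of (identical, deterministic) trajectories to return.
#' @param seed Ignored; the dynamics are deterministic.
#' @param initial,... Passed on to [simulate_trajectory()].
#' @export
simulate.concrete_network <- function(object, nsim = 1, seed = NULL,
                                      initial, length, clamps = NULL, ...) {
  one <- simulate_trajectory(object, initial, length, clamps)
  if (nsim == 1) one else replicate(nsim, one, simplify = FALSE)
}

#' @export
print.abn_trajectory <- function(x, ...) {
  cat("Synchronous trajectory: ", nrow(x), " states x ", ncol(x),
      " components\n", sep = "")
  m <- matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x))
  print(m)
  invisible(x)
}
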