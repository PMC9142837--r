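# Small networks and suites built in code, shared across test files.

# index of a semantic template among the 18 conditions (test-side copy of
# the lookup, kept tiny on purpose)
rc_idx <- function(name) boolsynth:::.rc_named_index(name)

# one self-sustaining component driving a chain A -> B -> C
chain_abn <- function() {
  abn(c("A", "B", "C"),
      interactions = data.frame(
        source = c("A", "A", "B"), target = c("A", "B", "C"),
        sign = TRUE, definite = TRUE),
      menus = list(A = rc_idx("some_activators"),
                   B = rc_idx("some_activators"),
                   C = rc_idx("some_activators")))
}

chain_net <- function() concrete_network(chain_abn())

# self-activator A represses B; B admits only the anchored condition, so B
# can never be active while A is and B has no activator
repressor_abn <- function() {
  abn(c("A", "B"),
      interactions = data.frame(
        source = c("A", "A"), target = c("A", "B"),
        sign = c(TRUE, FALSE), definite = TRUE),
      menus = list(A = rc_idx("some_activators"), B = 5L))
}

# experiment: both A and B active at the two final steps, A on initially
steady_on_experiment <- function(k = 6L) {
  experiment("both_on", length = k,
             constraints = data.frame(
               time = c(0L, k - 2L, k - 1L, k - 2L, k - 1L),
               component = c("A", "A", "A", "B", "B"),
               value = TRUE,
               role = c("initial", rep("outcome", 4L))))
}

# full-information fixture: no optional edges, singleton menus, every cell
# of every trajectory observed
determined_fixture <- function(seed) {
  spec <- fixture_spec(seed, n_components = 4L, n_definite = 5L,
                       n_optional = 0L, menu_size = 1L, n_experiments = 1L,
                       length = 6L, observed_fraction = 1)
  c(list(spec = spec), plant_and_observe(spec))
}

solution_keys <- function(res) {
  sort(vapply(res$models,
              function(m) boolsynth:::solution_key(m$network), ""))
}
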