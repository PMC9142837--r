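# The packaged C. elegans germline stem-cell fate network: 24 components,
# 40 signed interactions (32 definite + 8 optional), per-component
# regulation-condition menus, and the in-silico experiment suite
# (wild type + 8 knockout/forced-expression perturbations).

# Look up the index (0..17) of a named semantic template among the 18
# regulation conditions. a = activator level, r = repressor level (0..2).
.rc_named_index <- function(name) {
  a <- rep(0:2, each = 3L)
  r <- rep(0:2, times = 3L)
  tab <- switch(name,
    some_activators                = a >= 1L,
    all_activators                 = a == 2L,
    some_activators_no_repressors  = a >= 1L & r == 0L,
    all_activators_no_repressors   = a == 2L & r == 0L,
    no_repressors                  = r == 0L,
    anchored                       = a == 2L | (a >= 1L & r == 0L),
    stop("unknown template name: ", name))
  tabs <- unclass(regulation_conditions())
  idx <- which(apply(tabs, 1L, function(x) all(x == tab)))
  stopifnot(length(idx) == 1L)
  idx - 1L
}

.germline_edge_table <- function() {
  # source, sign ("act"/"rep"), target, definite, module
  e <- rbind(
    c("DTC",       "act", "APX1",        TRUE,  "notch"),
    c("DTC",       "act", "LAG2",        TRUE,  "notch"),
    c("LAG2",      "act", "GLP1",        TRUE,  "notch"),
    c("APX1",      "act", "GLP1",        TRUE,  "notch"),
    c("GLP1",      "act", "GLP1ICD",     TRUE,  "notch"),
    c("GLP1ICD",   "act", "SEL8",        TRUE,  "notch"),
    c("GLP1ICD",   "act", "LAG1",        TRUE,  "notch"),
    c("SEL8",      "act", "LAG1",        TRUE,  "notch"),
    c("GLP1",      "act", "HOP1",        TRUE,  "notch"),
    c("HOP1",      "act", "GLP1ICD",     TRUE,  "notch"),
    c("GLP1",      "act", "SEL12",       TRUE,  "notch"),
    c("SEL12",     "act", "GLP1ICD",     TRUE,  "notch"),
    c("SEL10",     "rep", "GLP1ICD",     TRUE,  "notch"),
    c("SEL10",     "rep", "SEL12",       TRUE,  "notch"),
    c("LAG1",      "act", "LST1",        TRUE,  "effectors"),
    c("LAG1",      "act", "SYGL1",       TRUE,  "effectors"),
    c("LST1",      "rep", "GLD1",        TRUE,  "gld1-accumulation"),
    c("LST1",      "act", "FBF1B",       TRUE,  "fbf1-two-state"),
    c("LST1",      "rep", "FBF1U",       TRUE,  "fbf1-two-state"),
    c("SYGL1",     "act", "FBF1B",       TRUE,  "fbf1-two-state"),
    c("SYGL1",     "rep", "FBF1U",       TRUE,  "fbf1-two-state"),
    c("FBF1B",     "rep", "GLD1",        TRUE,  "gld1-accumulation"),
    c("LAG1",      "act", "FBF2",        TRUE,  "effectors"),
    c("FBF2",      "rep", "GLD1",        TRUE,  "gld1-accumulation"),
    c("FBF1U",     "act", "GLD3",        TRUE,  "gld2-pathway"),
    c("FBF1B",     "rep", "GLD3",        TRUE,  "gld2-pathway"),
    c("FBF2",      "rep", "GLD3",        TRUE,  "gld2-pathway"),
    c("GLD3",      "act", "GLD2",        TRUE,  "gld2-pathway"),
    c("NOS3",      "act", "GLD1",        FALSE, "gld1-accumulation"),
    c("GLD2",      "act", "GLD1",        FALSE, "gld1-accumulation"),
    c("FBF1B",     "rep", "SCF_PROM1",   FALSE, "scf-prom1"),
    c("FBF1B",     "rep", "AXIS_SC",     FALSE, "axis-sc"),
    c("FBF2",      "rep", "AXIS_SC",     FALSE, "axis-sc"),
    c("SCF_PROM1", "rep", "CYE1_CDK2",   TRUE,  "scf-prom1"),
    c("GLD1",      "act", "MeioticDev",  FALSE, "fate-readout"),
    c("GLD2",      "act", "MeioticDev",  TRUE,  "fate-readout"),
    c("SCF_PROM1", "act", "MeioticDev",  FALSE, "fate-readout"),
    c("AXIS_SC",   "act", "MeioticDev",  FALSE, "fate-readout"),
    c("CYE1_CDK2", "act", "StemcellFate", TRUE, "fate-readout"),
    c("MeioticDev", "rep", "StemcellFate", TRUE, "fate-readout"))
  data.frame(source = e[, 1], sign = e[, 2] == "act", target = e[, 3],
             definite = e[, 4] == "TRUE", module = e[, 5],
             stringsAsFactors = FALSE)
}

.germline_menus <- function() {
  some <- .rc_named_index("some_activators")
  some_norep <- .rc_named_index("some_activators_no_repressors")
  all_norep <- .rc_named_index("all_activators_no_repressors")
  norep <- .rc_named_index("no_repressors")
  anch <- .rc_named_index("anchored")
  list(
    DTC = some, LAG2 = some, APX1 = some, GLP1 = some,
    GLP1ICD = sort(c(anch, some_norep)),
    SEL8 = some, LAG1 = some, HOP1 = some,
    SEL12 = anch, SEL10 = some,
    LST1 = some, SYGL1 = some,
    FBF1B = sort(c(some, .rc_named_index("all_activators"))),
    FBF1U = norep, FBF2 = some,
    GLD1 = sort(c(some_norep, anch)),
    GLD2 = some, GLD3 = anch, NOS3 = some,
    SCF_PROM1 = norep, AXIS_SC = norep, CYE1_CDK2 = norep,
    StemcellFate = some_norep, MeioticDev = some)
}

#' The germline stem-cell fate abstract Boolean network
#'
#' The core network of the stem cell fate versus meiotic development
#' decision circuit in the young adult *C. elegans* hermaphrodite germ line:
#' 24 components (the DTC niche signal, the core Notch pathway, the
#' LST-1/SYGL-1 effectors, the two-state FBF-1 (bound/unbound), FBF-2, the
#' GLD-1 accumulation and GLD-2/GLD-3 meiotic entry pathways, the
#' SCF^PROM-1^ and meiotic chromosome axis/SC routes, CYE-1/CDK-2 and the
#' two fate readouts) and 40 signed interactions, of which 32 are definite
#' and 8 optional. Each component carries a menu of admissible regulation
#' conditions; redundant effectors use some-activator (OR) templates.
#'
#' The edge-by-edge ledger, including which interactions are optional and
#' which functional module each belongs to, ships as
#' `system.file("extdata", "germline_edges.tsv", package = "boolsynth")`.
#'
#' @return An [abn] with 24 components and 40 interactions.
#' @examples
#' net <- germline_abn()
#' network_summary(net)$state_space  # 2^24
#' @export
germline_abn <- function() {
  edges <- .germline_edge_table()
  comps <- data.frame(
    name = c("DTC", "LAG2", "APX1", "GLP1", "GLP1ICD", "SEL8", "LAG1",
             "HOP1", "SEL12", "SEL10", "LST1", "SYGL1", "FBF1B", "FBF1U",
             "FBF2", "GLD1", "GLD2", "GLD3", "NOS3", "SCF_PROM1", "AXIS_SC",
             "CYE1_CDK2", "StemcellFate", "MeioticDev"),
    role = c("signal", rep("gene", 21), "fate-readout", "fate-readout"),
    stringsAsFactors = FALSE)
  abn(comps,
      interactions = edges[, c("source", "target", "sign", "definite")],
      menus = .germline_menus())
}

#' Setup-augmented germline network
#'
#' Adds the auxiliary input signals of the three distal-tip-cell signaling
#' setups to the core network. All setups carry `S0`, a self-sustaining
#' driver of the DTC signal: an experiment started with `S0 = 1` models a
#' cell inside the niche (constitutive DTC signal), one started with
#' `S0 = 0` models a cell losing the signal (DTC active at step 0 only,
#' then decaying). The `"reduced"` setup additionally carries `SD`, a
#' self-degrading signal (active for a single time step) gating CYE-1/CDK-2
#' activity, whose menu is switched to a some-activator/no-repressor
#' template so that CYE-1/CDK-2 decays with the signal.
#'
#' Auxiliary signals are setup-level additions and are not counted in the
#' core 24 components / 40 interactions.
#'
#' @param setup One of `"niche"`, `"losing"`, `"reduced"`.
#' @return An [abn] (25 or 26 components).
#' @export
germline_model <- function(setup = c("niche", "losing", "reduced")) {
  setup <- match.arg(setup)
  core <- germline_abn()
  comps <- rbind(core$components,
                 data.frame(name = "S0", role = "signal"))
  edges <- rbind(core$interactions,
                 data.frame(source = c("S0", "S0"), target = c("S0", "DTC"),
                            sign = TRUE, definite = TRUE))
  menus <- .germline_menus()
  menus$S0 <- .rc_named_index("some_activators")
  if (setup == "reduced") {
    comps <- rbind(comps, data.frame(name = "SD", role = "signal"))
    edges <- rbind(edges,
                   data.frame(source = "SD", target = "CYE1_CDK2",
                              sign = TRUE, definite = TRUE))
    menus$SD <- .rc_named_index("some_activators")
    menus$CYE1_CDK2 <- .rc_named_index("some_activators_no_repressors")
  }
  abn(comps, interactions = edges, menus = menus)
}

# registry of the packaged perturbation experiments: clamps, DTC-signal
# context and fate outcome
.germline_perturbations <- function() {
  list(
    glp1_ko       = list(clamps = c(GLP1 = "KO"),
                         context = "niche", outcome = "meiotic"),
    lst1_ko       = list(clamps = c(LST1 = "KO"),
                         context = "niche", outcome = "stem"),
    sygl1_ko      = list(clamps = c(SYGL1 = "KO"),
                         context = "niche", outcome = "stem"),
    lst1_sygl1_ko = list(clamps = c(LST1 = "KO", SYGL1 = "KO"),
                         context = "niche", outcome = "meiotic"),
    gld1_gld2_ko  = list(clamps = c(GLD1 = "KO", GLD2 = "KO"),
                         context = "losing", outcome = "no_meiosis"),
    glp1_fe       = list(clamps = c(GLP1 = "FE"),
                         context = "losing", outcome = "no_meiosis"),
    lst1_fe       = list(clamps = c(LST1 = "FE"),
                         context = "losing", outcome = "no_meiosis"),
    sygl1_fe      = list(clamps = c(SYGL1 = "FE"),
                         context = "losing", outcome = "no_meiosis"))
}

# outcome constraints at the last two steps (two equal consecutive
# constrained steps pin the steady fate)
.germline_outcome <- function(outcome, k) {
  t2 <- c(k - 2L, k - 1L)
  switch(outcome,
    stem = data.frame(time = rep(t2, 2L),
                      component = rep(c("StemcellFate", "MeioticDev"), each = 2L),
                      value = rep(c(TRUE, FALSE), each = 2L), role = "outcome"),
    meiotic = data.frame(time = rep(t2, 2L),
                         component = rep(c("StemcellFate", "MeioticDev"), each = 2L),
                         value = rep(c(FALSE, TRUE), each = 2L), role = "outcome"),
    no_meiosis = data.frame(time = t2, component = "MeioticDev",
                            value = FALSE, role = "outcome"),
    stop("unknown outcome: ", outcome))
}

.germline_experiment <- function(label, net, context, clamps, outcome,
                                 length = 21L, extra = NULL) {
  nm <- net$components$name
  init <- stats::setNames(rep(FALSE, length(nm)), nm)
  init["DTC"] <- TRUE
  if ("S0" %in% nm) init["S0"] <- context == "niche"
  if ("SD" %in% nm) init["SD"] <- TRUE
  # clamped components start at their clamp value
  if (length(clamps)) init[names(clamps)] <- clamps == "FE"
  cons <- data.frame(time = 0L, component = nm, value = unname(init),
                     role = "initial", stringsAsFactors = FALSE)
  cons <- rbind(cons, .germline_outcome(outcome, length))
  if (!is.null(extra)) cons <- rbind(cons, extra)
  pert <- if (length(clamps)) {
    data.frame(component = names(clamps), mode = unname(clamps),
               stringsAsFactors = FALSE)
  } else NULL
  experiment(label, length = length, perturbations = pert, constraints = cons)
}

#' The germline in-silico experiment suite
#'
#' Builds the packaged suite of timed observation constraints: a wild-type
#' experiment plus one experiment per requested perturbation, each of length
#' 21 (step indices 0..20) with outcomes constrained at the last two steps.
#'
#' In the `"niche"` setup the wild-type cell sits in the niche (constitutive
#' DTC signal via `S0 = 1`) and retains the stem-cell fate after 20 steps.
#' Perturbations whose phenotype concerns stem-fate maintenance (GLP-1 KO,
#' LST-1 / SYGL-1 single and double KO) run in the same niche context;
#' perturbations whose phenotype is failure to enter meiosis (GLD-1 GLD-2
#' double KO and the GLP-1 / LST-1 / SYGL-1 forced-expression experiments)
#' concern cells that would normally differentiate and run in the
#' signal-losing context (`S0 = 0`, DTC active at step 0 only). Outcomes:
#' GLP-1 KO and the lst-1 sygl-1 double KO end in meiotic development;
#' LST-1 or SYGL-1 single KO leave the stem-cell fate unaffected; the GLD-1
#' GLD-2 double KO and all three FE experiments end with meiotic development
#' off.
#'
#' In the `"losing"` and `"reduced"` setups every experiment runs in the
#' corresponding reduced-signal context and the wild-type outcome is meiotic
#' entry; the losing wild type additionally carries the timed observation
#' that the DTC signal, active at step 0, is inactive at step 20.
#'
#' @param setup One of `"niche"`, `"losing"`, `"reduced"`.
#' @param perturbations Character vector of perturbation names (see
#'   [germline_perturbation_names()]); defaults to all eight.
#' @param length Experiment length in states (default 21).
#' @return An [experiment_suite] over the components of
#'   [germline_model]`(setup)`.
#' @export
germline_suite <- function(setup = c("niche", "losing", "reduced"),
                           perturbations = germline_perturbation_names(),
                           length = 21L) {
  setup <- match.arg(setup)
  reg <- .germline_perturbations()
  bad <- setdiff(perturbations, names(reg))
  if (length(bad)) stop("unknown perturbation: ", paste(bad, collapse = ", "))
  net <- germline_model(setup)
  wt_context <- if (setup == "niche") "niche" else "losing"
  wt_outcome <- if (setup == "niche") "stem" else "meiotic"
  wt_extra <- if (setup == "losing") {
    data.frame(time = 20L, component = "DTC", value = FALSE,
               role = "intermediate", stringsAsFactors = FALSE)
  } else NULL
  exps <- list(.germline_experiment("wild_type", net, wt_context,
                                    character(), wt_outcome, length,
                                    extra = wt_extra))
  for (p in perturbations) {
    spec <- reg[[p]]
    context <- if (setup == "niche") spec$context else "losing"
    outcome <- spec$outcome
    if (setup != "niche" && outcome == "stem") outcome <- "meiotic"
    exps <- c(exps, list(.germline_experiment(p, net, context, spec$clamps,
                                              outcome, length)))
  }
  experiment_suite(exps)
}

#' Names of the packaged germline perturbation experiments
#'
#' @return Character vector of the eight knockout / forced-expression
#'   perturbations.
#' @export
germline_perturbation_names <- function() names(.germline_perturbations())

#' Germline synthesis problem
#'
#' Bundles the setup-augmented network with the corresponding experiment
#' suite, ready for [synthesize()].
#'
#' @inheritParams germline_suite
#' @return A list with elements `abn` and `suite`.
#' @export
germline_problem <- function(setup = c("niche", "losing", "reduced"),
                             perturbations = germline_perturbation_names(),
                             length = 21L) {
  setup <- match.arg(setup)
  list(abn = germline_model(setup),
       suite = germline_suite(setup, perturbations, length))
}
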