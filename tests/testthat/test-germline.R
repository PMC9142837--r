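# The packaged germline stem-cell fate network and its experiment suite.

test_that("the core network has the documented roster and counts", {
  net <- germline_abn()
  s <- network_summary(net)
  expect_equal(s$components, 24L)
  expect_equal(s$interactions, 40L)
  expect_equal(s$state_space, 16777216)
  ia <- net$interactions
  has_edge <- function(src, tgt, sign) {
    any(ia$source == src & ia$target == tgt & ia$sign == sign)
  }
  expect_true(has_edge("DTC", "LAG2", TRUE))       # niche ligand induction
  expect_true(has_edge("SEL10", "GLP1ICD", FALSE)) # Notch ICD turnover
  expect_true(has_edge("LAG1", "LST1", TRUE))
  expect_true(has_edge("LAG1", "SYGL1", TRUE))
  # two-state FBF-1: LST-1/SYGL-1 drive the bound form, repress the unbound
  expect_true(has_edge("LST1", "FBF1B", TRUE) && has_edge("LST1", "FBF1U", FALSE))
  expect_true(has_edge("SYGL1", "FBF1B", TRUE) && has_edge("SYGL1", "FBF1U", FALSE))
  expect_true(has_edge("SCF_PROM1", "CYE1_CDK2", FALSE))
})

test_that("the shipped interaction ledger matches the built network", {
  path <- system.file("extdata", "germline_edges.tsv", package = "boolsynth")
  expect_true(nzchar(path))
  tab <- read_interaction_table(path)
  net <- germline_abn()
  key <- function(d) sort(paste(d$source, d$target, d$sign, d$definite))
  expect_identical(key(tab), key(net$interactions))
})

test_that("setup-augmented models add only auxiliary signals", {
  for (s in c("niche", "losing")) {
    m <- germline_model(s)
    expect_equal(nrow(m$components), 25L)
    expect_true("S0" %in% m$components$name)
  }
  r <- germline_model("reduced")
  expect_equal(nrow(r$components), 26L)
  expect_true(all(c("S0", "SD") %in% r$components$name))
})

test_that("classify_regulators reports active repression of the Notch ICD by SEL-10", {
  m <- germline_model("niche")
  cn <- concrete_network(m)
  st <- stats::setNames(rep(FALSE, nrow(m$components)), m$components$name)
  st["SEL10"] <- TRUE
  expect_false(classify_regulators(cn, "GLP1ICD", st)[["repressors"]] == "none")
})

test_that("GLP-1 knockout silences the core Notch pathway under an active niche", {
  p <- germline_problem("niche", perturbations = "glp1_ko")
  res <- synthesize(p$abn, p$suite, limit = 1)
  expect_identical(res$status, "SAT")
  tr <- res$models[[1]]$witnesses[["glp1_ko"]]
  for (g in c("GLP1", "GLP1ICD", "LAG1", "LST1", "SYGL1", "FBF1B"))
    expect_true(all(!tr[, g]))
  # and meiotic entry is reached despite constitutive DTC
  expect_true(all(tr[20:21, "DTC"]))
  expect_true(tr[21, "MeioticDev"])
})

test_that("the full niche suite is satisfiable and witnesses show the fate matrix", {
  p <- germline_problem("niche")
  res <- synthesize(p$abn, p$suite, limit = 10)
  expect_identical(res$status, "SAT")
  expect_gte(length(res$models), 10L)
  final <- function(m, lab, g) m$witnesses[[lab]][21, g]
  for (m in res$models) {
    expect_true(final(m, "wild_type", "StemcellFate"))
    expect_false(final(m, "wild_type", "MeioticDev"))
    expect_true(final(m, "glp1_ko", "MeioticDev"))
    expect_true(final(m, "lst1_sygl1_ko", "MeioticDev"))
    expect_true(final(m, "lst1_ko", "StemcellFate"))
    expect_true(final(m, "sygl1_ko", "StemcellFate"))
    expect_false(final(m, "gld1_gld2_ko", "MeioticDev"))
    expect_false(final(m, "glp1_fe", "MeioticDev"))
  }
})

test_that("in wild-type witnesses FBF-1 occupies its bound state exactly when an effector partner is present at steady state", {
  p <- germline_problem("niche")
  res <- synthesize(p$abn, p$suite, limit = 10)
  for (m in res$models) {
    for (lab in c("wild_type", "lst1_ko", "sygl1_ko")) {
      tr <- m$witnesses[[lab]]
      partner <- tr[21, "LST1"] || tr[21, "SYGL1"]
      expect_true(partner)
      expect_identical(tr[21, "FBF1U"], FALSE)
    }
    wt <- m$witnesses[["wild_type"]]
    expect_true(wt[21, "FBF1B"])
    # and with both partners clamped away, only the unbound form remains
    ko <- m$witnesses[["lst1_sygl1_ko"]]
    expect_false(ko[21, "FBF1B"])
    expect_true(ko[21, "FBF1U"])
  }
})

test_that("exhaustive enumeration of the niche suite finds the full consistent family", {
  p <- germline_problem("niche")
  res <- synthesize(p$abn, p$suite, limit = Inf, witnesses = FALSE,
                    verify = FALSE)
  expect_identical(res$status, "SAT")
  expect_true(res$exhaustive)
  expect_equal(res$n_space, 2048)
  # size of the consistent model family packaged with this reconstruction
  expect_length(res$models, 800L)
})

test_that("single effector knockouts preserve the fate while the double knockout flips it", {
  p <- germline_problem("niche")
  for (lab in c("lst1_ko", "sygl1_ko"))
    expect_identical(test_null_hypothesis(p$abn, p$suite, lab)$status, "UNSAT")
  expect_identical(synthesize(p$abn, p$suite, limit = 1)$status, "SAT")
})

test_that("losing and reduced setups admit consistent networks with meiotic wild-type outcome", {
  for (s in c("losing", "reduced")) {
    p <- germline_problem(s, perturbations = c("glp1_ko", "glp1_fe"))
    res <- synthesize(p$abn, p$suite, limit = 1)
    expect_identical(res$status, "SAT")
    wt <- res$models[[1]]$witnesses[["wild_type"]]
    expect_true(wt[21, "MeioticDev"])
    expect_false(wt[21, "StemcellFate"])
    expect_false(wt[21, "DTC"])  # signal decays away from the niche
  }
})

test_that("perturbation names are validated", {
  expect_error(germline_suite("niche", perturbations = "glp2_ko"),
               "unknown perturbation")
  expect_setequal(germline_perturbation_names(),
                  c("glp1_ko", "lst1_ko", "sygl1_ko", "lst1_sygl1_ko",
                    "gld1_gld2_ko", "glp1_fe", "lst1_fe", "sygl1_fe"))
})
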