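test_that("residual-signal normalization is percent of the DMSO control", {
  expect_equal(normalize_residual(100, 100), 100)
  expect_equal(normalize_residual(0, 100), 0)
  expect_equal(normalize_residual(c(40, 60), 100), 50)  # replicate average
  expect_error(normalize_residual(50, 0), "positive")
  expect_error(normalize_residual(50, -10), "positive")
})

test_that("single-dose triage uses a strict cutoff", {
  res <- c(a = 59.9, b = 60.0, c = 60.1, d = 12)
  expect_identical(triage(res), c("a", "d"))
  expect_length(triage(numeric()), 0L)
  # a generated 47-compound panel with 9 planted below the cutoff
  set.seed(1)
  below <- paste0("hit", 1:9)
  panel <- data.frame(
    compound = c(below, paste0("miss", 1:38)),
    residual = c(runif(9, 10, 59.5), runif(38, 60.5, 110)))
  expect_setequal(triage(panel), below)
})

test_that("4PL fitting is self-consistent and flags undetermined fits", {
  # noise-free data at IC50 = 11 uM: recovered to numerical tolerance
  spec <- assay_gen_spec(true_ic50 = 11e-6, hill_slope = 1.2, top = 90,
                         bottom = 5, noise_cv = 0)
  fit <- fit_dose_response(generate_dose_response(spec))
  expect_true(fit$determined)
  expect_equal(fit$ic50, 11e-6, tolerance = 1e-6)
  expect_equal(fit$hill, 1.2, tolerance = 1e-4)
  expect_equal(fit$top, 90, tolerance = 1e-4)
  expect_equal(fit$bottom, 5, tolerance = 1e-4)

  # monotone-flat signal: flagged, no IC50 claimed
  flat <- data.frame(conc_M = 10^seq(-8, -3, by = 1), signal = 100)
  fit_flat <- fit_dose_response(flat)
  expect_false(fit_flat$determined)
  expect_true(is.na(fit_flat$ic50) || !fit_flat$determined)

  # an inactive compound (IC50 far above the tested range) is flagged
  weak <- generate_dose_response(assay_gen_spec(
    true_ic50 = 1, concentrations = 10^seq(-8, -4, by = 0.5),
    noise_cv = 0.02, seed = 2))
  fit_weak <- fit_dose_response(weak)
  expect_false(fit_weak$determined)
  expect_match(fit_weak$reason, "could not be determined")

  expect_error(fit_dose_response(data.frame(conc_M = c(1e-6, 1e-5),
                                            signal = c(90, 10))),
               "4 distinct")
})

test_that("Cheng-Prusoff conversion uses the printed probe parameters", {
  # DF2: divisor 1 + 3/5 = 1.6
  expect_equal(cheng_prusoff(1.6e-5, protein = "DF2"), 1e-5)
  # DC2: divisor 1 + 3/7
  expect_equal(cheng_prusoff(1e-5, protein = "DC2"), 1e-5 / (1 + 3 / 7))
  # probe concentration -> 0: Kd -> IC50
  p0 <- probe_spec(probe_concentration = 1e-15)
  expect_equal(cheng_prusoff(1e-5, p0, "DF2"), 1e-5, tolerance = 1e-4)
  expect_error(cheng_prusoff(1e-5, protein = "DF1"), "DF1")
  # monotonicity: Kd increases with IC50 and never exceeds it
  ic <- 10^seq(-7, -3, by = 0.5)
  kd <- cheng_prusoff(ic, protein = "DF2")
  expect_true(all(diff(kd) > 0))
  expect_true(all(kd <= ic))
})

test_that("ligand efficiency follows -RT ln(IC50)/HAC", {
  # ln(1) = 0 regardless of size
  expect_equal(suppressWarnings(ligand_efficiency(1, hac = 11)), 0)
  # the thienopyridinone parent: 18 uM at 11 heavy atoms, ~0.59 at 300 K
  expect_equal(ligand_efficiency(18e-6, hac = 11), 0.59, tolerance = 0.01)
  # proportionality: doubling HAC halves LE
  expect_equal(ligand_efficiency(1e-5, hac = 22),
               ligand_efficiency(1e-5, hac = 11) / 2)
  # strictly decreasing in IC50
  le <- ligand_efficiency(10^seq(-7, -4, 0.5), hac = 11)
  expect_true(all(diff(le) < 0))
  # >= 1 M is flagged non-physical
  expect_warning(ligand_efficiency(2, hac = 11), "non-physical")
})

test_that("selectivity ratios reproduce printed fold-changes and bounds", {
  # parent scaffold: Kd 3.8/88/32 uM on DF2/DC2/DC1
  sel <- selectivity(c(DF2 = 3.8e-6, DC2 = 88e-6, DC1 = 32e-6))
  expect_equal(sel$ratio[sel$protein == "DC2"], 88 / 3.8, tolerance = 1e-10)
  expect_equal(sel$ratio[sel$protein == "DC1"], 32 / 3.8, tolerance = 1e-10)
  expect_gte(sel$ratio[sel$protein == "DC2"], 20)
  expect_gte(sel$ratio[sel$protein == "DC1"], 8)

  # equal affinities: all ratios 1
  sel1 <- selectivity(c(DF2 = 1e-5, DC2 = 1e-5, DC1 = 1e-5))
  expect_true(all(sel1$ratio == 1))

  # censored Kd (> 400 uM) propagates as a lower-bound ratio
  selc <- selectivity(data.frame(protein = c("DF2", "DC2"),
                                 kd = c(1.3e-6, 400e-6),
                                 censored = c(FALSE, TRUE)))
  expect_true(selc$censored[selc$protein == "DC2"])
  expect_identical(selc$label[selc$protein == "DC2"], ">308")

  expect_error(selectivity(c(DC2 = 1e-5)), "DF2")
})

test_that("screening summaries round hit rates to whole percent", {
  res <- data.frame(compound = paste0("c", 1:47),
                    active = rep(c(TRUE, FALSE), c(6, 41)))
  expect_identical(screen_summary(res)$hit_rate_percent, 13)
  # SAR-by-catalogue follow-up set: 10 of 28
  res2 <- data.frame(compound = paste0("c", 1:28),
                     active = rep(c(TRUE, FALSE), c(10, 18)))
  expect_identical(screen_summary(res2)$hit_rate_percent, 36)
  expect_identical(
    screen_summary(data.frame(compound = "x", active = FALSE))$hit_rate_percent,
    0)
  expect_error(screen_summary(data.frame(compound = character(),
                                         active = logical())), "no compounds")
  # per-campaign breakdown
  res$campaign <- rep(c("xtal", "md"), length.out = 47)
  s <- screen_summary(res)
  expect_identical(sum(vapply(s$by_campaign, `[[`, numeric(1), "actives")), 6)
})

test_that("panel-level fitting keeps every compound with a status", {
  specs <- list(
    assay_gen_spec(true_ic50 = 2e-6, compound = "cpd23", seed = 11),
    assay_gen_spec(true_ic50 = 1, compound = "dud",
                   concentrations = 10^seq(-8, -4, 0.5), seed = 12))
  panel <- do.call(rbind, lapply(specs, generate_dose_response))
  hac <- c(cpd23 = 19, dud = 12)
  tab <- fit_affinity_panel(panel, hac = hac)
  expect_setequal(tab$compound, c("cpd23", "dud"))
  expect_identical(tab$status[tab$compound == "cpd23"], "ok")
  expect_match(tab$status[tab$compound == "dud"],
               "could not be determined|did not converge")
  # FP route got a Cheng-Prusoff Kd and an LE
  ok <- tab[tab$compound == "cpd23", ]
  expect_equal(ok$kd_M, ok$ic50_M / 1.6, tolerance = 1e-12)
  expect_gt(ok$le, 0)
})

test_that("generate -> fit -> Cheng-Prusoff round-trips the Kd within 15%", {
  true_kd <- 1.3e-6
  hits <- vapply(1:5, function(s) {
    spec <- assay_gen_spec(true_ic50 = true_kd * 1.6, noise_cv = 0.02,
                           n_replicates = 4,
                           concentrations = true_kd * 1.6 *
                             10^seq(-2.25, 2.25, by = 0.5),
                           seed = 100 + s)
    fit <- fit_dose_response(generate_dose_response(spec))
    kd <- cheng_prusoff(fit$ic50, protein = "DF2")
    abs(kd - true_kd) / true_kd < 0.15
  }, logical(1))
  expect_true(all(hits))
})
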