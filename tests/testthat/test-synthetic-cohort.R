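test_that("a fixed seed reproduces the cohort bitwise", {
  p <- simulation_params(seed = 7)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(simulation_params(seed = 8))
  expect_false(identical(c1$calls, c3$calls))
})

test_that("degenerate architecture rates yield an all-branch cohort", {
  p <- simulation_params(n_patients = 30,
                         clonality_rates = c(trunk = 0, shared = 0,
                                             private = 1.2),
                         seed = 3)
  co <- simulate_cohort(p)
  s <- summarize_clonality(co)
  expect_equal(unname(s$label_percent["branch"]), 100)
  expect_true(all(co$truth$true_label == "branch"))
})

test_that("impossible shared events are announced, not silently dropped", {
  p <- simulation_params(n_patients = 5,
                         lesion_count_probs = c("2" = 1, "3" = 0), seed = 1)
  expect_message(simulate_cohort(p), "no shared events")
})

test_that("the classifier recovers the generator's labels exactly", {
  for (seed in 1:5) {
    co <- simulate_cohort(simulation_params(seed = seed))
    s <- summarize_clonality(co)
    lab <- do.call(rbind, lapply(s$per_patient, function(pc) {
      if (nrow(pc$labels) == 0) return(NULL)
      data.frame(patient_id = pc$patient_id, key = pc$labels$key,
                 label = pc$labels$label, stringsAsFactors = FALSE)
    }))
    m <- merge(co$truth, lab, by = c("patient_id", "key"))
    expect_equal(nrow(m), nrow(co$truth))
    expect_true(all(m$true_label == m$label))
  }
})

test_that("empirical trunk share agrees with an independent re-simulation", {
  p <- simulation_params(n_patients = 300, seed = 21)
  co <- simulate_cohort(p)
  trunk_share <- mean(co$truth$true_label == "trunk")
  ## oracle: a ten-fold larger, independently seeded run of the same process
  p_big <- simulation_params(n_patients = 3000, seed = 22)
  big <- simulate_cohort(p_big)
  oracle_share <- mean(big$truth$true_label == "trunk")
  se <- sqrt(oracle_share * (1 - oracle_share) / nrow(co$truth))
  expect_lt(abs(trunk_share - oracle_share), 3 * se)
})

test_that("the programmed EGFR sex effect is recovered across seeds", {
  positive <- vapply(1:20, function(seed) {
    co <- simulate_cohort(simulation_params(n_patients = 200, seed = seed))
    pt <- patient_table(co)
    has_egfr <- vapply(pt$patient_id, function(p)
      any(co$calls$patient_id == p & co$calls$gene == "EGFR"), logical(1))
    mean(has_egfr[pt$sex == "female"]) > mean(has_egfr[pt$sex == "male"])
  }, logical(1))
  expect_gte(mean(positive), 0.95)
})

test_that("the deterministic fixture meets every required constraint", {
  fx <- generate_study_fixture()
  expect_identical(fx$calls, generate_study_fixture()$calls)  # no RNG
  pt <- patient_table(fx)
  expect_equal(nrow(pt), 42)
  expect_equal(nrow(fx$clinical), 93)
  expect_equal(sum(pt$n_lesions == 2), 33)
  expect_equal(sum(pt$n_lesions == 3), 9)
  report <- validate_fixture(fx)
  required <- report[report$tier == "required", ]
  expect_true(all(required$pass))
  expect_true(attr(report, "overall"))
})

test_that("the validator names a broken constraint instead of erroring", {
  fx <- generate_study_fixture()
  ## P34-T2 carries a single EGFR event; dropping it removes one EGFR lesion
  drop <- which(fx$calls$patient_id == "P34" & fx$calls$lesion_id == "T2")
  expect_length(drop, 1)
  fx$calls <- fx$calls[-drop, ]
  report <- validate_fixture(fx)
  egfr_row <- report[report$id == "egfr_tumours", ]
  expect_false(egfr_row$pass)
  expect_equal(egfr_row$observed, "56")
  expect_false(attr(report, "overall"))  # trunk constraint breaks too
})

test_that("the validator reports cleanly on a simulated cohort", {
  co <- simulate_cohort(simulation_params(seed = 12))
  report <- validate_fixture(co)
  expect_s3_class(report, "fixture_validation")
  expect_true(all(c("id", "tier", "expected", "observed", "pass") %in%
                    names(report)))
  expect_false(attr(report, "overall"))   # failures are data, not exceptions
})

test_that("worked patient profiles are embedded verbatim in the fixture", {
  fx <- generate_study_fixture()
  p20 <- fx$calls[fx$calls$patient_id == "P20", ]
  expect_equal(nrow(p20), 2)
  expect_true(all(p20$gene == "EGFR" & p20$alteration == "L858R"))
  p9 <- fx$calls[fx$calls$patient_id == "P9", ]
  expect_setequal(paste(p9$lesion_id, p9$gene, p9$alteration),
                  c("T1 KRAS G12V", "T1 TP53 H193Y", "T1 A1CF-RET fusion",
                    "T2 KRAS G12C"))
})

test_that("cohort TSVs round-trip through the readers", {
  dir <- tempfile()
  fx <- generate_study_fixture()
  paths <- write_cohort(fx, dir)
  clin <- read_clinical_table(paths["clinical"])
  calls <- read_variant_table(paths["variants"])
  co2 <- attach_calls(clin, calls)
  expect_equal(co2$calls$vaf, fx$calls$vaf)
  expect_equal(nrow(co2$clinical), 93)
  s <- summarize_clonality(co2)
  expect_equal(unname(s$label_counts), c(5, 4, 92))
})
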