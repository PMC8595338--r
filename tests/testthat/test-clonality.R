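fx <- generate_study_fixture()

test_that("event matrix holds distinct events against lesions", {
  m <- build_event_matrix(fx, "P25")
  expect_equal(dim(m$presence), c(3, 3))
  l858r <- event_key("EGFR", "L858R", "nonsynonymous_SNV")
  expect_equal(unname(m$presence[l858r, ]),
               m$lesions %in% c("T1", "T3"))
  ## wild-type pair: 0 x 2 matrix
  m19 <- build_event_matrix(fx, "P19")
  expect_equal(dim(m19$presence), c(0, 2))
  single <- attach_calls(make_clinical("P1", 1))
  expect_error(build_event_matrix(single, "P1"), "fewer than 2 lesions")
})

test_that("worked patients classify to their published architecture", {
  p27 <- classify_events(build_event_matrix(fx, "P27"))
  expect_equal(unname(p27$counts), c(1, 0, 2))
  expect_equal(p27$concordance, "discordant")
  trunk27 <- p27$labels[p27$labels$label == "trunk", ]
  expect_equal(paste(trunk27$gene, trunk27$alteration), "EGFR 19del")

  p20 <- classify_events(build_event_matrix(fx, "P20"))
  expect_equal(unname(p20$counts), c(1, 0, 0))
  expect_equal(p20$concordance, "concordant_mutant")

  p9 <- classify_events(build_event_matrix(fx, "P9"))
  expect_equal(unname(p9$counts), c(0, 0, 4))
  expect_equal(p9$concordance, "discordant")

  p25 <- classify_events(build_event_matrix(fx, "P25"))
  shared <- p25$labels[p25$labels$label == "shared", ]
  expect_equal(paste(shared$gene, shared$alteration), "EGFR L858R")
})

test_that("two-lesion patients can never carry shared events", {
  set.seed(11)
  for (i in 1:50) {
    co <- cohort_from_presence(random_presence(sample(1:6, 1), 2))
    pc <- classify_events(build_event_matrix(co, "PX"))
    expect_equal(unname(pc$counts["shared"]), 0L)
  }
})

test_that("labels agree with brute-force carrier-set logic on random matrices", {
  set.seed(42)
  for (i in 1:1000) {
    n_lesions <- sample(2:4, 1)
    presence <- random_presence(sample(1:8, 1), n_lesions)
    co <- cohort_from_presence(presence)
    pc <- classify_events(build_event_matrix(co, "PX"))
    ## oracle: compare each event's carrier set with the lesion set
    oracle <- apply(presence, 1, function(row) {
      carriers <- which(row)
      if (length(carriers) == n_lesions) "trunk"
      else if (length(carriers) == 1) "branch"
      else "shared"
    })
    key_order <- order(paste0("M", seq_len(nrow(presence)), "X"))
    expect_equal(pc$labels$label, oracle[key_order])
    ## conservation
    expect_equal(sum(pc$counts), nrow(presence))
    ## concordance consistency
    if (pc$concordance == "concordant_mutant")
      expect_equal(unname(pc$counts["shared"] + pc$counts["branch"]), 0L)
  }
})

test_that("adding a private event never relabels existing events", {
  set.seed(7)
  for (i in 1:50) {
    presence <- random_presence(4, 3)
    co <- classify_events(build_event_matrix(cohort_from_presence(presence), "PX"))
    grown <- rbind(presence, c(TRUE, FALSE, FALSE))
    co2 <- classify_events(build_event_matrix(cohort_from_presence(grown), "PX"))
    before <- setNames(co$labels$label, co$labels$key)
    after <- setNames(co2$labels$label, co2$labels$key)
    expect_equal(after[names(before)], before)
  }
})

test_that("cohort summary reproduces the fixture's published proportions", {
  s <- summarize_clonality(fx)
  expect_equal(unname(s$label_counts), c(5, 4, 92))
  expect_equal(s$n_events, 101)
  expect_equal(unname(s$label_percent), c(4.95, 3.96, 91.09))
  expect_equal(s$percent_discordant, 92.9)
  expect_equal(s$percent_matched, 2.4)
  expect_equal(unname(s$concordance_counts["discordant"]), 39)
  ## both denominators surfaced: distinct events and per-lesion calls
  expect_equal(s$n_calls, 110)
  expect_equal(s$n_gene_mutation_calls, 108)
  expect_equal(unname(s$architecture), c(4, 4, 1, 33))
})

test_that("an all-trunk toy cohort is 100% trunk and fully concordant", {
  clinical <- make_clinical(c("A", "B"), c(2, 2))
  calls <- make_calls(list("A", "T1", "EGFR", "L858R"),
                      list("A", "T2", "EGFR", "L858R"),
                      list("B", "T1", "KRAS", "G12C"),
                      list("B", "T2", "KRAS", "G12C"))
  s <- summarize_clonality(attach_calls(clinical, calls))
  expect_equal(unname(s$label_percent["trunk"]), 100)
  expect_equal(s$percent_discordant, 0)
  empty <- structure(list(clinical = make_clinical("Z", 2)[0, ],
                          calls = mplaclone:::empty_calls(),
                          provenance = list()),
                     class = "mpla_cohort")
  expect_error(summarize_clonality(empty), "empty")
})

test_that("VAF comparison recovers class medians and rank-sum p-values", {
  v <- compare_vaf_by_class(fx)
  expect_equal(unname(v$medians), c(0.164, 0.091, 0.086))
  expect_true(v$medians["trunk"] > v$medians["shared"])
  expect_true(v$medians["shared"] > v$medians["branch"])
  expect_equal(nrow(v$tests), 3)

  ## identical VAF vectors in two classes -> p = 1
  clinical <- make_clinical("A", 2)
  calls <- make_calls(list("A", "T1", "G1", "M1X", "nonsynonymous_SNV", 0.2),
                      list("A", "T2", "G1", "M1X", "nonsynonymous_SNV", 0.2),
                      list("A", "T1", "G2", "M2X", "nonsynonymous_SNV", 0.2))
  v2 <- suppressMessages(compare_vaf_by_class(attach_calls(clinical, calls)))
  expect_equal(v2$tests$p_value[v2$tests$pair == "trunk_vs_branch"], 1)

  ## a class with no observations is skipped with a notice
  calls3 <- make_calls(list("A", "T1", "G2", "M2X", "nonsynonymous_SNV", 0.1))
  expect_message(
    v3 <- compare_vaf_by_class(attach_calls(clinical, calls3)), "skipped")
  expect_true("trunk_vs_shared" %in% v3$skipped)
})

test_that("well-separated VAF classes give the exact enumerated rank-sum p", {
  trunk_vafs <- seq(0.36, 0.45, by = 0.01)    # n = 10, distinct, no ties
  branch_vafs <- seq(0.06, 0.15, by = 0.01)
  res <- wilcoxon_rank_sum(trunk_vafs, branch_vafs)
  expect_true(res$exact)
  expect_equal(res$p_value, ranksum_oracle(trunk_vafs, branch_vafs))
  expect_true(res$U == length(trunk_vafs) * length(branch_vafs))
})
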