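fx <- generate_study_fixture()

test_that("topology enumeration matches the double-factorial count", {
  expect_length(enumerate_topologies(c("T1", "T2")), 1)       # k=3
  expect_length(enumerate_topologies(c("T1", "T2", "T3")), 3) # k=4
  expect_length(enumerate_topologies(paste0("T", 1:5)), 105)  # k=6
  expect_error(enumerate_topologies("T1"), "3 to 8 taxa")
  expect_error(enumerate_topologies(paste0("T", 1:8)), "3 to 8 taxa")
})

test_that("forced assignments: trunk on the root edge, private on the leaf", {
  clinical <- make_clinical("A", 2)
  calls <- make_calls(list("A", "T1", "G1", "TRK", "nonsynonymous_SNV"),
                      list("A", "T2", "G1", "TRK", "nonsynonymous_SNV"),
                      list("A", "T2", "G2", "PRV", "nonsynonymous_SNV"))
  tr <- build_parsimony_tree(attach_calls(clinical, calls), "A")
  expect_equal(tr$score, 2)
  expect_equal(tr$trunk_events, event_key("G1", "TRK", "nonsynonymous_SNV"))
  prv <- tr$assignments[tr$assignments$key ==
                          event_key("G2", "PRV", "nonsynonymous_SNV"), ]
  leaf_label <- tr$edges$tip_label[tr$edges$edge == prv$edge]
  expect_equal(leaf_label, "T2")
})

test_that("P25's tree groups T1 and T3 with the shared L858R on their stem", {
  tr <- build_parsimony_tree(fx, "P25")
  expect_equal(tr$score, 3)
  expect_equal(tr$n_mpt, 1)
  expect_match(tr$newick, "\\(T1:0,T3:1\\)")
  expect_length(tr$trunk_events, 0)
  l858r <- event_key("EGFR", "L858R", "nonsynonymous_SNV")
  edge <- tr$assignments$edge[tr$assignments$key == l858r]
  ## the L858R gain sits on an internal, non-root-incident edge
  expect_false(edge == 3L)
  expect_true(is.na(tr$edges$tip_label[tr$edges$edge == edge]))
})

test_that("P27 carries its 19del on the trunk and two TP53 events on T1", {
  tr <- build_parsimony_tree(fx, "P27")
  expect_equal(tr$trunk_events,
               event_key("EGFR", "19del", "nonframeshift_deletion"))
  t1_edge <- tr$edges$edge[!is.na(tr$edges$tip_label) &
                             tr$edges$tip_label == "T1"]
  expect_equal(sum(tr$assignments$edge == t1_edge), 2)
  expect_equal(tr$edges$length[tr$edges$edge == t1_edge], 2)
})

test_that("wild-type pairs give zero-length trees; P20 the hand-derived Newick", {
  tr19 <- build_parsimony_tree(fx, "P19")
  expect_equal(tr19$score, 0)
  expect_true(all(tr19$edges$length == 0))
  tr20 <- build_parsimony_tree(fx, "P20")
  expect_equal(tr20$newick, "((T1:0,T2:0):1,germline:0);")
})

test_that("purely private three-lesion data leaves all topologies tied", {
  clinical <- make_clinical("A", 3)
  calls <- make_calls(list("A", "T1", "G1", "M1X"),
                      list("A", "T2", "G2", "M2X"),
                      list("A", "T3", "G3", "M3X"))
  tr <- build_parsimony_tree(attach_calls(clinical, calls), "A")
  expect_equal(tr$n_mpt, 3)     # every 4-taxon topology is equally good
  expect_equal(tr$score, 3)
})

test_that("scores match the exhaustive internal-labeling oracle", {
  set.seed(99)
  for (i in 1:150) {
    n_lesions <- sample(2:4, 1)    # up to 5 taxa with the germline
    presence <- random_presence(sample(1:6, 1), n_lesions)
    co <- cohort_from_presence(presence)
    m <- build_event_matrix(co, "PX")
    topologies <- enumerate_topologies(m$lesions)
    for (top in topologies[sample(length(topologies),
                                  min(3, length(topologies)))]) {
      sc <- score_tree(top, m)
      flat <- mplaclone:::flatten_topology(top, m$lesions)
      oracle <- sum(vapply(seq_len(nrow(m$presence)), function(r) {
        st <- as.list(as.integer(m$presence[r, ]))
        names(st) <- m$lesions
        parsimony_oracle(flat, st)
      }, numeric(1)))
      expect_equal(sc$score, oracle)
    }
    ## score bound: at least one change per distinct event
    tr <- build_parsimony_tree(co, "PX")
    expect_gte(tr$score, nrow(presence))
  }
})

test_that("trunk-edge assignment is equivalent to the trunk clonality label", {
  for (seed in 1:10) {
    co <- simulate_cohort(simulation_params(n_patients = 20, seed = seed))
    s <- summarize_clonality(co)
    for (pc in s$per_patient) {
      if (nrow(pc$labels) == 0) next
      tr <- build_parsimony_tree(co, pc$patient_id)
      expect_setequal(tr$trunk_events,
                      pc$labels$key[pc$labels$label == "trunk"])
    }
  }
})

test_that("Newick output is deterministic and parseable round-trip", {
  skip_if_not_installed("ape")
  tr1 <- build_parsimony_tree(fx, "P25")
  tr2 <- build_parsimony_tree(fx, "P25")
  expect_identical(tr1$newick, tr2$newick)
  ph <- ape::read.tree(text = tr1$newick)
  expect_setequal(ph$tip.label, c("germline", "T1", "T2", "T3"))
  expect_equal(sum(ph$edge.length), tr1$score)
  ## clade (T1, T3) is preserved through parsing
  mrca <- ape::getMRCA(ph, c("T1", "T3"))
  desc <- ape::extract.clade(ph, mrca)$tip.label
  expect_setequal(desc, c("T1", "T3"))
})
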