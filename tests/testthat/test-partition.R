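test_that("systemic score reproduces the SJIA scoring table at every level", {
  expect_equal(score_systemic(character()), 0L)
  # any single mild feature scores 1
  for (f in c("rash", "fever_lt10d", "esr_40_90", "plt_gt450k")) {
    expect_equal(score_systemic(f), 1L)
  }
  # at least three moderate features score 2
  expect_equal(score_systemic(c("rash", "fever_gt10d", "wbc_gt20k")), 2L)
  expect_equal(score_systemic(c("esr_gt90", "plt_gt550k", "ddimer_250_500",
                                "elevated_fibrinogen")), 2L)
  # two moderate features are not enough (rash alone is still mild)
  expect_equal(score_systemic(c("fever_gt10d", "wbc_gt20k")), 0L)
  expect_equal(score_systemic(c("rash", "wbc_gt20k")), 1L)
  # any severe feature dominates
  for (f in c("pneumonitis", "pericarditis", "pleural_effusion", "MAS")) {
    expect_equal(score_systemic(f), 3L)
    expect_equal(score_systemic(c(f, "rash", "fever_gt10d", "wbc_gt20k")), 3L)
  }
  expect_error(score_systemic("rash", disease = "POLY"), "SJIA")
  expect_error(score_systemic("not_a_feature"), "unknown systemic feature")
})

test_that("arthritis scores map every joint-count boundary correctly", {
  sjia_expect <- c(`0` = "A", `1` = "B", `4` = "B", `5` = "C", `10` = "C",
                   `11` = "D", `20` = "D", `21` = "D")
  poly_expect <- c(`0` = "0", `1` = "1", `4` = "1", `5` = "1", `10` = "1",
                   `11` = "2", `20` = "2", `21` = "3")
  for (jc in names(sjia_expect)) {
    expect_equal(score_arthritis(as.numeric(jc), "SJIA"), unname(sjia_expect[jc]))
    expect_equal(score_arthritis(as.numeric(jc), "POLY"), unname(poly_expect[jc]))
  }
})

test_that("flare classification follows the disease-specific rules", {
  cl <- clinical_table(
    sample_id = paste0("S", 1:6),
    disease = c("SJIA", "SJIA", "SJIA", "POLY", "POLY", "SJIA"),
    esr = c(50, 10, 10, 30, 5, 10),
    joint_count = c(0, 6, 0, 3, 0, 1),
    systemic_features = c("esr_40_90", "", "", "", "", "")
  )
  cs <- classify_state(cl)
  # systemic feature alone, JC >= 5 alone, and neither
  expect_equal(cs$state[1:3], c("F", "F", "Q"))
  # POLY: any active joint flares
  expect_equal(cs$state[4:5], c("F", "Q"))
  # SJIA with one joint and no systemic features: quiescent under jc5 rule
  expect_equal(cs$state[6], "Q")
  # ...but flare under the literal arthritis-score >= B reading
  expect_equal(classify_state(cl, "literal_b")$state[6], "F")
})

test_that("pre-assigned states override derivation with a logged discrepancy", {
  cl <- clinical_table(sample_id = c("S1", "S2"), disease = "SJIA",
                       esr = c(50, 50), joint_count = c(9, 9),
                       systemic_features = "rash", state = c("F", "Q"))
  expect_warning(cs <- classify_state(cl), "S2")
  expect_equal(cs$state, c("F", "Q"))
  expect_equal(cs$state_derived, c("F", "F"))
  expect_equal(cs$state_discrepancy, c(FALSE, TRUE))
})

test_that("ESR partition splits flares at the cutoff, boundary going to F2", {
  cl <- clinical_table(sample_id = paste0("S", 1:6), disease = "SJIA",
                       esr = c(5, 15, 25, 81, 20, 3),
                       joint_count = c(6, 6, 6, 6, 6, 0),
                       systemic_features = "")
  state <- c("F", "F", "F", "F", "F", "Q")
  part <- partition_by_esr(cl, state)
  expect_equal(unname(part), c("F1", "F1", "F2", "F2", "F2", "Q"))

  cl_na <- clinical_table(sample_id = "S1", disease = "SJIA", esr = NA,
                          joint_count = 9, systemic_features = "rash")
  expect_warning(p2 <- partition_by_esr(cl_na, "F"), "missing ESR")
  expect_true(is.na(p2[["S1"]]))
})

test_that("an all-quiescent cohort leaves F2 empty and breaks the t-test grouping", {
  cl <- clinical_table(sample_id = paste0("S", 1:8), disease = "SJIA",
                       esr = rep(5, 8), joint_count = rep(0, 8),
                       systemic_features = "")
  g <- sample_grouping(cl)
  expect_true(all(g$esr_partition == "Q"))
  set.seed(1)
  x <- expr_matrix(matrix(2^rnorm(40), 5, 8,
                          dimnames = list(paste0("G", 1:5), cl$sample_id)),
                   "G1", "normalized")
  expect_error(
    ttest_track(log2_expr(x),
                group_high = g$sample_id[g$esr_partition == "F2"],
                group_low = g$sample_id[g$esr_partition %in% c("F1", "Q")]),
    ">= 2 samples")
})

test_that("SAF/AF subgrouping follows systemic score and joint count", {
  cl <- clinical_table(
    sample_id = paste0("S", 1:5),
    disease = c("SJIA", "SJIA", "SJIA", "SJIA", "POLY"),
    esr = c(50, 12, 12, 5, 40),
    joint_count = c(10, 12, 0, 0, 20),
    systemic_features = c("rash;fever_lt10d", "", "MAS", "", "")
  )
  cs <- classify_state(cl)
  saf <- partition_saf_af(cl, cs$state, cs$systemic_score)
  expect_equal(unname(saf),
               c("SAF", "AF", "not_applicable", "not_applicable", "not_applicable"))
})

test_that("grouping labels are exhaustive, exclusive and state-monotone", {
  co <- generate_cohort(simulation_design(seed = 13))
  g <- sample_grouping(co$clinical)
  expect_true(all(g$state %in% c("F", "Q")))
  expect_true(all(g$esr_partition %in% c("F1", "F2", "Q")))
  expect_identical(g$esr_partition == "Q", g$state == "Q")
  expect_true(all(g$saf_af[g$state == "Q"] == "not_applicable"))
  expect_true(all(g$saf_af[g$disease == "POLY"] == "not_applicable"))

  # monotonicity: raising JC or adding features never demotes F to Q
  cl <- co$clinical
  base <- classify_state(cl)$state_derived
  cl2 <- cl
  cl2$joint_count <- cl2$joint_count + 5
  cl2$state <- NA_character_
  up_jc <- classify_state(cl2)$state_derived
  expect_true(all(!(base == "F" & up_jc == "Q")))
  cl3 <- cl
  cl3$systemic_features <- ifelse(cl3$disease == "SJIA",
                                  paste0(cl3$systemic_features,
                                         ifelse(nzchar(cl3$systemic_features), ";", ""),
                                         "rash"),
                                  cl3$systemic_features)
  cl3$state <- NA_character_
  up_feat <- classify_state(cl3)$state_derived
  expect_true(all(!(base == "F" & up_feat == "Q")))
})
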