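test_that("the COS share statistic matches published values and its identities", {
  expect_equal(round(cos_share(3.68, 0.08), 2), 0.98)
  expect_equal(cos_share(1.92, 0), 1)
  expect_equal(cos_share(2.5, 2.5), 0.5)
  expect_error(cos_share(0, 0), "absent")
  expect_error(cos_share(-1, 2), "non-negative")
  # complement identity over random pairs
  set.seed(1)
  a <- runif(50); b <- runif(50)
  expect_equal(cos_share(a, b) + cos_share(b, a), rep(1, 50))
  expect_true(all(cos_share(a, b) >= 0 & cos_share(a, b) <= 1))
})

test_that("the ROS rule drops only strictly-more-than-1/10 ROS presence", {
  cfg <- filter_config()
  expect_true(ros_exclusion(0, 5, cfg))
  expect_false(ros_exclusion(0.5, 4.0, cfg))  # 0.5 > 0.4: drop
  expect_true(ros_exclusion(0.4, 4.0, cfg))   # exactly 1/10: keep
})

test_that("the abundance floor drops only strictly-below-1/100 candidates", {
  cfg <- filter_config()
  expect_true(abundance_floor(0.29, 28.3, cfg))   # 0.29 >= 0.283
  expect_false(abundance_floor(0.28, 28.3, cfg))  # 0.28 < 0.283
  expect_true(abundance_floor(5, 5, cfg))
  expect_error(abundance_floor(1, 0, cfg), "positive")
})

test_that("the published candidate list is retained in full with printed shares", {
  ref <- cos_reference_candidates()
  cand <- build_candidate_list(reference_fraction_table(),
                               reference_annotations(),
                               share = ref$share_printed)
  expect_equal(nrow(cand), 48L)
  expect_equal(cand$protein_id[1], "creatine kinase b-type")
  expect_equal(cand$share[1], 1)
  # every published row passes both stated retention rules
  expect_true(all(ref$share_printed >= 0.8))
  expect_true(all(ref$empai_cos >= max(ref$empai_cos) / 100))
})

test_that("ties at share 1 order by COS emPAI descending", {
  cand <- build_candidate_list(reference_fraction_table(),
                               share = cos_reference_candidates()$share_printed)
  ones <- cand[cand$share == 1, ]
  expect_true(all(diff(ones$empai_cos) <= 0))
  i_arf <- match("ADP-ribosylation factor 1", cand$protein_id)
  i_rd3 <- match("protein RD3", cand$protein_id)
  expect_lt(i_arf, i_rd3)  # 1.34 before 1.04
})

test_that("proteins present only in the CIS fraction yield an empty list", {
  tab <- data.frame(protein_id = "cis_only", ROS = 0, RIS = 0, COS = 0,
                    CIS = 2.0)
  cand <- build_candidate_list(tab)
  expect_equal(nrow(cand), 0L)
  all_rec <- attr(cand, "all_records")
  expect_equal(all_rec$exclusion_reason, "low_share")
})

test_that("proteins absent from both scored fractions are set aside silently", {
  tab <- data.frame(protein_id = c("a", "b"), ROS = c(1, 0), RIS = 0,
                    COS = c(0, 2), CIS = c(0, 0))
  expect_message(cand <- build_candidate_list(tab), "not scored")
  expect_equal(attr(cand, "n_unscored"), 1L)
  expect_equal(cand$protein_id, "b")
})

test_that("tightening any threshold never adds a candidate", {
  tab <- reference_fraction_table()
  tab$ROS <- seq(0, 0.4, length.out = nrow(tab))  # some ROS presence
  base <- build_candidate_list(tab)
  tighter <- list(
    filter_config(share_report_min = 0.9),
    filter_config(ros_ratio_max = 0.05),
    filter_config(abundance_floor_frac = 0.05)
  )
  for (cfg in tighter) {
    got <- build_candidate_list(tab, config = cfg)
    expect_true(all(got$protein_id %in% base$protein_id))
    expect_lte(nrow(got), nrow(base))
  }
})

test_that("filtering its own retained output is idempotent", {
  tab <- reference_fraction_table()
  tab$ROS <- c(rep(0.02, 24), rep(0, 24))
  first <- build_candidate_list(tab)
  rt <- data.frame(protein_id = first$protein_id, ROS = 0, RIS = 0,
                   COS = first$empai_cos, CIS = first$empai_cis)
  second <- build_candidate_list(rt)
  expect_setequal(second$protein_id, first$protein_id)
})

test_that("annotation classes are counted and unknown classes rejected", {
  ref <- cos_reference_candidates()
  cand <- build_candidate_list(reference_fraction_table(),
                               reference_annotations(),
                               share = ref$share_printed)
  counts <- classify_candidates(cand)
  expect_equal(unname(counts["known_cos_specific"]), 8L)
  expect_equal(unname(counts["known_elsewhere"]), 16L)
  expect_equal(unname(counts["unassigned"]), 24L)
  expect_equal(sum(counts), nrow(cand))

  plain <- build_candidate_list(reference_fraction_table(),
                                share = ref$share_printed)
  expect_equal(unname(classify_candidates(plain)["unassigned"]), 48L)
  expect_equal(sum(classify_candidates(plain[0, ])), 0L)

  bad_ann <- data.frame(protein_id = "creatine kinase b-type",
                        annotation_class = "mystery")
  expect_error(build_candidate_list(reference_fraction_table(), bad_ann),
               "mystery")
})

test_that("the ROS volume correction rescales before the 1/10 comparison", {
  tab <- data.frame(protein_id = "p", ROS = 0.3, RIS = 0, COS = 2, CIS = 0)
  kept <- build_candidate_list(tab)  # 0.3 > 0.2 with ratio 1: dropped
  expect_equal(nrow(kept), 0L)
  kept2 <- build_candidate_list(
    tab, config = filter_config(ros_cos_volume_ratio = 0.5))
  expect_equal(nrow(kept2), 1L)  # 0.15 <= 0.2: kept
})
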