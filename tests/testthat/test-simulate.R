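test_that("simulation is fully deterministic given the seed", {
  cfg <- sim_config(n_per_group = c(schizophrenia = 5, bipolar = 5,
                                    control = 6),
                    n_regions = 20, seed = 61)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$thickness, co2$thickness)
  expect_identical(co1$metadata, co2$metadata)
  co3 <- simulate_cohort(sim_config(n_per_group = c(schizophrenia = 5,
                                                    bipolar = 5, control = 6),
                                    n_regions = 20, seed = 62))
  expect_false(identical(co1$thickness, co3$thickness))

  # written files are byte-identical across reruns
  tdir <- withr::local_tempdir()
  write_cohort(co1, file.path(tdir, "t1.tsv"), file.path(tdir, "m1.tsv"))
  write_cohort(co2, file.path(tdir, "t2.tsv"), file.path(tdir, "m2.tsv"))
  expect_identical(unname(tools::md5sum(file.path(tdir, "t1.tsv"))),
                   unname(tools::md5sum(file.path(tdir, "t2.tsv"))))
})

test_that("simulated cohorts respect the configured shapes and ranges", {
  co <- simulate_cohort(sim_config(seed = 63, score_effect = 0))
  expect_equal(dim(co$thickness), c(108, 148))
  expect_equal(as.integer(table(co$metadata$group)[c("schizophrenia",
                                                     "bipolar", "control")]),
               c(39L, 37L, 32L))
  expect_true(all(co$thickness > 0))
  expect_true(all(is.na(co$metadata$medication_dose[
    co$metadata$group == "control"])))
  expect_true(all(is.finite(co$metadata$premorbid_iq)))
  gt <- co$ground_truth
  expect_equal(dim(gt$planted_offsets), dim(co$thickness))
  # controls carry no planted offsets
  expect_true(all(gt$planted_offsets[co$metadata$group == "control", ] == 0))
})

test_that("planted deviation heterogeneity moves group means the expected way", {
  dev <- c(schizophrenia = 0.8, bipolar = 0.8, control = 0)
  co <- simulate_cohort(sim_config(deviation_sd = dev, score_effect = 0,
                                   seed = 64))
  b <- build_cohort_scns(co)
  m <- cohort_metrics(b$scns)
  pat <- co$metadata$group != "control"
  expect_lt(mean(m$global$strength[pat]), mean(m$global$strength[!pat]))
  expect_lt(mean(m$global$clustering[pat]), mean(m$global$clustering[!pat]))
  expect_lt(mean(m$global$efficiency[pat]), mean(m$global$efficiency[!pat]))
  expect_gt(mean(m$global$path_length[pat]), mean(m$global$path_length[!pat]))
})

test_that("with leave-one-out scoring an unplanted cohort shows no group effect", {
  # deviation_sd = 0 for everyone: with each control scored against the other
  # controls, patients and controls are exchangeable and the comparison
  # should stay null (the default in-sample scoring is deliberately not used
  # here; see the vignette's discussion of the normative-reference bias)
  nsig <- sapply(1:8, function(s) {
    co <- simulate_cohort(sim_config(
      deviation_sd = c(schizophrenia = 0, bipolar = 0, control = 0),
      score_effect = 0, seed = 6400 + s))
    b <- build_cohort_scns(co, control_scoring = "loo")
    m <- cohort_metrics(b$scns)
    cmp <- compare_global(m$global, co$metadata$group,
                          co$metadata$premorbid_iq)
    sum(cmp$omnibus$p_fdr < 0.05)
  })
  expect_lte(mean(nsig > 0), 0.25)   # loose small-sample bound on a 5% rate
})

test_that("the planted score-index correlation is recovered", {
  rec <- sapply(1:8, function(s) {
    co <- simulate_cohort(sim_config(seed = 6500 + s))
    b <- build_cohort_scns(co)
    bd <- which(co$metadata$group == "bipolar")
    reg <- co$ground_truth$score$index$region
    cc <- sapply(bd, function(i) nodal_clustering(b$scns[[i]])[[reg]])
    md <- co$metadata[bd, ]
    partial_correlation(cc, md$ymrs,
                        cbind(md$medication_dose, md$illness_duration))$r
  })
  expect_lt(abs(median(rec) - 0.45), 0.2)
})

test_that("the worked fixture is tiny, valid and hand-checkable", {
  fx <- make_worked_fixture()
  expect_equal(dim(fx$cohort$thickness), c(10, 5))
  expect_equal(as.integer(table(fx$cohort$metadata$group)[c("groupA",
                                                            "groupB",
                                                            "control")]),
               c(3L, 3L, 4L))
  W0 <- build_scn(fx$deviations$zero)
  expect_true(all(W0[row(W0) != col(W0)] == 1))
  W1 <- build_scn(fx$deviations$unit_region2)
  expect_equal(unname(W1[2, -2]), rep(exp(-1), 4))
  expect_equal(unname(W1[1, 3]), 1)
  # fixture metrics equal the brute-force oracles
  built <- build_cohort_scns(fx$cohort)
  m <- compute_metrics(built$scns[[1]])
  W <- built$scns[[1]]
  expect_equal(m$global[["strength"]], mean(oracle_strength(W)))
  expect_equal(unname(m$nodal$clustering), oracle_onnela(W))
  D <- oracle_floyd_warshall(W)
  expect_equal(m$global[["path_length"]], oracle_path_length(D))
  # and one hand-set ANCOVA runs end to end on it
  mets <- cohort_metrics(built$scns)
  cmp <- compare_global(mets$global, fx$cohort$metadata$group,
                        fx$cohort$metadata$premorbid_iq)
  expect_equal(nrow(cmp$omnibus), 4)
  expect_true(all(cmp$omnibus$p_fdr >= cmp$omnibus$p_raw))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_per_group = c(schizophrenia = 5, bipolar = 5)),
               "control")
  expect_error(sim_config(n_per_group = c(control = 1, x = 5)), "at least 2")
  expect_error(sim_config(n_regions = 2), "3 regions")
  expect_error(sim_config(deviation_sd = c(control = -1)), ">= 0")
})
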