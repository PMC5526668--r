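cfg <- analysis_config()

test_that("normalization divides by OD and zeroes strictly below threshold", {
  s <- data.frame(day = 1:3, od600 = c(0.5, 0.05, 0.075),
                  yfp = c(100, 100, 75), cfp = c(50, 10, 15))
  tr <- normalize_trajectory(s, cfg)
  expect_equal(tr$norm_yfp, c(200, 0, 1000))   # 0.075 is NOT below threshold
  expect_equal(tr$norm_cfp, c(100, 0, 200))
  # zeroing invariant on random trajectories
  withr::local_seed(1)
  for (i in 1:20) {
    s <- data.frame(day = 1:8, od600 = runif(8, 0, 0.3),
                    yfp = runif(8, 0, 100), cfp = runif(8, 0, 100))
    tr <- normalize_trajectory(s, cfg)
    expect_true(all(tr$norm_yfp[s$od600 < 0.075] == 0))
    expect_true(all(tr$norm_cfp[s$od600 >= 0.075] ==
                      (s$cfp / s$od600)[s$od600 >= 0.075]))
  }
})

test_that("ancestral reference averages OD-normalized wells", {
  w <- data.frame(od600 = c(1, 1), yfp = c(90, 110), cfp = c(100, 100))
  ref <- ancestral_reference(w, cfg)
  expect_equal(ref$mean_norm_yfp, 100)
  expect_equal(ref$n_wells, 2L)
  one <- ancestral_reference(w[1, ], cfg)
  expect_equal(one$mean_norm_yfp, 90)
  expect_error(ancestral_reference(data.frame(od600 = 0.01, yfp = 1, cfp = 1)),
               "reference undefined")
})

test_that("rescue is a strict final-day OD rule", {
  s <- data.frame(day = 1:5, od600 = c(0.9, 0.9, 0.9, 0.9, 0.5),
                  yfp = 1, cfp = 1)
  expect_true(classify_rescue(s, cfg))
  s$od600[5] <- 0.075
  expect_false(classify_rescue(s, cfg))   # "exceeded" is strict
  # transient dip below threshold does not disqualify
  s$od600 <- c(0.9, 0.02, 0.02, 0.3, 0.4)
  expect_true(classify_rescue(s, cfg))
})

test_that("phenotype elevation is per channel with strict fold threshold", {
  ref <- toy_reference()
  mk <- function(yfinal, cfinal) data.frame(
    day = 1:5, od600 = 1, norm_yfp = c(1, 1, 1, 1, yfinal) * 100,
    norm_cfp = c(1, 1, 1, 1, cfinal) * 100)
  expect_true(classify_phenotype(mk(3.0, 1), ref, cfg)$yfp_elevated)
  expect_false(classify_phenotype(mk(2.77, 1), ref, cfg)$yfp_elevated)
  both <- classify_phenotype(mk(4, 4), ref, cfg)
  expect_equal(both$phenotype, "YFP+CFP")
  expect_equal(classify_phenotype(mk(3, 1), ref, cfg)$phenotype, "YFP")
  # monotone threshold property: raising the threshold never elevates
  withr::local_seed(2)
  for (i in 1:25) {
    tr <- mk(runif(1, 0, 6), runif(1, 0, 6))
    lo <- classify_phenotype(tr, ref, analysis_config(fold_threshold = 2))
    hi <- classify_phenotype(tr, ref, analysis_config(fold_threshold = 4))
    expect_false(hi$yfp_elevated & !lo$yfp_elevated)
    expect_false(hi$cfp_elevated & !lo$cfp_elevated)
  }
})

test_that("stringent transient detection needs 2 qualifying high-OD days", {
  ref <- toy_reference()
  mk <- function(od, cf) data.frame(day = seq_along(od), od600 = od,
                                    norm_yfp = 100, norm_cfp = cf * 100)
  expect_true(detect_transient_elevation(mk(c(0.9, 0.9, 0.02), c(3, 3, 0)),
                                         ref, cfg, "cfp"))
  # OD condition fails at 0.25
  expect_false(detect_transient_elevation(mk(c(0.25, 0.25, 0.02), c(3, 3, 0)),
                                          ref, cfg, "cfp"))
  # one qualifying day is not enough
  expect_false(detect_transient_elevation(mk(c(0.9, 0.2, 0.02), c(3, 3, 0)),
                                          ref, cfg, "cfp"))
})

test_that("cost-analysis amplification flag covers transient-only rescues", {
  expect_true(amplified_for_cost(FALSE, FALSE, TRUE))    # extinct + transient
  expect_true(amplified_for_cost(TRUE, FALSE, TRUE))     # rescued, fold fell back
  expect_true(amplified_for_cost(TRUE, TRUE, FALSE))
  expect_false(amplified_for_cost(TRUE, FALSE, FALSE))
  expect_false(amplified_for_cost(FALSE, FALSE, FALSE))
})

test_that("final ratio uses raw units and guards zero CFP", {
  s <- data.frame(day = 1:2, od600 = 0.9, yfp = c(10, 500), cfp = c(10, 250))
  expect_equal(final_ratio(s, cfg), 2.0)
  s$cfp[2] <- 0
  expect_true(is.na(final_ratio(s, cfg)))
})

test_that("amplification timing follows the high-flat vs step rules", {
  expect_equal(infer_amplification_timing(c(3.0, 3.1, 2.9, 3.0, 3.1), 1, cfg),
               "amplification_second")
  expect_equal(infer_amplification_timing(c(1.0, 1.0, 1.0, 2.8, 3.0), 1, cfg),
               "amplification_first")
  expect_equal(infer_amplification_timing(c(1, 1, 1.05, 1, 0.95), 1, cfg),
               "indeterminate")
  expect_equal(infer_amplification_timing(c(3, 3, 3), 1, cfg), "indeterminate")
})

test_that("spot amplification thresholding: 6x-mean default, mean+6SD option", {
  anc <- c(9, 10, 11)
  expect_true(classify_spot_amplification(61, anc))
  expect_false(classify_spot_amplification(59, anc))
  anc2 <- c(8, 10, 12)   # mean 10, sd 2
  expect_true(classify_spot_amplification(23, anc2, rule = "sd"))
  expect_false(classify_spot_amplification(21, anc2, rule = "sd"))
  expect_error(classify_spot_amplification(10, numeric(0)), "ancestor")
})

test_that("classify_plate integrates all calls and the tally inequality holds", {
  plates <- validate_plate_series(toy_plate())
  calls <- classify_plate(plates, toy_reference(), cfg)
  expect_equal(nrow(calls), 3L)
  a01 <- calls[calls$well == "A01", ]
  expect_true(a01$rescued); expect_equal(a01$phenotype, "YFP")
  a02 <- calls[calls$well == "A02", ]
  expect_false(a02$rescued); expect_true(a02$transient_cfp)
  expect_true(a02$amplified_for_cost)
  a03 <- calls[calls$well == "A03", ]
  expect_equal(a03$phenotype, "YFP+CFP")
  # on any plate: cost-analysis amplifications >= endpoint CFP-elevated rescues
  expect_gte(sum(calls$amplified_for_cost),
             sum(calls$cfp_elevated & calls$rescued))
})
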