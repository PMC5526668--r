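params_small <- sim_params(n_wells = 12L)
sched10 <- make_schedule(1, days = 10)

test_that("same seed gives bit-identical output", {
  a <- simulate_plate(params_small, scenario_preset("B"), sched10,
                      n_wells = 6, seed = 42)
  b <- simulate_plate(params_small, scenario_preset("B"), sched10,
                      n_wells = 6, seed = 42)
  expect_identical(a, b)
  c <- simulate_plate(params_small, scenario_preset("B"), sched10,
                      n_wells = 6, seed = 43)
  expect_false(identical(a$plates, c$plates))
})

test_that("degenerate drug regimes behave deterministically", {
  # no drug: never extinct, OD at carrying capacity every day
  nodrug <- make_schedule(1, days = 10, start_fraction = 1e-9)
  p0 <- sim_params(noise_sd = 0, od_noise_sd = 0)
  w <- simulate_well(p0, scenario_preset("A"), nodrug, seed = 1)
  expect_true(w$truth$rescued)
  expect_true(all(w$series$od600 > 0.8))
  # no mutation supply, schedule beyond tolerance from day 2 -> extinct
  p_norate <- sim_params(rate_point = 0, rate_is = 0, rate_cooption = 0,
                         duplication_rate_homology = 0,
                         duplication_rate_base = 0, secondary_rate = 0)
  hot <- make_schedule(1, days = 10, start_fraction = 2)
  w <- simulate_well(p_norate, scenario_preset("B"), hot, seed = 1)
  expect_false(w$truth$rescued)
  expect_lt(w$series$od600[10], 0.075)
})

test_that("copy number never drops below 1 and CFP tracks copy load", {
  sim <- simulate_plate(params_small, scenario_preset("E"), sched10,
                        n_wells = 12, seed = 5)
  expect_true(all(sim$truth$final_k >= 1))
  expect_true(all(sim$truth$max_k >= sim$truth$final_k | sim$truth$max_k >= 1))
  # noise-free CFP fold equals the population mean copy number by construction
  expect_true(all(sim$truth$cfp_fold_true >= 1 - 1e-9))
})

test_that("rescue fraction increases with the duplication rate", {
  sched <- make_schedule(1, days = 8)
  p <- sim_params(days = 8L)
  lo <- simulate_plate(p, scenario_preset("A"), sched, n_wells = 25, seed = 2)
  hi <- simulate_plate(p, scenario_preset("B"), sched, n_wells = 25, seed = 2)
  expect_gte(sum(hi$truth$rescued), sum(lo$truth$rescued))
})

test_that("simulated plates pass the io validator and classify end to end", {
  sim <- simulate_plate(params_small, scenario_preset("D"), sched10,
                        n_wells = 8, seed = 9)
  expect_s3_class(sim$plates, "plate_series")
  anc <- simulate_ancestor_plate(params_small, n_wells = 20, seed = 1)
  ref <- ancestral_reference(anc)
  calls <- classify_plate(sim$plates, ref)
  expect_equal(nrow(calls), 8L)
  expect_true(all(calls$phenotype %in% c("extinct", "none", "YFP", "YFP+CFP")))
})

test_that("ancestor plate mean recovers the generative brightness", {
  p <- sim_params()
  anc <- simulate_ancestor_plate(p, n_wells = 95, seed = 17)
  ref <- ancestral_reference(anc)
  se_y <- sd(anc$yfp / anc$od600) / sqrt(95)
  expect_lt(abs(ref$mean_norm_yfp - p$yfp_per_od), 3 * se_y + 1.5)
  expect_equal(ref$n_wells, 95L)
})

test_that("toy annotation generator validates its own packing", {
  toy <- make_toy_annotation(2, n_filler = 50)   # capped to available slots
  expect_s3_class(toy$ann, "annotation_bundle")
  expect_error(make_toy_annotation(2, genome_length = 10000), "genome_length")
})
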