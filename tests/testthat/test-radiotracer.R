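meas_row <- function(status, dpm, section = 1L, condition = "light",
                     weight = 0.5, cylinder = "c1", exp = "e1",
                     incubation = 2) {
  data.frame(experiment_id = exp, cylinder_id = cylinder,
             section_index = section, condition = condition,
             phenotype = "pink", status = status, wet_weight = weight,
             dpm = dpm, incubation = incubation, stringsAsFactors = FALSE)
}
medium_fix <- function(tdpm = 1e6, total_ci = 25000, sf = 1, exp = "e1") {
  data.frame(experiment_id = exp, tdpm = tdpm, total_ci = total_ci,
             sampled_fraction = sf, stringsAsFactors = FALSE)
}

test_that("the fixed-carbon worked example is exact", {
  # live 2100, kill 100, fraction 1, tDPM 1e6, Ci 25000 ug, 0.5 g, factor 1
  # -> (2000/1e6) * 25000 / 0.5 = 100 ug C per g
  meas <- rbind(meas_row("live", 2100), meas_row("kill", 100))
  got <- compute_fixed_carbon(meas, medium_fix(), discrimination = 1.0)
  expect_equal(got$fixed_c, 100)

  # live mean equal to the kill control: zero fixation
  null <- rbind(meas_row("live", 100), meas_row("kill", 100))
  expect_equal(compute_fixed_carbon(null, medium_fix(),
                                    discrimination = 1.0)$fixed_c, 0)

  # live below kill: clamped to 0 with the raw value preserved
  neg <- rbind(meas_row("live", 50), meas_row("kill", 100))
  expect_warning(got_neg <- compute_fixed_carbon(neg, medium_fix(),
                                                 discrimination = 1.0),
                 "clamped")
  expect_equal(got_neg$fixed_c, 0)
  expect_lt(got_neg$fixed_c_raw, 0)
})

test_that("group validation catches missing kill controls and bad medium", {
  live_only <- meas_row("live", 2100)
  expect_error(compute_fixed_carbon(live_only, medium_fix()), "kill")
  meas <- rbind(meas_row("live", 2100), meas_row("kill", 100))
  expect_error(compute_fixed_carbon(meas, medium_fix(tdpm = 0)), "tdpm")
  expect_error(compute_fixed_carbon(meas, medium_fix(exp = "other")),
               "medium")
})

test_that("the estimator is linear in activity and carbon pool", {
  meas <- rbind(meas_row("live", c(2100, 2300, 1900), cylinder = "c1"),
                meas_row("kill", 100))
  base <- compute_fixed_carbon(meas, medium_fix())
  # doubling every DPM together with tDPM leaves fixed_c unchanged
  doubled <- meas; doubled$dpm <- doubled$dpm * 2
  same <- compute_fixed_carbon(doubled, medium_fix(tdpm = 2e6))
  expect_equal(same$fixed_c, base$fixed_c)
  # doubling total Ci doubles fixed_c
  twice <- compute_fixed_carbon(meas, medium_fix(total_ci = 50000))
  expect_equal(twice$fixed_c, 2 * base$fixed_c)
})

test_that("light and dark shares always sum to 100 when total > 0", {
  res <- structure(data.frame(
    experiment_id = "e1",
    condition = c("light", "dark", "light", "dark"),
    section_index = c(1, 1, 2, 2),
    fixed_c = c(97, 3, 0, 0)), class = c("fixation_results", "data.frame"))
  part <- light_dark_partition(res)
  expect_equal(part$light_pct, 97)
  expect_equal(part$light_pct + part$dark_pct, 100)

  res$fixed_c <- c(50, 0, 0, 0)
  expect_equal(light_dark_partition(res)$light_pct, 100)
  res$fixed_c <- c(10, 10, 0, 0)
  expect_equal(light_dark_partition(res)$light_pct, 50)
  res$fixed_c <- 0
  expect_true(is.na(light_dark_partition(res)$light_pct))
})

test_that("section gradients report rank trend and direction", {
  prof <- function(v) data.frame(section_index = seq_along(v), fixed_c = v)
  dec <- section_gradient(prof(c(100, 20, 5)))
  expect_equal(dec$rho, -1)
  expect_identical(dec$direction, "decreasing")
  inc <- section_gradient(prof(c(1, 2, 3)))
  expect_equal(inc$rho, 1)
  flat <- section_gradient(prof(c(4, 4, 4)))
  expect_equal(flat$rho, 0)
  expect_identical(flat$direction, "none")
  expect_error(section_gradient(prof(c(1, 2))), "3")
})

test_that("medium depletion slopes, flat kills and crush release", {
  series <- rbind(
    data.frame(container_id = "live1", status = "live",
               time = c(0, 0.5, 1), dpm = c(1000, 900, 800)),
    data.frame(container_id = "kill1", status = "kill",
               time = c(0, 0.5, 1), dpm = c(1000, 1000, 1000)))
  tc <- medium_depletion_timecourse(series)
  sl <- tc$slopes
  expect_equal(sl$slope[sl$container_id == "live1"], -200)
  expect_equal(sl$slope[sl$container_id == "kill1"], 0)
  expect_equal(tc$live_vs_kill, -200)

  crush <- rbind(
    data.frame(container_id = "live1", status = "live",
               time = c(0, 1, 2, 3, 3.5, 4), dpm = c(1000, 900, 800, 700, 900, 950)),
    data.frame(container_id = "kill1", status = "kill",
               time = c(0, 2, 4), dpm = c(1000, 995, 1000)))
  tc2 <- medium_depletion_timecourse(crush, events = c(crush = 3))
  expect_true(tc2$release[["live1"]])   # post-crush 900 > pre-crush 700
  expect_true(all(c("baseline", "post_crush") %in% tc2$slopes$phase))

  bad <- data.frame(container_id = "x", status = "live",
                    time = c(1, 0.5), dpm = c(1, 2))
  expect_error(medium_depletion_timecourse(bad), "increasing")
})

test_that("noiseless synthetic tracer data invert to the planted truth", {
  cfg <- sim_config(seed = 5, tracer = list(noise_frac = 0))
  tr <- gen_tracer(cfg)
  got <- compute_fixed_carbon(tr$measurements, tr$medium,
                              discrimination = cfg$tracer$discrimination)
  key <- paste(got$condition, got$section_index)
  truth <- tr$truth[match(key, paste(tr$truth$condition,
                                     tr$truth$section_index)), ]
  expect_equal(got$fixed_c, truth$fixed_c)

  # the planted light profile decreases toward inner sections
  light <- got[got$condition == "light", ]
  light <- light[order(light$section_index), ]
  expect_identical(section_gradient(light)$direction, "decreasing")
})
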