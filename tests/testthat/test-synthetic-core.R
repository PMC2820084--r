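# Core-record generator: phase layout, coupling, chronology plumbing.

test_that("phase sequences lay out contiguous intervals young to old", {
  spec <- data.frame(phase_class = c("GI", "GS"), duration = c(2, 1),
                     label = c("GI 1", "GS 1"))
  ph <- generate_phase_sequence(spec, start_age = 10)
  expect_equal(ph$age_end, c(10, 12))
  expect_equal(ph$age_start, c(12, 13))
  expect_equal(ph$label, c("GI 1", "GS 1"))
  # conservation: total span equals the sum of durations
  expect_equal(max(ph$age_start) - min(ph$age_end), sum(spec$duration))

  empty <- generate_phase_sequence(spec[0, ], start_age = 10)
  expect_equal(nrow(empty), 0L)
  expect_error(generate_phase_sequence(
    data.frame(phase_class = "GI", duration = -1)), "positive")
})

test_that("noise-free cores follow the coupling exactly", {
  p <- core_sim_params(biomass_noise_sd = 0, ccsurf_noise_sd = 0, seed = 2)
  core <- generate_core_record(p)
  gi <- core$samples[core$samples$phase_class == "GI", ]
  gs <- core$samples[core$samples$phase_class %in% c("GS", "HS"), ]
  expect_true(nrow(gi) > 0 && nrow(gs) > 0)
  expect_equal(unique(gi$ccsurf),
               p$coupling_alpha + p$coupling_beta * log(p$biomass_GI_mean))
  expect_equal(unique(gs$ccsurf),
               p$coupling_alpha + p$coupling_beta * log(p$biomass_GS_mean))
})

test_that("a single phase covering the record labels every sample", {
  spec <- data.frame(phase_class = "GI", duration = 60, label = "GI 1")
  core <- generate_core_record(core_sim_params(phase_spec = spec, seed = 5))
  expect_true(all(core$samples$phase == "GI 1"))
})

test_that("noise-free regression recovers beta to machine precision", {
  p <- core_sim_params(ccsurf_noise_sd = 0, sampling_step = 3.16, seed = 8)
  core <- generate_core_record(p)
  expect_gte(nrow(core$samples), 500L)
  fit <- lm(ccsurf ~ log(biomass), data = core$samples)
  expect_equal(unname(coef(fit)[2]), p$coupling_beta, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1]), p$coupling_alpha, tolerance = 1e-9)
})

test_that("implied pixel counts reproduce latent CCsurf within one pixel", {
  core <- generate_core_record(core_sim_params(seed = 21))
  s <- core$samples
  px_value <- compute_ccsurf(1, s$Sp_um2[1], s$Sr_um2[1], s$D[1], s$W_g[1],
                             s$Ss_um2[1])
  back <- compute_ccsurf(s$charcoal_pixels_P, s$Sp_um2[1], s$Sr_um2[1],
                         s$D[1], s$W_g[1], s$Ss_um2[1])
  expect_true(all(abs(back - s$ccsurf) <= px_value / 2 + 1e-9))
})

test_that("depth and age increase strictly; biomass stays in (0, 100]", {
  core <- generate_core_record(core_sim_params(seed = 31,
                                               biomass_noise_sd = 30))
  expect_true(all(diff(core$samples$depth) > 0))
  expect_true(all(diff(core$samples$age) > 0))
  expect_true(all(diff(core$control_points$age) > 0))
  expect_true(all(core$samples$biomass > 0 & core$samples$biomass <= 100))
})

test_that("a phase spec that falls short of the age range errors", {
  spec <- data.frame(phase_class = c("GI", "GS"), duration = c(2, 2))
  expect_error(generate_core_record(core_sim_params(phase_spec = spec)),
               "uncovered")
})

test_that("core generation is deterministic in the seed", {
  a <- generate_core_record(core_sim_params(seed = 77))
  b <- generate_core_record(core_sim_params(seed = 77))
  expect_identical(a$samples, b$samples)
  c <- generate_core_record(core_sim_params(seed = 78))
  expect_false(identical(a$samples$ccsurf, c$samples$ccsurf))
})

test_that("synthetic cores serialize to CSV tables plus a config snapshot", {
  core <- generate_core_record(core_sim_params(seed = 4))
  dir <- withr::local_tempdir()
  write_synthetic_core(core, dir)
  expect_true(all(file.exists(file.path(
    dir, c("samples.csv", "control_points.csv", "phases.csv",
           "core_sim_params.json")))))
  back <- read.csv(file.path(dir, "samples.csv"))
  expect_equal(back$ccsurf, core$samples$ccsurf)
})
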