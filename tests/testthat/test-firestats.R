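# Phase assignment, biomass indices, fits, ellipses, independence, trend.

hs4_table <- function() {
  phase_table(data.frame(
    label = c("GI 8", "HS 4", "GS 9"),
    phase_class = c("GI", "HS", "GS"),
    age_start = c(38.2, 40.2, 41.5),
    age_end = c(36.5, 38.2, 40.2)))
}

test_that("phase membership uses older-bound-inclusive intervals", {
  tb <- hs4_table()
  expect_equal(assign_phase(39.0, tb), "HS 4")
  expect_equal(assign_phase(40.2, tb), "HS 4")   # older bound inclusive
  expect_equal(assign_phase(38.2, tb), "GI 8")   # passes to the younger phase
  expect_true(is.na(assign_phase(50, tb)))       # older than every phase
  expect_equal(assign_phase(36.5, tb), "GI 8")   # record's young terminus
  expect_true(is.na(assign_phase(30, tb)))
})

test_that("hiatus intervals and overlaps are handled at validation", {
  tb <- phase_table(data.frame(
    label = c("GI 1", "GS 1", "hiatus-a"),
    phase_class = c("GI", "GS", "HIATUS"),
    age_start = c(12, 13, 12.6),
    age_end = c(10, 12, 12.2)))
  expect_equal(assign_phase(11, tb), "GI 1")
  expect_true(is.na(assign_phase(12.4, tb)))  # inside the hiatus
  expect_error(phase_table(data.frame(
    label = c("A", "B"), phase_class = c("GI", "GS"),
    age_start = c(12, 13), age_end = c(10, 11.5))), "overlap")
  expect_error(phase_table(data.frame(
    label = "A", phase_class = "GI", age_start = 10, age_end = 12)),
    "older bound")
})

test_that("every sample lands in at most one phase (partition property)", {
  core <- generate_core_record(core_sim_params(seed = 13))
  ages <- c(core$samples$age, 5, 200)  # plus ages outside the table
  lab <- assign_phase(ages, core$phases)
  n_assigned <- sum(!is.na(lab))
  expect_equal(n_assigned + sum(is.na(lab)), length(ages))
  # cross-check a random subset against direct interval containment
  set.seed(1)
  for (i in sample(seq_along(ages), 25)) {
    hits <- sum(ages[i] > core$phases$age_end &
                  ages[i] <= core$phases$age_start)
    expect_lte(hits, 1L)
    if (hits == 1L) expect_false(is.na(lab[i]))
  }
})

test_that("biomass indices sum included groups and honor exclusions", {
  spec <- c(Ericaceae = 12, MedForest = 25, SemiDesert = 40)
  expect_equal(biomass_index(spec, biomass_definition("iberia")), 37)
  spec_fr <- c(AP_noPinus = 30, Pinus = 55)
  expect_equal(biomass_index(spec_fr, biomass_definition("france")), 30)
  expect_equal(biomass_index(c(Ericaceae = 0, MedForest = 0),
                             biomass_definition("iberia")), 0)
  expect_error(biomass_index(c(MedForest = 10),
                             biomass_definition("iberia")), "Ericaceae")
  expect_warning(
    idx <- biomass_index(c(A = 70, B = 60),
                         biomass_definition("custom",
                                            include = c("A", "B"))),
    "capped")
  expect_equal(idx, 100)
  expect_error(biomass_definition("custom"), "non-empty")
})

test_that("phase summaries report hand-computable statistics", {
  tb <- phase_table(data.frame(label = c("GI 1", "GS 1"),
                               phase_class = c("GI", "GS"),
                               age_start = c(12, 14), age_end = c(10, 12)))
  rec <- data.frame(age = c(11, 11.5, 11.9, 13.5),
                    ccsurf = c(2, 4, 6, 9), biomass = c(30, 40, 50, 8))
  s <- phase_summaries(rec, tb)
  gi <- s[s$label == "GI 1", ]
  expect_equal(gi$n, 3)
  expect_equal(gi$mean_ccsurf, 4)
  expect_equal(gi$sd_ccsurf, 2)
  expect_equal(gi$mean_biomass, 40)
  gs <- s[s$label == "GS 1", ]
  expect_equal(gs$n, 1)
  expect_true(is.na(gs$sd_ccsurf))   # SD undefined below n = 2
  # empty phases stay in the output
  rec2 <- rec[rec$age < 12, ]
  s2 <- phase_summaries(rec2, tb)
  expect_equal(s2$n[s2$label == "GS 1"], 0)
  # reordering samples changes nothing
  s3 <- phase_summaries(rec[c(3, 1, 4, 2), ], tb)
  expect_equal(s3, s)
})

test_that("log_fit recovers exact logarithmic couplings", {
  B <- c(5, 10, 20, 40, 80)
  fit <- suppressWarnings(log_fit(B, 2 + 0.8 * log(B)))  # exact fit
  expect_equal(fit$beta, 0.8, tolerance = 1e-12)
  expect_equal(fit$alpha, 2, tolerance = 1e-12)
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_error(log_fit(B, rep(3, 5)), "constant")
  expect_error(log_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(log_fit(c(2, 3), c(1, 2)), "at least 3")
})

test_that("log_fit is equivariant under scaling of ccsurf", {
  set.seed(7)
  B <- runif(40, 2, 90)
  cc <- 1e5 + 4e4 * log(B) + rnorm(40, 0, 2e4)
  f1 <- log_fit(B, cc)
  f2 <- log_fit(B, 3 * cc)
  expect_equal(f2$beta, 3 * f1$beta)
  expect_equal(f2$alpha, 3 * f1$alpha)
  expect_equal(f2$b, f1$b)
  expect_equal(f2$p_value, f1$p_value)
})

test_that("t-test p-value agrees with the permutation oracle", {
  set.seed(31)
  B <- runif(60, 2, 90)
  cc <- 1e5 + 1.2e4 * log(B) + rnorm(60, 0, 4e4)  # moderate signal
  fit <- log_fit(B, cc, n_perm = 4000)
  # Monte-Carlo binomial error around the permutation estimate
  mc_sd <- sqrt(fit$p_perm * (1 - fit$p_perm) / 4000)
  expect_lt(abs(fit$p_value - fit$p_perm), 4 * mc_sd + 0.005)
})

test_that("confidence ellipse matches the chi-square radius oracle", {
  # four points with exactly the identity sample covariance
  s <- sqrt(3 / 2)
  x <- c(s, -s, 0, 0); y <- c(0, 0, s, -s)
  e <- confidence_ellipse(x, y, level = 0.95)
  # chi-square(2) quantile has the closed form -2*log(1 - level)
  expect_equal(unname(e$semi_axes), rep(sqrt(-2 * log(0.05)), 2),
               tolerance = 1e-12)
  expect_equal(e$center, c(0, 0))
  expect_error(confidence_ellipse(1:5, 2 * (1:5) + 3), "collinear")
  expect_error(confidence_ellipse(1:2, c(2, 4)), "at least 3")
})

test_that("rotating the point cloud rotates the ellipse identically", {
  set.seed(12)
  x <- rnorm(200, sd = 3); y <- rnorm(200, sd = 1)
  th <- 0.7
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  e0 <- confidence_ellipse(x, y)
  e1 <- confidence_ellipse(xr, yr)
  expect_equal(e1$semi_axes, e0$semi_axes, tolerance = 1e-9)
  ang <- (e1$orientation - e0$orientation) %% pi
  expect_equal(min(ang, pi - ang), min(th %% pi, pi - th %% pi),
               tolerance = 1e-9)
  # containment is rotation-invariant too
  expect_equal(sum(ellipse_contains(e1, xr, yr)),
               sum(ellipse_contains(e0, x, y)))
})

test_that("independence_check handles identity, misalignment, degeneracy", {
  x <- rnorm(20)
  r <- independence_check(x, x)
  expect_equal(r$overall$r, 1)
  expect_error(independence_check(x, x[-1]), "lengths differ")
  expect_error(independence_check(x, rep(1, 20)), "constant")
  # phase-level test runs on per-phase means
  core <- generate_core_record(core_sim_params(seed = 3))
  s <- core$samples
  res <- independence_check(s$ccsurf, s$sed_rate_cm_per_kyr, ages = s$age,
                            phases = core$phases)
  expect_true(abs(res$phase_level$r) <= 1)
  expect_equal(res$phase_level$n,
               length(unique(s$phase[!is.na(s$phase)])))
})

test_that("long-term trend recovers an exact linear drift", {
  rec <- data.frame(age = seq(25, 70, by = 0.5))
  rec$ccsurf <- 3e5 - 2000 * rec$age
  tr <- suppressWarnings(long_term_trend(rec, c(25, 70)))  # exact fit
  expect_equal(tr$slope, -2000, tolerance = 1e-9)
  expect_lt(tr$se, 1e-6)
  expect_error(long_term_trend(rec, c(80, 90)), "fewer than 3")
})
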