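sched <- itc_schedule()

test_that("schedule defaults mirror the titration protocol", {
  expect_equal(sched$n_injections, 13L)
  expect_equal(sched$injection_volume_ul, 3.22)
  expect_equal(sched$syringe_conc_M, 0.5e-3)
  expect_equal(sched$cell_conc_M, 20e-6)
  expect_equal(sched$temperature_K, 298.15)
  expect_error(itc_schedule(n_injections = 0), "positive")
})

test_that("simulated isotherms honour the physical limits", {
  no_heat <- simulate_isotherm(binding_params(1e-5, 0), sched)
  expect_true(all(no_heat$heat == 0))

  no_binding <- simulate_isotherm(binding_params(1e3, -10), sched)
  expect_true(all(abs(no_binding$heat) < 1e-6))

  # stoichiometric limit: a step isotherm around molar ratio 1
  step <- simulate_isotherm(binding_params(1e-12, -10), sched)
  pre <- step$heat[step$molar_ratio < 0.9]
  post <- step$heat[step$molar_ratio > 1.3]  # past the transition injection
  expect_true(all(abs(pre - (-10)) < 0.15))
  expect_true(all(abs(post) < 1e-2))
  expect_true(all(diff(step$molar_ratio) > 0))
})

test_that("heats conserve total enthalpy and decay past saturation", {
  p <- binding_params(1e-5, -10)
  iso <- simulate_isotherm(p, sched, displacement = FALSE)
  # total normalized heat * injected moles == dH * final bound moles
  inj_conc <- sched$syringe_conc_M * sched$injection_volume_ul /
    sched$cell_volume_ul
  lt <- sched$syringe_conc_M * seq_len(13) * sched$injection_volume_ul /
    sched$cell_volume_ul
  s <- sched$cell_conc_M + lt[13] + p$Kd
  ml_final <- (s - sqrt(s^2 - 4 * sched$cell_conc_M * lt[13])) / 2
  expect_equal(sum(iso$heat) * inj_conc, p$dH * ml_final, tolerance = 1e-12)
  # exothermic heats shrink in magnitude past the stoichiometric point
  tail_heats <- iso$heat[iso$molar_ratio > 1]
  expect_true(all(diff(abs(tail_heats)) < 0))
})

test_that("fitting recovers simulated parameters", {
  truth <- binding_params(1e-5, -10)
  fit <- fit_isotherm(simulate_isotherm(truth, sched), sched)
  expect_false(fit$no_binding)
  expect_lt(abs(fit$Kd - truth$Kd) / truth$Kd, 1e-3)
  expect_lt(abs(fit$dH - truth$dH) / abs(truth$dH), 1e-3)
  expect_equal(fit$N, 1.0)

  # floating N still recovers the planted stoichiometry
  truth2 <- binding_params(5e-6, -8, N = 0.8)
  fit2 <- fit_isotherm(simulate_isotherm(truth2, sched), sched,
                       fix_N = FALSE)
  expect_lt(abs(fit2$N - 0.8), 1e-3)
  expect_lt(abs(fit2$Kd - truth2$Kd) / truth2$Kd, 1e-2)
})

test_that("flat isotherms report no detectable binding", {
  flat <- simulate_isotherm(binding_params(1e-5, 0), sched)
  fit <- fit_isotherm(flat, sched)
  expect_true(fit$no_binding)
  expect_true(is.na(fit$Kd))
  short <- flat[1:3, ]
  expect_error(fit_isotherm(short, sched), "at least 5")
})

test_that("thermodynamic identities hold to machine precision", {
  expect_equal(compute_thermodynamics(1, -10)$dG, 0)
  th <- compute_thermodynamics(1e-5, -10, 298.15)
  expect_equal(th$dG, 1.987e-3 * 298.15 * log(1e-5))
  withr::with_seed(19, {
    for (kd in 10^runif(20, -9, -3)) {
      dh <- runif(1, -20, 5)
      th <- compute_thermodynamics(kd, dh)
      expect_equal(dh, th$dG + 298.15 * th$dS, tolerance = 1e-12)
    }
  })
  expect_error(compute_thermodynamics(0, -10), "positive")
})

test_that("competition model separates same-site and other-site ligands", {
  s1 <- binding_params(1e-5, -10)
  s2 <- binding_params(5e-5, -5)
  control <- simulate_isotherm(s2, sched)
  other <- predict_competition(s1, s2, titrated_site = 2,
                               preincubated_site = 1,
                               preincubation_conc = 1e-3,
                               schedule = sched)
  expect_identical(other$heat, control$heat)   # exactly unperturbed
  same <- predict_competition(s1, s2, titrated_site = 1,
                              preincubated_site = 1,
                              preincubation_conc = 5e-3,
                              schedule = sched)
  expect_true(all(abs(same$heat) < 0.05))      # blocked binding
  none <- predict_competition(s1, s2, titrated_site = 1,
                              preincubated_site = 1,
                              preincubation_conc = 0, schedule = sched)
  expect_identical(none$heat, simulate_isotherm(s1, sched)$heat)
  expect_error(predict_competition(s1, s2, titrated_site = 3), "site ids")
})

test_that("isotherm CSV reader handles both heat conventions", {
  iso <- simulate_isotherm(binding_params(1e-5, -10), sched)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(injection_index = iso$injection,
                       heat_kcal_per_mol = iso$heat), tmp,
            row.names = FALSE)
  back <- read_isotherm_csv(tmp, sched)
  expect_equal(back$heat, iso$heat)
  # raw microcalories per injection normalize to the same values
  inj_mol <- sched$syringe_conc_M * sched$injection_volume_ul * 1e-6
  write.csv(data.frame(injection_index = iso$injection,
                       heat_ucal = iso$heat * inj_mol * 1e9), tmp,
            row.names = FALSE)
  raw <- read_isotherm_csv(tmp, sched)
  expect_equal(raw$heat, iso$heat)
  fit <- fit_isotherm(back, sched)
  expect_lt(abs(fit$Kd - 1e-5) / 1e-5, 1e-3)
})
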