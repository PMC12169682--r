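test_that("reorganization energy is the vertical/adiabatic split", {
  expect_equal(reorganization_energy(34.3, 19.9), 14.4)
  expect_equal(reorganization_energy(26.1, 13.2), 13.0, tolerance = 0.1 / 13)
  expect_error(reorganization_energy(5, 5), "> 0")
  expect_error(reorganization_energy(3, 5), "> 0")
})

test_that("Marcus activation energy reproduces published barriers", {
  expect_equal(round(activation_energy(-25.0, 12.3), 1), 3.3)
  expect_equal(round(activation_energy(37.6, 16.5), 1), 44.3)
  expect_equal(activation_energy(-12.3, 12.3), 0)  # barrierless vertex
  expect_error(activation_energy(1, 0), "> 0")
})

test_that("the Marcus parabola has its vertex at -lambda and an inverted region", {
  lam <- 14
  dg <- seq(-60, 40, by = 0.5)
  barrier <- activation_energy(dg, lam)
  expect_true(all(barrier >= 0))
  expect_equal(dg[which.min(barrier)], -lam)
  inv <- dg < -lam
  expect_true(all(diff(barrier[inv]) < 0))       # decreasing toward vertex
  expect_true(all(diff(barrier[dg > -lam]) > 0)) # normal region
})

test_that("Eyring rates reproduce the published prefactor and table entries", {
  expect_equal(rate_constant(0), 6.2124e12, tolerance = 1e-4)
  k_trp <- rate_constant(activation_energy(-5.3, 12.6))
  expect_equal(k_trp, 1.04e12, tolerance = 0.10)
  expect_error(rate_constant(-1), ">= 0")
  # log-linear in the barrier with slope -1/RT (regression oracle)
  ga <- seq(0, 30, by = 0.5)
  fit <- lm(log(rate_constant(ga)) ~ ga)
  expect_equal(unname(coef(fit)[2]), -1 / RT_298, tolerance = 1e-9)
  # bounded by the prefactor, strictly decreasing
  expect_true(all(rate_constant(ga) <= rate_constant(0)))
  expect_true(all(diff(rate_constant(ga)) < 0))
})

test_that("reaction_table completes rows, flags the diffusion limit, and isolates bad rows", {
  d <- aloe()
  rx <- reaction_table(species_by_label(d, "AE")$reactions)
  expect_equal(nrow(rx), 11L)
  expect_true(all(rx$status == "ok"))
  # composition identity per row
  lam <- rx$delta_E_vertical - rx$delta_G_adiabatic
  expect_equal(rx$lambda_reorg, lam)
  expect_equal(rx$delta_G_activation,
               activation_energy(rx$delta_G_adiabatic, lam))
  expect_equal(rx$rate_k, rate_constant(rx$delta_G_activation))
  # triplet-triplet annihilation of the neutral exceeds the diffusion limit
  expect_true(rx$diffusion_limited[rx$label == "10b"])
  expect_false(rx$diffusion_limited[rx$label == "10a"])
  # empty input, and a lambda <= 0 row recorded without killing the batch
  expect_equal(nrow(reaction_table(data.frame())), 0L)
  mixed <- data.frame(label = c("bad", "good"),
                      delta_E_vertical = c(5, 20),
                      delta_G_adiabatic = c(7, 5))
  out <- reaction_table(mixed)
  expect_match(out$status[1], "lambda")
  expect_true(is.na(out$rate_k[1]))
  expect_equal(out$status[2], "ok")
  expect_true(is.finite(out$rate_k[2]))
})

test_that("published reorganization energies are recovered for every table row", {
  d <- aloe()
  for (sp in d$species) {
    lam <- sp$reactions$delta_E_vertical - sp$reactions$delta_G_adiabatic
    expect_equal(lam, sp$reactions$lambda_reorg, tolerance = 0.1 / 5,
                 label = sp$label)
  }
})
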