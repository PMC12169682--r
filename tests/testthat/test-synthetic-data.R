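test_that("generation is deterministic per seed and leaves the global RNG alone", {
  a <- generate_dataset(2, 3, 3, seed = 99)
  b <- generate_dataset(2, 3, 3, seed = 99)
  expect_true(datasets_equal(a, b))
  c <- generate_dataset(2, 3, 3, seed = 100)
  expect_false(datasets_equal(a, c))
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_dataset(1, 2, 2, seed = 7)); after <- runif(1)
  expect_equal(before, after)
  expect_error(generate_dataset(0, 2, 2, seed = 1), ">= 1")
})

test_that("generated datasets validate and run through every pipeline stage", {
  for (seed in c(2, 12, 22)) {
    g <- generate_dataset(2, 3, 3, seed = seed)
    expect_equal(nrow(validate_dataset(g)), 0L)
    a <- ps_analyze(g)
    expect_true(all(is.finite(a$speciation$molar_fraction)))
    expect_equal(sum(a$speciation$molar_fraction), 1, tolerance = 1e-12)
    expect_true(all(a$kinetics$phi_T >= 0 & a$kinetics$phi_T <= 1))
    expect_true(all(vapply(a$reactions, function(r)
      all(r$status == "ok"), logical(1))))
    expect_gt(nrow(jablonski_export(g, "sp1")), 0L)
    sp <- broaden_spectrum(g$species[[1]]$states)
    expect_true(all(sp$intensity >= 0))
  }
})

test_that("generator ground truth is recovered exactly through the Marcus stage", {
  g <- generate_dataset(2, 2, 2, seed = 5, n_reactions = 8)
  for (sp in g$species) {
    rx <- reaction_table(sp$reactions)
    # dE was constructed as lambda + dG, so lambda comes back exactly
    expect_equal(rx$lambda_reorg,
                 rx$delta_E_vertical - rx$delta_G_adiabatic)
    expect_true(all(rx$lambda_reorg > 5 - 1e-9 & rx$lambda_reorg < 25 + 1e-9))
    # and the closed-form yield matches the generated rates
    s <- kinetics_summary(sp)
    expect_equal(s$phi_T, sum(sp$rates$isc$rate) /
                   (sum(sp$rates$isc$rate) + sp$rates$k_F + sp$rates$k_IC))
  }
})

test_that("perturbation is seeded, bounded, and the identity at zero noise", {
  g <- generate_dataset(1, 2, 2, seed = 6)
  expect_true(datasets_equal(g, perturb_dataset(g, 0, seed = 1)))
  p1 <- perturb_dataset(g, 0.01, seed = 3)
  p2 <- perturb_dataset(g, 0.01, seed = 3)
  expect_true(datasets_equal(p1, p2))
  expect_false(datasets_equal(g, p1))
  expect_error(perturb_dataset(g, 1), "\\[0, 1\\)")
  # energies move by at most the requested relative amount
  v0 <- g$species[[1]]$states$vertical_energy
  v1 <- p1$species[[1]]$states$vertical_energy
  expect_true(all(abs(v1 - v0) <= 0.01 * abs(v0) + 1e-12))
})

test_that("rounding-scale noise on table-like reactions shifts rates by about the tolerance policy", {
  # 0.005 relative noise mimics 1-d.p. printing of tens-of-kcal energies;
  # propagated through lambda, the barrier and the exponential it should
  # move k by no more than ~10%
  rx <- data.frame(label = c("10b", "Trp"),
                   delta_E_vertical = c(-12.7, 7.3),
                   delta_G_adiabatic = c(-25.0, -5.3))
  base <- reaction_table(rx)
  worst <- 0
  for (seed in 1:20) {
    d <- ps_dataset(list(ps_species("x", reactions = rx)), ps_conditions())
    pd <- perturb_dataset(d, 0.005, seed = seed)
    out <- reaction_table(pd$species[[1]]$reactions)
    worst <- max(worst, abs(out$rate_k / base$rate_k - 1))
  }
  expect_lt(worst, 0.15)
})
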