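test_that("total ISC rate is the exact channel sum and matches the published total", {
  d <- aloe()
  rs <- species_by_label(d, "AE")$rates
  k <- total_isc_rate(rs)
  expect_equal(k, 1.32e10 + 2.15e9 + 3.59e8)   # 1.5709e10
  expect_equal(k, 1.57e10, tolerance = 0.02)   # published total, rounded
  expect_equal(total_isc_rate(list(isc = rs$isc[0, ])), 0)
  # permutation invariance and independent summation oracle
  set.seed(9)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    isc <- data.frame(singlet_index = sample(1:3, n, TRUE),
                      triplet_index = seq_len(n), rate = 10^runif(n, 6, 12))
    expect_equal(total_isc_rate(list(isc = isc)), sum(isc$rate))
    perm <- isc[sample(n), ]
    expect_equal(total_isc_rate(list(isc = perm)), sum(isc$rate))
  }
})

test_that("channel subsets select scenarios and absent channels are named errors", {
  d <- aloe()
  an <- species_by_label(d, "AE-")$rates
  s1_only <- total_isc_rate(an, channels = cbind(1, 2))
  expect_equal(s1_only, 1.18e11)
  all_ch <- total_isc_rate(an)
  expect_equal(all_ch, 1.18e11 + 1.90e10 + 2.16e7)
  expect_error(total_isc_rate(an, channels = cbind(3, 1)), "S3,T1")
})

test_that("triplet quantum yield reproduces the published 0.51 and its limits", {
  expect_equal(round(triplet_quantum_yield(1.57e10, 1.53e8, 1.47e10), 2), 0.51)
  expect_equal(triplet_quantum_yield(5e9, 0, 0), 1)
  expect_error(triplet_quantum_yield(0, 0, 0), "undefined")
  expect_error(triplet_quantum_yield(-1, 0, 0), ">= 0")
  # strictly increasing in k'_ISC; scale-invariant
  set.seed(13)
  for (i in 1:20) {
    kf <- 10^runif(1, 6, 10); kic <- 10^runif(1, 6, 11)
    ks <- sort(10^runif(2, 7, 12))
    expect_lt(triplet_quantum_yield(ks[1], kf, kic),
              triplet_quantum_yield(ks[2], kf, kic))
    c0 <- 10^runif(1, -3, 3)
    expect_equal(triplet_quantum_yield(ks[1] * c0, kf * c0, kic * c0),
                 triplet_quantum_yield(ks[1], kf, kic))
  }
})

test_that("speciation-weighted apparent yield reproduces 0.52 under both anion scenarios", {
  fr <- c(0.9846, 0.0154)
  expect_equal(round(apparent_quantum_yield(c(0.51, 0.88), fr), 2), 0.52)
  expect_equal(round(apparent_quantum_yield(c(0.51, 0.89), fr), 2), 0.52)
  expect_equal(apparent_quantum_yield(0.7, 1), 0.7)
  expect_error(apparent_quantum_yield(c(0.5, 0.5), c(0.6, 0.6)), "sum")
  set.seed(17)
  for (i in 1:20) {
    y <- runif(3); w <- runif(3); w <- w / sum(w)
    app <- apparent_quantum_yield(y, w)
    expect_gte(app, min(y)); expect_lte(app, max(y))
  }
})

test_that("triplet lifetime is the phosphorescence reciprocal", {
  expect_equal(triplet_lifetime(1), 1)
  expect_equal(triplet_lifetime(0.038462), 26.0, tolerance = 1e-4)
  d <- aloe()
  expect_equal(triplet_lifetime(species_by_label(d, "AE")$rates$k_P), 26.0,
               tolerance = 1e-6)
  expect_equal(triplet_lifetime(species_by_label(d, "AE-")$rates$k_P), 0.66,
               tolerance = 1e-6)
  set.seed(19)
  k <- 10^runif(50, -3, 3)
  expect_equal(triplet_lifetime(k) * k, rep(1, 50))
  expect_error(triplet_lifetime(0), "positive")
})

test_that("the singlet-oxygen energy gate is inclusive at 0.98 eV", {
  r <- type_ii_check(1.80)
  expect_true(r$feasible); expect_equal(r$margin, 0.82)
  expect_true(type_ii_check(1.32)$feasible)
  b <- type_ii_check(0.98)
  expect_true(b$feasible); expect_equal(b$margin, 0); expect_true(b$boundary)
  expect_false(type_ii_check(0.50)$feasible)
  expect_error(type_ii_check(-0.1), ">= 0")
})

test_that("Jablonski export assembles states and annotated channels", {
  d <- aloe()
  jab <- jablonski_export(d, "AE-")
  expect_equal(jab$zeta_cm1[jab$label == "S2->T1"], 29.54)
  expect_equal(jab$zeta_cm1[jab$label == "S1->T2"], 33.35)
  expect_equal(jab$energy_eV[jab$label == "T1"], 1.32)
  # counting oracle on synthetic data: #states + #isc channels + 3 scalars
  g <- generate_dataset(1, 3, 2, seed = 4)
  jg <- jablonski_export(g, "sp1")
  expect_equal(nrow(jg), 5L + 6L + 3L)
  # missing adiabatic energy names the state
  d$species[[1]]$states$adiabatic_energy[2] <- NA_real_
  expect_error(jablonski_export(d, "AE"), "T1")
  # degenerate input: no states, no channels
  empty <- ps_dataset(list(ps_species("x")), ps_conditions())
  expect_equal(nrow(jablonski_export(empty, "x")), 0L)
})

test_that("kinetics summary ties the pieces together for the worked example", {
  d <- aloe()
  s <- kinetics_summary(species_by_label(d, "AE"))
  expect_equal(round(s$phi_T, 2), 0.51)
  expect_equal(s$tau_T1, 26.0, tolerance = 1e-6)
  expect_true(s$type_ii_feasible)
  expect_equal(s$energy_gap_T1_S0, 1.80)
  an <- kinetics_summary(species_by_label(d, "AE-"))
  expect_equal(an$energy_gap_T1_S0, 1.32)
  expect_true(an$type_ii_feasible)
})
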