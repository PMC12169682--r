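test_that("bundled aloe-emodin dataset loads, validates, and matches the published shape", {
  d <- aloe()
  expect_length(d$species, 2L)
  expect_identical(vapply(d$species, `[[`, character(1), "label"),
                   c("AE", "AE-"))
  expect_equal(nrow(validate_dataset(d)), 0L)
  # both reaction blocks of the electron-transfer table are present
  expect_equal(vapply(d$species, function(s) nrow(s$reactions), integer(1)),
               c(11L, 11L))
  expect_setequal(d$species[[1]]$reactions$label,
                  c("10a", "10b", "10c", "10d", "2dG", "Cys", "His+", "Met",
                    "Trp", "Tyr", "Lin"))
})

test_that("save/load round trips preserve datasets in YAML and JSON", {
  d <- aloe()
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    save_dataset(d, p)
    expect_true(datasets_equal(d, load_dataset(p)))
  }
  g <- generate_dataset(2, 3, 3, seed = 1)
  p <- withr::local_tempfile(fileext = ".yaml")
  save_dataset(g, p)
  expect_true(datasets_equal(g, load_dataset(p)))
})

test_that("round trip holds over many generator seeds", {
  p <- withr::local_tempfile(fileext = ".yaml")
  for (seed in 1:100) {
    g <- generate_dataset(1, 2, 2, seed = seed, n_reactions = 2)
    save_dataset(g, p)
    expect_true(datasets_equal(g, load_dataset(p)), label = paste("seed", seed))
  }
})

test_that("validation reports violations as data and names the offending field", {
  d <- aloe()
  expect_equal(nrow(validate_dataset(d)), 0L)

  bad <- d
  bad$species[[1]]$states$oscillator_strength[1] <- -0.1
  rep <- validate_dataset(bad)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$field, "oscillator_strength")

  bad <- d
  bad$species[[1]]$rates$k_F <- -1
  rep <- validate_dataset(bad)
  expect_match(rep$field, "k_F")

  # SOC magnitude inconsistent with components (Euclidean-norm oracle)
  bad <- d
  zx <- 3; zy <- 4; zz <- 12  # norm 13
  bad$species[[2]]$soc[1, c("zeta_x", "zeta_y", "zeta_z", "zeta_magnitude")] <-
    c(zx, zy, zz, 10)
  rep <- validate_dataset(bad)
  expect_match(rep$field, "zeta_magnitude")
  ok <- d
  ok$species[[2]]$soc[1, c("zeta_x", "zeta_y", "zeta_z", "zeta_magnitude")] <-
    c(zx, zy, zz, sqrt(zx^2 + zy^2 + zz^2))
  expect_equal(nrow(validate_dataset(ok)), 0L)

  # validation is total: it flags rather than raises
  bad <- d
  bad$species[[1]]$molar_fraction <- 1.5
  expect_no_error(rep <- validate_dataset(bad))
  expect_gt(nrow(rep), 0L)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(load_dataset(file.path(tempdir(), "nope.yaml")), "not found")
  d <- aloe()
  d$species <- list()
  expect_error(save_dataset(d, withr::local_tempfile(fileext = ".yaml")),
               "empty species")
  bad <- aloe()
  bad$species[[1]]$states$oscillator_strength[1] <- -1
  p <- withr::local_tempfile(fileext = ".yaml")
  expect_error(save_dataset(bad, p), "oscillator_strength")
})

test_that("en-dash labels are normalized to ASCII hyphens", {
  sp <- ps_species("AE–x",
                   binding_sites = data.frame(label = "AT–TA",
                                              delta_G_binding = -8.2,
                                              K_b = NA_real_))
  expect_identical(sp$label, "AE-x")
  expect_identical(sp$binding_sites$label, "AT-TA")
})
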