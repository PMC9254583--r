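test_that("the dose-response surface honors its boundary behavior", {
  sp <- surface_params()
  zero <- true_surface(c(0, 0, 0, 20), sp)
  expect_equal(zero$de_true, 0)
  expect_equal(zero$nde_true, 0)

  huge <- true_surface(c(0, 1e6, 0, 20), sp)
  expect_gt(huge$de_true, 99.99)
  expect_lte(huge$de_true, 100)
  expect_lte(huge$nde_true, 100)
})

test_that("disinfection efficiency is monotone in every dose and in time", {
  sp <- surface_params()
  b <- default_bounds()
  set.seed(6)
  for (i in 1:200) {
    x <- sapply(1:4, function(j) runif(1, b[j, 1], b[j, 2]))
    j <- sample.int(4, 1)
    x2 <- x
    x2[j] <- x2[j] + runif(1, 0, b[j, 2] - x2[j])
    lo <- true_surface(x, sp)
    hi <- true_surface(x2, sp)
    expect_gte(hi$de_true, lo$de_true - 1e-9)
    expect_gte(hi$nde_true, lo$nde_true - 1e-9)
  }
})

test_that("the generator is reproducible and respects the noise model", {
  sp0 <- surface_params(noise_sd = 0)
  tab <- generate_table(40, sp0, design = "random", seed = 14)
  truth <- true_surface(tab, sp0)
  expect_equal(tab$de_actual, truth$de_true, tolerance = 1e-12)
  expect_equal(tab$nde_actual, truth$nde_true, tolerance = 1e-12)

  spn <- surface_params(noise_sd = 5)
  a <- generate_table(40, spn, design = "random", seed = 14)
  b <- generate_table(40, spn, design = "random", seed = 14)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$de_actual,
                         generate_table(40, spn, design = "random",
                                        seed = 15)$de_actual))
  # observed percentages are truncated to the physical scale
  big_noise <- generate_table(200, surface_params(noise_sd = 60), seed = 3)
  expect_true(all(big_noise$de_actual >= 0 & big_noise$de_actual <= 100))
})

test_that("generated tables are schema-identical to the packaged study table", {
  tab <- generate_table(28, surface_params(), design = "grid", seed = 2)
  expect_equal(nrow(tab), 28)
  expect_setequal(names(tab)[1:7], names(study_table())[1:7])
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tab, path)
  back <- load_table(path)
  expect_equal(as.data.frame(back)[, 1:7], as.data.frame(tab)[, 1:7],
               tolerance = 1e-12)
})

test_that("a network fit to the default noisy regime generalizes", {
  tab <- generate_table(150, surface_params(), design = "random", seed = 31)
  rep <- train_mlp(tab, split_table(tab, seed = 31), fit_scaler(tab),
                   train_config(seed = 31, max_epochs = 300))
  held <- generate_table(100, surface_params(noise_sd = 0),
                         design = "random", seed = 77)
  fit <- predict_treatments(held, rep$params, fit_scaler(tab))
  expect_gt(r_squared(fit$de_pred, held$de_actual), 0.8)
  expect_gt(r_squared(fit$nde_pred, held$nde_actual), 0.8)
})

test_that("the full pipeline beats maximal dosing on synthetic ground truth", {
  spz <- surface_params(noise_sd = 0)
  tab <- generate_table(200, spz, design = "random", seed = 21)
  scal <- fit_scaler(tab)
  rep <- train_mlp(tab, split_table(tab, seed = 21), scal,
                   train_config(seed = 21, max_epochs = 500))
  front <- optimize_protocol(rep$params, scal,
                             ga_config(seed = 21, max_generations = 150,
                                       n_explore = 5000))
  rec <- select_recommendation(front, "target_de")
  truth <- true_surface(as.numeric(rec[1, 1:4]), spz)
  corner <- true_surface(default_bounds()[, 2], spz)
  expect_gte(truth$de_true, 95)
  expect_lte(truth$nde_true, corner$nde_true)
  # materially less damage than dosing everything maximally
  expect_lt(truth$nde_true, corner$nde_true - 20)
})
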