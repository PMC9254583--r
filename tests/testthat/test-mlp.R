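test_that("tansig is an odd, saturating sigmoid", {
  expect_equal(tansig(0), 0)
  v <- seq(-5, 5, by = 0.37)
  expect_equal(tansig(-v), -tansig(v))
  expect_true(all(diff(tansig(v)) > 0))
  expect_equal(tansig(50), 1)
  expect_equal(tansig(-50), -1)
  expect_true(all(abs(tansig(v)) < 1))
})

test_that("vectorized forward pass agrees with a naive double-loop oracle", {
  for (seed in 1:5) {
    h <- sample(c(1, 3, 10, 17), 1)
    p <- random_mlp(h, seed)
    set.seed(seed + 100)
    xn <- matrix(runif(40, -1.5, 1.5), ncol = 4)
    expect_equal(unname(mlp_forward(xn, p)), naive_forward(xn, p),
                 tolerance = 1e-9)
  }
})

test_that("degenerate networks behave as the algebra dictates", {
  z <- mlp_params(matrix(0, 10, 4), rep(0, 10), rep(0, 10), rep(0, 10),
                  b2_de = 3.5, b2_nde = -1.25)
  out <- mlp_forward(c(0.3, -0.2, 0.9, 0), z)
  expect_equal(unname(out[1, ]), c(3.5, -1.25))

  one <- mlp_params(matrix(c(1, 1, 1, 1), 1, 4), b1 = -2, w2_de = 1,
                    w2_nde = 1, b2_de = 0, b2_nde = 0)
  # hidden pre-activation 0.5*4 - 2 = 0, so tansig gives 0
  expect_equal(unname(mlp_forward(rep(0.5, 4), one)[1, ]), c(0, 0))

  expect_error(mlp_forward(c(1, 2, 3), z), "4 columns")
  expect_error(mlp_params(matrix(0, 10, 4), rep(0, 9), rep(0, 10),
                          rep(0, 10), 0, 0), "b1")
})

test_that("published parameters load with the printed values and shapes", {
  p <- published_mlp()
  expect_equal(p$hidden_size, 10)
  expect_equal(dim(p$w1), c(10, 4))
  expect_length(p$b1, 10)
  expect_length(p$w2_de, 10)
  expect_length(p$w2_nde, 10)
  expect_equal(p$w1[1, 1], -2.2264843404709231)
  expect_equal(p$w1[10, 3], 2.9754824151678636)
  expect_equal(p$b1[1], 2.7373703731067001)
  expect_equal(p$b2_de, 0.35872919821907595)
  expect_equal(p$b2_nde, -0.19926566214623609)
})

test_that("parameter files round-trip and corruption is detected", {
  p <- random_mlp(7, 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mlp_params(p, path)
  back <- read_mlp_params(path)
  expect_equal(back$w1, p$w1, tolerance = 1e-15)
  expect_equal(back$b2_nde, p$b2_nde, tolerance = 1e-15)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("hidden_size: 3", "[w1]", "1 2 3 4", "5 6 7 8"), bad)
  expect_error(read_mlp_params(bad), "corrupt")
})

test_that("raw-unit prediction reproduces published spot values", {
  p <- published_mlp()
  sc <- published_scaler()
  pred <- predict_treatments(rbind(c(0, 0, 0, 20),
                                   c(0, 5.25, 0, 10),
                                   c(0, 0, 0.1, 10),
                                   c(0, 0, 0.2, 15)), p, sc)
  expect_equal(pred$de_pred, c(2.62, 88.09, 92.63, 134.70), tolerance = 0.005)
  expect_equal(pred$nde_pred[3:4], c(60.53, 76.73), tolerance = 1e-4)
  # predictions are not clipped to the percentage scale
  expect_gt(pred$de_pred[4], 100)
})

test_that("prediction is continuous in the inputs", {
  p <- published_mlp()
  sc <- published_scaler()
  x0 <- c(0.5, 6, 0.1, 15)
  base <- predict_treatments(x0, p, sc)
  for (j in 1:4) {
    x1 <- x0
    x1[j] <- x1[j] + 1e-9
    moved <- predict_treatments(x1, p, sc)
    expect_lt(abs(moved$de_pred - base$de_pred), 1e-6)
    expect_lt(abs(moved$nde_pred - base$nde_pred), 1e-6)
  }
})
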