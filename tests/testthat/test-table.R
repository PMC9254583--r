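test_that("the packaged experiment table matches the published study design", {
  tab <- study_table()
  expect_s3_class(tab, "disinfection_table")
  expect_equal(nrow(tab), 28)
  expect_equal(sum(is.na(tab$nde_actual)), 1)
  expect_true(is.na(tab$nde_actual[tab$code == "T0"]))

  t27 <- tab[tab$code == "T27", ]
  expect_equal(unlist(t27[, c("naocl_pct", "h2o2_pct", "hgcl2_pct",
                              "time_min")], use.names = FALSE),
               c(0, 0, 0.2, 15))
  expect_equal(t27$de_actual, 100)

  # every observed response within the percentage scale
  expect_true(all(tab$de_actual >= 0 & tab$de_actual <= 100))
  expect_true(all(is.na(tab$nde_actual) |
                    (tab$nde_actual >= 0 & tab$nde_actual <= 100)))
})

test_that("loading rejects malformed input without returning partial tables", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("code,naocl_pct,h2o2_pct,hgcl2_pct,time_min,de_actual,nde_actual",
             empty)
  expect_error(load_table(empty), "no data rows")

  bad_cell <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,naocl_pct,h2o2_pct,hgcl2_pct,time_min,de_actual,nde_actual",
               "T1,0.5,0,0,10,44.4,0", "T2,abc,0,0,20,27.8,0"), bad_cell)
  expect_error(load_table(bad_cell), "row 2, column naocl_pct")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,naocl_pct,h2o2_pct,hgcl2_pct,time_min,de_actual,nde_actual",
               "T1,0.5,0,0,10,44.4,0", "T1,0.9,0,0,20,27.8,0"), dup)
  expect_error(load_table(dup), "duplicate")

  expect_error(disinfection_table(data.frame(code = "T1", naocl_pct = 0.5,
                                             h2o2_pct = 0, hgcl2_pct = 0,
                                             time_min = 0, de_actual = 10,
                                             nde_actual = 0)),
               "time")
  expect_error(disinfection_table(data.frame(code = "T1", naocl_pct = 0.5,
                                             h2o2_pct = 0, hgcl2_pct = 0,
                                             time_min = 10, de_actual = 120,
                                             nde_actual = 0)),
               "\\[0, 100\\]")
})

test_that("CSV write/load round-trips arbitrary valid tables", {
  for (seed in 1:5) {
    tab <- disinfection_table(random_table(12, seed), provenance = "prop")
    path <- withr::local_tempfile(fileext = ".csv")
    write_table(tab, path)
    back <- load_table(path, provenance = "prop")
    expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  }
  # missing NDE must round-trip as missing, not zero
  tab <- study_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tab, path)
  raw <- read.csv(path)
  expect_true(is.na(raw$nde_actual[raw$code == "T0"]))
  expect_equal(ncol(raw), 11)
})

test_that("splits are reproducible partitions with the published proportions", {
  tab <- study_table()
  sp <- split_table(tab, seed = 7)
  expect_equal(lengths(sp[c("train_idx", "val_idx", "test_idx")]),
               c(train_idx = 20, val_idx = 4, test_idx = 4))
  expect_identical(sp, split_table(tab, seed = 7))

  for (seed in 1:10) {
    s <- split_table(tab, seed = seed)
    all_idx <- c(s$train_idx, s$val_idx, s$test_idx)
    expect_equal(sort(all_idx), 1:28)
    expect_equal(anyDuplicated(all_idx), 0)
  }

  s_all <- split_table(tab, fractions = c(1, 0, 0), seed = 1)
  expect_equal(s_all$train_idx, 1:28)
  expect_length(s_all$val_idx, 0)

  tiny <- disinfection_table(random_table(6, 1)[1:2, ])
  expect_error(split_table(tiny, seed = 1), "at least 3")
  expect_error(split_table(tab), "seed")
})

test_that("splitting does not disturb the caller's random state", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(split_table(study_table(), seed = 99))
  expect_identical(runif(3), expected)
})
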