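test_that("dominance follows the strict Pareto definition", {
  expect_true(dominates(c(-100, 5), c(-90, 10)))
  expect_false(dominates(c(-100, 10), c(-90, 5)))
  expect_false(dominates(c(-90, 10), c(-100, 5)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("non-dominated sorting matches the exhaustive pairwise oracle", {
  # structured cases
  nd <- non_dominated_sort(cbind(c(0, 1, 2), c(2, 1, 0)))
  expect_equal(nd$rank, c(1, 1, 1))
  chain <- non_dominated_sort(cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(chain$rank, c(1, 2, 3))

  # random clouds versus the O(n^2) oracle
  for (seed in 1:5) {
    set.seed(seed)
    obj <- cbind(rnorm(50), rnorm(50))
    nd <- non_dominated_sort(obj)
    expect_equal(nd$rank == 1, brute_front(obj))
  }
})

test_that("crowding rewards isolation and boundary points", {
  obj <- cbind(c(0, 1, 1.1, 3), c(3, 2, 1.9, 0))
  nd <- non_dominated_sort(obj)
  expect_true(all(is.infinite(nd$crowding[c(1, 4)])))
  # the clustered middle pair is tighter than nothing else on this front
  expect_true(all(nd$crowding[2:3] < Inf))
})

test_that("tournament selection follows rank then crowding", {
  rank <- c(2, 1, 1, 3)
  crowd <- c(Inf, 0.2, 0.9, Inf)
  set.seed(1)
  # exhaustive tournament always returns the best individual (rank 1, most
  # isolated)
  for (i in 1:20) expect_equal(tournament_select(rank, crowd, k = 4), 3)
  # k = 1 is a uniform draw: all individuals appear
  picks <- replicate(300, tournament_select(rank, crowd, k = 1))
  expect_setequal(unique(picks), 1:4)
})

test_that("intermediate crossover stays in the parental hyper-rectangle", {
  b <- default_bounds()
  pa <- c(0.5, 3, 0.1, 10)
  pb <- c(1.0, 9, 0.05, 25)
  set.seed(2)
  expect_equal(intermediate_crossover(pa, pa, 1, b), pa)
  expect_equal(intermediate_crossover(pa, pb, 0, b), pa)
  kids <- t(replicate(1000, intermediate_crossover(pa, pb, 1, b)))
  for (j in 1:4) {
    expect_true(all(kids[, j] >= min(pa[j], pb[j]) - 1e-12))
    expect_true(all(kids[, j] <= max(pa[j], pb[j]) + 1e-12))
  }
})

test_that("adaptive feasible mutation never leaves the box", {
  b <- default_bounds()
  corner <- b[, 2]
  set.seed(3)
  expect_equal(adaptive_feasible_mutation(corner, b, step = 0), corner)
  for (start in list(corner, b[, 1], c(0.6, 6, 0.1, 17))) {
    mut <- t(replicate(1000, adaptive_feasible_mutation(start, b, step = 0.3)))
    expect_true(all(mut >= matrix(b[, 1], 1000, 4, byrow = TRUE)))
    expect_true(all(mut <= matrix(b[, 2], 1000, 4, byrow = TRUE)))
  }
})

test_that("the GA recovers the analytic front of a convex test problem", {
  # objectives (g^2, (g-2)^2) on one gene: the Pareto set is exactly [0, 2]
  fn <- function(x) cbind(x[, 1]^2, (x[, 1] - 2)^2)
  cfg <- ga_config(pop_size = 40, max_generations = 60,
                   bounds = matrix(c(-2, 4), 1), seed = 5,
                   n_explore = 2000, n_refine = 30)
  front <- run_moga(fn, cfg)
  g <- sort(front$solutions[[1]])
  # the analytic Pareto set is [0, 2]; points may sit a hair outside where
  # the trade-off is numerically flat
  expect_gte(min(g), -1e-4)
  expect_lte(max(g), 2 + 1e-4)
  # coverage: no gap wider than 0.1 anywhere on [0, 2]
  expect_lt(max(diff(c(0, g, 2))), 0.1)
})

test_that("the returned front is internally non-dominated and seed-deterministic", {
  fn <- function(x) cbind(x[, 1]^2 + x[, 2], (x[, 1] - 2)^2 + 2 * x[, 2])
  cfg <- ga_config(pop_size = 20, max_generations = 25,
                   bounds = matrix(c(-2, 4, 0, 1), 2, byrow = TRUE),
                   seed = 9, n_explore = 500, n_refine = 10)
  a <- run_moga(fn, cfg)
  obj <- as.matrix(a$solutions[, c("f1", "f2")])
  expect_true(all(brute_front(obj)))
  expect_true(all(diff(a$history$hypervolume) >= -1e-9))

  b <- run_moga(fn, cfg)
  expect_equal(a$solutions, b$solutions)
})

test_that("zero generations returns the rank-0 set of the initial population", {
  fn <- function(x) cbind(x[, 1]^2, (x[, 1] - 2)^2)
  bounds <- matrix(c(-2, 4), 1)
  cfg <- ga_config(pop_size = 30, max_generations = 0, bounds = bounds,
                   seed = 12)
  front <- run_moga(fn, cfg)
  expect_equal(front$generations_run, 0)
  # reconstruct the seeded initial population
  init <- disinfopt:::with_seed(12,
    sapply(1, function(j) stats::runif(30, bounds[1, 1], bounds[1, 2])))
  obj <- fn(init)
  keep <- brute_front(obj) & !duplicated(obj[, 1])
  expect_setequal(round(front$solutions[[1]], 10), round(init[keep], 10))
})

test_that("ring migration mode exchanges members and still yields a valid front", {
  fn <- function(x) cbind(x[, 1]^2, (x[, 1] - 2)^2)
  cfg <- ga_config(pop_size = 24, max_generations = 45,
                   bounds = matrix(c(-2, 4), 1), seed = 4, n_subpops = 2,
                   migration_interval = 10, n_explore = 500, n_refine = 10)
  front <- run_moga(fn, cfg)
  g <- sort(front$solutions[[1]])
  expect_lt(max(diff(c(0, g, 2))), 0.15)
  expect_true(all(brute_front(as.matrix(front$solutions[, c("f1", "f2")]))))
})

test_that("recommendation rules behave as documented", {
  sol <- data.frame(naocl = c(0.1, 0.2, 0.3), h2o2 = 1, hgcl2 = 0.1,
                    time = 10,
                    f1 = c(-100, -60, -20), f2 = c(30, 10, 2))
  front <- structure(list(solutions = sol), class = "pareto_front")
  # symmetric two-point front: the tie breaks toward lower second objective
  sym <- structure(list(solutions = sol[c(1, 3), ]), class = "pareto_front")
  pick <- select_recommendation(sym)
  expect_equal(pick$f2, 2)
  # single-member front returns that member
  single <- structure(list(solutions = sol[2, ]), class = "pareto_front")
  expect_equal(select_recommendation(single)$f1, -60)
  # target_de keeps only near-best first-objective members
  expect_equal(select_recommendation(front, "target_de")$f1, -100)
  # custom rule function is honored
  expect_equal(select_recommendation(front, function(o) which.min(o[, 2]))$f2, 2)
  empty <- structure(list(solutions = sol[0, ]), class = "pareto_front")
  expect_error(select_recommendation(empty), "empty")
})

test_that("objective evaluation matches direct prediction with sign flip", {
  p <- published_mlp()
  sc <- published_scaler()
  genes <- rbind(c(0, 0, 0, 20), c(0, 0, 0.2, 15))
  obj <- evaluate_objectives(genes, p, sc)
  pred <- predict_treatments(genes, p, sc)
  expect_equal(obj[, 1], -pred$de_pred)
  expect_equal(obj[, 2], pred$nde_pred)
  expect_equal(obj[1, 1], -2.62, tolerance = 0.005)
  expect_equal(obj[2, 1], -134.70, tolerance = 0.005)
})
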