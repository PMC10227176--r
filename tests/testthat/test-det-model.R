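test_that("seed cost is proportional to seed volume", {
  expect_equal(seed_cost(30, 0), 0)
  expect_equal(seed_cost(30, 1e-4), 1e-4 * pi * 27000 / 6)
  expect_equal(seed_cost(0.5, 1e-4), 1e-4 * pi * 0.125 / 6)
  expect_error(seed_cost(0, 1e-4), "positive")
  expect_error(seed_cost(10, -1), "c1")
})

test_that("per-cell seed numbers scale the deposition weights by the post-cost budget", {
  k <- half_kernel()  # lambda = 0.5 at every size
  p <- det_params(n_tot = 7, c1 = 0, d_max = 3)
  expect_equal(seeds_per_cell(10, k, p), c(4, 2, 1))
  # strictly decreasing with distance
  p2 <- det_params(d_max = 100)
  n_d <- seeds_per_cell(5, fig3a_kernel(), p2)
  expect_true(all(diff(n_d) < 0))
  # a cost >= 1 is a configuration error when seeds are produced
  expect_error(seeds_per_cell(30, fig3a_kernel(), det_params()), "cost")
})

test_that("seed mass is conserved: total deposited equals n_tot (1 - c)", {
  set.seed(42)
  for (i in 1:100) {
    d05 <- runif(1, 20, 300)
    d30 <- runif(1, max(50, d05), 750)
    k <- dispersal_kernel(d05, d30)
    c1 <- 10^runif(1, -6, -4)
    s <- runif(1, 0.5, 25)
    p <- det_params(n_tot = runif(1, 100, 1e5), c1 = c1,
                    d_max = sample(100:5000, 1))
    n_d <- seeds_per_cell(s, k, p)
    expect_true(all(n_d > 0))
    expect_equal(sum(n_d), p$n_tot * (1 - seed_cost(s, c1)),
                 tolerance = 1e-9)
  }
})

test_that("occupancy probability follows 1 - (1 - g)^n for real-valued counts", {
  expect_equal(occupancy_prob(0, 0.3), 0)
  expect_equal(occupancy_prob(2, 0.3), 0.51)
  expect_equal(occupancy_prob(1.5, 1), 1)
  expect_equal(occupancy_prob(0, 1), 0)
  expect_equal(occupancy_prob(2.5, 0.3), 1 - 0.7^2.5)
  expect_error(occupancy_prob(-1, 0.3), "n_d")
})

test_that("fitness equals an independent cell-by-cell evaluation", {
  # oracle: loop over every cell, recompute deposition, cost and occupancy
  # from scratch with plain arithmetic
  oracle <- function(size, x_h, x_ipd, d05, d30, n_tot, g, c1, d_max) {
    lam <- 1 - 1 / (1 + exp(qlogis(0.5^(1 / d05)) +
      (qlogis(0.5^(1 / d30)) - qlogis(0.5^(1 / d05))) / 29.5 * (size - 0.5)))
    cost <- c1 / 6 * pi * size^3
    total <- 0
    for (d in 0:(d_max - 1)) {
      if ((d %% (x_h + x_ipd)) >= x_h) next  # matrix: g = 0
      n_d <- n_tot * (lam^d - lam^(d + 1)) / (1 - lam^d_max) * (1 - cost)
      total <- total + (1 - (1 - g)^n_d)
    }
    total
  }
  set.seed(11)
  for (i in 1:50) {
    d05 <- runif(1, 20, 150); d30 <- runif(1, 200, 750)
    x_h <- sample(5:50, 1); x_ipd <- sample(0:80, 1)
    n_tot <- runif(1, 100, 2e4); g <- runif(1, 0.05, 0.95)
    c1 <- 10^runif(1, -6, -4.5); d_max <- sample(50:400, 1)
    size <- runif(1, 0.5, 25)
    k <- dispersal_kernel(d05, d30)
    p <- det_params(n_tot = n_tot, g = g, c1 = c1, d_max = d_max)
    ls <- landscape(x_h, x_ipd, mode = "bounded", d_max = d_max)
    expect_equal(det_fitness(size, ls, k, p),
                 oracle(size, x_h, x_ipd, d05, d30, n_tot, g, c1, d_max),
                 tolerance = 1e-9)
  }
})

test_that("fitness is zero without germination and bounded by the habitable-cell count", {
  k <- fig3a_kernel()
  ls <- landscape(50, 10, mode = "bounded", d_max = 200)
  expect_equal(det_fitness(10, ls, k, det_params(g = 0, d_max = 200)), 0)
  f <- det_fitness(10, ls, k, det_params(d_max = 200))
  expect_gt(f, 0)
  expect_lte(f, sum(is_habitable(ls, 0:199)))
})

test_that("a single habitable cell at the origin with g = 1 gives fitness 1", {
  k <- half_kernel()
  ls <- landscape(1, 2, mode = "bounded", d_max = 3)  # habitable: cell 0 only
  p <- det_params(n_tot = 7, g = 1, c1 = 0, d_max = 3)
  expect_equal(det_fitness(10, ls, k, p), 1)
})

test_that("hill climbing finds local optima, never decreasing fitness along the way", {
  k <- fig3a_kernel()
  p <- det_params(d_max = 200)
  ls <- landscape(50, 0, mode = "bounded", d_max = 200)
  opt <- optimize_seed_size(0.5, ls, k, p)
  # local optimality
  f_star <- det_fitness(opt$s_star, ls, k, p)
  expect_gte(f_star, det_fitness(opt$s_star - 0.01, ls, k, p))
  expect_gte(f_star + 1e-12, det_fitness(min(opt$s_star + 0.01, 26.7), ls, k, p))
  # monotone trajectory
  f_traj <- vapply(opt$trajectory, det_fitness, numeric(1),
                   landscape = ls, kernel = k, params = p)
  expect_true(all(diff(f_traj) > 0))
  expect_lte(length(opt$trajectory), 2951)
  # the walk reaches the global argmax here (unimodal reachable landscape):
  # exhaustive 0.01-mm grid scan oracle restricted to the ascent path
  grid <- seq(0.5, 26.7, by = 0.01)
  f_grid <- vapply(grid, det_fitness, numeric(1),
                   landscape = ls, kernel = k, params = p)
  expect_equal(opt$s_star, grid[which.max(f_grid)], tolerance = 1e-9)
})

test_that("degenerate fitness landscapes pin the hill climb", {
  k <- fig3a_kernel()
  ls <- landscape(50, 0, mode = "bounded", d_max = 100)
  # flat fitness (g = 0): no strict improvement exists anywhere
  opt <- optimize_seed_size(3, ls, k, det_params(g = 0, d_max = 100))
  expect_equal(opt$s_star, 3)
  expect_equal(opt$n_steps, 0L)
  # prohibitive cost: with a flat kernel (beta = 0) size changes nothing but
  # the cost, so fitness is strictly decreasing and the boundary wins
  k_flat <- half_kernel()
  p_cost <- det_params(n_tot = 100, g = 0.05, c1 = 1e-3, d_max = 100)
  opt2 <- optimize_seed_size(5, ls, k_flat, p_cost)
  expect_equal(opt2$s_star, 0.5)
  grid <- seq(0.5, 10, by = 0.01)
  f_grid <- vapply(grid, det_fitness, numeric(1),
                   landscape = ls, kernel = k_flat, params = p_cost)
  expect_true(all(diff(f_grid) < 0))
})

test_that("off-grid starting sizes are snapped with a warning", {
  k <- fig3a_kernel()
  ls <- landscape(50, 0, mode = "bounded", d_max = 100)
  expect_warning(optimize_seed_size(1.005, ls, k, det_params(g = 0, d_max = 100)),
                 "grid")
})

test_that("simulated dispersal-germination reproduces the occupancy law", {
  # Monte-Carlo oracle for the occupancy equation: scatter the seed budget
  # multinomially over the deposition weights, germinate each seed with
  # probability g, count a cell as occupied if any seed succeeds. Run at
  # small g, where occupancy at the expected count is accurate.
  set.seed(202)
  k <- dispersal_kernel(20, 200)
  g <- 0.01
  p <- det_params(n_tot = 2000, g = g, c1 = 0, d_max = 100)
  n_d <- seeds_per_cell(5, k, p)
  pmf <- deposition_pmf(lambda_of_size(k, 5), 100)
  reps <- 1e4
  counts <- rmultinom(reps, p$n_tot, pmf)
  germinated <- rbinom(length(counts), as.vector(counts), g)
  occ <- matrix(germinated > 0, nrow = nrow(counts))
  p_hat <- rowMeans(occ)
  p_exp <- occupancy_prob(n_d, g)
  z <- (p_hat - p_exp) / sqrt(pmax(p_exp * (1 - p_exp), 1e-12) / reps)
  # family-wise equivalent of a per-cell 3-SE criterion across 100 cells
  expect_lte(max(abs(z)), qnorm(1 - pnorm(-3) / 100))
  expect_lte(mean(z^2), 1.6)
})
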