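test_that("per-plant seed numbers follow the rounded post-cost budget", {
  expect_equal(seeds_per_plant(10, tiny_stoch_params(c1 = 0, n_tot = 1000)), 1000L)
  p <- tiny_stoch_params(n_tot = 1000, c1 = 1e-5)
  expect_equal(seeds_per_plant(30, p), 859L)  # round(1000 * (1 - 0.141372))
  p2 <- tiny_stoch_params(n_tot = 1000, c1 = 1e-4)
  expect_equal(seeds_per_plant(0.5, p2), 1000L)  # cost ~ 6.5e-6 rounds away
  # cost >= 1 floors production at zero seeds
  expect_equal(seeds_per_plant(30, p2), 0L)
})

test_that("mutation shifts sizes by one step at the configured rate, with clamping", {
  set.seed(5)
  expect_equal(mutate_sizes(rep(20, 100), mu = 0), rep(20, 100))
  out <- mutate_sizes(rep(30, 1e5), mu = 0.5)
  expect_true(all(out %in% c(29, 30)))  # +1 is clamped back to 30
  # empirical mutation frequency at mu = 0.001
  out2 <- mutate_sizes(rep(20, 1e5), mu = 0.001)
  freq <- mean(out2 != 20)
  expect_lt(abs(freq - 0.001), 3 * sqrt(0.001 * 0.999 / 1e5))
  # both directions occur
  expect_true(all(c(19, 21) %in% out2))
  expect_error(mutate_sizes(20, mu = 2), "mu")
})

test_that("populations reject duplicate or mismatched occupants", {
  expect_error(population(c(1, 1), c(2, 3)), "one plant")
  expect_error(population(1:3, 1:2), "equal length")
  ls <- landscape(3, 2, mode = "periodic", n_patches = 2)
  pop <- init_population(ls, 20)
  expect_equal(pop$cells, habitable_cells(ls))
  expect_true(all(pop$sizes == 20))
})

test_that("a generation with g = 0 goes extinct and mu = 0 adds no variation", {
  k <- fig3a_kernel()
  ls <- landscape(10, 5, mode = "periodic", n_patches = 3)
  pop <- init_population(ls, 20)
  set.seed(1)
  dead <- run_generation(pop, ls, k, tiny_stoch_params(g = 0))
  expect_length(dead$cells, 0)
  expect_equal(dead$generation, 1L)
  p0 <- tiny_stoch_params(mu = 0)
  nxt <- pop
  for (i in 1:5) nxt <- run_generation(nxt, ls, k, p0)
  expect_true(all(nxt$sizes == 20))
})

test_that("seedlings only ever occupy habitable cells, at most one per cell", {
  set.seed(33)
  k <- dispersal_kernel(30, 300)
  ls <- landscape(10, 25, mode = "periodic", n_patches = 4)
  pop <- init_population(ls, 15)
  p <- tiny_stoch_params()
  for (i in 1:10) {
    pop <- run_generation(pop, ls, k, p)
    expect_lte(length(pop$cells), 40)
    expect_false(anyDuplicated(pop$cells) > 0)
    expect_true(all(is_habitable(ls, pop$cells)))
    expect_true(all(pop$sizes >= 0.5 & pop$sizes <= 30))
    if (length(pop$cells) == 0) break
  }
})

test_that("identical seeds reproduce identical populations bit-for-bit", {
  k <- fig3a_kernel()
  ls <- landscape(10, 10, mode = "periodic", n_patches = 3)
  p <- tiny_stoch_params()
  run <- function() {
    set.seed(99)
    pop <- init_population(ls, 20)
    for (i in 1:8) pop <- run_generation(pop, ls, k, p)
    pop
  }
  expect_identical(run(), run())
})

test_that("single-parent colonization frequencies match the closed-form occupancy law", {
  # shared oracle with the deterministic model: a lone parent on a fully
  # habitable 100-cell ring; the folded geometric landing distribution
  # equals the bounded-window deposition weights, so per-cell occupancy
  # should follow 1 - (1 - g)^{N p_d}. Evaluated at small g, where the
  # expected-count exponent is accurate.
  set.seed(404)
  k <- dispersal_kernel(20, 200)
  size <- 5
  g <- 0.01
  n_tot <- 2000
  ls <- landscape(100, 0, mode = "periodic", n_patches = 1)
  p <- stoch_params(n_tot = n_tot, g = g, c1 = 0, mu = 0, n_gens = 1,
                    s_init = size)
  reps <- 1e4
  occ <- matrix(FALSE, nrow = reps, ncol = 100)
  parent <- population(0L, size)
  for (r in seq_len(reps)) {
    out <- run_generation(parent, ls, k, p)
    occ[r, out$cells + 1L] <- TRUE
  }
  p_hat <- colMeans(occ)
  n_d <- n_tot * deposition_pmf(lambda_of_size(k, size), 100)
  p_exp <- occupancy_prob(n_d, g)
  z <- (p_hat - p_exp) / sqrt(p_exp * (1 - p_exp) / reps)
  # 100 simultaneous cells: use the family-wise equivalent of a 3-SE check
  # (same 0.27% error rate), plus an aggregate dispersion bound
  expect_lte(max(abs(z)), qnorm(1 - pnorm(-3) / 100))
  expect_lte(mean(z^2), 1.6)
})

test_that("run_level reports the population median and survives at a benign config", {
  k <- fig3a_kernel()
  ls <- landscape(10, 0, mode = "periodic", n_patches = 3)
  p <- tiny_stoch_params(n_gens = 0)
  pop <- init_population(ls, 20)
  res <- run_level(pop, ls, k, p)
  expect_equal(res$summary$pop_size, 30L)
  expect_equal(res$summary$median_size, 20)
  expect_equal(res$summary$generations_run, 0L)
  # smoke property: populations persist in continuous habitat over replicates
  p20 <- tiny_stoch_params(n_gens = 20)
  for (s in 1:10) {
    set.seed(s)
    res <- run_level(init_population(ls, 20), ls, k, p20)
    expect_false(res$summary$extinct)
    expect_true(res$summary$median_size >= 0.5 && res$summary$median_size <= 30)
    expect_equal(res$summary$median_dispersal,
                 median_distance(lambda_of_size(k, res$summary$median_size)))
  }
})
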