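test_that("shock draws follow the Beta(alpha, beta) reduction law", {
  p <- model_params()
  r <- withr::with_seed(11, draw_shock(p, n = 1e5))
  expect_true(all(r >= 0 & r <= p$R_max))

  # mean: E[R] = R_max * beta / (alpha + beta) = R_max * 15/16
  vB <- (1 * 15) / ((1 + 15)^2 * (1 + 15 + 1))
  se <- p$R_max * sqrt(vB / 1e5)
  expect_lt(abs(mean(r) - p$R_max * 15 / 16), 4 * se)

  # tail: P(B > 0.2) = (1 - 0.2)^15 for Beta(1, 15)
  p_tail <- 0.8^15 # = 0.03518437208883203
  emp <- mean(r < p$R_max * 0.8)
  expect_lt(abs(emp - p_tail), 4 * sqrt(p_tail * (1 - p_tail) / 1e5))
})

test_that("shocks vanish in the concentrated-Beta limit", {
  p <- model_params(beta = 1e6)
  r <- withr::with_seed(2, draw_shock(p, n = 1000))
  expect_gt(min(r) / p$R_max, 0.999)
})

test_that("degenerate shock shapes are rejected", {
  p <- model_params()
  p$alpha <- -1 # bypass the constructor to hit draw_shock's own guard
  expect_error(draw_shock(p), "shape")
})

test_that("energy production matches the utility function", {
  p <- model_params()
  # unperturbed all-laborer society produces exactly 1 per capita
  expect_equal(compute_energy(400, 0, p$R_max, p) / 400, 1)
  # empty labor force produces nothing
  expect_identical(compute_energy(0, 0, 3.7, p), 0)
  # frozen oracle: 10^0.75 + 1.05 * 5^0.75 at R = 1
  expect_equal(compute_energy(10, 5, 1, p), 9.134299853029706, tolerance = 1e-12)
  expect_error(compute_energy(-1, 0, 1, p), "non-negative")
  expect_error(compute_energy(1, 0, -2, p), "non-negative")
})

test_that("energy is non-decreasing in the productivity factor c", {
  cs <- seq(1, 3, by = 0.25)
  E <- vapply(cs, function(cc) {
    compute_energy(10, 50, 2, model_params(c = cc))
  }, numeric(1))
  expect_true(all(diff(E) >= 0))
})

test_that("recruitment picks the best-connected eligible node", {
  # no admins yet: the hub has the most connections
  expect_identical(select_recruit(star_society(5)), 1L)
  # edgeless graph: nobody can ever be recruited
  expect_identical(select_recruit(society(4)), NA_integer_)
  # path 1-2-3-4, admin 1: only node 2 is coordinated, so node 3's equal
  # degree does not make it eligible
  expect_identical(select_recruit(path_society(4, admin = 1)), 2L)
  # fragmented: admins exist but no coordinated laborers remain
  s <- society(4, rbind(c(1, 2)), admin = c(1, 2))
  expect_identical(select_recruit(s), NA_integer_)
})

test_that("degree ties are broken by the seeded RNG", {
  s <- society(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) # 4-cycle
  picks <- withr::with_seed(5, replicate(40, select_recruit(s)))
  expect_true(all(picks %in% 1:4))
  expect_gt(length(unique(picks)), 1)
  expect_identical(
    withr::with_seed(9, select_recruit(s)),
    withr::with_seed(9, select_recruit(s))
  )
})

test_that("exploration flips are Bernoulli per node, committed synchronously", {
  s <- star_society(5, admin = 1)
  # p_e = 0: nothing moves
  r0 <- exploration_step(s, model_params(N = 6, p_e = 0))
  expect_identical(r0$n_flips, 0L)
  expect_identical(r0$state$admin, s$admin)
  # p_e = 1: every node flips, so the admin set becomes its complement
  r1 <- withr::with_seed(1, exploration_step(s, model_params(N = 6, p_e = 1)))
  expect_identical(r1$n_flips, 6L)
  expect_identical(r1$state$admin, !s$admin)
  # flip counts are Binomial(N, p_e) on average
  p <- model_params(N = 200, p_e = 0.05)
  s2 <- society(200)
  flips <- withr::with_seed(8, {
    replicate(500, exploration_step(s2, p)$n_flips)
  })
  se <- sqrt(200 * 0.05 * 0.95 / 500)
  expect_lt(abs(mean(flips) - 10), 4 * se)
})

test_that("a step recruits only when per-capita energy drops below epsilon", {
  # epsilon = 0 disables recruitment entirely; with p_e = 0 nothing changes
  p0 <- model_params(N = 20, rho = 0.3, epsilon = 0, p_e = 0, seed = 4)
  s <- withr::with_seed(4, build_network(p0))
  out <- withr::with_seed(5, simulate_step(s, p0))
  expect_false(out$record$recruited)
  expect_identical(out$state$admin, s$admin)

  # at defaults any positive shock pushes E/N below 1, so the very first
  # step recruits (whenever the graph has edges)
  p1 <- model_params(N = 50, rho = 0.2, seed = 4)
  s1 <- withr::with_seed(4, build_network(p1))
  out1 <- withr::with_seed(5, simulate_step(s1, p1))
  expect_true(out1$record$recruited)
  expect_identical(out1$record$N_A, 0L) # recorded counts are pre-recruitment
  expect_identical(sum(out1$state$admin), 1L) # effect lands next step
})

test_that("promotion changes energy from the next step onward", {
  # star hub promoted: E jumps from R * 6^a to R * c * 5^b
  p <- model_params(N = 6, seed = 1)
  s <- star_society(5)
  st1 <- simulate_step(s, p, t = 1L)
  expect_equal(st1$record$E, st1$record$R * 6^0.75)
  st2 <- simulate_step(st1$state, p, prev_E = st1$record$E, t = 2L)
  expect_equal(st2$record$E, st2$record$R * 1.05 * 5^0.75)
  expect_equal(st2$record$roc, st2$record$E - st1$record$E)
})

test_that("runs are deterministic in the seed and conserve the partition", {
  p <- small_params(p_e = 0.01, seed = 21)
  a <- run_simulation(p)
  b <- run_simulation(p)
  expect_identical(a$records, b$records)
  expect_identical(a$survival_time, b$survival_time)
  with(a$records, expect_true(all(N_L + N_C + N_A == 100L)))
})

test_that("without exploration the administration can only grow", {
  sim <- run_simulation(small_params(seed = 3))
  expect_true(all(diff(sim$records$N_A) >= 0))
})

test_that("the edgeless zero-mobility society stays in its initial state", {
  sim <- run_simulation(model_params(N = 30, rho = 0, p_e = 0, t_max = 100))
  expect_true(sim$censored)
  expect_identical(sim$terminal_cause, "reached-t_max")
  expect_true(all(sim$records$N_A == 0L))
  expect_false(any(sim$final_state$admin))
})

test_that("full administration is the absorbing zero-energy collapse state", {
  sim <- run_simulation(model_params(N = 60, rho = 0.2, t_max = 2000, seed = 2))
  expect_identical(sim$terminal_cause, "all-administrators")
  expect_false(sim$censored)
  expect_true(all(sim$final_state$admin))
  p <- sim$params
  expect_identical(compute_energy(0, 0, p$R_max, p), 0)
})

test_that("the energy-vs-administration curve smooths as requested", {
  # constant energy stays flat
  df <- tibble::tibble(t = 1:60, N_A = 1:60, E = 5)
  rc <- roc_curve(df, window = 7)
  expect_true(all(abs(stats::na.omit(rc$E_smooth) - 5) < 1e-12))
  # window 1 leaves E untouched, so differences equal raw energy steps
  rc1 <- roc_curve(df |> dplyr::mutate(E = c(1:30, 30:1)), window = 1)
  expect_identical(rc1$E_smooth, rc1$E)
  # a parabolic arc keeps its vertex (up to window bias)
  arc <- tibble::tibble(t = 1:101, N_A = 1:101, E = -(1:101 - 51)^2 + 2600)
  sm <- roc_curve(arc, window = 9)
  expect_lt(abs(sm$N_A[which.max(sm$E_smooth)] - 51), 5)
  expect_error(roc_curve(tibble::tibble()), "empty")
})
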