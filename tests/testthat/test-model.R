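test_that("Holling type-II response has the right values, limits and domain", {
  expect_identical(holling_response(2, 1, 0.5), 1)
  expect_identical(holling_response(0, 1, 0.5), 0)
  expect_lt(abs(holling_response(1e6, 1, 0.5) - 2), 1e-5)
  # saturation: sup over q equals 1/h_q
  expect_lt(abs(holling_response(1e8, 1.3, 0.25) - 1 / 0.25) / (1 / 0.25),
            1e-4)
  # monotone non-decreasing in q and in c_q
  q <- seq(0, 50, by = 0.25)
  expect_true(all(diff(holling_response(q, 0.7, 0.5)) >= 0))
  cs <- seq(0.1, 3, by = 0.1)
  vals <- vapply(cs, function(cq) holling_response(1.7, cq, 0.5), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(holling_response(-1, 1, 0.5), "q must be")
  expect_error(holling_response(1, 1, 0), "h_q")
})

test_that("dormancy switching function is a bounded decreasing sigmoid", {
  p <- dormprey_params()
  expect_identical(dormancy_switch(1, p), 0.2 + 0.75 / 2)  # midpoint
  expect_identical(dormancy_switch(1e6, p), 0.2)           # crowded limit
  expect_equal(dormancy_switch(0, p), 0.2 + 0.75 / (1 + exp(-10)),
               tolerance = 1e-12)
  # overflow-safe far beyond the threshold: exact chi, never NaN
  huge <- dormancy_switch(1e9, dormprey_params(sigma = 1e-6))
  expect_identical(huge, 0.2)
  # phi = 0 pins the function at chi for any predator density
  p10 <- dormprey_params(chi = 1, phi = 0)
  expect_identical(dormancy_switch(c(0, 0.3, 1, 42), p10), rep(1, 4))
  # strictly decreasing when phi > 0, and always inside [chi, chi + phi]
  set.seed(11)
  for (k in 1:20) {
    prm <- dormprey_params(eta = runif(1, 0.2, 3), sigma = runif(1, 0.02, 1),
                           chi = runif(1, 0, 0.5), phi = runif(1, 0.01, 0.5))
    z <- sort(runif(50, 0, 6))
    mu <- dormancy_switch(z, prm)
    expect_true(all(diff(mu) <= 0))   # tails saturate to the bounds
    expect_lt(dormancy_switch(prm$eta + prm$sigma, prm),
              dormancy_switch(prm$eta - prm$sigma, prm))
    expect_true(all(mu >= prm$chi & mu <= prm$chi + prm$phi))
  }
})

test_that("model right-hand side matches hand-evaluated rates", {
  p <- dormprey_params()
  d <- derivatives(initial_state(), p)
  # crowding 7/11, f_p(2) = f_y1(2) = 1, mu(1) = 0.575
  expect_equal(unname(d), c(-0.3, -6.975 / 11, 2.975 / 11, 0.8),
               tolerance = 1e-14)
  expect_identical(unname(derivatives(c(p = 0, y1 = 0, y2 = 0, z = 0), p)),
                   rep(0, 4))
  # only the dormancy-termination flux is active; it conserves y1 + y2
  d2 <- derivatives(c(p = 0, y1 = 0, y2 = 5, z = 0), p)
  expect_equal(unname(d2), c(0, 0.25, -0.25, 0), tolerance = 1e-14)
})

test_that("dormancy-termination flux conserves y1 + y2 without growth or predation", {
  prm <- dormprey_params(r_y = 0)
  set.seed(7)
  for (k in 1:50) {
    s <- c(p = runif(1, 0, 8), y1 = runif(1, 0, 8), y2 = runif(1, 0, 8), z = 0)
    d <- derivatives(s, prm)
    expect_equal(unname(d[["y1"]] + d[["y2"]]), 0, tolerance = 1e-14)
  }
})

test_that("a lone predator starves at its constant mortality rate", {
  p <- dormprey_params()
  for (z in c(0.1, 1, 7)) {
    d <- derivatives(c(p = 0, y1 = 0, y2 = 0, z = z), p)
    expect_equal(unname(d[["z"]]), -p$d_z * z, tolerance = 1e-14)
    expect_lt(d[["z"]], 0)
  }
})

test_that("with no dormitive prey the RHS reduces to Rosenzweig-MacArthur", {
  # rm_derivatives is independently coded two-species dynamics
  set.seed(42)
  p <- dormprey_params()
  for (k in 1:1000) {
    s <- c(p = runif(1, 0, 12), y1 = 0, y2 = 0, z = runif(1, 0, 4))
    d4 <- derivatives(s, p)
    d2 <- dormprey:::rm_derivatives(c(s[["p"]], s[["z"]]), p)
    expect_identical(unname(d4[c("p", "z")]), unname(d2))
    expect_identical(unname(d4[c("y1", "y2")]), c(0, 0))
  }
})

test_that("predator nullcline density solves k_p f_p(p) = d_z", {
  p <- dormprey_params()
  expect_identical(rm_prey_nullcline(p), 0.5)
  set.seed(3)
  for (k in 1:20) {
    prm <- dormprey_params(d_z = runif(1, 0.05, 0.4),
                           k_p = runif(1, 0.3, 0.9),
                           c_p = runif(1, 0.5, 2))
    pstar <- rm_prey_nullcline(prm)
    expect_equal(prm$k_p * holling_response(pstar, prm$c_p, prm$h_p),
                 prm$d_z, tolerance = 1e-12)
  }
  # predator that cannot persist: no finite nullcline
  expect_identical(rm_prey_nullcline(dormprey_params(d_z = 2)), Inf)
})
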