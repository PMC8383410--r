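make_traj <- function(time, ...) {
  df <- data.frame(time = time, ...)
  class(df) <- c("dormprey_trajectory", "data.frame")
  df
}

test_that("peak finder handles flat, sinusoidal and plateau signals", {
  t <- seq(0, 4 * pi, by = 0.1)
  flat <- make_traj(t, p = rep(2, length(t)))
  expect_identical(nrow(find_peaks(flat, "p")), 0L)

  sine <- make_traj(t, p = sin(t) + 2)
  pk <- find_peaks(sine, "p")
  expect_identical(nrow(pk), 2L)
  expect_lt(max(abs(pk$time - c(pi / 2, 5 * pi / 2))), 1e-3)
  expect_lt(max(abs(pk$value - 3)), 1e-4)

  # plateau counts once, at its midpoint; endpoints are never peaks
  v <- c(0, 1, 2, 2, 2, 1, 0, 5)
  plat <- make_traj(seq_along(v), p = v)
  pk2 <- find_peaks(plat, "p")
  expect_identical(nrow(pk2), 1L)
  expect_identical(pk2$time, 4)
  expect_identical(pk2$value, 2)

  expect_error(find_peaks(sine, "beaver"), "unknown species")
  expect_error(find_peaks(make_traj(1:2, p = 1:2), "p"), "3 samples")
})

test_that("peak finder agrees with a brute-force scan on random smooth signals", {
  set.seed(19)
  t <- seq(0, 30, by = 0.05)
  for (k in 1:200) {
    v <- 3 + rowSums(sapply(1:3, function(j)
      runif(1, 0.2, 1) * sin(runif(1, 0.3, 2) * t + runif(1, 0, 2 * pi))))
    got <- dormprey:::find_peaks_series(t, v, prominence = 0, refine = FALSE)
    want <- brute_peaks(t, v)
    expect_identical(got$time, want$time)
    expect_identical(got$value, want$value)
  }
})

test_that("prominence floor suppresses near-extinct ripple", {
  t <- seq(0, 10, by = 0.1)
  ripple <- make_traj(t, p = 1e-9 * (1 + sin(3 * t)))
  expect_identical(nrow(find_peaks(ripple, "p")), 0L)
  expect_gt(nrow(find_peaks(ripple, "p", prominence = 0)), 0L)
})

test_that("extinction time marks permanent decline below threshold", {
  tr <- make_traj(0:10, p = rep(2, 11))
  expect_identical(extinction_time(tr, "p"), NA_real_)
  # decays, recovers briefly, then stays down: extinction after the recovery
  tr2 <- make_traj(0:10, p = c(2, 1, 1e-4, 1e-5, 0.5, 2e-3, 1e-4, 1e-5,
                               1e-6, 1e-7, 1e-8))
  expect_identical(extinction_time(tr2, "p"), 6)
  # never above threshold: extinct from the start
  tr3 <- make_traj(0:10, p = rep(1e-6, 11))
  expect_identical(extinction_time(tr3, "p"), 0)
  expect_error(extinction_time(tr, "p", threshold = 0), "> 0")
})

test_that("extinction time is monotone in the threshold", {
  tr <- traj_K(11)
  ths <- c(1e-4, 1e-3, 1e-2, 0.05, 0.07, 0.1, 0.5, 1)
  ext <- vapply(ths, function(th) {
    e <- extinction_time(tr, "p", th)
    if (is.na(e)) Inf else e
  }, numeric(1))
  expect_true(all(diff(ext) <= 0))
})

test_that("single-form dormitive prey loses against the PA prey", {
  # active form alone: slow starvation through its growth handicap
  ext_a <- extinction_time(traj_preset("fig1a"), "y1")
  expect_identical(round(ext_a / 10) * 10, 40)
  # dormant form alone: gone within the first predator-prey cycle
  ext_b <- extinction_time(traj_preset("fig1b"), "y2")
  expect_lt(ext_b, 50)
  expect_true(all(traj_preset("fig1b")$y2[traj_preset("fig1b")$time > 50] < 1e-3))
  # the PA prey persists: its cycles keep returning long after y1 is gone
  tra <- traj_preset("fig1a")
  expect_gt(max(tra$p[tra$time > 100]), 1)
})

test_that("PA prey collapses under full competition at reference parameters", {
  tr <- traj_K(11)
  ext <- extinction_time(tr, "p")
  # the last macroscopic cycle collapses just after t = 370; a residual
  # sub-0.07 mg/L ripple keeps p above the 1e-3 floor until t ~ 420
  expect_lt(abs(ext - 420.6), 1)
  expect_identical(round(extinction_time(tr, "p", 0.1) / 10) * 10, 370)
  expect_true(all(tr$p[tr$time > 450] < 1e-3))
})

test_that("reversal time matches the reported values at K = 13 and K = 20", {
  expect_lt(abs(reversal_time(traj_K(13)) - 195.1), 5)
  expect_lt(abs(reversal_time(traj_K(20)) - 89.2), 5)
  # enrichment shortens the reversal
  expect_gt(reversal_time(traj_K(13)), reversal_time(traj_K(20)))
})

test_that("reversal time is insensitive to halving the output interval", {
  p13 <- update_params(dormprey_params(), K = 13)
  fine <- integrate_model(p13, t_span = c(0, 400),
                          settings = solver_settings(output_dt = 0.05))
  coarse <- integrate_model(p13, t_span = c(0, 400))
  expect_lt(abs(reversal_time(fine) - reversal_time(coarse)), 0.1)
})

test_that("winner label and reversal presence co-occur across carrying capacities", {
  t9 <- traj_K(9, 3000)
  expect_identical(classify_winner(t9)$winner, "PA")
  expect_identical(reversal_time(t9), NA_real_)
  for (K in c(11, 13, 20)) {
    tr <- traj_K(K, 3000)
    expect_identical(classify_winner(tr)$winner, "dormitive")
    expect_false(is.na(reversal_time(tr)))
  }
})

test_that("winner classification handles extinction, ties and bad windows", {
  t <- seq(2700, 3000, by = 0.5)
  dead <- make_traj(t, p = rep(0, length(t)), y1 = rep(0, length(t)))
  expect_identical(classify_winner(dead)$winner, "none")
  tie <- make_traj(t, p = rep(2, length(t)), y1 = rep(2, length(t)))
  expect_identical(classify_winner(tie)$winner, "none")
  expect_error(classify_winner(dead, window = c(0, 3000)), "outside")
})

test_that("cycle peaks in the enlarged window keep the reported order", {
  tr <- traj_K(11)
  w <- c(400, 450)
  pz <- find_peaks(tr, "z", window = w)
  py1 <- find_peaks(tr, "y1", window = w)
  py2 <- find_peaks(tr, "y2", window = w)
  expect_identical(nrow(pz), 1L)
  # dominant y2 peak falls between the y1 peak and the z peak
  t_y1 <- py1$time[which.max(py1$value)]
  t_y2 <- py2$time[which.max(py2$value)]
  expect_true(t_y1 < t_y2 && t_y2 < pz$time)
})

test_that("reversal curve shortens with K and plateaus at high K", {
  rc <- reversal_curve(dormprey_params(), c(9, 13, 20, 25, 30))
  expect_true(is.na(rc$T_w[rc$K == 9]))
  expect_gt(rc$T_w[rc$K == 13], rc$T_w[rc$K == 20])
  plateau <- abs(rc$T_w[rc$K == 25] - rc$T_w[rc$K == 30]) / rc$T_w[rc$K == 25]
  expect_lt(plateau, 0.1)
  expect_error(reversal_curve(dormprey_params(), c(-1, 5)), "positive")
})
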