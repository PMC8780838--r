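rooms3 <- c("a", "b", "c")

rand_adj <- function(n = 3, max = 20) {
  adjacency_matrix(matrix(sample.int(max, n * n, TRUE), n, n),
                   letters[seq_len(n)])
}

test_that("baseline is the entrywise mean of the first k days", {
  M <- rand_adj()
  same <- stats::setNames(rep(list(M), 7), format(as.Date("2021-03-01") + 0:6))
  B <- compute_baseline(same, 7)
  expect_equal(unclass(B), unclass(M), ignore_attr = TRUE)
  expect_equal(attr(B, "k"), 7)
  # a cell whose 7 days sum to 800 averages to 800/7 (114.29 at 2 d.p.)
  days <- lapply(c(100, 120, 110, 130, 115, 105, 120), function(v) {
    A <- adjacency_matrix(matrix(0, 2, 2), c("bathroom", "hallway"))
    A["bathroom", "bathroom"] <- v
    A
  })
  B2 <- compute_baseline(days, 7)
  expect_equal(B2["bathroom", "bathroom"], 800 / 7)
  expect_equal(round(B2["bathroom", "bathroom"], 2), 114.29)
  # random integer matrices vs a per-cell arithmetic oracle
  set.seed(5)
  dl <- replicate(7, rand_adj(), simplify = FALSE)
  B3 <- compute_baseline(dl, 7)
  for (i in 1:3) for (j in 1:3)
    expect_equal(B3[i, j], mean(vapply(dl, function(m) m[i, j], numeric(1))))
  expect_error(compute_baseline(dl[1:3], 7), "insufficient")
})

test_that("weight matrix has the standard 1 / 1.5 structure", {
  expect_equal(make_weight_matrix(2), matrix(c(1, 1.5, 1.5, 1), 2, 2))
  expect_equal(make_weight_matrix(1), matrix(1, 1, 1))
  expect_equal(make_weight_matrix(3, 1, 1), matrix(1, 3, 3))
  expect_error(make_weight_matrix(2, 0, 1.5), "positive")
  expect_error(make_weight_matrix(2, 1, -1), "positive")
})

test_that("weighted difference has its algebraic identities", {
  set.seed(9)
  B <- rand_adj()
  W <- make_weight_matrix(3)
  expect_equal(graph_diff(B, B, W), 0)
  half <- adjacency_matrix(unclass(B) / 2, rownames(B))
  expect_equal(graph_diff(B, half, W), sum(W * unclass(B)) / 2)
  # linearity in the daily argument
  D1 <- rand_adj(); D2 <- rand_adj()
  a <- 0.3; b <- 0.6
  mix <- adjacency_matrix(a * unclass(D1) + b * unclass(D2), rownames(B))
  zero <- adjacency_matrix(matrix(0, 3, 3), rownames(B))
  expect_equal(graph_diff(B, mix, W),
               a * graph_diff(B, D1, W) + b * graph_diff(B, D2, W) +
                 (1 - a - b) * graph_diff(B, zero, W))
  expect_error(graph_diff(B, rand_adj(4), make_weight_matrix(3)), "shape")
})

test_that("printed example matrices reproduce the spreadsheet oracle", {
  B <- baseline_example()
  D <- day_example()
  orc <- diff_oracle(B, D)
  expect_equal(graph_diff(B, D), orc$diff, tolerance = 1e-12)
  res <- percent_difference(B, D)
  expect_equal(res$raw, orc$diff, tolerance = 1e-12)
  expect_equal(res$pd, orc$pd, tolerance = 1e-12)
  # frozen values computed with the independent loop oracle
  expect_equal(orc$diff, -21.10, tolerance = 1e-9)
  expect_equal(orc$denom, 1115.90, tolerance = 1e-9)
  expect_equal(res$pd, -0.0189085043, tolerance = 1e-7)
})

test_that("percent difference has its exact limits", {
  set.seed(13)
  B <- rand_adj()
  W <- make_weight_matrix(3)
  expect_equal(percent_difference(B, B, W)$pd, 0)
  zero <- adjacency_matrix(matrix(0, 3, 3), rownames(B))
  expect_equal(percent_difference(B, zero, W)$pd, 1)
  for (c in c(0, 0.25, 0.5, 1)) {
    Dc <- adjacency_matrix((1 - c) * unclass(B), rownames(B))
    expect_equal(percent_difference(B, Dc, W)$pd, c, tolerance = 1e-12)
  }
  expect_error(percent_difference(zero, B, W), "degenerate")
})

test_that("adding mass to any daily cell strictly decreases pd", {
  set.seed(17)
  B <- rand_adj()
  D <- rand_adj()
  W <- make_weight_matrix(3)
  pd0 <- percent_difference(B, D, W)$pd
  for (i in 1:3) for (j in 1:3) {
    D2 <- D
    D2[i, j] <- D2[i, j] + 1
    expect_lt(percent_difference(B, D2, W)$pd, pd0)
  }
})

test_that("off-diagonal up-weighting makes pd sensitive to transition mix", {
  B <- adjacency_matrix(matrix(10, 2, 2), c("a", "b"))
  # same total mass, shifted between diagonal and off-diagonal
  D1 <- adjacency_matrix(matrix(c(20, 0, 0, 20), 2, 2), c("a", "b"))
  D2 <- adjacency_matrix(matrix(c(0, 20, 20, 0), 2, 2), c("a", "b"))
  Wflat <- make_weight_matrix(2, 1, 1)
  expect_equal(percent_difference(B, D1, Wflat)$pd,
               percent_difference(B, D2, Wflat)$pd)
  Wstd <- make_weight_matrix(2)
  expect_lt(percent_difference(B, D2, Wstd)$pd,
            percent_difference(B, D1, Wstd)$pd)
})

test_that("daily series applies the statistic day by day", {
  B <- baseline_example()
  dailies <- stats::setNames(rep(list(B), 10),
                             format(as.Date("2021-04-01") + 0:9))
  s <- daily_series(B, dailies)
  expect_equal(nrow(s), 10L)
  expect_equal(s$pd, rep(0, 10))
  # uniform decay has the exact closed form pd(t) = c * t
  c0 <- 0.002
  decay <- lapply(0:9, function(t)
    adjacency_matrix(unclass(B) * (1 - c0 * t), rownames(B)))
  names(decay) <- format(as.Date("2021-04-01") + 0:9)
  s2 <- daily_series(B, decay)
  expect_equal(s2$pd, c0 * (0:9), tolerance = 1e-12)
  expect_error(daily_series(B, stats::setNames(rep(list(B), 2),
                                               rep("2021-04-01", 2))),
               "duplicate")
})

test_that("a simulated stream's series equals per-day recomputation", {
  topo <- flat5()
  model <- resident_model(topo)
  sim <- simulate_participant(model, days = 40, seed = 3, slope = -0.002)
  dailies <- daily_matrices(sim$log, topo)
  B <- compute_baseline(dailies, 7)
  W <- make_weight_matrix(topo$n)
  s <- daily_series(B, dailies)
  # oracle: recompute each day independently from scratch
  for (k in sample(seq_len(nrow(s)), 8)) {
    d <- format(s$date[k])
    expect_equal(s$pd[k], percent_difference(B, dailies[[d]], W)$pd)
  }
  # baseline days excluded
  expect_false(any(format(s$date) %in% attr(B, "baseline_dates")))
})

test_that("difference series CSV round-trips in percent units", {
  s <- make_series(c(0.01, -0.02, 0.3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_difference_series(s, f)
  raw <- utils::read.csv(f)
  expect_equal(raw$pd_percent, c(1, -2, 30))
  s2 <- read_difference_series(f)
  expect_equal(s2$pd, s$pd)
  expect_equal(s2$date, s$date)
})
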