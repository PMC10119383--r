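test_that("filter_tracks removes negative rates and reports per strain", {
  t0 <- make_tracks(birth = seq(0, 9), rate = rep(0.2, 10))
  r0 <- filter_tracks(t0)
  expect_equal(r0$tracks, t0)
  expect_equal(r0$report$frac_excluded, 0)

  t1 <- make_tracks(birth = seq(0, 9), rate = c(rep(0.2, 8), -0.1, -0.2))
  r1 <- filter_tracks(t1)
  expect_equal(nrow(r1$tracks), 8)
  expect_equal(r1$report$frac_excluded, 0.2)

  # mixed strains: per-strain fractions equal an independent recount
  set.seed(5)
  tm <- do.call(rbind, lapply(c("a", "b", "c"), function(s)
    make_tracks(strain = s, birth = runif(20, 0, 28),
                rate = runif(20, -0.1, 0.4))))
  rm_ <- filter_tracks(tm)
  for (s in c("a", "b", "c")) {
    brute <- mean(tm$rate[tm$strain == s] < 0)
    expect_equal(rm_$report$frac_excluded[rm_$report$strain == s], brute)
  }

  expect_error(filter_tracks(make_tracks(birth = 1, rate = -1)), "all rows")
  expect_error(filter_tracks(t0[0, ]), "empty")
})

test_that("bin_by_birth bins, counts presence, and conserves cells", {
  # one cell born at 0, never departing: present in every one of 14 intervals
  t1 <- make_tracks(birth = 0, rate = 0.3)
  b1 <- bin_by_birth(t1)
  expect_equal(nrow(b1), 14)
  expect_equal(b1$n_present, rep(1, 14))
  expect_equal(b1$n_born, c(1, rep(0, 13)))

  # half-open convention: birth at exactly 2.0 goes to [2, 4)
  t2 <- make_tracks(birth = 2.0, rate = 0.3)
  b2 <- bin_by_birth(t2)
  expect_equal(b2$n_born[b2$t0 == 2], 1)
  expect_equal(b2$n_born[b2$t0 == 0], 0)

  # median of five rates
  t3 <- make_tracks(birth = rep(1, 5), rate = c(0.1, 0.2, 0.3, 0.4, 0.5))
  b3 <- bin_by_birth(t3)
  expect_equal(b3$median_rate[1], 0.3)

  # conservation: total births across bins = number of tracked cells
  set.seed(7)
  t4 <- make_tracks(birth = runif(200, 0, 28), rate = runif(200),
                    depart = ifelse(runif(200) < 0.3, runif(200, 14, 28), NA))
  t4$depart <- pmax(t4$depart, t4$birth)
  b4 <- bin_by_birth(t4)
  expect_equal(sum(b4$n_born), 200)

  # departures end presence; instant leavers are never present
  t5 <- make_tracks(birth = c(0, 0, 3), rate = 0.1, depart = c(NA, 5, 3))
  b5 <- bin_by_birth(t5)
  expect_equal(b5$n_present[b5$t0 == 0], 2)
  expect_equal(b5$n_present[b5$t0 == 4], 2) # departure at 5 overlaps [4,6)
  expect_equal(b5$n_present[b5$t0 == 6], 1)

  expect_error(bin_by_birth(make_tracks(birth = 30, rate = 1)), "rows")
})

test_that("fit_density_response recovers noiseless truth and derives N_half", {
  # noiseless self-consistency at (a, K_N, K_I) = (1, 20, 500)
  N <- c(2, 5, 10, 20, 40, 80, 160, 320, 640)
  mu <- density_response(N, 1, 20, 500)
  bins <- data.frame(chamber = 1, median_rate = mu, n_present = N)
  fit <- fit_density_response(bins)
  expect_true(fit$converged)
  expect_equal(fit$a, 1, tolerance = 1e-4)
  expect_equal(fit$K_N, 20, tolerance = 1e-4)
  expect_equal(fit$K_I, 500, tolerance = 1e-4)
  expect_gt(fit$R2, 0.99999)

  # N_half is consistent with the independent closed-form truth
  expect_equal(fit$N_half, polychamber:::n_half_truth(1, 20, 500),
               tolerance = 1e-6)

  # pure Monod limit: N_half equals K_N
  expect_equal(n_half_from_fit(1, 20, Inf), 20)

  # scale equivariance: mu * c scales a by c and leaves N_half unchanged
  bins2 <- bins; bins2$median_rate <- mu * 3
  fit2 <- fit_density_response(bins2)
  expect_equal(fit2$a, 3 * fit$a, tolerance = 1e-4)
  expect_equal(fit2$N_half, fit$N_half, tolerance = 1e-4)

  # too few bins: flagged, not fitted
  fit3 <- fit_density_response(bins[1:3, ])
  expect_false(fit3$converged)
})

test_that("fit_logistic_counts recovers exact and noisy logistic truth", {
  times <- seq(0, 28, by = 1)
  exact <- gen_logistic_counts(times, K_max = 100, k = 0.5, N0 = 1)
  fit <- fit_logistic_counts(exact)
  expect_true(fit$converged)
  expect_equal(fit$K_max, 100, tolerance = 1e-4)
  expect_equal(fit$k, 0.5, tolerance = 1e-4)
  expect_equal(fit$N0, 1, tolerance = 1e-3)

  # constant series: rejected as no growth signal
  flat <- data.frame(chamber = 1, time = times, count = 5)
  expect_false(fit_logistic_counts(flat)$converged)

  # noisy logistic (sd = 5 counts, fixed seed): K_max within 5%
  noisy <- gen_logistic_counts(times, K_max = 100, k = 0.5, N0 = 1, sd = 5,
                               seed = 42)
  fitn <- fit_logistic_counts(noisy)
  expect_true(fitn$converged)
  expect_lt(abs(fitn$K_max - 100) / 100, 0.05)
})

test_that("aggregate_metric finds the peak lineage size via event sweep", {
  # single founder, 8 resident cells
  t1 <- make_tracks(birth = seq(0, 7), rate = 0.1, founder = rep(1, 8))
  expect_equal(aggregate_metric(t1)$max_aggregate, 8)

  # two founders with peaks 3 and 5
  t2 <- make_tracks(birth = c(0, 1, 2, 0, 1, 2, 3, 4), rate = 0.1,
                    founder = c(1, 1, 1, 2, 2, 2, 2, 2))
  expect_equal(aggregate_metric(t2)$max_aggregate, 5)

  # departures: peak computed before departures, verified by brute-force
  # replay over a dense time grid (independent oracle)
  set.seed(11)
  birth <- sort(runif(40, 0, 20))
  depart <- ifelse(runif(40) < 0.5, birth + rexp(40, 0.2), NA)
  t3 <- make_tracks(birth = birth, rate = 0.1,
                    founder = sample(1:3, 40, replace = TRUE),
                    depart = depart)
  got <- aggregate_metric(t3)$max_aggregate
  grid <- sort(unique(c(birth, depart[!is.na(depart)]))) + 1e-9
  brute <- max(vapply(1:3, function(f) {
    tf <- t3[t3$founder == f, ]
    max(vapply(grid, function(tt)
      sum(tf$birth <= tt & (is.na(tf$depart) | tf$depart > tt)), numeric(1)))
  }, numeric(1)))
  expect_equal(got, brute)

  t4 <- t1; t4$founder <- NA
  expect_error(aggregate_metric(t4), "founder")
})

test_that("compare_groups: exact U, p, and Hodges-Lehmann difference", {
  # enumerate all C(4,2) = 6 labelings: U = 0, two-sided p = 2/6
  r <- compare_groups(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")

  # identical samples: HL difference 0
  expect_equal(compare_groups(c(5, 6, 7), c(5, 6, 7))$hl, 0)

  # median of the 9 enumerated pairwise differences
  expect_equal(compare_groups(c(1, 2, 3), c(2, 4, 6))$hl, 2)

  # matches R's exact Mann-Whitney for tie-free samples
  set.seed(21)
  for (i in 1:5) {
    x <- round(runif(5), 3); y <- round(runif(6) + 0.2, 3)
    r2 <- compare_groups(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(r2$p, ref$p.value, tolerance = 1e-12)
    expect_equal(r2$U, unname(ref$statistic))
  }

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("compare_groups matches an exhaustive-enumeration oracle (n+m <= 12)", {
  # independent oracle: rank-sum formulation over explicit labelings
  oracle <- function(x, y) {
    n <- length(x); pooled <- c(x, y); N <- length(pooled)
    rk <- rank(pooled)
    W_obs <- sum(rk[seq_len(n)])
    U_obs <- W_obs - n * (n + 1) / 2
    labelings <- utils::combn(N, n)
    Ws <- apply(labelings, 2, function(ix) sum(rk[ix]))
    p <- min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
    hl <- median(as.numeric(sapply(y, function(b) b - x)))
    list(U = U_obs, p = p, hl = hl)
  }
  set.seed(33)
  cases <- list(
    list(x = rnorm(4), y = rnorm(5)),
    list(x = rnorm(6), y = rnorm(6) + 1),
    list(x = c(1, 1, 2, 3), y = c(2, 2, 3, 5)), # ties
    list(x = rpois(5, 3), y = rpois(7, 5)) # discrete, many ties
  )
  for (cs in cases) {
    got <- compare_groups(cs$x, cs$y)
    ref <- oracle(cs$x, cs$y)
    expect_equal(got$U, ref$U, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
    expect_equal(got$hl, ref$hl, tolerance = 1e-12)
  }
})

test_that("compare_groups falls back to a tie-corrected normal approximation", {
  set.seed(8)
  x <- rnorm(12); y <- rnorm(10) + 0.8
  r <- compare_groups(x, y)
  expect_equal(r$method, "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
})
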