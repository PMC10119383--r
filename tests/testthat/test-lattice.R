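test_that("make_fields places interior and boundary values as specified", {
  # 50x50 chamber, polymer everywhere at the boundary value: uniform field
  spec <- lattice_spec(50, 50)
  f <- make_fields(spec, c(P = 0.1, E = 0, O = 0))
  expect_true(all(f$P == 0.1))
  expect_true(all(f$E == 0) && all(f$O == 0))

  # all-zero case
  spec0 <- lattice_spec(6, 6, boundary = c(P = 0, E = 0, O = 0))
  f0 <- make_fields(spec0, c(P = 0, E = 0, O = 0))
  expect_true(all(f0$P == 0) && all(f0$E == 0) && all(f0$O == 0))

  # 5x5: 9 interior sites at 1, 16 boundary sites at 0
  spec5 <- lattice_spec(5, 5, boundary = c(P = 0, E = 0, O = 0))
  f5 <- make_fields(spec5, c(O = 1))
  expect_equal(sum(f5$O == 1), 9)
  expect_equal(sum(f5$O == 0), 16)

  expect_error(make_fields(spec, c(O = -1)), "field O")
})

test_that("lattice_spec and parameter constructors validate their inputs", {
  expect_error(lattice_spec(2, 10), "n_rows")
  expect_error(lattice_spec(10, 10, spacing = 0), "spacing")
  expect_error(lattice_spec(10, 10, boundary = c(P = -0.1)), "boundary")
  expect_error(transport_params(D_rel = 0), "D_rel")
  expect_error(transport_params(D_P = -1))
  expect_error(depoly_params(K_P = 0), "K_P")
  expect_error(depoly_params(conv = 1.5), "conv")
})

test_that("diffuse_step: outflow, identity at D = 0, and dense-solve oracle", {
  spec <- tiny_spec(7, boundary = c(P = 0, E = 0, O = 0))
  f <- make_fields(spec, c(P = 1, E = 1, O = 1))
  tr <- slow_transport(50)
  g <- diffuse_step(f, tr, 0.01)
  m <- polychamber:::interior_mask(spec)
  expect_true(all(g$P[m] < 1)) # strict outflow to the zero boundary
  expect_true(all(g$P >= 0))

  tr0 <- transport_params(D_P = 0, D_E = 0, D_O = 0)
  expect_equal(diffuse_step(f, tr0, 0.01), f)

  # one implicit step against an independently assembled dense solve
  src <- make_fields(spec, c(P = 0, E = 0, O = 0))
  src$O[4, 4] <- 1
  stepped <- diffuse_step(src, tr, 0.02)
  L <- dense_dirichlet_laplacian(7, 7)
  alpha <- 50 * 0.02 / 1
  u <- solve(diag(25) + alpha * L, src$O[2:6, 2:6][TRUE])
  expect_equal(stepped$O[2:6, 2:6], matrix(u, 5, 5), tolerance = 1e-12)

  # point source on a symmetric grid stays symmetric under all reflections
  expect_equal(stepped$O, stepped$O[7:1, ], tolerance = 1e-14)
  expect_equal(stepped$O, stepped$O[, 7:1], tolerance = 1e-14)
  expect_equal(stepped$O, t(stepped$O), tolerance = 1e-14)
})

test_that("iterated implicit stepping converges to the matrix-exponential limit", {
  # brute-force dense matrix exponential on a 7x7 grid as the time-accuracy
  # oracle: backward Euler converges to it linearly in dt
  spec <- tiny_spec(7, boundary = c(P = 0, E = 0, O = 0))
  L <- dense_dirichlet_laplacian(7, 7)
  u0 <- numeric(25); u0[13] <- 1
  D <- 30; t_end <- 0.05
  exact <- as.numeric(Matrix::expm(-D * t_end * L) %*% u0)
  err <- vapply(c(20, 80), function(nsteps) {
    f <- make_fields(spec, c(P = 0, E = 0, O = 0))
    f$O[4, 4] <- 1
    tr <- slow_transport(D)
    sv <- make_diffusion_solvers(spec, tr, t_end / nsteps)
    for (i in seq_len(nsteps)) f <- diffuse_step(f, tr, t_end / nsteps, sv)
    max(abs(f$O[2:6, 2:6][TRUE] - exact))
  }, numeric(1))
  expect_lt(err[2], err[1] / 2.5) # ~first-order convergence
  expect_lt(err[2], 2e-3)
})

test_that("closed-mode diffusion conserves mass; open mode obeys the maximum principle", {
  spec <- lattice_spec(9, 11, closed = TRUE)
  f <- make_fields(spec, c(P = 0, E = 0, O = 0))
  set.seed(42)
  f$P[] <- runif(99); f$O[] <- runif(99, 0, 5)
  tr <- slow_transport(200)
  sv <- make_diffusion_solvers(spec, tr, 0.01)
  m0 <- field_mass(f)
  for (i in 1:1000) f <- diffuse_step(f, tr, 0.01, sv)
  expect_equal(field_mass(f), m0, tolerance = 1e-10)

  # no sources: interior values stay within [min, max] of initial + boundary
  spec2 <- tiny_spec(9, boundary = c(P = 0.5, E = 0, O = 0))
  g <- make_fields(spec2, c(P = 2))
  sv2 <- make_diffusion_solvers(spec2, slow_transport(80), 0.02)
  for (i in 1:200) {
    g <- diffuse_step(g, slow_transport(80), 0.02, sv2)
    expect_true(all(g$P <= 2 + 1e-12) && all(g$P >= 0.5 - 1e-12))
  }
})

test_that("steady_state_oracle solves trivial and sourced cases", {
  spec <- lattice_spec(10, 10, boundary = c(P = 0, E = 0, O = 0))
  tr <- slow_transport(100)
  z <- steady_state_oracle(spec, tr)
  expect_true(all(z$P == 0) && all(z$O == 0))

  spec_c <- lattice_spec(10, 10, boundary = c(P = 0.3, E = 0.3, O = 0.3))
  u <- steady_state_oracle(spec_c, tr)
  expect_equal(u$P, matrix(0.3, 10, 10), tolerance = 1e-12)

  expect_error(steady_state_oracle(lattice_spec(25, 25), tr), "20 x 20")
})

test_that("iterated diffuse_step with constant source reaches the oracle fixed point", {
  spec <- lattice_spec(10, 10, boundary = c(P = 0.1, E = 0, O = 0))
  tr <- slow_transport(100)
  src <- matrix(0, 10, 10); src[5, 6] <- 1
  ora <- steady_state_oracle(spec, tr, list(O = src))
  f <- make_fields(spec)
  dt <- 0.05
  sv <- make_diffusion_solvers(spec, tr, dt)
  for (i in 1:3000) {
    f$O <- f$O + src * dt
    f <- diffuse_step(f, tr, dt, sv)
  }
  expect_lt(max(abs(f$O - ora$O)), 1e-6)
  expect_lt(max(abs(f$P - ora$P)), 1e-6) # P: no source, boundary-driven
})

test_that("depolymerize_step follows the rate law and conserves mass", {
  spec <- tiny_spec(6)
  dp <- depoly_params(k_cat = 2, K_P = 0.05, conv = 1)

  # no catalyst: nothing happens
  f <- make_fields(spec, c(P = 0.5, E = 0, O = 0))
  r <- depolymerize_step(f, dp, 0.1)
  expect_equal(r$fields, f)
  expect_equal(r$depolymerized, 0)

  # saturation limit P >> K_P: dP ~ k_cat E dt at that site
  f2 <- make_fields(spec, c(P = 0, E = 0, O = 0))
  f2$P[3, 3] <- 500; f2$E[3, 3] <- 1
  r2 <- depolymerize_step(f2, dp, 1e-3)
  expect_equal(r2$depolymerized, 2 * 1e-3, tolerance = 1e-4)

  # half-saturation identity P = K_P: dP -> k_cat dt / 2, O gains the same
  f3 <- make_fields(spec, c(P = 0, E = 0, O = 0))
  f3$P[4, 4] <- 0.05; f3$E[4, 4] <- 1
  dt <- 1e-5
  r3 <- depolymerize_step(f3, dp, dt)
  expect_equal(r3$depolymerized, 2 * dt / 2, tolerance = 1e-3)
  expect_equal(r3$fields$O[4, 4], r3$depolymerized, tolerance = 1e-12)

  # exact conservation at conv = 1 for arbitrary fields and a coarse step
  f4 <- make_fields(spec, c(P = 0.2, E = 3, O = 0.01))
  r4 <- suppressWarnings(depolymerize_step(f4, dp, 5))
  dP_tot <- sum(f4$P) - sum(r4$fields$P)
  dO_tot <- sum(r4$fields$O) - sum(f4$O)
  expect_equal(dP_tot, dO_tot, tolerance = 1e-12)
  expect_true(all(r4$fields$P >= 0))

  # step-size diagnostic fires when the Euler predictor overshoots
  expect_warning(depolymerize_step(f4, depoly_params(k_cat = 100), 10),
                 "dt too coarse")
})
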