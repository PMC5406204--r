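test_that("well-tempered height law reproduces its closed forms", {
  w0 <- kj_to_kcal(5)
  expect_equal(w0, 5 / 4.184)
  expect_equal(wt_hill_height(0, w0, 10, 300), w0)
  # at V = kB (f-1) T the height drops to w0 / e
  v <- KB_KCAL * 9 * 300
  expect_equal(wt_hill_height(v, w0, 10, 300), w0 / exp(1))
  expect_lt(wt_hill_height(1e4, w0, 10, 300), 1e-300)
  expect_error(wt_hill_height(0, w0, 1, 300), "bias factor")
  # f -> 1+ collapses deposition for any positive bias
  expect_equal(wt_hill_height(0.1, w0, 1 + 1e-9, 300), 0)
})

test_that("bias evaluation matches the naive full Gaussian sum", {
  expect_equal(bias_potential_and_force(NULL, c(0.5, 0.5)),
               list(value = 0, gradient = c(0, 0)))
  one <- tibble::tibble(time = 0, cv1 = 0.3, cv2 = 0.7, sigma_cv1 = 0.05,
                        sigma_cv2 = 0.05, height = 1.2, biasf = 10)
  at_center <- bias_potential_and_force(one, c(0.3, 0.7))
  expect_equal(at_center$value, 1.2)
  expect_equal(at_center$gradient, c(0, 0))

  set.seed(99)
  hills <- tibble::tibble(
    time = 1:100, cv1 = stats::runif(100), cv2 = stats::runif(100),
    sigma_cv1 = 0.05, sigma_cv2 = 0.05,
    height = stats::runif(100, 0.2, 1.2), biasf = 10)
  naive <- function(p) {
    v <- 0; g <- c(0, 0)
    for (i in 1:100) {
      e <- hills$height[i] *
        exp(-(p[1] - hills$cv1[i])^2 / (2 * 0.05^2) -
              (p[2] - hills$cv2[i])^2 / (2 * 0.05^2))
      v <- v + e
      g <- g + c(-e * (p[1] - hills$cv1[i]) / 0.05^2,
                 -e * (p[2] - hills$cv2[i]) / 0.05^2)
    }
    list(value = v, gradient = g)
  }
  for (p in list(c(0.5, 0.5), c(0.1, 0.9), c(0.77, 0.23))) {
    full <- bias_potential_and_force(hills, p)
    trunc <- bias_potential_and_force(hills, p, truncate = TRUE)
    ref <- naive(p)
    expect_equal(full$value, ref$value, tolerance = 1e-12)
    expect_equal(full$gradient, ref$gradient, tolerance = 1e-12)
    expect_equal(trunc$value, ref$value, tolerance = 1e-6)
  }
})

test_that("overdamped step is a fixed point at T = 0 in a minimum and samples kBT/k", {
  pot <- potential_harmonic(c(0.5, 0.5), stiffness = 50)
  p <- engine_params(temperature_ladder = 300, seed = 1)
  st <- list(coordinates = c(0.5, 0.5), temperature = 0)
  st2 <- langevin_step(st, pot, NULL, p)
  expect_equal(st2$coordinates, c(0.5, 0.5))

  # long compiled run: stationary variance = kB T / k within 3 SE
  run <- run_pt_metad(pot, p, n_steps = 400000, deposit_hills = FALSE,
                      record_stride = 25)
  v <- stats::var(run$colvar$cv1)
  expected <- KB_KCAL * 300 / 50
  n_eff <- nrow(run$colvar) / 5  # conservative autocorrelation allowance
  se <- expected * sqrt(2 / n_eff)
  expect_lt(abs(v - expected), 3 * se)
})

test_that("runs are reproducible from the seed and replica streams are disjoint", {
  pot <- potential_double_well()
  p <- engine_params(seed = 8)
  r1 <- run_pt_metad(pot, p, n_steps = 5000)
  r2 <- run_pt_metad(pot, p, n_steps = 5000)
  expect_identical(r1$hills, r2$hills)
  expect_identical(r1$replica_traj, r2$replica_traj)

  # base replica's unbiased path is unchanged by the ladder size
  p1 <- engine_params(temperature_ladder = 300, seed = 8,
                      exchange_stride = 1e9)
  p3 <- engine_params(temperature_ladder = c(300, 350, 400), seed = 8,
                      exchange_stride = 1e9)
  a <- run_pt_metad(pot, p1, 2000, deposit_hills = FALSE,
                    record_stride = 10)
  b <- run_pt_metad(pot, p3, 2000, deposit_hills = FALSE,
                    record_stride = 10)
  expect_identical(a$colvar, b$colvar)
})

test_that("exchange acceptance follows the Metropolis closed form", {
  # equal energies: always accepted
  ri <- list(coordinates = c(0, 0), potential_energy = 1, temperature = 300)
  rj <- list(coordinates = c(1, 1), potential_energy = 1, temperature = 400)
  expect_equal(exchange_probability(1, 1, 300, 400), 1)
  res <- attempt_exchange(ri, rj)
  expect_true(res$accepted)
  expect_equal(res$replica_i$coordinates, c(1, 1))

  # closed form: T 300/400, dU = -2 kcal/mol -> p = exp(-0.83871)
  p <- exchange_probability(0, 2, 300, 400)
  expect_equal(p, 0.4323, tolerance = 1e-4)
  expect_equal(p, exp((1 / (KB_KCAL * 300) - 1 / (KB_KCAL * 400)) * -2))

  # acceptance frequency over many attempts vs analytic expectation
  set.seed(5)
  n <- 1e5
  ui <- stats::rnorm(n, 0, 1)
  uj <- stats::rnorm(n, 0.5, 1)
  pvec <- pmin(1, exp((1 / (KB_KCAL * 300) - 1 / (KB_KCAL * 400)) *
                        (ui - uj)))
  acc <- stats::runif(n) < pvec
  sigma <- sqrt(sum(pvec * (1 - pvec)))
  expect_lt(abs(sum(acc) - sum(pvec)), 3 * sigma)
})

test_that("paired Metropolis dynamics with exchanges preserves Boltzmann occupancies", {
  # two-level system (E = 0 or 1 kcal/mol) at two temperatures with
  # exchange attempts every sweep
  set.seed(17)
  temps <- c(300, 400)
  E <- c(0, 1)
  state <- c(1L, 1L)
  n_sweep <- 4e4
  occ_hi <- matrix(FALSE, n_sweep, 2)
  for (t in seq_len(n_sweep)) {
    for (r in 1:2) {
      prop <- 3L - state[r]
      if (log(stats::runif(1)) <
            -(E[prop] - E[state[r]]) / (KB_KCAL * temps[r])) {
        state[r] <- prop
      }
    }
    ri <- list(coordinates = state[1], potential_energy = E[state[1]],
               temperature = temps[1])
    rj <- list(coordinates = state[2], potential_energy = E[state[2]],
               temperature = temps[2])
    ex <- attempt_exchange(ri, rj)
    state <- c(ex$replica_i$coordinates, ex$replica_j$coordinates)
    occ_hi[t, ] <- state == 2L
  }
  for (r in 1:2) {
    p_exp <- exp(-1 / (KB_KCAL * temps[r])) /
      (1 + exp(-1 / (KB_KCAL * temps[r])))
    phat <- mean(occ_hi[, r])
    se <- sqrt(p_exp * (1 - p_exp) / (n_sweep / 5))  # autocorrelation slack
    expect_lt(abs(phat - p_exp), 3 * se)
  }
})

test_that("hill bookkeeping: none before the first stride, heights decay on revisits", {
  pot <- potential_harmonic(c(0.5, 0.5), stiffness = 200)
  p <- engine_params(temperature_ladder = 300, seed = 4)
  short <- run_pt_metad(pot, p, n_steps = p$deposition_stride - 1)
  expect_equal(nrow(short$hills), 0)

  # the bias only grows, so the height the law would deposit at any
  # fixed revisited point is non-increasing in time
  run <- run_pt_metad(pot, p, n_steps = 60 * p$deposition_stride)
  h <- run$hills
  probe <- c(0.5, 0.5)
  v_after <- vapply(seq_len(nrow(h)), function(k) {
    bias_potential_and_force(h[seq_len(k), ], probe)$value
  }, numeric(1))
  would_deposit <- wt_hill_height(v_after, p$w0, p$bias_factor, 300)
  expect_true(all(diff(would_deposit) <= 1e-12))
  # overall decay at the revisited basin
  expect_lt(mean(tail(h$height, 5)), mean(head(h$height, 5)))
  # recorded heights obey the law against the engine's own bias state
  expect_true(all(h$height <= p$w0 + 1e-12))
})

test_that("metadynamics multiplies barrier crossings on the double well", {
  pot <- potential_double_well(delta_f = 3, barrier = 6)
  p <- engine_params(temperature_ladder = 300, seed = 21)
  n <- 400000
  biased <- run_pt_metad(pot, p, n, record_stride = 50)
  unbiased <- run_pt_metad(pot, p, n, deposit_hills = FALSE,
                           record_stride = 50)
  crossings <- function(run) {
    side <- sign(run$colvar$cv1 + run$colvar$cv2 - 1)
    side <- side[side != 0]
    sum(diff(side) != 0)
  }
  cb <- crossings(biased)
  cu <- crossings(unbiased)
  expect_gt(cb, max(10 * max(cu, 1), 10))
})

test_that("frozen energy bias is static, broadens energies, and round-trips", {
  pot <- potential_harmonic(c(0.5, 0.5), stiffness = 50)
  p <- engine_params(temperature_ladder = c(300, 400), seed = 3)
  wte <- precompute_energy_bias(pot, p, n_steps = 5000)
  expect_gt(max(wte$bias), 0)

  # scale 0: production identical to unbiased PT under the same seed
  wte0 <- wte; wte0$scale <- 0
  a <- run_pt_metad(pot, p, 4000, deposit_hills = FALSE,
                    record_stride = 10)
  b <- run_pt_metad(pot, p, 4000, deposit_hills = FALSE,
                    record_stride = 10, wte = wte0)
  expect_identical(a$colvar, b$colvar)

  # the frozen bias flattens the energy distribution
  ru <- run_pt_metad(pot, p, 50000, deposit_hills = FALSE,
                     record_stride = 10)
  rb <- run_pt_metad(pot, p, 50000, deposit_hills = FALSE,
                     record_stride = 10, wte = wte)
  eu <- model_value(pot, as.matrix(ru$colvar[, c("cv1", "cv2")]))
  eb <- model_value(pot, as.matrix(rb$colvar[, c("cv1", "cv2")]))
  expect_gte(stats::var(eb), stats::var(eu))

  f <- withr::local_tempfile(fileext = ".dat")
  write_energy_bias(wte, f)
  expect_identical(unclass(read_energy_bias(f)), unclass(wte))
})

test_that("structure mode needs a contact set and deposits hills at the walker's CVs", {
  fx <- two_state_fixture()
  p <- engine_params(temperature_ladder = 300, seed = 2, friction = 50)
  expect_error(run_pt_metad(fx$ts$inactive_reference, p, 100),
               "contact_set")
  run <- run_pt_metad(fx$ts$inactive_reference, p,
                      n_steps = 6 * p$deposition_stride,
                      contact_set = fx$cs)
  expect_equal(nrow(run$hills), 6)
  expect_true(all(run$hills$height > 0))
  # the walker starts at the inactive reference: cv1 stays small
  expect_true(all(run$colvar$cv1 < 0.2))
  r2 <- run_pt_metad(fx$ts$inactive_reference, p,
                     n_steps = 6 * p$deposition_stride,
                     contact_set = fx$cs)
  expect_identical(run$colvar, r2$colvar)
})

test_that("HILLS files round-trip in the PLUMED-compatible layout", {
  pot <- potential_double_well()
  p <- engine_params(seed = 31)
  run <- run_pt_metad(pot, p, n_steps = 10 * p$deposition_stride)
  f <- withr::local_tempfile(fileext = ".hills")
  write_hills(run$hills, f)
  expect_match(readLines(f, n = 1),
               "^#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf$")
  back <- read_hills(f)
  expect_equal(as.data.frame(back), as.data.frame(run$hills),
               tolerance = 1e-8)
})

test_that("ladder tuning reaches the target acceptance window", {
  pot <- potential_double_well()
  p <- engine_params(temperature_ladder = c(300, 500, 700, 900), seed = 6)
  tuned <- tune_temperature_ladder(pot, p, target = 0.5, tol = 0.15,
                                   pilot_steps = 20000)
  run <- run_pt_metad(pot, tuned, 20000, deposit_hills = FALSE,
                      record_stride = 1000)
  expect_lt(abs(mean(run$exchange$rate) - 0.5), 0.2)
  expect_true(all(diff(tuned$temperature_ladder) > 0))
})
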