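test_that("identical seeds give bitwise-identical trajectories", {
  p <- model_params(k_on = 1, k_off = 1, v_tx = 20, k_fold = 0.5,
                    k_unfold = 0.5, k_tl = 2, gamma_R = 1, gamma_P = 0.5)
  a <- simulate_ssa(p, t_end = 20, seed = 42)
  b <- simulate_ssa(p, t_end = 20, seed = 42)
  expect_identical(a$time, b$time)
  expect_identical(a$P, b$P)
  c <- simulate_ssa(p, t_end = 20, seed = 43)
  expect_false(identical(a$time, c$time))
})

test_that("event-recorded trajectories obey the reaction stoichiometry", {
  p <- model_params(k_on = 1, k_off = 1, v_tx = 10, k_fold = 1,
                    k_unfold = 1, k_tl = 1, gamma_R = 1, gamma_P = 1)
  tr <- simulate_ssa(p, t_end = 30, seed = 5)
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(tr$R_u >= 0 & tr$R_f >= 0 & tr$P >= 0))
  expect_true(all(tr$promoter %in% c(0, 1)))
  # every step changes the state by exactly one reaction's stoichiometry
  d <- apply(as.matrix(tr[, c("promoter", "R_u", "R_f", "P")]), 2, diff)
  legal <- rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(0, 1, 0, 0),
                 c(0, 0, 1, 0), c(0, -1, 1, 0), c(0, 1, -1, 0),
                 c(0, 0, 0, 1), c(0, -1, 0, 0), c(0, 0, -1, 0),
                 c(0, 0, 0, -1))
  key <- apply(d, 1, paste, collapse = ",")
  expect_true(all(key %in% apply(legal, 1, paste, collapse = ",")))
})

test_that("pure-death protein decay has the closed-form extinction time", {
  p <- model_params(k_on = 0, k_off = 0, v_tx = 0, gamma_R = 1, gamma_P = 1)
  set.seed(11)
  ext <- replicate(400, {
    tr <- simulate_ssa(p, init = c(promoter = 0, R_u = 0, R_f = 0, P = 5,
                                   t = 0), t_end = 100)
    expect_true(all(diff(tr$P) <= 0))
    min(tr$time[tr$P == 0])
  })
  # E[T] = sum_{k=1..5} 1/k, Var[T] = sum 1/k^2
  expect_equal(mean(ext), sum(1 / (1:5)),
               tolerance = 3 * sqrt(sum(1 / (1:5)^2) / 400) / sum(1 / (1:5)))
})

test_that("unreachable folded state stays empty when folding is off", {
  p <- model_params(k_on = 1, k_off = 1, v_tx = 10, k_fold = 0,
                    k_unfold = 0, gamma_R = 1)
  tr <- simulate_ssa(p, t_end = 50, seed = 3)
  expect_true(all(tr$R_f == 0))
})

test_that("grid recording samples the trajectory at fixed steps", {
  p <- model_params(k_on = 1, k_off = 1, v_tx = 10, gamma_R = 1)
  tr <- simulate_ssa(p, t_end = 10, seed = 8, record = "grid", dt = 0.5)
  expect_equal(tr$time, seq(0, 10, by = 0.5))
  # grid states are integers (piecewise-constant sampling, not interpolation)
  expect_true(all(tr$R_u == round(tr$R_u)))
})

test_that("a long time-average reproduces the telegraph stationary law", {
  p <- model_params(k_on = 1, k_off = 1, v_tx = 20, gamma_R = 1)
  tr <- simulate_ssa(p, t_end = 3000, seed = 21, record = "grid", dt = 0.5)
  burn <- tr$time > 20
  m <- mean(tr$R_u[burn]); f <- var(tr$R_u[burn]) / m
  expect_equal(m, 10, tolerance = 0.1)
  expect_equal(f, 4.333, tolerance = 0.25)
})

test_that("simulation rejects invalid domains", {
  p <- model_params()
  expect_error(simulate_ssa(p, t_end = 0), "t_end")
  expect_error(simulate_ssa(p, init = c(promoter = 1, R_u = -1, R_f = 0,
                                        P = 0, t = 0), t_end = 1),
               "non-negative")
  expect_error(ensemble_moments(p, n_cells = 1), "n_cells")
})

test_that("ensemble moments are seed-reproducible and match the telegraph oracle", {
  p <- model_params(k_on = 1, k_off = 1, v_tx = 20, gamma_R = 1)
  em <- ensemble_moments(p, n_cells = 1000, seed = 7)
  em2 <- ensemble_moments(p, n_cells = 1000, seed = 7)
  expect_identical(as.data.frame(em), as.data.frame(em2))
  s <- attr(em, "samples")[, "R_total"]
  truth <- telegraph_moments(p)
  expect_equal(em["R_total", "mean"], truth$mean_R,
               tolerance = 3 * se_mean(s) / truth$mean_R)
  fano_se <- boot_se(s, function(x) var(x) / mean(x))
  expect_equal(em["R_total", "fano"], truth$fano_R,
               tolerance = 3 * fano_se / truth$fano_R)
})

test_that("constitutive no-folding mRNA is Poisson at stationarity", {
  p <- model_params(k_on = 1, k_off = 0, v_tx = 10, gamma_R = 1)
  em <- ensemble_moments(p, n_cells = 2000, seed = 9)
  s <- attr(em, "samples")[, "R_total"]
  expect_equal(em["R_total", "mean"], 10, tolerance = 3 * se_mean(s) / 10)
  fano_se <- boot_se(s, function(x) var(x) / mean(x))
  expect_equal(em["R_total", "fano"], 1, tolerance = 3 * fano_se)
})

test_that("folding sweep conserves total mRNA and collapses to telegraph at k=0", {
  base <- model_params(k_on = 1, k_off = 1, v_tx = 10, k_tl = 2,
                       gamma_R = 1, gamma_P = 1)
  sw <- folding_noise_sweep(base, k_fold_grid = c(0, 0.5),
                            k_unfold_grid = c(0, 0.5),
                            n_cells = 600, seed = 13)
  expect_equal(nrow(sw), 4)
  truth <- telegraph_moments(model_params(k_on = 1, k_off = 1, v_tx = 10,
                                          gamma_R = 1))
  # total mRNA mean invariant across the folding grid
  expect_true(all(abs(sw$mean_R_total - truth$mean_R) <
                    3 * sw$mean_R_total * sw$cv_R_total / sqrt(600)))
  expect_error(folding_noise_sweep(base, numeric(0), 1, n_cells = 10),
               "non-empty")
})

test_that("fast folding at unfolded fraction 1/2 approaches the halved-rate model", {
  # fast-exchange limit: translation at k_tl with half the mRNA unfolded
  # behaves as k_tl/2 acting on all mRNA
  base <- model_params(k_on = 1, k_off = 0, v_tx = 10, k_tl = 10,
                       gamma_R = 1, gamma_P = 1)
  fast <- base; fast$k_fold <- 100; fast$k_unfold <- 100
  em <- ensemble_moments(fast, n_cells = 800, seed = 17)
  limit <- two_stage_protein_cv2(model_params(k_off = 0, v_tx = 10,
                                              k_tl = 5, gamma_R = 1,
                                              gamma_P = 1))
  sP <- attr(em, "samples")[, "P"]
  cv2_se <- boot_se(sP, function(x) var(x) / mean(x)^2)
  expect_equal(em["P", "mean"], limit$mean_P,
               tolerance = 3 * se_mean(sP) / limit$mean_P)
  expect_equal(em["P", "cv"]^2, limit$cv2_P,
               tolerance = (3 * cv2_se + 0.004) / limit$cv2_P)
})
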