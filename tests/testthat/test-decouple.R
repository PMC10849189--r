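test_that("BIC selects the true number of clusters", {
  sim <- simulate_two_cluster(n_control = 1000, n_perturb = 2, d = 4, r = 0,
                              beta = c(0, 0), seed = 61)
  cm2 <- fit_control_gmm(sim$control_scores[, 1, drop = FALSE], k_range = 1:3)
  expect_equal(cm2$K, 2L)

  set.seed(62)
  cm1 <- fit_control_gmm(matrix(rnorm(1000), ncol = 1), k_range = 1:3)
  expect_equal(cm1$K, 1L)

  # structural invariants
  for (cm in list(cm1, cm2)) {
    expect_equal(sum(cm$delta), 1, tolerance = 1e-9)
    expect_equal(names(which.min(cm$bic_by_k)), paste0("K", cm$K))
    for (L in cm$Lambda) {
      expect_equal(L, t(L), tolerance = 1e-9)
      expect_true(all(eigen(L, only.values = TRUE)$values > 0))
    }
  }
})

test_that("candidate K values violating the cell guard are dropped", {
  set.seed(63)
  x <- matrix(rnorm(25), ncol = 1)
  expect_warning(cm <- fit_control_gmm(x, k_range = 1:4, min_cells_per_k = 10),
                 "dropping")
  expect_true(all(as.integer(sub("K", "", names(cm$bic_by_k))) <= 2))
  expect_error(fit_control_gmm(x, k_range = 5:6, min_cells_per_k = 10),
               "exceed")
})

test_that("a null perturbation recovers beta = 0 and lambda = delta", {
  sim <- simulate_two_cluster(n_control = 2000, n_perturb = 1500, d = 3.5,
                              r = 0, beta = c(0, 0), seed = 71)
  cm <- fit_control_gmm(sim$control_scores, k_range = 2)
  fit <- em_perturbation(sim$perturb_scores, cm)
  se <- sqrt(diag(var(sim$perturb_scores)) / nrow(sim$perturb_scores) +
             diag(var(sim$control_scores)) / nrow(sim$control_scores))
  expect_true(all(abs(fit$beta) < 3 * se))
  expect_true(all(abs(fit$lambda - cm$delta) < 0.05))
})

test_that("with K = 1 the decoupled response is exactly the observed change", {
  set.seed(72)
  z <- matrix(rnorm(400, 1, 2), ncol = 2)
  y <- matrix(rnorm(300, 2, 2), ncol = 2)
  cm <- fit_control_gmm(z, k_range = 1)
  fit <- em_perturbation(y, cm)
  oc <- compute_observed_change(z, y)
  expect_equal(fit$beta, oc, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("EM trace is non-decreasing and internally consistent", {
  sim <- simulate_two_cluster(n_control = 800, n_perturb = 400, d = 3,
                              r = 0.15, seed = 73)
  cm <- fit_control_gmm(sim$control_scores, k_range = 2)
  for (fixm in c(TRUE, FALSE)) {
    fit <- em_perturbation(sim$perturb_scores, cm, fix_M_to_Lambda = fixm)
    expect_true(all(diff(fit$log_likelihood_trace) >= -1e-7))
    # trace tail equals an independent recomputation of the likelihood
    ll <- loglik_perturbation(sim$perturb_scores, cm, fit)
    expect_equal(ll, tail(fit$log_likelihood_trace, 1), tolerance = 1e-9)
    if (fixm) for (k in seq_len(cm$K))
      expect_identical(fit$M[[k]], cm$Lambda[[k]])
    expect_equal(sum(fit$lambda), 1, tolerance = 1e-9)
    expect_equal(rowSums(fit$responsibilities), rep(1, 400),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("mixture log-density obeys Gaussian normalization identities", {
  cm <- make_control_model(delta = 1, mu = matrix(0.5, 1, 1),
                           Sigma = list(matrix(1, 1, 1)))
  y <- matrix(1.5, 1, 1)  # point at mu + beta with beta = 1
  ll <- loglik_perturbation(y, cm, list(lambda = 1, beta = 1,
                                        M = list(matrix(1, 1, 1))))
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
  # doubling the precision at the mode adds half log 2
  ll2 <- loglik_perturbation(y, cm, list(lambda = 1, beta = 1,
                                         M = list(matrix(2, 1, 1))))
  expect_equal(ll2 - ll, 0.5 * log(2), tolerance = 1e-12)
})

test_that("decoupling is invariant to permuting cluster labels", {
  sim <- simulate_two_cluster(n_control = 800, n_perturb = 400, d = 3,
                              r = 0.15, seed = 74)
  cm <- fit_control_gmm(sim$control_scores, k_range = 2)
  cmp <- cm
  cmp$delta <- rev(cm$delta)
  cmp$mu <- cm$mu[2:1, , drop = FALSE]
  cmp$Lambda <- cm$Lambda[2:1]
  cmp$Sigma <- cm$Sigma[2:1]
  f1 <- em_perturbation(sim$perturb_scores, cm)
  f2 <- em_perturbation(sim$perturb_scores, cmp)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$lambda, rev(f2$lambda), tolerance = 1e-8)
  # the observed-change decomposition is label-free
  dec1 <- f1$beta + colSums((f1$lambda - cm$delta) * cm$mu)
  dec2 <- f2$beta + colSums((f2$lambda - cmp$delta) * cmp$mu)
  expect_equal(dec1, dec2, tolerance = 1e-8)
})

test_that("observed change decomposes into response plus proportion bias", {
  sim <- simulate_two_cluster(n_control = 1500, n_perturb = 1000, d = 3,
                              r = 0.15, seed = 75)
  cm <- fit_control_gmm(sim$control_scores, k_range = 2)
  fit <- em_perturbation(sim$perturb_scores, cm, fix_M_to_Lambda = TRUE)
  oc <- compute_observed_change(sim$control_scores, sim$perturb_scores)
  resid <- oc - fit$beta - colSums((fit$lambda - cm$delta) * cm$mu)
  expect_lt(max(abs(resid)), 0.05 * sim$truth$d)
})

test_that("recovery sharpens with the perturbation group size", {
  mu <- rbind(c(-1.5, 0), c(1.5, 0))
  Sigma <- list(diag(2), diag(2))
  cm <- make_control_model(c(0.5, 0.5), mu, Sigma)
  lambda <- c(0.65, 0.35); beta <- c(0.8, -0.4)
  mae <- sapply(1:10, function(s) {
    set.seed(s)
    vapply(c(200, 2000), function(n) {
      y <- sample_perturbation(n, lambda, mu, Sigma, beta)$y
      f <- em_perturbation(y, cm)
      mean(abs(f$beta - beta))
    }, 0)
  })
  expect_lt(median(mae[2, ]), median(mae[1, ]))
})
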