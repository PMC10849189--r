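test_that("two-cluster generator honors its null configuration", {
  sim <- simulate_two_cluster(n_control = 4000, n_perturb = 4000, d = 3,
                              r = 0, beta = c(0, 0), seed = 91)
  oc <- compute_observed_change(sim$control_scores, sim$perturb_scores)
  se <- sqrt(diag(var(sim$control_scores)) / 4000 +
             diag(var(sim$perturb_scores)) / 4000)
  expect_true(all(abs(oc) < 3 * se))
  expect_equal(sim$truth$lambda, sim$truth$delta)

  # invalid proportions are refused
  expect_error(simulate_two_cluster(delta = c(0.7, 0.7)), "simplex")
  expect_error(simulate_two_cluster(delta = c(0.95, 0.05), r = 0.2),
               "lambda")
})

test_that("two-cluster geometry matches its parameters", {
  sim <- simulate_two_cluster(n_control = 3000, n_perturb = 3000, d = 4,
                              r = 0.1, beta = c(1, -0.5), seed = 92)
  # bimodality on PC1 only; cluster means at -+ d/2
  m1 <- mean(sim$control_scores[sim$truth$control_labels == 1, 1])
  m2 <- mean(sim$control_scores[sim$truth$control_labels == 2, 1])
  expect_equal(m1, -2, tolerance = 0.1)
  expect_equal(m2, 2, tolerance = 0.1)
  expect_equal(mean(sim$control_scores[, 2]), 0, tolerance = 0.1)
  # perturbed cells carry the added response
  shift <- colMeans(sim$perturb_scores[sim$truth$perturb_labels == 1, ]) -
           colMeans(sim$control_scores[sim$truth$control_labels == 1, ])
  expect_equal(shift, sim$truth$beta, tolerance = 0.15, ignore_attr = TRUE)
})

test_that("angle scenario rotates covariances and applies efficiencies", {
  # parallel axes at angle 0: leading eigenvectors colinear
  sim0 <- simulate_angle_scenario(n_control = 4000, cov_angle = 0, seed = 93)
  ev <- function(scores, labels, k)
    eigen(var(scores[labels == k, ]))$vectors[, 1]
  v1 <- ev(sim0$control_scores, sim0$truth$control_labels, 1)
  v2 <- ev(sim0$control_scores, sim0$truth$control_labels, 2)
  expect_gt(abs(sum(v1 * v2)), 0.98)

  # perpendicular at 90 degrees
  sim90 <- simulate_angle_scenario(n_control = 4000, cov_angle = 90, seed = 94)
  v1 <- ev(sim90$control_scores, sim90$truth$control_labels, 1)
  v2 <- ev(sim90$control_scores, sim90$truth$control_labels, 2)
  expect_lt(abs(sum(v1 * v2)), 0.2)

  # lambda follows the infection-efficiency arithmetic
  eff <- c(0.2, 0.3)
  simE <- simulate_angle_scenario(n_control = 1000, efficiency = eff,
                                  seed = 95)
  expect_equal(simE$truth$lambda,
               c(0.5 * 0.2, 0.5 * 0.3) / (0.5 * 0.2 + 0.5 * 0.3))
  expect_equal(simE$truth$n_perturb, round(1000 * (0.5 * 0.2 + 0.5 * 0.3)))
})

test_that("multicluster gRNA proportions follow the efficiency arrays", {
  K <- 4
  effs <- rbind(rep(0.3, K),            # equal efficiencies -> lambda = delta
                c(1, 1e-12, 1e-12, 1e-12),  # cluster-1-only infection
                runif(K, 0.05, 0.5))
  sim <- simulate_multicluster(n_control = 500, K = K, n_grnas = 3,
                               efficiencies = effs, seed = 96)
  expect_equal(sim$grnas[[1]]$truth$lambda, sim$truth$delta, tolerance = 1e-9)
  expect_true(all(sim$grnas[[2]]$truth$labels == 1))
  w <- sim$truth$delta * effs[3, ]
  expect_equal(sim$grnas[[3]]$truth$lambda, w / sum(w), tolerance = 1e-9)
  # distinct cluster means, reproducible draws
  expect_gte(min(dist(sim$truth$mu)), 2.5)
  sim2 <- simulate_multicluster(n_control = 500, K = K, n_grnas = 3,
                                efficiencies = effs, seed = 96)
  expect_identical(sim$control_scores, sim2$control_scores)
})

test_that("conventional baseline recovers a pure shift and is order-invariant", {
  sim <- simulate_two_cluster(n_control = 2000, n_perturb = 2000, d = 8,
                              r = 0, beta = c(1, 1), seed = 97)
  est <- conventional_baseline(sim$control_scores, sim$perturb_scores, K = 2,
                               init_subset = 4000)
  expect_equal(est, c(1, 1), tolerance = 0.15, ignore_attr = TRUE)

  set.seed(42)
  perm <- sample(nrow(sim$perturb_scores))
  est2 <- conventional_baseline(sim$control_scores,
                                sim$perturb_scores[perm, ], K = 2,
                                init_subset = 4000)
  expect_equal(est2, est, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(conventional_baseline(sim$control_scores,
                                     sim$perturb_scores, K = 1), "K >= 2")
})

test_that("MAE evaluation is plain arithmetic", {
  truth <- c(1, -2, 0.5)
  ev <- evaluate_estimates(list(exact = truth, off = truth + 1,
                                mixed = truth + c(0.3, -0.6, 0)), truth)
  expect_equal(ev$mae, c(0, 1, 0.3))
  expect_equal(as.numeric(ev[3, c("err_PC1", "err_PC2", "err_PC3")]),
               c(0.3, 0.6, 0))
  expect_error(evaluate_estimates(list(bad = 1:2), truth), "length")
})

test_that("dropout masks the requested fraction and nothing else", {
  set.seed(98)
  m <- matrix(rexp(20000) + 0.1, 200, 100)
  expect_identical(apply_dropout(m, 0), m)
  out <- apply_dropout(m, 0.4, seed = 5)
  frac <- mean(out == 0)
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / length(m)))
  expect_true(all(out == 0 | out == m))
  expect_identical(apply_dropout(m, 0.4, seed = 5), out)
  expect_error(apply_dropout(m, 1), "rate")
})

test_that("gene-space lift produces valid counts with the stated geometry", {
  sim <- simulate_two_cluster(n_control = 300, n_perturb = 200, seed = 99)
  lifted <- lift_to_genes(sim, n_genes = 120, seed = 100)
  expect_s3_class(lifted$control, "count_matrix")
  expect_equal(dim(lifted$control$values), c(300, 120))
  expect_equal(dim(lifted$perturb$values), c(200, 120))
  expect_true(all(lifted$control$values >= 0))
  expect_true(all(lifted$control$values == round(lifted$control$values)))
  # orthonormal true basis; true gene response is its image of beta
  expect_equal(crossprod(lifted$true_basis), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(lifted$true_gene_response,
               as.numeric(lifted$true_basis %*%
                          (lifted$score_scale * sim$truth$beta)))
})
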