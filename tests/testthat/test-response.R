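test_that("observed change is the per-PC difference of group means", {
  z <- matrix(c(0, 2), 2, 1)
  y <- matrix(c(2, 4), 2, 1)
  expect_equal(compute_observed_change(z, y), 2, ignore_attr = TRUE)
  expect_equal(compute_observed_change(z, z), 0, ignore_attr = TRUE)
  expect_error(compute_observed_change(z[0, , drop = FALSE], y), "at least one")
  expect_error(compute_observed_change(z, cbind(y, y)), "disagree")
})

test_that("sample observed change matches the two-cluster closed form", {
  # delta=(.5,.5), lambda=(.6,.4), mu=(0,3), beta=0:
  # expected OC = (lambda_1-delta_1)(mu_1-mu_2) = -0.3
  set.seed(81)
  n <- 5000
  zlab <- sample(1:2, n, TRUE, c(0.5, 0.5))
  ylab <- sample(1:2, n, TRUE, c(0.6, 0.4))
  mu <- c(0, 3)
  z <- matrix(rnorm(n, mu[zlab]), ncol = 1)
  y <- matrix(rnorm(n, mu[ylab]), ncol = 1)
  oc <- compute_observed_change(z, y)
  se <- sqrt(var(z) / n + var(y) / n)
  expect_lt(abs(oc - (-0.3)), 3 * as.numeric(se))
})

test_that("assemble_response mixes beta and OC by PC source", {
  cls <- data.frame(pc_index = 1:2, selected = c(TRUE, FALSE))
  fit <- list(beta = 0.7)
  prof <- assemble_response(fit, cls, oc = c(1.0, -0.2))
  expect_equal(prof$per_pc_response, c(0.7, -0.2))
  expect_equal(prof$source_per_pc, c("decoupled", "observed_change"))

  cls0 <- data.frame(pc_index = 1:3, selected = rep(FALSE, 3))
  prof0 <- assemble_response(list(beta = numeric(0)), cls0, oc = 1:3)
  expect_equal(prof0$per_pc_response, 1:3)
  expect_true(all(prof0$source_per_pc == "observed_change"))

  cls1 <- data.frame(pc_index = 1:2, selected = c(TRUE, TRUE))
  prof1 <- assemble_response(list(beta = c(5, 6)), cls1, oc = c(0, 0))
  expect_equal(prof1$per_pc_response, c(5, 6))

  expect_error(assemble_response(list(beta = 1), cls1, oc = c(0, 0)),
               "selected")
})

test_that("backprojection is the exact adjoint of projection", {
  set.seed(82)
  basis <- qr.Q(qr(matrix(rnorm(50 * 5), 50, 5)))
  rownames(basis) <- sprintf("g%02d", 1:50)
  expect_equal(unname(backproject(rep(0, 5), basis)), rep(0, 50))
  expect_equal(unname(backproject(c(1, 0, 0, 0, 0), basis)), basis[, 1],
               ignore_attr = TRUE)
  r <- rnorm(5)
  g <- backproject(r, basis)
  expect_equal(as.numeric(g %*% basis), r, tolerance = 1e-9)  # roundtrip
  # linearity
  r2 <- rnorm(5)
  expect_equal(backproject(r + 2 * r2, basis),
               backproject(r, basis) + 2 * backproject(r2, basis),
               tolerance = 1e-12)
})

test_that("gene ranking is by |response| with lexicographic ties", {
  resp <- c(A = 0.1, B = -0.9, C = 0.5)
  expect_equal(rank_genes(resp), c("B", "C", "A"))
  expect_equal(rank_genes(resp, top_n = 2), c("B", "C"))
  expect_equal(rank_genes(c(z = 1, a = 1, m = 1)), c("a", "m", "z"))
  expect_identical(rank_genes(resp), rank_genes(resp))
  expect_error(rank_genes(c(1, NA)), "finite")
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  universe <- sprintf("g%04d", 1:1000)
  diffg <- universe[1:100]
  gset <- universe[c(1:30, 101:120)]  # overlap 30, set-only 20
  e <- fisher_enrichment(diffg, gset, universe)
  expect_equal(c(e$n_overlap, e$n_diff, e$n_set, e$n_universe),
               c(30, 100, 50, 1000))
  # brute-force tail: sum over k >= 30 of the hypergeometric pmf
  p_brute <- sum(vapply(30:50, function(k)
    choose(50, k) * choose(950, 100 - k) / choose(1000, 100), 0))
  expect_equal(e$p_value, p_brute, tolerance = 1e-9)
  expect_equal(e$enrichment_score, -log10(p_brute), tolerance = 1e-9)

  # zero overlap where much is expected: p ~ 1
  e0 <- fisher_enrichment(universe[1:100], universe[301:800], universe)
  expect_gt(e0$p_value, 0.999)

  # perfect overlap: infinite sample odds ratio, flagged
  half <- universe[1:500]
  e1 <- fisher_enrichment(half, half, universe)
  expect_true(e1$infinite_odds)
  expect_lt(e1$p_value, 1e-200)

  expect_error(fisher_enrichment("not_in_universe", gset, universe), "subset")
  expect_error(fisher_enrichment(diffg, gset, character(0)), "empty")
})

test_that("a resampled-control pipeline response is centered at zero", {
  # perturbation drawn from the control distribution: the assembled
  # response has no systematic component on any PC
  mu <- rbind(c(-1.5, 0), c(1.5, 0))
  Sigma <- list(diag(2), diag(2))
  cm <- make_control_model(c(0.5, 0.5), mu, Sigma)
  cls <- data.frame(pc_index = 1:2, selected = c(TRUE, TRUE))
  resp <- sapply(1:40, function(s) {
    set.seed(s)
    z <- sample_perturbation(400, c(0.5, 0.5), mu, Sigma, c(0, 0))$y
    y <- sample_perturbation(400, c(0.5, 0.5), mu, Sigma, c(0, 0))$y
    fit <- em_perturbation(y, cm)
    assemble_response(fit, cls, compute_observed_change(z, y))$per_pc_response
  })
  med <- apply(resp, 1, median)
  se <- 1.2533 * apply(resp, 1, sd) / sqrt(ncol(resp))
  expect_true(all(abs(med) < 3 * se + 0.02))
})
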