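#' Two-cluster synthetic design in PC space
#'
#' Generates the canonical benchmarking scenario: 2-D PC-space data whose
#' bimodality is confined to PC 1. Control cells follow a two-cluster
#' Gaussian mixture with means `(-d/2, 0)` and `(d/2, 0)` and proportions
#' `delta`; perturbation cells are drawn from the same mixture with
#' proportions `lambda` (cluster 1 shifted by the ratio change `r`), after
#' which the response `beta` is added to every cell. The bias of the
#' observed change on PC 1 is then `(lambda_1 - delta_1)(mu_1 - mu_2)` in
#' expectation, i.e. `+- r d`.
#'
#' @param n_control,n_perturb group sizes (defaults 1000).
#' @param d distance between the cluster means on PC 1.
#' @param r ratio change `|lambda_1 - delta_1|` (applied as
#'   `lambda_1 = delta_1 + r`).
#' @param beta length-2 response vector added to every perturbed cell.
#' @param delta control-group cluster proportions (simplex of length 2).
#' @param cluster_sd per-cluster isotropic standard deviation.
#' @param seed optional seed.
#' @return list with `control_scores`, `perturb_scores` (matrices with
#'   columns PC1, PC2) and `truth` (`beta`, `delta`, `lambda`, `mu`,
#'   `Sigma`, `d`, `r`).
#' @export
simulate_two_cluster <- function(n_control = 1000L, n_perturb = 1000L,
                                 d = 3, r = 0.1, beta = c(1, 1),
                                 delta = c(0.5, 0.5), cluster_sd = c(1, 1),
                                 seed = NULL) {
  .check_simplex(delta, 2L)
  lambda <- c(delta[1] + r, delta[2] - r)
  .check_simplex(lambda, 2L, "lambda (delta_1 + r exceeds [0, 1])")
  stopifnot(length(beta) == 2L, d >= 0)
  mu <- rbind(c(-d / 2, 0), c(d / 2, 0))
  Sigma <- lapply(cluster_sd, function(s) diag(s^2, 2L))
  .with_seed(seed, {
    zc <- .sample_gmm(n_control, delta, mu, Sigma)
    zp <- .sample_gmm(n_perturb, lambda, mu, Sigma)
    list(control_scores = .pc_names(zc$x),
         perturb_scores = .pc_names(sweep(zp$x, 2L, beta, `+`)),
         truth = list(beta = beta, delta = delta, lambda = lambda,
                      mu = mu, Sigma = Sigma, d = d, r = r,
                      control_labels = zc$labels, perturb_labels = zp$labels))
  })
}

#' Two-cluster design with rotated anisotropic covariances
#'
#' Both clusters are anisotropic Gaussians; cluster 2's major axis lies
#' along PC 1 and cluster 1's major axis is rotated by `cov_angle` degrees,
#' so `cov_angle = 0` gives parallel principal axes (the hardest case for
#' cluster-matching baselines). Perturbation-group proportions derive from
#' per-cluster gRNA infection efficiencies:
#' `lambda = delta * efficiency / sum(delta * efficiency)`, and the
#' perturbation group size is the expected number of infected cells
#' `round(n_control * sum(delta * efficiency))`.
#'
#' @param n_control control group size.
#' @param d distance between cluster means on PC 1.
#' @param cov_angle angle (degrees, in `[0, 90]`) between the two clusters'
#'   maximum-variance axes.
#' @param efficiency length-2 per-cluster infection efficiencies
#'   (e.g. cluster 1 swept over 0.4..0.1 with cluster 2 fixed at 0.3).
#' @param delta control proportions.
#' @param beta response added to every perturbed cell (identical for both
#'   clusters).
#' @param axis_sd standard deviations along the major/minor axes.
#' @param seed optional seed.
#' @return same shape as [simulate_two_cluster()]; `truth` additionally
#'   records `efficiency`, `cov_angle` and `n_perturb`.
#' @export
simulate_angle_scenario <- function(n_control = 1000L, d = 3, cov_angle = 60,
                                    efficiency = c(0.4, 0.3),
                                    delta = c(0.5, 0.5), beta = c(1, 1),
                                    axis_sd = c(1, 1 / 3), seed = NULL) {
  .check_simplex(delta, 2L)
  stopifnot(cov_angle >= 0, cov_angle <= 90, length(efficiency) == 2L,
            all(efficiency > 0), length(axis_sd) == 2L)
  lambda <- delta * efficiency / sum(delta * efficiency)
  n_perturb <- max(2L, round(n_control * sum(delta * efficiency)))
  mu <- rbind(c(-d / 2, 0), c(d / 2, 0))
  core <- diag(axis_sd^2)
  R1 <- .rot2(cov_angle)
  Sigma <- list(R1 %*% core %*% t(R1), core)
  .with_seed(seed, {
    zc <- .sample_gmm(n_control, delta, mu, Sigma)
    zp <- .sample_gmm(n_perturb, lambda, mu, Sigma)
    list(control_scores = .pc_names(zc$x),
         perturb_scores = .pc_names(sweep(zp$x, 2L, beta, `+`)),
         truth = list(beta = beta, delta = delta, lambda = lambda, mu = mu,
                      Sigma = Sigma, d = d, efficiency = efficiency,
                      cov_angle = cov_angle, n_perturb = n_perturb,
                      control_labels = zc$labels, perturb_labels = zp$labels))
  })
}

#' Multi-cluster design with a panel of gRNAs
#'
#' `K` clusters with distinct means and covariances on a 2-D PC space form
#' the control group. Each of `n_grnas` gRNAs gets its own array of
#' per-cluster infection efficiencies (drawn uniformly from
#' `efficiency_range`), its own response vector, and a perturbation sample
#' with proportions `lambda_g = delta * eff_g / sum(delta * eff_g)`.
#'
#' @param n_control control group size.
#' @param K number of clusters (default 4).
#' @param n_grnas number of gRNAs (default 10).
#' @param efficiency_range range of the per-cluster infection efficiencies.
#' @param beta_sd standard deviation of the random per-gRNA responses.
#' @param efficiencies optional `n_grnas x K` matrix overriding the random
#'   efficiencies.
#' @param seed optional seed.
#' @return list with `control_scores`, `truth` (cluster parameters) and
#'   `grnas`: per-gRNA lists of `perturb_scores` and `truth`
#'   (`beta`, `lambda`, `efficiency`).
#' @export
simulate_multicluster <- function(n_control = 1000L, K = 4L, n_grnas = 10L,
                                  efficiency_range = c(0.05, 0.5),
                                  beta_sd = 1, efficiencies = NULL,
                                  seed = NULL) {
  stopifnot(K >= 2L, n_grnas >= 1L)
  .with_seed(seed, {
    # well-separated cluster means (rejection sampling), distinct covariances
    repeat {
      mu <- matrix(runif(K * 2, -4, 4), K, 2L)
      if (min(dist(mu)) >= 2.5) break
    }
    Sigma <- lapply(seq_len(K), function(k) {
      R <- .rot2(runif(1, 0, 180))
      R %*% diag(runif(2, 0.2, 1)) %*% t(R)
    })
    delta <- runif(K, 0.5, 1.5); delta <- delta / sum(delta)
    zc <- .sample_gmm(n_control, delta, mu, Sigma)
    if (is.null(efficiencies)) {
      efficiencies <- matrix(runif(n_grnas * K, efficiency_range[1],
                                   efficiency_range[2]), n_grnas, K)
    } else stopifnot(nrow(efficiencies) == n_grnas, ncol(efficiencies) == K)
    grnas <- lapply(seq_len(n_grnas), function(g) {
      eff <- efficiencies[g, ]
      w <- delta * eff
      lambda <- w / sum(w)
      n_p <- max(K + 2L, round(n_control * sum(w)))
      beta <- rnorm(2L, 0, beta_sd)
      zp <- .sample_gmm(n_p, lambda, mu, Sigma)
      list(perturb_scores = .pc_names(sweep(zp$x, 2L, beta, `+`)),
           truth = list(beta = beta, lambda = lambda, efficiency = eff,
                        labels = zp$labels))
    })
    names(grnas) <- paste0("gRNA_", seq_len(n_grnas))
    list(control_scores = .pc_names(zc$x),
         truth = list(delta = delta, mu = mu, Sigma = Sigma, K = K,
                      control_labels = zc$labels),
         grnas = grnas)
  })
}

#' Conventional cluster-matching baseline
#'
#' The strategy this package's decoupling is benchmarked against: fit a
#' K-component Gaussian mixture to each group *independently*, annotate
#' clusters by the rank of their centers on PC 1, match clusters across
#' groups by that rank, and average the matched center shifts. With
#' overlapping clusters, small groups, or interleaved center ranks the
#' matching goes wrong; the decoupling EM avoids the problem by carrying
#' the control-group cluster structure over.
#'
#' @param control_scores,perturb_scores score matrices with identical
#'   numbers of columns.
#' @param K number of clusters (at least 2).
#' @param seed optional seed for the mixture fits.
#' @param init_subset deterministic initialization subset size, as in
#'   [fit_control_gmm()].
#' @param details return the rank-matched fitted cluster centers along with
#'   the estimate (for diagnosing matching failures).
#' @return per-PC response estimate (numeric vector); with
#'   `details = TRUE`, a list with `estimate`, `control_centers` and
#'   `perturb_centers` (rows ordered by the PC 1 rank used for matching).
#' @export
conventional_baseline <- function(control_scores, perturb_scores, K,
                                  seed = NULL, init_subset = 300L,
                                  details = FALSE) {
  stopifnot(K >= 2L)
  fit_one <- function(x) {
    x <- as.matrix(x)
    mn <- if (ncol(x) == 1L) "V" else "VVV"
    init <- if (nrow(x) > init_subset) list(subset = seq_len(init_subset))
    f <- .with_seed(seed,
      tryCatch(mclust::Mclust(x, G = K, modelNames = mn, verbose = FALSE,
                              initialization = init),
               error = function(e) NULL))
    if (is.null(f) || is.null(f$parameters$mean))
      .stop2("baseline mixture fit failed")
    centers <- if (ncol(x) == 1L) matrix(f$parameters$mean, ncol = 1L)
               else t(f$parameters$mean)
    if (nrow(centers) < K || any(f$parameters$pro < 1e-8))
      .stop2("baseline mixture collapsed to fewer than K clusters")
    centers
  }
  cc <- fit_one(control_scores)
  cp <- fit_one(perturb_scores)
  cc <- cc[order(cc[, 1L]), , drop = FALSE]
  cp <- cp[order(cp[, 1L]), , drop = FALSE]
  est <- colMeans(cp - cc)
  if (details)
    list(estimate = est, control_centers = cc, perturb_centers = cp)
  else est
}

#' Mean absolute error of response estimates against ground truth
#'
#' @param estimates named list of per-PC response estimates (or a single
#'   vector).
#' @param truth_beta true response vector.
#' @return data.frame with one row per method: `method`, `mae`, and one
#'   `err_PCj` column per PC with the absolute per-PC errors.
#' @export
evaluate_estimates <- function(estimates, truth_beta) {
  if (!is.list(estimates)) estimates <- list(estimate = estimates)
  rows <- lapply(names(estimates), function(nm) {
    est <- estimates[[nm]]
    if (length(est) != length(truth_beta))
      .stop2("estimate '", nm, "' has wrong length")
    err <- abs(est - truth_beta)
    out <- data.frame(method = nm, mae = mean(err))
    for (j in seq_along(err)) out[[paste0("err_PC", j)]] <- err[j]
    out
  })
  do.call(rbind, rows)
}

#' Random zero-masking (dropout) of an expression matrix
#'
#' Sets each entry to zero independently with probability `rate`, emulating
#' the extra sparsity of a technically degraded batch.
#'
#' @param x numeric matrix or [count_matrix].
#' @param rate dropout probability in `[0, 1)`.
#' @param seed optional seed.
#' @return object of the same type as `x`.
#' @export
apply_dropout <- function(x, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(x)
  if (inherits(x, "count_matrix")) {
    x$values <- apply_dropout(x$values, rate, seed)
    return(x)
  }
  .with_seed(seed, {
    keep <- matrix(rbinom(length(x), 1L, 1 - rate), nrow(x), ncol(x))
    x * keep
  })
}

#' Lift a PC-space simulation into gene-space count matrices
#'
#' Embeds simulated PC scores in a `n_genes`-dimensional log-expression
#' space through a random orthonormal loading matrix plus per-gene baseline
#' means, then draws Poisson counts around the exponentiated values. The
#' result feeds the full preprocessing pipeline (normalization, HVF
#' selection, PCA) end to end; `true_gene_response` gives the response in
#' log-expression units for benchmarking.
#'
#' @param sim result of [simulate_two_cluster()] or
#'   [simulate_angle_scenario()].
#' @param n_genes number of genes.
#' @param base_log_mean range of per-gene baseline log-expression.
#' @param score_scale scaling applied to PC scores before lifting. The
#'   per-gene amplitude of the lifted signal is roughly
#'   `score_scale / sqrt(n_genes)` log-units (orthonormal loadings), so
#'   values near 1 keep the cluster structure visible above Poisson noise
#'   while preserving positive log-expression.
#' @param seed optional seed.
#' @return list with `control` and `perturb` ([count_matrix] objects),
#'   `true_basis` (genes x 2 orthonormal), `true_gene_response` and
#'   `score_scale`.
#' @export
lift_to_genes <- function(sim, n_genes = 200L, base_log_mean = c(1, 3),
                          score_scale = 1, seed = NULL) {
  stopifnot(is.list(sim), !is.null(sim$control_scores))
  .with_seed(seed, {
    P <- ncol(sim$control_scores)
    Q <- qr.Q(qr(matrix(rnorm(n_genes * P), n_genes, P)))
    m <- runif(n_genes, base_log_mean[1], base_log_mean[2])
    make_counts <- function(scores, prefix) {
      le <- sweep(score_scale * scores %*% t(Q), 2L, m, `+`)
      le[le < 0] <- 0
      cnt <- matrix(rpois(length(le), expm1(le)), nrow(le), ncol(le))
      rownames(cnt) <- paste0(prefix, seq_len(nrow(cnt)))
      colnames(cnt) <- paste0("gene_", seq_len(n_genes))
      cnt
    }
    ctl <- make_counts(sim$control_scores, "ctl_")
    prt <- make_counts(sim$perturb_scores, "prt_")
    list(control = count_matrix(ctl, group_label = "control"),
         perturb = count_matrix(prt, group_label = "perturbation"),
         true_basis = Q,
         true_gene_response = as.numeric(Q %*% (score_scale * sim$truth$beta)),
         score_scale = score_scale)
  })
}

# ---- internal helpers -------------------------------------------------------

.check_simplex <- function(w, len, what = "proportions") {
  if (length(w) != len || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    .stop2("invalid ", what, ": must be a non-negative simplex of length ", len)
}

.sample_gmm <- function(n, weights, mu, Sigma) {
  K <- length(weights)
  counts <- as.integer(rmultinom(1L, n, weights))
  x <- matrix(0, n, ncol(mu))
  labels <- integer(n)
  pos <- 0L
  for (k in seq_len(K)) {
    if (counts[k] == 0L) next
    idx <- pos + seq_len(counts[k])
    x[idx, ] <- .rmvn(counts[k], mu[k, ], Sigma[[k]])
    labels[idx] <- k
    pos <- pos + counts[k]
  }
  perm <- sample.int(n)
  list(x = x[perm, , drop = FALSE], labels = labels[perm])
}

.pc_names <- function(x) {
  colnames(x) <- paste0("PC", seq_len(ncol(x)))
  x
}
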