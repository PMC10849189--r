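#' Fit the control-group Gaussian mixture with BIC-selected K
#'
#' Fits a full-covariance Gaussian mixture to the control scores on the
#' selected PCs for each candidate number of clusters, and keeps the K
#' minimizing `BIC(K) = -2 max log L_K + log(n) d(K)` with
#' `d(K) = (K - 1) + K P + K P (P + 1) / 2` (mixing weights, means, and
#' full covariances). The EM fits are delegated to \pkg{mclust}, whose
#' model-based hierarchical initialization is deterministic; `n_init` is
#' accepted for interface compatibility but additional random restarts are
#' not needed with that initializer.
#'
#' @param scores numeric matrix (control cells x selected PCs) or vector.
#' @param k_range candidate cluster numbers (default `1:5`).
#' @param n_init accepted for compatibility; see above.
#' @param seed optional seed (the fit itself is deterministic).
#' @param min_cells_per_k guard: K is only considered when
#'   `K <= N_C / min_cells_per_k` (default 10).
#' @param init_subset size of the deterministic subset (the first rows) used
#'   for the hierarchical initialization when the group is larger; the EM
#'   itself always runs on all cells. Initialization on a few hundred cells
#'   is equally accurate and much faster for large groups.
#' @return an object of class `control_model`: `K`, `delta` (mixing
#'   proportions), `mu` (K x P means), `Lambda`/`Sigma` (per-cluster
#'   precision/covariance matrices), `log_likelihood`, `bic_by_k`,
#'   `responsibilities`, `n_obs`, `P`.
#' @export
fit_control_gmm <- function(scores, k_range = 1:5, n_init = 1L, seed = NULL,
                            min_cells_per_k = 10, init_subset = 300L) {
  scores <- as.matrix(scores)
  n <- nrow(scores); p <- ncol(scores)
  stopifnot(n > 1L, length(k_range) >= 1L)
  k_range <- sort(unique(as.integer(k_range)))
  ok <- k_range <= max(1L, floor(n / min_cells_per_k))
  if (!any(ok)) .stop2("all candidate K exceed N_C / ", min_cells_per_k)
  if (!all(ok)) {
    warning("dropping candidate K > N_C / ", min_cells_per_k, ": ",
            paste(k_range[!ok], collapse = ", "))
    k_range <- k_range[ok]
  }

  fits <- list(); bic <- setNames(rep(NA_real_, length(k_range)),
                                  paste0("K", k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    mn <- if (p == 1L) (if (K == 1L) "X" else "V")
          else (if (K == 1L) "XXX" else "VVV")
    init <- if (n > init_subset) list(subset = seq_len(init_subset))
    fit <- .with_seed(seed,
      tryCatch(mclust::Mclust(scores, G = K, modelNames = mn, verbose = FALSE,
                              initialization = init),
               error = function(e) NULL))
    if (is.null(fit) || !is.finite(fit$loglik)) next
    d_k <- (K - 1) + K * p + K * p * (p + 1) / 2
    bic[i] <- -2 * fit$loglik + log(n) * d_k
    fits[[i]] <- fit
  }
  if (all(is.na(bic)))
    .stop2("the mixture fit failed for every candidate K; ",
           "consider more cells or fewer selected PCs")
  best <- which.min(bic)
  fit <- fits[[best]]; K <- k_range[best]

  pro <- fit$parameters$pro %||% 1
  mean_par <- fit$parameters$mean
  mu <- if (p == 1L) matrix(as.numeric(mean_par), K, 1L) else t(mean_par)
  Sigma <- vector("list", K)
  vpar <- fit$parameters$variance
  for (k in seq_len(K)) {
    Sigma[[k]] <- if (p == 1L) {
      s2 <- vpar$sigmasq
      matrix(if (length(s2) > 1L) s2[k] else s2, 1L, 1L)
    } else if (!is.null(vpar$sigma)) {
      as.matrix(vpar$sigma[, , k])
    } else as.matrix(vpar$Sigma)
  }
  Lambda <- lapply(Sigma, .safe_precision)
  z <- fit$z %||% matrix(1, n, 1L)

  structure(list(K = K, delta = as.numeric(pro), mu = mu,
                 Lambda = Lambda, Sigma = Sigma,
                 log_likelihood = fit$loglik,
                 bic_by_k = bic[!is.na(bic)],
                 responsibilities = z,
                 n_obs = n, P = p),
            class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf("<control_model> K = %d clusters on %d PC(s), n = %d cells\n",
              x$K, x$P, x$n_obs))
  cat("  delta:", paste(sprintf("%.3f", x$delta), collapse = " "), "\n")
  cat("  BIC:", paste(sprintf("%s=%.1f", names(x$bic_by_k), x$bic_by_k),
                      collapse = "  "), "\n")
  invisible(x)
}

# invert a covariance matrix, adding a small diagonal ridge if near-singular
.safe_precision <- function(sigma, ridge = 1e-6) {
  sigma <- as.matrix(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    sigma <- sigma + diag(ridge * mean(diag(sigma)) + 1e-12, nrow(sigma))
    ch <- chol(sigma)
  }
  chol2inv(ch)
}

# log N(y | mean, M^-1) for all rows of y; M a precision matrix
.log_dmvnorm_prec <- function(y, mean, M) {
  p <- ncol(y)
  ch <- chol(M)
  yc <- sweep(y, 2L, mean)
  q <- rowSums((yc %*% t(ch))^2)
  0.5 * (2 * sum(log(diag(ch)))) - 0.5 * p * log(2 * pi) - 0.5 * q
}

#' Log-likelihood of a perturbation group under the linked mixture
#'
#' Evaluates the mixture `p(y) = sum_k lambda_k N(y | mu_k + beta, M_k^-1)`
#' exactly, with the cluster means `mu_k` taken from the control model and
#' `lambda`, `beta`, `M` from the fit (or given explicitly). Pure function;
#' it is also what the EM records in its trace.
#'
#' @param y matrix of perturbation scores on the selected PCs.
#' @param control a [fit_control_gmm()] result.
#' @param fit a [em_perturbation()] result, or a list with elements
#'   `lambda`, `beta` and (optionally) `M`.
#' @return total log-likelihood (a single number).
#' @export
loglik_perturbation <- function(y, control, fit) {
  y <- as.matrix(y)
  stopifnot(inherits(control, "control_model"), ncol(y) == control$P)
  lambda <- fit$lambda; beta <- fit$beta
  M <- fit$M %||% control$Lambda
  ll_k <- vapply(seq_len(control$K), function(k) {
    .log_dmvnorm_prec(y, control$mu[k, ] + beta, M[[k]]) + log(lambda[k])
  }, numeric(nrow(y)))
  ll_k <- matrix(ll_k, nrow = nrow(y))
  m <- apply(ll_k, 1L, max)
  sum(m + log(rowSums(exp(ll_k - m))))
}

#' EM estimation of cluster proportions and the shared cellular response
#'
#' Fits the perturbation-group mixture
#' `p(y) = sum_k lambda_k N(y | mu_k + beta, M_k^-1)` with the cluster means
#' `mu_k` held fixed at their control-group estimates. The E-step computes
#' cluster responsibilities under the current parameters; the M-step updates
#' `lambda_k` as the mean responsibility, the single shared response vector
#' `beta`, and (unless `fix_M_to_Lambda`) the cluster precisions `M_k`.
#' Iteration stops when the log-likelihood improves by less than `tol`.
#'
#' Two `beta` updates are available. `"precision_weighted"` (default) is the
#' exact maximizer of the expected complete-data log-likelihood,
#' `beta = (sum_k N_k M_k)^{-1} sum_k M_k sum_j r_jk (y_j - mu_k)`, which
#' guarantees a monotone log-likelihood trace. `"cluster_average"` instead
#' averages the K responsibility-weighted per-cluster shifts with equal
#' weight `1/K`; the two coincide when all `N_k M_k` are equal, but the
#' plain average is not an ascent step in general. See the methods vignette.
#'
#' Initialization: `lambda = delta`, `beta` = observed change relative to
#' the control mixture mean, `M = Lambda`, which makes a null perturbation a
#' fixed point.
#'
#' @param y matrix (or vector) of perturbation scores on the selected PCs.
#' @param control a [fit_control_gmm()] result on the same PCs.
#' @param fix_M_to_Lambda keep cluster shapes equal to the control group
#'   (default `TRUE`; recommended for the small per-gRNA cell counts typical
#'   of scCRISPR-seq).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param beta_update `"precision_weighted"` (exact M-step) or
#'   `"cluster_average"`.
#' @param seed unused (the algorithm is deterministic); kept for interface
#'   symmetry.
#' @return an object of class `perturbation_fit`: `lambda`, `beta`, `M`,
#'   `responsibilities` (N x K), `log_likelihood_trace`, `converged`,
#'   `n_iter`, `fix_M_to_Lambda`, `beta_update`.
#' @export
em_perturbation <- function(y, control, fix_M_to_Lambda = TRUE,
                            tol = 1e-6, max_iter = 500L,
                            beta_update = c("precision_weighted",
                                            "cluster_average"),
                            seed = NULL) {
  y <- as.matrix(y)
  stopifnot(inherits(control, "control_model"), ncol(y) == control$P)
  beta_update <- match.arg(beta_update)
  K <- control$K; P <- control$P; n <- nrow(y)
  if (n < K + 1L) .stop2("need at least K + 1 perturbation cells")
  mu <- control$mu

  lambda <- control$delta
  beta <- colMeans(y) - colSums(control$delta * mu)
  M <- control$Lambda
  trace <- loglik_perturbation(y, control,
                               list(lambda = lambda, beta = beta, M = M))
  converged <- FALSE
  warned <- FALSE

  for (it in seq_len(max_iter)) {
    # E-step (Bayes responsibilities under current lambda, beta, M)
    lk <- vapply(seq_len(K), function(k) {
      .log_dmvnorm_prec(y, mu[k, ] + beta, M[[k]]) + log(lambda[k])
    }, numeric(n))
    lk <- matrix(lk, nrow = n)
    mrow <- apply(lk, 1L, max)
    r <- exp(lk - mrow)
    r <- r / rowSums(r)

    # M-step
    Nk <- colSums(r)
    lambda <- Nk / n
    shift_k <- vapply(seq_len(K), function(k) {
      if (Nk[k] < 1e-10) return(rep(0, P))
      colSums(r[, k] * sweep(y, 2L, mu[k, ])) / Nk[k]
    }, numeric(P))
    shift_k <- matrix(shift_k, nrow = P)
    beta <- if (beta_update == "cluster_average") {
      rowMeans(shift_k)
    } else {
      A <- matrix(0, P, P); b <- rep(0, P)
      for (k in seq_len(K)) {
        A <- A + Nk[k] * M[[k]]
        b <- b + Nk[k] * (M[[k]] %*% shift_k[, k])
      }
      as.numeric(solve(A, b))
    }
    if (!fix_M_to_Lambda) {
      for (k in seq_len(K)) {
        if (Nk[k] < max(1e-10, 1e-8 * n)) {
          if (!warned) {
            warning("cluster ", k, " received near-zero responsibility; ",
                    "its covariance update was skipped")
            warned <- TRUE
          }
          next
        }
        yc <- sweep(y, 2L, mu[k, ] + beta)
        S <- crossprod(yc * sqrt(r[, k])) / Nk[k]
        M[[k]] <- .safe_precision(S)
      }
    }

    ll <- loglik_perturbation(y, control,
                              list(lambda = lambda, beta = beta, M = M))
    if (!is.finite(ll)) .stop2("non-finite log-likelihood during EM")
    trace <- c(trace, ll)
    if (abs(ll - trace[length(trace) - 1L]) < tol) { converged <- TRUE; break }
  }

  structure(list(lambda = lambda, beta = beta, M = M,
                 responsibilities = r,
                 log_likelihood_trace = trace,
                 converged = converged, n_iter = length(trace) - 1L,
                 fix_M_to_Lambda = fix_M_to_Lambda,
                 beta_update = beta_update),
            class = "perturbation_fit")
}

#' @export
print.perturbation_fit <- function(x, ...) {
  cat(sprintf("<perturbation_fit> K = %d, %d iterations (%s)\n",
              length(x$lambda), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  lambda:", paste(sprintf("%.3f", x$lambda), collapse = " "), "\n")
  cat("  beta:  ", paste(sprintf("%.4f", x$beta), collapse = " "), "\n")
  invisible(x)
}
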