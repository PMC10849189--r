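# shared fixtures, generated in code

# small random Poisson count matrix with guaranteed nonzero cell totals
make_counts <- function(n_cells, n_genes, seed = 1, group = "control",
                        lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  m[, 1] <- m[, 1] + 1  # no all-zero cells
  rownames(m) <- sprintf("cell_%03d", seq_len(n_cells))
  colnames(m) <- sprintf("gene_%03d", seq_len(n_genes))
  count_matrix(m, group_label = group)
}

# hand-built pc_space (control scores only), for PC classification tests
make_pc_space <- function(control_scores, extra_var = 0) {
  ev <- unname(apply(control_scores, 2, var))
  structure(list(control_scores = as.matrix(control_scores),
                 perturb_scores = list(),
                 basis = NULL, hvf_ids = NULL, hvf_means = NULL,
                 explained_variance = ev,
                 total_variance = sum(ev) + extra_var,
                 n_control = nrow(control_scores)),
            class = "pc_space")
}

# hand-built control model with known parameters (no fitting)
make_control_model <- function(delta, mu, Sigma, n_obs = 1000) {
  mu <- as.matrix(mu)
  structure(list(K = length(delta), delta = delta, mu = mu,
                 Lambda = lapply(Sigma, solve), Sigma = Sigma,
                 log_likelihood = NA_real_, bic_by_k = c(K0 = NA_real_),
                 responsibilities = NULL,
                 n_obs = n_obs, P = ncol(mu)),
            class = "control_model")
}

# sample from a perturbation mixture with known lambda, beta (shared shift)
sample_perturbation <- function(n, lambda, mu, Sigma, beta) {
  K <- length(lambda)
  lab <- sample.int(K, n, replace = TRUE, prob = lambda)
  out <- vapply(lab, function(k) {
    p <- length(beta)
    as.numeric(mu[k, ] + rnorm(p) %*% chol(Sigma[[k]]) + beta)
  }, numeric(length(beta)))
  y <- if (is.matrix(out)) t(out) else matrix(out, ncol = 1L)
  list(y = y, labels = lab)
}

# a small shared dip null table so tests do not regenerate it repeatedly
.dip_null_cache <- new.env(parent = emptyenv())
cached_dip_null <- function(n, n_null = 500, seed = 400) {
  key <- paste(n, n_null, seed)
  if (is.null(.dip_null_cache[[key]]))
    .dip_null_cache[[key]] <- dip_null_distribution(n, n_null, seed = seed)
  .dip_null_cache[[key]]
}
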