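#' Total-count normalization and log transform
#'
#' Scales every cell so that its total expression equals `scale_total`
#' (damping sequencing-depth differences), then applies `log1p`. Operates
#' on raw counts; the input object is not modified.
#'
#' @param counts a [count_matrix] of raw counts.
#' @param scale_total target per-cell total after scaling (default 10000).
#' @return a new [count_matrix] of log-normalized expression.
#' @export
normalize_log <- function(counts, scale_total = 1e4) {
  stopifnot(inherits(counts, "count_matrix"), scale_total > 0)
  totals <- rowSums(counts$values)
  if (any(totals == 0))
    .stop2("cannot normalize cells with zero total counts: ",
           paste(head(counts$cell_ids[totals == 0], 5L), collapse = ", "))
  out <- counts
  out$values <- log1p(counts$values * (scale_total / totals))
  attr(out, "normalized") <- TRUE
  attr(out, "scale_total") <- scale_total
  out
}

#' Select highly variable features on the control group
#'
#' Genes are ranked by the dispersion of their log-normalized expression.
#' With `method = "binned"` (the default) the per-gene variance is
#' standardized within equal-frequency bins of the gene mean, which removes
#' the trend of variance with expression level; `method = "variance"` ranks
#' by plain variance. Ties are broken by gene id so the selection is
#' deterministic.
#'
#' @param control a normalized control-group [count_matrix].
#' @param n_hvf number of features to keep (must not exceed the gene count).
#' @param method dispersion criterion, see above.
#' @param n_bins number of mean bins for the binned criterion.
#' @return character vector of `n_hvf` gene ids, ordered by decreasing
#'   dispersion.
#' @export
select_hvf <- function(control, n_hvf, method = c("binned", "variance"),
                       n_bins = 20L) {
  stopifnot(inherits(control, "count_matrix"))
  method <- match.arg(method)
  v <- control$values
  if (n_hvf > ncol(v))
    .stop2("n_hvf (", n_hvf, ") exceeds the number of genes (", ncol(v), ")")
  mu <- colMeans(v)
  va <- apply(v, 2L, var)
  score <- if (method == "variance") va else {
    n_bins <- max(1L, min(n_bins, max(1L, floor(ncol(v) / 5))))
    brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
    bins <- if (length(brk) < 2L) rep(1L, length(mu))
            else cut(mu, breaks = brk, labels = FALSE, include.lowest = TRUE)
    z <- numeric(length(va))
    for (b in unique(bins)) {
      idx <- bins == b
      s <- sd(va[idx])
      z[idx] <- if (is.na(s) || s == 0) 0 else (va[idx] - mean(va[idx])) / s
    }
    z
  }
  ord <- order(-score, control$gene_ids)
  control$gene_ids[ord][seq_len(n_hvf)]
}

#' Fit PCA on the control group and project both groups
#'
#' The principal-component space is anchored on the control group: the PCA
#' basis is fitted to the control HVF submatrix after centering by the
#' control feature means, and perturbation cells are centered by the *same*
#' control means and projected on the *same* basis. This common frame is
#' what makes the observed change a difference of score means. PC signs are
#' fixed by forcing the largest-magnitude loading of each component to be
#' positive so results are reproducible across linear-algebra backends.
#'
#' @param control normalized control [count_matrix].
#' @param perturb_groups a [count_matrix] or (named) list of them.
#' @param hvf_ids features defining the space; all matrices must contain them.
#' @param n_pcs number of components (at most `min(N_C, length(hvf_ids))`).
#' @return an object of class `pc_space` with elements `control_scores`
#'   (N_C x P), `perturb_scores` (named list of N x P matrices), `basis`
#'   (HVF x P loadings), `hvf_ids`, `hvf_means`, `explained_variance`
#'   (per-PC score variance, non-increasing) and `total_variance` (summed
#'   feature variance of the centered control HVF matrix).
#' @export
fit_project_pca <- function(control, perturb_groups, hvf_ids, n_pcs = 20L) {
  stopifnot(inherits(control, "count_matrix"))
  if (inherits(perturb_groups, "count_matrix"))
    perturb_groups <- list(perturbation = perturb_groups)
  stopifnot(length(perturb_groups) >= 1L)
  if (is.null(names(perturb_groups)))
    names(perturb_groups) <- paste0("group_", seq_along(perturb_groups))

  miss <- setdiff(hvf_ids, control$gene_ids)
  if (length(miss))
    .stop2("control matrix lacks HVFs: ", paste(head(miss, 5L), collapse = ", "))
  for (nm in names(perturb_groups)) {
    miss <- setdiff(hvf_ids, perturb_groups[[nm]]$gene_ids)
    if (length(miss))
      .stop2("perturbation group '", nm, "' lacks HVFs: ",
             paste(head(miss, 5L), collapse = ", "))
  }
  xc <- control$values[, hvf_ids, drop = FALSE]
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1L || n_pcs > min(nrow(xc), length(hvf_ids)))
    .stop2("n_pcs must lie in [1, min(N_C, |HVF|)]")

  mu <- colMeans(xc)
  xc_c <- sweep(xc, 2L, mu)
  pca <- prcomp(xc_c, center = FALSE, scale. = FALSE, rank. = n_pcs)
  basis <- pca$rotation[, seq_len(n_pcs), drop = FALSE]
  flip <- apply(basis, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  basis <- sweep(basis, 2L, flip, `*`)
  control_scores <- xc_c %*% basis
  perturb_scores <- lapply(perturb_groups, function(g) {
    xp <- sweep(g$values[, hvf_ids, drop = FALSE], 2L, mu)
    xp %*% basis
  })
  colnames(control_scores) <- paste0("PC", seq_len(n_pcs))
  for (nm in names(perturb_scores))
    colnames(perturb_scores[[nm]]) <- colnames(control_scores)
  dimnames(basis) <- list(hvf_ids, colnames(control_scores))

  structure(list(control_scores = control_scores,
                 perturb_scores = perturb_scores,
                 basis = basis, hvf_ids = hvf_ids, hvf_means = mu,
                 explained_variance = pca$sdev[seq_len(n_pcs)]^2,
                 total_variance = sum(pca$sdev^2),
                 n_control = nrow(xc)),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("<pc_space> %d control cells, %d perturbation group(s), %d PCs on %d HVFs\n",
              nrow(x$control_scores), length(x$perturb_scores),
              ncol(x$control_scores), length(x$hvf_ids)))
  vf <- x$explained_variance / x$total_variance
  cat("  variance fraction PC1..PC",
      min(5L, length(vf)), ": ",
      paste(sprintf("%.3f", head(vf, 5L)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write PC scores and basis as TSV files
#' @param x a `pc_space`.
#' @param dir output directory.
#' @export
write_pc_space <- function(x, dir) {
  stopifnot(inherits(x, "pc_space"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv <- function(m, path, id_col) {
    dt <- data.table::data.table(id = rownames(m) %||% seq_len(nrow(m)))
    data.table::setnames(dt, "id", id_col)
    data.table::fwrite(cbind(dt, data.table::as.data.table(m)), path, sep = "\t")
  }
  .write_tsv(x$control_scores, file.path(dir, "control_scores.tsv"), "cell_id")
  for (nm in names(x$perturb_scores))
    .write_tsv(x$perturb_scores[[nm]],
               file.path(dir, paste0("perturb_scores_", nm, ".tsv")), "cell_id")
  .write_tsv(x$basis, file.path(dir, "pc_basis.tsv"), "gene_id")
  invisible(dir)
}
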