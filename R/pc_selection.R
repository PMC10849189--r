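#' Hartigan's dip test of unimodality
#'
#' The dip statistic is the largest distance between the empirical CDF and
#' the closest unimodal CDF (the classic greatest-convex-minorant /
#' least-concave-majorant construction); it is at least `1/(2n)`, at most
#' `0.25`, and invariant to affine rescaling and to the order of the input.
#' The p-value is calibrated by Monte Carlo against samples of the same size
#' from the uniform distribution, the standard reference null for the test:
#' `p = (1 + #\{null dips >= observed\}) / (n_null + 1)`.
#'
#' @param values numeric vector with at least 4 finite, not all equal values.
#' @param n_null number of Monte-Carlo null replicates.
#' @param seed optional seed for the null draws.
#' @param null_dips optional precomputed vector of null dip statistics for
#'   the same sample size (see [dip_null_distribution()]); when supplied,
#'   `n_null` and `seed` are ignored. Reusing one null table across many
#'   tests of equal size saves most of the cost.
#' @return list with `statistic`, `p_value` and `n_null`.
#' @export
hartigan_dip <- function(values, n_null = 2000L, seed = NULL,
                         null_dips = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    .stop2("the dip test needs at least 4 finite values")
  if (max(values) == min(values))
    .stop2("the dip test is degenerate for a constant sample")
  stat <- .dip_stat_cpp(values)
  if (is.null(null_dips))
    null_dips <- dip_null_distribution(length(values), n_null, seed)
  p <- (1 + sum(null_dips >= stat)) / (length(null_dips) + 1)
  list(statistic = stat, p_value = p, n_null = length(null_dips))
}

#' Monte-Carlo null distribution of the dip statistic
#'
#' Dip statistics of `n_null` uniform samples of size `n`. All PCs of one
#' embedding share a sample size, so one table serves every test.
#'
#' @param n sample size of each null draw.
#' @param n_null number of replicates.
#' @param seed optional seed.
#' @return numeric vector of `n_null` dip statistics.
#' @export
dip_null_distribution <- function(n, n_null = 2000L, seed = NULL) {
  .with_seed(seed, .dip_null_cpp(as.integer(n), as.integer(n_null)))
}

#' Classify principal components for decoupling
#'
#' Infection-proportion bias only contaminates the observed change on
#' components whose control-group distribution is both high-variance and
#' multimodal; on unimodal or low-variance components the observed change
#' already equals the cellular response, so those are passed through. A PC
#' is selected when its share of total variance reaches
#' `variance_threshold` *and* its multimodality is significant (dip test on
#' the control scores).
#'
#' @param pcs a [pc_space] (classification uses the control scores only).
#' @param variance_threshold minimum variance fraction (default 0.05).
#' @param dip_alpha significance level for the dip p-value (default 0.05).
#' @param n_null,seed Monte-Carlo settings for the dip null distribution.
#' @param criterion threshold the dip `"p_value"` (default) or the raw
#'   `"statistic"` (then `dip_stat_threshold` applies).
#' @param dip_stat_threshold dip-statistic cutoff when
#'   `criterion = "statistic"`.
#' @param max_selected optional cap: keep only the `max_selected` selected
#'   PCs with the highest variance.
#' @param select optional explicit integer vector of PC indices, overriding
#'   the automatic rule.
#' @param compute_dip set `FALSE` to skip the dip test (its columns become
#'   `NA`); only allowed together with an explicit `select`, where the
#'   Monte-Carlo null would be paid for nothing.
#' @return data.frame with one row per PC: `pc_index`, `explained_variance`,
#'   `variance_fraction`, `dip_statistic`, `dip_pvalue`, `selected`.
#' @export
classify_pcs <- function(pcs, variance_threshold = 0.05, dip_alpha = 0.05,
                         n_null = 2000L, seed = NULL,
                         criterion = c("p_value", "statistic"),
                         dip_stat_threshold = 0.02, max_selected = NULL,
                         select = NULL, compute_dip = TRUE) {
  stopifnot(inherits(pcs, "pc_space"),
            variance_threshold >= 0, variance_threshold <= 1,
            dip_alpha >= 0, dip_alpha <= 1)
  criterion <- match.arg(criterion)
  if (!compute_dip && is.null(select))
    .stop2("compute_dip = FALSE requires an explicit PC selection")
  sc <- pcs$control_scores
  p <- ncol(sc)
  vf <- pcs$explained_variance / pcs$total_variance
  if (compute_dip) {
    null_dips <- dip_null_distribution(nrow(sc), n_null, seed)
    stat <- pval <- numeric(p)
    for (j in seq_len(p)) {
      dt <- hartigan_dip(sc[, j], null_dips = null_dips)
      stat[j] <- dt$statistic; pval[j] <- dt$p_value
    }
    multimodal <- if (criterion == "p_value") pval <= dip_alpha
                  else stat >= dip_stat_threshold
    selected <- vf >= variance_threshold & multimodal
  } else {
    stat <- pval <- rep(NA_real_, p)
    selected <- rep(FALSE, p)
  }
  if (!is.null(max_selected) && sum(selected) > max_selected) {
    sel_idx <- which(selected)
    keep <- sel_idx[order(-vf[sel_idx])][seq_len(max_selected)]
    selected <- seq_len(p) %in% keep
  }
  if (!is.null(select)) {
    if (length(setdiff(select, seq_len(p))))
      .stop2("explicit PC selection outside 1..", p)
    selected <- seq_len(p) %in% as.integer(select)
  }
  data.frame(pc_index = seq_len(p),
             explained_variance = pcs$explained_variance,
             variance_fraction = vf,
             dip_statistic = stat,
             dip_pvalue = pval,
             selected = selected)
}

#' Write a PC classification report as TSV
#' @param classification result of [classify_pcs()].
#' @param path output file.
#' @export
write_pc_report <- function(classification, path) {
  data.table::fwrite(classification, path, sep = "\t")
  invisible(path)
}
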