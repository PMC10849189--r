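#' Observed change between perturbation and control group
#'
#' Per-PC difference of group means,
#' `OC = mean(perturbation scores) - mean(control scores)`. Under the
#' linked-mixture model this decomposes into the cellular response plus the
#' infection-proportion bias `sum_k (lambda_k - delta_k) mu_k`.
#'
#' @param control_scores,perturb_scores matrices with the same number of
#'   columns (PCs), one row per cell.
#' @return numeric vector of per-PC observed changes.
#' @export
compute_observed_change <- function(control_scores, perturb_scores) {
  control_scores <- as.matrix(control_scores)
  perturb_scores <- as.matrix(perturb_scores)
  if (nrow(control_scores) == 0L || nrow(perturb_scores) == 0L)
    .stop2("both groups must contain at least one cell")
  if (ncol(control_scores) != ncol(perturb_scores))
    .stop2("groups disagree on the number of PCs")
  colMeans(perturb_scores) - colMeans(control_scores)
}

#' Assemble the full-length per-PC cellular response
#'
#' Decoupled estimates (`beta`) are used on the selected PCs; on every
#' other PC the observed change is already an unbiased estimate of the
#' response and is passed through.
#'
#' @param fit a [em_perturbation()] result covering exactly the selected PCs.
#' @param classification the [classify_pcs()] data.frame.
#' @param oc full-length observed-change vector (one entry per PC).
#' @return object of class `response_profile`: `per_pc_response`,
#'   `source_per_pc` (`"decoupled"` or `"observed_change"`), plus fields
#'   filled in by [backproject()]/[rank_genes()] when used via
#'   [build_response_profile()].
#' @export
assemble_response <- function(fit, classification, oc) {
  sel <- classification$selected
  if (length(oc) != nrow(classification))
    .stop2("oc and classification disagree on the number of PCs")
  if (length(fit$beta) != sum(sel))
    .stop2("fit covers ", length(fit$beta), " PCs but ", sum(sel),
           " are selected")
  resp <- oc
  resp[sel] <- fit$beta
  structure(list(per_pc_response = resp,
                 source_per_pc = ifelse(sel, "decoupled", "observed_change"),
                 gene_response = NULL, gene_ranking = NULL,
                 grna_or_target_id = NULL),
            class = "response_profile")
}

#' Back-project a per-PC response into gene space
#'
#' Linear map `response %*% t(basis)`. No mean offset is re-added: a
#' response is a difference of expression profiles, so the centering
#' offsets cancel.
#'
#' @param response numeric per-PC vector (or a `response_profile`).
#' @param basis loadings matrix (genes x PCs), e.g. `pc_space$basis`.
#' @return named numeric vector over the basis genes.
#' @export
backproject <- function(response, basis) {
  if (inherits(response, "response_profile")) response <- response$per_pc_response
  basis <- as.matrix(basis)
  if (length(response) != ncol(basis))
    .stop2("response length does not match the number of basis columns")
  setNames(as.numeric(basis %*% response), rownames(basis))
}

#' Rank genes by the magnitude of their response
#'
#' @param gene_response named numeric vector (finite values).
#' @param top_n optional truncation of the ranking (e.g. 1500 to define a
#'   differential-gene set).
#' @return character vector of gene ids ordered by decreasing `|response|`,
#'   ties broken by gene id.
#' @export
rank_genes <- function(gene_response, top_n = NULL) {
  if (!all(is.finite(gene_response))) .stop2("gene_response must be finite")
  ids <- names(gene_response) %||% as.character(seq_along(gene_response))
  ord <- order(-abs(gene_response), ids)
  out <- ids[ord]
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher's exact test on the 2x2 table of
#' differential genes versus gene-set membership within the universe. The
#' gene set is intersected with the universe before testing; the
#' differential genes must be a subset of the universe.
#'
#' @param diff_genes character vector of differential genes.
#' @param gene_set character vector of the signature/pathway genes.
#' @param universe background gene set (e.g. the HVF list).
#' @return list with `n_overlap`, `n_diff`, `n_set`, `n_universe`,
#'   `odds_ratio` (sample odds ratio; `Inf` with `infinite_odds = TRUE` for
#'   degenerate tables), `p_value` and `enrichment_score` (`-log10 p`).
#' @export
fisher_enrichment <- function(diff_genes, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) .stop2("empty universe")
  diff_genes <- unique(as.character(diff_genes))
  if (length(setdiff(diff_genes, universe)))
    .stop2("diff_genes must be a subset of the universe")
  gene_set <- intersect(unique(as.character(gene_set)), universe)
  a <- length(intersect(diff_genes, gene_set))
  b <- length(diff_genes) - a
  cc <- length(gene_set) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2L, byrow = TRUE)
  p <- fisher.test(tab, alternative = "greater")$p.value
  or <- (a * d) / (b * cc)   # sample odds ratio; Inf/NaN for degenerate tables
  list(n_overlap = a, n_diff = length(diff_genes), n_set = length(gene_set),
       n_universe = length(universe),
       odds_ratio = or, infinite_odds = !is.finite(or),
       p_value = p, enrichment_score = -log10(p))
}

#' Enrichment of one differential-gene set against many gene sets
#' @inheritParams fisher_enrichment
#' @param gene_sets named list of gene sets (see [read_gene_sets()]).
#' @return data.frame with one row per set.
#' @export
enrich_gene_sets <- function(diff_genes, gene_sets, universe) {
  rows <- lapply(names(gene_sets), function(nm) {
    e <- fisher_enrichment(diff_genes, gene_sets[[nm]], universe)
    data.frame(set_name = nm, n_overlap = e$n_overlap, n_diff = e$n_diff,
               n_set = e$n_set, n_universe = e$n_universe,
               odds_ratio = e$odds_ratio, p_value = e$p_value,
               enrichment_score = e$enrichment_score)
  })
  do.call(rbind, rows)
}

#' Full response profile for one perturbation group
#'
#' Convenience wrapper chaining [compute_observed_change()],
#' [assemble_response()], [backproject()] and [rank_genes()].
#'
#' @param fit a [em_perturbation()] result on the selected PCs.
#' @param classification the [classify_pcs()] data.frame.
#' @param pcs the [pc_space].
#' @param group name of the perturbation group inside `pcs$perturb_scores`.
#' @param top_n optional ranking truncation (see [rank_genes()]).
#' @return a `response_profile` with `gene_response` and `gene_ranking`
#'   filled in.
#' @export
build_response_profile <- function(fit, classification, pcs, group,
                                   top_n = NULL) {
  stopifnot(inherits(pcs, "pc_space"))
  oc <- compute_observed_change(pcs$control_scores,
                                pcs$perturb_scores[[group]])
  prof <- assemble_response(fit, classification, oc)
  prof$gene_response <- backproject(prof$per_pc_response, pcs$basis)
  prof$gene_ranking <- rank_genes(prof$gene_response, top_n)
  prof$grna_or_target_id <- group
  prof
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("<response_profile>%s %d PCs (%d decoupled)\n",
              if (is.null(x$grna_or_target_id)) ""
              else paste0(" ", x$grna_or_target_id, ":"),
              length(x$per_pc_response),
              sum(x$source_per_pc == "decoupled")))
  if (!is.null(x$gene_ranking))
    cat("  top genes:", paste(head(x$gene_ranking, 5L), collapse = ", "), "\n")
  invisible(x)
}
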