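#' Pipeline configuration
#'
#' Collects every tunable of the workflow with its default. The resolved
#' configuration is written next to the results of each run and can be
#' serialized to JSON and read back unchanged.
#'
#' @param scale_total per-cell total for normalization.
#' @param n_hvf number of highly variable features (default 700, the value
#'   used for the Jurkat-cell analysis this workflow follows).
#' @param hvf_method dispersion criterion for [select_hvf()].
#' @param n_pcs number of principal components.
#' @param variance_threshold,dip_alpha,n_null PC-selection settings, see
#'   [classify_pcs()].
#' @param pc_select optional explicit PC indices overriding the automatic
#'   selection (`NULL` for automatic).
#' @param k_range candidate cluster numbers for the control mixture.
#' @param fix_M keep perturbation cluster shapes fixed at the control
#'   estimates, see [em_perturbation()].
#' @param beta_update M-step variant for the response vector.
#' @param tol,max_iter EM convergence settings.
#' @param group_by pool perturbation cells by `"target"` or `"grna"`.
#' @param top_n differential-gene cut for the enrichment step (default
#'   1500).
#' @param seed master seed for every stochastic step.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(scale_total = 1e4, n_hvf = 700L,
                       hvf_method = "binned", n_pcs = 20L,
                       variance_threshold = 0.05, dip_alpha = 0.05,
                       n_null = 2000L, pc_select = NULL, k_range = 1:5,
                       fix_M = TRUE, beta_update = "precision_weighted",
                       tol = 1e-6, max_iter = 500L,
                       group_by = "target", top_n = 1500L, seed = 1L) {
  cfg <- list(scale_total = as.numeric(scale_total),
              n_hvf = as.numeric(n_hvf),
              hvf_method = as.character(hvf_method),
              n_pcs = as.numeric(n_pcs),
              variance_threshold = as.numeric(variance_threshold),
              dip_alpha = as.numeric(dip_alpha),
              n_null = as.numeric(n_null),
              pc_select = if (!is.null(pc_select)) as.numeric(pc_select),
              k_range = as.numeric(k_range),
              fix_M = as.logical(fix_M),
              beta_update = as.character(beta_update),
              tol = as.numeric(tol),
              max_iter = as.numeric(max_iter),
              group_by = as.character(group_by),
              top_n = as.numeric(top_n),
              seed = as.numeric(seed))
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to JSON
#' @param config a [run_config()].
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration back from JSON
#' @param path JSON file written by [write_run_config()].
#' @return a [run_config()] equal to the one written.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, TRUE)])
}

#' Run the full decoupling workflow
#'
#' Preprocessing (normalize, HVFs on the control group, PCA projection),
#' PC classification, control-mixture fit, per-group decoupling EM, and
#' response assembly with optional gene-set enrichment, in one call. Given
#' the same inputs, configuration and seed the outputs are identical across
#' runs.
#'
#' @param control control-group counts: a [count_matrix], or a path to a
#'   CSV/TSV matrix or a matrix-market directory.
#' @param perturb perturbation counts in the same formats; with a gRNA
#'   assignment the matrix is split into per-target (or per-gRNA) groups,
#'   otherwise it is treated as a single group.
#' @param assignment optional cell-to-gRNA table: result of
#'   [read_grna_assignment()] or a path to one.
#' @param gene_sets optional gene sets for enrichment: named list or a path
#'   for [read_gene_sets()].
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, the resolved
#'   config, a log file, the PC report and all per-group result tables are
#'   written there.
#' @param verbose print per-stage progress (the log file is written either
#'   way).
#' @return list with `pcs`, `classification`, `control_model`, `fits`,
#'   `responses`, `enrichment` and `config`.
#' @export
run_pipeline <- function(control, perturb, assignment = NULL,
                         gene_sets = NULL, config = run_config(),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%7.2fs] %s: %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stop2("stage ", name, ": ", conditionMessage(e)))
  }
  seeds <- split_seed(config$seed, 4L)

  # ---- load -----------------------------------------------------------------
  res <- stage("load", {
    ctl <- .load_counts(control, "control")
    prt <- .load_counts(perturb, "perturbation")
    if (!is.null(assignment)) {
      if (is.character(assignment)) assignment <- read_grna_assignment(assignment)
      prt$grna_assignment <- assignment$grna_assignment
      prt$target_assignment <- assignment$target_assignment
    }
    if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
    list(ctl = ctl, prt = prt, gene_sets = gene_sets)
  })
  say("load", "%d control cells, %d perturbation cells, %d genes",
      nrow(res$ctl$values), nrow(res$prt$values), ncol(res$ctl$values))

  # ---- preprocess ------------------------------------------------------------
  pcs <- stage("preprocess", {
    ctl_n <- normalize_log(res$ctl, config$scale_total)
    prt_n <- normalize_log(res$prt, config$scale_total)
    groups <- if (!is.null(prt_n$grna_assignment)) {
      split_by_group(prt_n, config$group_by)
    } else {
      if (config$group_by == "target" && !is.null(assignment))
        .stop2("gRNA assignment covers no perturbation cell")
      list(perturbation = prt_n)
    }
    hvf <- select_hvf(ctl_n, min(config$n_hvf, ncol(ctl_n$values)),
                      method = config$hvf_method)
    n_pcs <- min(config$n_pcs, length(hvf), nrow(ctl_n$values))
    fit_project_pca(ctl_n, groups, hvf, n_pcs)
  })
  say("preprocess", "%d HVFs, %d PCs, %d perturbation group(s)",
      length(pcs$hvf_ids), ncol(pcs$control_scores),
      length(pcs$perturb_scores))

  # ---- PC selection ----------------------------------------------------------
  classification <- stage("classify_pcs",
    classify_pcs(pcs, config$variance_threshold, config$dip_alpha,
                 n_null = config$n_null, seed = seeds[1L],
                 select = config$pc_select,
                 compute_dip = is.null(config$pc_select)))
  sel_pcs <- classification$pc_index[classification$selected]
  say("classify_pcs", "selected PCs: %s",
      if (length(sel_pcs)) paste(sel_pcs, collapse = ", ") else "none")

  sel <- classification$selected
  control_model <- NULL
  if (any(sel)) {
    control_model <- stage("fit_control_gmm",
      fit_control_gmm(pcs$control_scores[, sel, drop = FALSE],
                      k_range = config$k_range, seed = seeds[2L]))
    say("fit_control_gmm", "K = %d (BIC over {%s})", control_model$K,
        paste(sub("^K", "", names(control_model$bic_by_k)), collapse = ","))
  } else {
    say("fit_control_gmm",
        "no PC selected; observed change is the response everywhere")
  }

  # ---- decoupling + responses ------------------------------------------------
  fits <- list(); responses <- list(); enrichment <- list()
  for (nm in names(pcs$perturb_scores)) {
    yp <- pcs$perturb_scores[[nm]]
    oc <- compute_observed_change(pcs$control_scores, yp)
    if (any(sel)) {
      fit <- stage(paste0("em_perturbation[", nm, "]"),
        em_perturbation(yp[, sel, drop = FALSE], control_model,
                        fix_M_to_Lambda = config$fix_M,
                        tol = config$tol, max_iter = config$max_iter,
                        beta_update = config$beta_update))
      fits[[nm]] <- fit
      prof <- assemble_response(fit, classification, oc)
      say(paste0("decouple[", nm, "]"),
          "%d iterations, lambda = %s", fit$n_iter,
          paste(sprintf("%.3f", fit$lambda), collapse = " "))
    } else {
      prof <- structure(list(per_pc_response = oc,
                             source_per_pc = rep("observed_change", length(oc)),
                             gene_response = NULL, gene_ranking = NULL,
                             grna_or_target_id = nm),
                        class = "response_profile")
    }
    prof$gene_response <- backproject(prof$per_pc_response, pcs$basis)
    prof$gene_ranking <- rank_genes(prof$gene_response)
    prof$grna_or_target_id <- nm
    responses[[nm]] <- prof
    if (!is.null(res$gene_sets)) {
      diff_genes <- head(prof$gene_ranking, config$top_n)
      enrichment[[nm]] <- enrich_gene_sets(diff_genes, res$gene_sets,
                                           pcs$hvf_ids)
    }
  }

  out <- list(pcs = pcs, classification = classification,
              control_model = control_model, fits = fits,
              responses = responses,
              enrichment = if (length(enrichment)) enrichment,
              config = config)
  if (!is.null(out_dir)) {
    stage("write_outputs", .write_pipeline_outputs(out, out_dir, log_lines))
    say("write_outputs", "results in %s", out_dir)
  }
  invisible(out)
}

.load_counts <- function(x, group_label) {
  if (inherits(x, "count_matrix")) return(x)
  if (!is.character(x) || !file.exists(x))
    .stop2(group_label, " input must be a count_matrix or an existing path")
  if (dir.exists(x)) read_counts_mtx(x, group_label = group_label)
  else read_counts_csv(x, group_label = group_label)
}

.write_pipeline_outputs <- function(out, dir, log_lines) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(out$config, file.path(dir, "config.json"))
  write_pc_report(out$classification, file.path(dir, "pc_report.tsv"))
  if (!is.null(out$control_model)) {
    cm <- out$control_model
    jsonlite::write_json(
      list(K = cm$K, delta = cm$delta, mu = cm$mu,
           Lambda = lapply(cm$Lambda, identity),
           log_likelihood = cm$log_likelihood, bic_by_k = as.list(cm$bic_by_k)),
      file.path(dir, "control_model.json"), digits = NA, auto_unbox = TRUE)
  }
  for (nm in names(out$responses)) {
    prof <- out$responses[[nm]]
    data.table::fwrite(
      data.table::data.table(pc_index = seq_along(prof$per_pc_response),
                             response = prof$per_pc_response,
                             source = prof$source_per_pc),
      file.path(dir, paste0("response_", nm, ".tsv")), sep = "\t")
    data.table::fwrite(
      data.table::data.table(gene_id = names(prof$gene_response),
                             response = as.numeric(prof$gene_response)),
      file.path(dir, paste0("gene_response_", nm, ".tsv")), sep = "\t")
    data.table::fwrite(
      data.table::data.table(rank = seq_along(prof$gene_ranking),
                             gene_id = prof$gene_ranking),
      file.path(dir, paste0("ranking_", nm, ".tsv")), sep = "\t")
    if (!is.null(out$fits[[nm]])) {
      f <- out$fits[[nm]]
      jsonlite::write_json(
        list(lambda = f$lambda, beta = f$beta, M = lapply(f$M, identity),
             log_likelihood_trace = f$log_likelihood_trace,
             converged = f$converged, n_iter = f$n_iter,
             fix_M_to_Lambda = f$fix_M_to_Lambda,
             beta_update = f$beta_update),
        file.path(dir, paste0("fit_", nm, ".json")), digits = NA,
        auto_unbox = TRUE)
    }
    if (!is.null(out$enrichment[[nm]]))
      data.table::fwrite(out$enrichment[[nm]],
                         file.path(dir, paste0("enrichment_", nm, ".tsv")),
                         sep = "\t")
  }
  writeLines(log_lines, file.path(dir, "log.txt"))
  invisible(dir)
}
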