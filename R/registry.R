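## Built-in model registrations: every reimplemented model is exposed to the
## harness as a runner (data, hyper, seed) -> named metric list, with its
## documented default preprocessing pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
clustering_pipeline <- function() sc_pipeline(list(
  transform_step("filter_features", min_cells_expressing = 3L),
  transform_step("normalize_total", target_sum = 1e4),
  transform_step("log1p"),
  transform_step("select_top_genes", k = 3000L)))

#' @keywords internal
linear_pipeline <- function() sc_pipeline(list(
  transform_step("filter_features", min_cells_expressing = 3L),
  transform_step("normalize_total", target_sum = 1e4)))

#' @keywords internal
hyper_to_cfg <- function(hyper, seed, drop = character(0)) {
  cfg <- hyper[setdiff(names(hyper), drop)]
  cfg$seed <- as.integer(seed)
  cfg
}

#' @keywords internal
clustering_metrics <- function(ds, labels) {
  truth <- ds$cell_table$cell_type
  list(ari = ari(truth, labels), nmi = nmi(truth, labels))
}

#' @keywords internal
register_builtin_models <- function() {
  clp <- clustering_pipeline()

  register_model("zinb_dec", "clustering", clp, function(data, hyper, seed) {
    ds <- apply_pipeline(clp, data)
    K <- as.integer(hyper$K %||% length(unique(ds$cell_table$cell_type)))
    m <- fit_zinb_dec(ds, K, hyper_to_cfg(hyper, seed, "K"))
    clustering_metrics(ds, predict(m))
  })

  register_model("zinb_dec_constrained", "clustering", clp,
                 function(data, hyper, seed) {
    ds <- apply_pipeline(clp, data)
    K <- as.integer(hyper$K %||% length(unique(ds$cell_table$cell_type)))
    cons <- sample_constraints(ds$cell_table$cell_type,
                               n_must = as.integer(hyper$n_must %||% 100L),
                               n_cannot = as.integer(hyper$n_cannot %||% 100L),
                               seed = seed)
    m <- fit_zinb_dec(ds, K,
                      hyper_to_cfg(hyper, seed, c("K", "n_must", "n_cannot")),
                      constraints = cons)
    clustering_metrics(ds, predict(m))
  })

  register_model("graph_ae_cluster", "clustering", clp,
                 function(data, hyper, seed) {
    ds <- apply_pipeline(clp, data)
    K <- as.integer(hyper$K %||% length(unique(ds$cell_table$cell_type)))
    m <- fit_graph_ae_cluster(ds, K, hyper_to_cfg(hyper, seed, "K"))
    clustering_metrics(ds, predict(m))
  })

  ann_runner <- function(fit_fn) function(data, hyper, seed) {
    ds <- apply_pipeline(clustering_pipeline(), data)
    parts <- split_dataset(ds,
                           test_fraction = hyper$test_fraction %||% 0.2,
                           stratify_by = "cell_type", seed = seed)
    m <- fit_fn(parts$train, hyper_to_cfg(hyper, seed, "test_fraction"))
    list(accuracy = score(m, parts$test))
  }
  register_model("logreg", "annotation", clustering_pipeline(),
                 ann_runner(fit_logreg_annotator))
  register_model("mlp", "annotation", clustering_pipeline(),
                 ann_runner(fit_mlp_annotator))
  register_model("gnn", "annotation", clustering_pipeline(),
                 function(data, hyper, seed) {
    ds <- apply_pipeline(clustering_pipeline(), data)
    parts <- split_dataset(ds,
                           test_fraction = hyper$test_fraction %||% 0.2,
                           stratify_by = "cell_type", seed = seed)
    m <- fit_gnn_annotator(parts$train, parts$test,
                           hyper_to_cfg(hyper, seed, "test_fraction"))
    list(accuracy = accuracy(parts$test$cell_table$cell_type, predict(m)))
  })

  imp_runner <- function(fit_fn) function(data, hyper, seed) {
    mds <- mask_nonzero_entries(data,
                                fraction = hyper$mask_fraction %||% 0.1,
                                seed = seed)
    m <- fit_fn(mds, data, hyper_to_cfg(hyper, seed, "mask_fraction"))
    list(mse = score(m))
  }
  register_model("block_mlp", "imputation", linear_pipeline(),
                 imp_runner(fit_block_mlp_imputer))
  register_model("graph_ae_imputer", "imputation", linear_pipeline(),
                 imp_runner(fit_graph_ae_imputer))
  register_model("gene_mean", "imputation", linear_pipeline(),
                 function(data, hyper, seed) {
    mds <- mask_nonzero_entries(data,
                                fraction = hyper$mask_fraction %||% 0.1,
                                seed = seed)
    mats <- imputation_matrices(mds, data)
    pred <- baseline_gene_mean_impute(mds)
    list(mse = masked_mse(mats$truth, pred, mats$mask))
  })

  register_model("nnls_deconv", "deconvolution", linear_pipeline(),
                 function(data, hyper, seed) {
    stopifnot(inherits(data, "sc_mixture"))
    sig <- build_signature(data$reference,
                           n_markers = as.integer(hyper$n_markers %||% 20L))
    P <- nnls_deconvolve(data$spots, sig,
                         log_weighting = isTRUE(hyper$log_weighting))
    list(mse = score_deconvolution(P, data$truth))
  })

  register_model("seeded_nmf", "deconvolution", linear_pipeline(),
                 function(data, hyper, seed) {
    stopifnot(inherits(data, "sc_mixture"))
    sig <- build_signature(data$reference,
                           n_markers = as.integer(hyper$n_markers %||% 20L))
    P <- seeded_nmf_deconvolve(data$reference, data$spots, sig,
                               hyper_to_cfg(hyper, seed, "n_markers"))
    list(mse = score_deconvolution(P, data$truth))
  })
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_fixtures()
  register_builtin_models()
}
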