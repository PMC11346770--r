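#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default.
#' Unknown keys are rejected. Stage seeds are fanned out from the single
#' `seed` as `seed + stage offset` (preprocess/gmm/cbs use offsets 0/1/2),
#' so each stage is independently reproducible.
#'
#' @param ... named overrides of the defaults listed below.
#' @return list of class `acn_config`.
#' @export
acn_config <- function(...) {
  defaults <- list(
    gc_low = 0.2, gc_high = 0.8, map_min = 0.9,   # bin masking
    gini_threshold = 0.12,                        # normal-cell detection
    gini_method = "cluster", gini_margin = 0.02,
    norm_robust = TRUE,                           # median-based lambda
    k_min = 8, k_max = 25, n_restarts = 5,        # GMM / BIC search
    k_extend = TRUE,                              # extend scan past boundary optimum
    delta = 0.1, baf_weight = 0.5,                # component merging
    smooth_window = 3,                            # assignment de-flickering
    cbs_alpha = 0.05, cbs_n_perm = 1000, cbs_min_width = 2,
    min_cells = 5,                                # ensemble frequency t
    max_total = 10, max_wgd = 2, balanced_tol = 0.05,
    tolerance_l = 1,                              # evaluation tolerance
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = c("acn_config", "list"))
}

#' @rdname acn_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(acn_config, yaml::read_yaml(path))
}

#' @rdname acn_config
#' @param config an `acn_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full calling pipeline on count/BAF matrices
#'
#' Composes the stages: bin masking and normal-cell normalization, feature
#' computation, global mixture segmentation with BIC selection and component
#' merging, per-cell CBS, ensemble breakpoint filtering, segment
#' construction, and weighted-BIC ploidy / allele-specific state calling.
#' Deterministic given `config$seed`.
#'
#' @param R raw count matrix (cells x bins).
#' @param baf BAF matrix.
#' @param bt a `bin_table`.
#' @param config an `acn_config`.
#' @param known_ploidy optional per-cell ploidies bypassing estimation.
#' @return list of class `acn_result` with elements `features`,
#'   `normal_cells`, `model` (merged), `candidates`, `cbs`, `final_bps`,
#'   `segments`, `calls`, `config`.
#' @export
run_pipeline <- function(R, baf, bt, config = acn_config(),
                         known_ploidy = NULL) {
  pre <- preprocess(R, baf, bt, config$gc_low, config$gc_high,
                    config$map_min, config$gini_threshold,
                    config$gini_method, config$gini_margin,
                    config$norm_robust)
  feats <- pre$features
  model <- fit_gmm(feats, config$k_min, config$k_max,
                   seed = config$seed + 1L, n_restarts = config$n_restarts,
                   k_extend = config$k_extend)
  model <- merge_components(model, config$delta, config$baf_weight)
  model <- smooth_assignments(model, config$smooth_window)
  cand <- candidate_breakpoints(model)
  loc <- cbs_all_cells(feats, config$cbs_alpha, config$cbs_n_perm,
                       config$cbs_min_width, seed = config$seed + 2L)
  final <- ensemble_breakpoints(cand, loc, config$min_cells)
  segs <- build_segments(final, feats)
  segs_cbs <- build_segments(loc, feats)
  calls <- call_cells(feats, model, segs, config$max_total, config$max_wgd,
                      config$balanced_tol, known_ploidy,
                      phi_segments = segs_cbs)
  structure(list(features = feats, normal_cells = pre$normal_cells,
                 model = model, candidates = cand, cbs = loc,
                 final_bps = final, segments = segs, calls = calls,
                 config = config),
            class = "acn_result")
}

#' @export
print.acn_result <- function(x, ...) {
  cat(sprintf(
    "acn_result: %d cells, %d bins, K = %d components, %d normal cell(s)\n",
    nrow(x$features$R), ncol(x$features$R), x$model$K,
    length(x$normal_cells)))
  invisible(x)
}

#' Simulate a dataset, run the pipeline, and evaluate against truth
#'
#' One-call wrapper used throughout the tests and the worked examples.
#'
#' @param config an `acn_config`; its `seed` drives the simulation too.
#' @param ... simulation parameters passed to [simulate_dataset()].
#' @return list: `result` (an `acn_result`), `truth`, `eval` (an
#'   `acn_eval`).
#' @export
run_simulated <- function(config = acn_config(), ...) {
  sim <- simulate_dataset(..., seed = config$seed)
  res <- run_pipeline(sim$R, sim$baf, sim$bin_table, config)
  ev <- evaluate_calls(res$calls, sim$truth, res$final_bps,
                       config$tolerance_l)
  list(result = res, truth = sim$truth, eval = ev)
}
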