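# One-command orchestration: simulate -> fit -> evaluate -> baseline ->
# searchlight -> components -> rsa -> report, with per-stage seeding and a
# JSON run manifest sufficient to reproduce every output byte-identically.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_full_pipeline()].
#' The defaults define the desk-scale demo condition: 300 concepts, 66
#' stimulus dimensions, 3 latent components, 642 vertices per hemisphere and
#' 200 permutations per test.
#'
#' @param n_concepts,n_stim_dims,k_true,subdivisions,snr,smoothness,symmetric,signal_fraction,mesh_radius
#'   forwarded to [generator_config()].
#' @param n_train training-set size (remaining concepts form the test set).
#' @param k number of PLSR components to fit.
#' @param grid_search `FALSE`, or an integer vector of candidate `k` values
#'   to run the nested grid search over before fitting.
#' @param radius searchlight disc radius (same units as the mesh, mm).
#' @param n_perms permutations for the R-squared and decoding nulls.
#' @param rsa_n_perms permutations for the RSA null.
#' @param alpha familywise error level.
#' @param run_rsa logical; skip the RSA stage when `FALSE`.
#' @param seed single global seed; per-stage seeds are derived as
#'   `seed * 10 + stage_index` (stages indexed 1..7 in run order).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_concepts = 300L, n_stim_dims = 66L,
                            k_true = 3L, subdivisions = 3L, snr = 1,
                            smoothness = 2L, symmetric = TRUE,
                            signal_fraction = 0.25, mesh_radius = 100,
                            n_train = NULL, k = NULL, grid_search = FALSE,
                            radius = 30, n_perms = 200L, rsa_n_perms = 200L,
                            alpha = 0.05, run_rsa = TRUE, seed = 1L) {
  n_train <- as.integer(n_train %||% round(2 * n_concepts / 3))
  stop_if_not(n_train >= 2 && n_train < n_concepts,
              "the train/test split must leave both parts non-empty")
  k <- as.integer(k %||% k_true)
  stop_if_not(k >= 1 && k <= n_stim_dims, "invalid component count k")
  stop_if_not(n_perms >= 20 && rsa_n_perms >= 20, "n_perms must be >= 20")
  structure(list(n_concepts = as.integer(n_concepts),
                 n_stim_dims = as.integer(n_stim_dims),
                 k_true = as.integer(k_true),
                 subdivisions = as.integer(subdivisions), snr = snr,
                 smoothness = as.integer(smoothness),
                 symmetric = isTRUE(symmetric),
                 signal_fraction = signal_fraction,
                 mesh_radius = mesh_radius, n_train = n_train, k = k,
                 grid_search = grid_search, radius = radius,
                 n_perms = as.integer(n_perms),
                 rsa_n_perms = as.integer(rsa_n_perms), alpha = alpha,
                 run_rsa = isTRUE(run_rsa), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  stop_if_not(length(bad) == 0,
              "unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

.stage_seed <- function(config, index) config$seed * 10L + as.integer(index)

# Generic labelled-matrix TSV writer (full precision).
.write_matrix_tsv <- function(m, path, id_header = "id") {
  if (is.data.frame(m)) m <- as.matrix(m)
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  cn <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  write_concept_matrix(concept_matrix(as_values(m), rn, cn), path,
                       id_header = id_header)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.hemi_maps <- function(map) split_map_hemispheres(map)

#' Split a two-hemisphere vertex map by hemisphere tag
#' @param map a [vertex_map()].
#' @return Named list of single-hemisphere [vertex_map()]s.
#' @export
split_map_hemispheres <- function(map) {
  hemis <- unique(map$vertex_index$hemisphere)
  out <- lapply(hemis, function(h) {
    sel <- map$vertex_index$hemisphere == h
    vertex_map(map$values[sel], map$vertex_index[sel, , drop = FALSE],
               name = map$name)
  })
  names(out) <- hemis
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic dataset drawn from the configured
#' generator: simulation, standardization + PLSR fit (optionally preceded by
#' the component-count grid search), cross-validated R-squared with its
#' max-statistic permutation null, the full linear-regression baseline and
#' difference map, searchlight pairwise decoding with its permutation null,
#' component analyses (held-out GLM, hemispheric symmetry, PLSR-GLM
#' agreement, property correlations), RSA against the generated layer
#' activations, and a summary report. All stage outputs are plain text
#' (TSV/JSON/GIFTI-ASCII) under `out_dir`; reruns with an identical config
#' are byte-identical.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir output directory (created if missing).
#' @return The run manifest (list of class `run_manifest`), invisibly also
#'   written to `out_dir/manifest.json`.
#' @export
run_full_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config or a YAML path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = .stage_seed(config, 1), fit = .stage_seed(config, 2),
                evaluate = .stage_seed(config, 3), baseline = .stage_seed(config, 4),
                searchlight = .stage_seed(config, 5),
                components = .stage_seed(config, 6), rsa = .stage_seed(config, 7))
  manifest <- list(config = unclass(config), seeds = seeds,
                   package_version = as.character(utils::packageVersion("plsrmap")),
                   stages = list())
  sdir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }

  ## -- simulate ------------------------------------------------------------
  message("stage simulate: generating synthetic dataset")
  gen <- generator_config(n_concepts = config$n_concepts,
                          n_stim_dims = config$n_stim_dims,
                          k_true = config$k_true,
                          subdivisions = config$subdivisions,
                          snr = config$snr, smoothness = config$smoothness,
                          symmetric = config$symmetric,
                          signal_fraction = config$signal_fraction,
                          mesh_radius = config$mesh_radius,
                          seed = seeds$simulate)
  ds <- generate_dataset(gen)
  d <- sdir("simulate")
  write_concept_matrix(ds$X, file.path(d, "X.tsv"))
  yh <- split_hemispheres(ds$Y)
  for (h in names(yh)) {
    .write_matrix_tsv(
      `dimnames<-`(yh[[h]]$values,
                   list(rownames(yh[[h]]$values),
                        sprintf("v%d", yh[[h]]$vertex_index$vertex))),
      file.path(d, sprintf("Y_%s.tsv", h)), id_header = "concept_id")
    write_mesh(ds$meshes[[h]], file.path(d, sprintf("%s.surf.gii", h)))
    write_vertex_mask(ds$masks[[h]], file.path(d, sprintf("mask_%s.tsv", h)))
  }
  .write_matrix_tsv(ds$correspondence, file.path(d, "correspondence.tsv"))
  td <- sdir("simulate/truth")
  .write_matrix_tsv(ds$truth$Z, file.path(td, "Z.tsv"), "concept_id")
  .write_matrix_tsv(ds$truth$A_x, file.path(td, "A_x.tsv"), "dim")
  .write_matrix_tsv(ds$truth$A_y, file.path(td, "A_y.tsv"), "vertex")
  writeLines(c("signal", as.integer(ds$truth$signal)),
             file.path(td, "signal.tsv"))
  write_concept_matrix(ds$ratings, file.path(d, "ratings.tsv"))
  ad <- sdir("simulate/activations")
  for (nm in names(ds$activations)) {
    write_concept_matrix(ds$activations[[nm]],
                         file.path(ad, paste0(nm, ".tsv")))
  }
  manifest$stages$simulate <- list(
    outputs = "simulate/",
    summary = list(n_concepts = config$n_concepts,
                   n_vertices = ncol(ds$Y$values),
                   n_signal_vertices = sum(ds$truth$signal)))

  ## -- fit -----------------------------------------------------------------
  message("stage fit: standardizing and fitting PLSR")
  spec <- first_last_split(config$n_concepts, config$n_train)
  Xs <- split_concepts(ds$X, spec)
  Ys <- split_concepts(ds$Y, spec)
  Xtr <- zscore_columns(Xs$train)$values
  Xte <- zscore_columns(Xs$test)$values
  Ytr <- zscore_columns(Ys$train)$values
  Yte <- zscore_columns(Ys$test)$values
  d <- sdir("fit")
  k_fit <- config$k
  grid <- NULL
  if (!isFALSE(config$grid_search)) {
    grid <- grid_search_components(Xtr, Ytr, k_range = config$grid_search,
                                   seed = seeds$fit)
    k_fit <- grid$selected_k
    .write_matrix_tsv(as.matrix(grid$results), file.path(d, "grid_search.tsv"), "row")
  }
  model <- fit_plsr(Xtr, Ytr, k_fit)
  .write_matrix_tsv(model$x_loadings, file.path(d, "B_X.tsv"), "dim")
  .write_matrix_tsv(model$x_weights, file.path(d, "x_weights.tsv"), "dim")
  .write_matrix_tsv(model$train_scores, file.path(d, "scores.tsv"), "concept")
  by_hemi <- split(seq_len(nrow(model$y_loadings)),
                   Ytr$vertex_index$hemisphere)
  for (h in names(by_hemi)) {
    .write_matrix_tsv(model$y_loadings[by_hemi[[h]], , drop = FALSE],
                      file.path(d, sprintf("B_Y_%s.tsv", h)), "vertex")
  }
  manifest$stages$fit <- list(
    outputs = "fit/",
    summary = c(list(k = k_fit),
                if (!is.null(grid)) list(selected_k = grid$selected_k)))

  ## -- evaluate ------------------------------------------------------------
  message("stage evaluate: cross-validated R2 and permutation null")
  Yhat <- predict_responses(model, Xte)
  r2 <- r2_map(Yte, Yhat)
  null_r2 <- max_stat_null_r2(Xtr, Ytr, Xte, Yte, k_fit,
                              n_perms = config$n_perms,
                              seed = seeds$evaluate, alpha = config$alpha)
  thr <- threshold_map(r2, null_r2)
  d <- sdir("evaluate")
  r2h <- .hemi_maps(r2)
  for (h in names(r2h)) {
    write_vertex_map(r2h[[h]], ds$masks[[h]],
                     file.path(d, sprintf("r2_%s.tsv", h)))
  }
  writeLines(c("max_r2", fmt_num(null_r2$max_stats)),
             file.path(d, "null_max.tsv"))
  .write_json(list(threshold = null_r2$threshold, alpha = config$alpha,
                   n_perms = config$n_perms,
                   n_significant = sum(thr$significant)),
              file.path(d, "threshold.json"))
  manifest$stages$evaluate <- list(
    outputs = "evaluate/",
    summary = list(peak_r2 = max(r2$values), threshold = null_r2$threshold,
                   n_significant = sum(thr$significant)))

  ## -- baseline ------------------------------------------------------------
  message("stage baseline: full linear-regression encoding model")
  lin <- fit_linear_baseline(Xtr, Ytr)
  r2_lin <- r2_map(Yte, predict_linear(lin, Xte))
  diff_map <- r2_difference_map(r2_lin, r2)  # linear > PLSR is positive
  d <- sdir("baseline")
  for (h in names(.hemi_maps(r2_lin))) {
    write_vertex_map(.hemi_maps(r2_lin)[[h]], ds$masks[[h]],
                     file.path(d, sprintf("r2_linear_%s.tsv", h)))
    write_vertex_map(.hemi_maps(diff_map)[[h]], ds$masks[[h]],
                     file.path(d, sprintf("r2_diff_%s.tsv", h)))
  }
  manifest$stages$baseline <- list(
    outputs = "baseline/",
    summary = list(peak_r2_linear = max(r2_lin$values),
                   mean_diff_significant =
                     mean(diff_map$values[thr$significant])))

  ## -- searchlight ---------------------------------------------------------
  message("stage searchlight: pairwise decoding map and permutation null")
  assignments <- lapply(names(ds$meshes), function(h) {
    build_searchlights(ds$meshes[[h]], ds$masks[[h]], config$radius)
  })
  acc_map <- searchlight_decoding_map(Yhat, Yte, assignments)
  null_dec <- max_stat_null_decoding(Yhat, Yte, assignments,
                                     n_perms = config$n_perms,
                                     seed = seeds$searchlight,
                                     alpha = config$alpha)
  thr_dec <- threshold_map(acc_map, null_dec)
  d <- sdir("searchlight")
  acch <- .hemi_maps(acc_map)
  for (h in names(acch)) {
    write_vertex_map(acch[[h]], ds$masks[[h]],
                     file.path(d, sprintf("accuracy_%s.tsv", h)))
  }
  writeLines(c("size", attr(acc_map, "sizes")),
             file.path(d, "searchlight_sizes.tsv"))
  writeLines(c("max_accuracy", fmt_num(null_dec$max_stats)),
             file.path(d, "null_max.tsv"))
  .write_json(list(threshold = null_dec$threshold, alpha = config$alpha,
                   n_perms = config$n_perms,
                   median_searchlight_size =
                     stats::median(attr(acc_map, "sizes"))),
              file.path(d, "threshold.json"))
  manifest$stages$searchlight <- list(
    outputs = "searchlight/",
    summary = list(peak_accuracy = max(acc_map$values),
                   threshold = null_dec$threshold,
                   n_significant = sum(thr_dec$significant),
                   median_searchlight_size =
                     stats::median(attr(acc_map, "sizes"))))

  ## -- components ----------------------------------------------------------
  message("stage components: GLM reproducibility, symmetry, property correlations")
  L_hat <- project_latent(model, Xte)
  glm_fit <- glm_component_fit(L_hat, Yte)
  r2_split <- .hemi_maps(r2)
  thr_left <- threshold_map(r2_split$left, null_r2)
  thr_right <- threshold_map(r2_split$right, null_r2)
  sym <- symmetry_correlations(model$y_loadings, Ytr$vertex_index,
                               thr_left, thr_right, ds$correspondence)
  agree <- loading_agreement(model$y_loadings, glm_fit, thr)
  ratings_train <- concept_matrix(
    unclass(ds$ratings)[spec$train_indices, , drop = FALSE])
  props <- property_correlations(model$train_scores, ratings_train,
                                 alpha = config$alpha)
  d <- sdir("components")
  gh <- split(seq_len(nrow(glm_fit$values)), glm_fit$vertex_index$hemisphere)
  for (h in names(gh)) {
    .write_matrix_tsv(glm_fit$values[gh[[h]], , drop = FALSE],
                      file.path(d, sprintf("glm_loadings_%s.tsv", h)), "vertex")
  }
  .write_matrix_tsv(sym$correlations, file.path(d, "symmetry_report.tsv"), "component")
  .write_matrix_tsv(agree, file.path(d, "agreement.tsv"), "component")
  utils::write.table(props, file.path(d, "property_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  k <- model$n_components
  sym_diag <- diag(sym$correlations[seq_len(k), k + seq_len(k), drop = FALSE])
  manifest$stages$components <- list(
    outputs = "components/",
    summary = list(symmetry_diag_mean = mean(sym_diag),
                   agreement_diag_mean = mean(diag(agree)),
                   roi_size = sym$roi_size,
                   n_significant_property_pairs = sum(props$significant)))

  ## -- rsa -----------------------------------------------------------------
  if (config$run_rsa) {
    message("stage rsa: representational similarity analysis")
    L_train <- model$train_scores
    targets <- c(list(full_space = latent_rdm(L_train)),
                 stats::setNames(
                   lapply(seq_len(k), function(j) component_absdiff_rdm(L_train[, j])),
                   sprintf("component_%d", seq_len(k))))
    layers <- lapply(ds$activations, function(a) {
      correlation_distance_rdm(
        unclass(a)[spec$train_indices, , drop = FALSE])
    })
    rsa <- rsa_max_stat_threshold(targets, layers,
                                  n_perms = config$rsa_n_perms,
                                  seed = seeds$rsa, alpha = config$alpha)
    d <- sdir("rsa")
    .write_matrix_tsv(rsa$correlations, file.path(d, "rsa_profile.tsv"), "target")
    .write_json(list(threshold = rsa$threshold, alpha = config$alpha,
                     n_perms = config$rsa_n_perms),
                file.path(d, "threshold.json"))
    manifest$stages$rsa <- list(
      outputs = "rsa/",
      summary = list(peak_correlation = max(rsa$correlations),
                     threshold = rsa$threshold,
                     full_space_profile =
                       as.numeric(rsa$correlations["full_space", ])))
  }

  ## -- report --------------------------------------------------------------
  class(manifest) <- "run_manifest"
  write_report(manifest, out_dir)
  .write_json(unclass(manifest), file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Write the human-readable summary report for a run
#'
#' Collects the per-stage summary statistics of a manifest into
#' `report.json` and a flat `report.tsv`. Stages absent from the manifest
#' (e.g. a disabled RSA stage) are omitted cleanly; a started-but-incomplete
#' stage is an error.
#'
#' @param manifest a `run_manifest` from [run_full_pipeline()].
#' @param out_dir run directory to write into.
#' @return Path of `report.json`, invisibly.
#' @export
write_report <- function(manifest, out_dir) {
  stop_if_not(inherits(manifest, "run_manifest") || is.list(manifest),
              "manifest must be a run manifest")
  stages <- manifest$stages
  stop_if_not(length(stages) > 0, "manifest has no completed stages")
  for (nm in names(stages)) {
    stop_if_not(!is.null(stages[[nm]]$summary),
                "stage '", nm, "' has no summary (incomplete run?)")
  }
  summaries <- lapply(stages, `[[`, "summary")
  .write_json(summaries, file.path(out_dir, "report.json"))
  rows <- do.call(rbind, unlist(lapply(names(summaries), function(s) {
    lapply(names(summaries[[s]]), function(key) {
      val <- summaries[[s]][[key]]
      data.frame(stage = s, statistic = key,
                 value = paste(fmt_num(as.numeric(val)), collapse = ","),
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  utils::write.table(rows, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(out_dir, "report.json"))
}
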