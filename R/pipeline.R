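#' Shared downstream chain: embed, model normatively, associate
#'
#' The stage sequence applied identically to autoencoder latents and to
#' every baseline representation: (i) fit UMAP on the training scans'
#' latent vectors and transform all scans; (ii) per embedding component,
#' fit the hierarchical Bayesian normative model on the training scans
#' (age as regressor, sex as batch) and score every scan's deviation
#' ("latent index"); (iii) screen the per-subject indices against the
#' nIDP table with Spearman correlation under Bonferroni control.
#'
#' Test-scan ages are clamped to the fitted spline support before scoring
#' (deviations at the support edge are evaluated at the boundary rather
#' than extrapolated).
#'
#' @param latents Latent-record tibble (`subject_id`, `contrast_label`,
#'   `z_latent`).
#' @param demographics,nidps,nidp_meta Cohort tables ([read_demographics()]
#'   and friends).
#' @param train_subjects Subject IDs used for fitting (embedder and
#'   normative models); all scans are transformed and scored.
#' @param n_neighbors,min_dist,umap_seed UMAP settings ([fit_umap()]).
#' @param norm_cfg A [normative_config()].
#' @param alpha Bonferroni family-wise error level.
#' @return List with `embedder`, `embeddings`, `normative_fits` (one per
#'   component), `latent_index` tibble and `associations`.
#' @export
downstream_chain <- function(latents, demographics, nidps,
                             nidp_meta = NULL, train_subjects,
                             n_neighbors = 15, min_dist = 0.1,
                             umap_seed = 42L,
                             norm_cfg = normative_config(),
                             alpha = 0.05) {
  demo <- match_demographics(latents, demographics)
  is_train <- latents$subject_id %in% train_subjects
  if (!any(is_train)) abort("no training subjects among the latents")

  embedder <- fit_umap(latents[is_train, ], n_neighbors = n_neighbors,
                       min_dist = min_dist, seed = umap_seed)
  embeddings <- transform_latents(embedder, latents)

  comp_cols <- grep("^umap", names(embeddings), value = TRUE)
  fits <- list()
  idx_rows <- list()
  for (ci in seq_along(comp_cols)) {
    y_all <- embeddings[[comp_cols[ci]]]
    fit <- fit_hbr(y_all[is_train], demo$age[is_train],
                   demo$sex[is_train], cfg = norm_cfg)
    ages <- pmin(pmax(demo$age, fit$basis$bounds[1]),
                 fit$basis$bounds[2])
    z <- latent_index(fit, y_all, ages, demo$sex)
    fits[[ci]] <- fit
    idx_rows[[ci]] <- tibble(subject_id = latents$subject_id,
                             contrast_label = latents$contrast_label,
                             component = ci, z = z,
                             train = is_train)
  }
  latent_idx <- bind_rows(idx_rows)
  assoc <- associate(latent_idx, nidps, alpha = alpha,
                     nidp_meta = nidp_meta)
  list(embedder = embedder, embeddings = embeddings,
       normative_fits = fits, latent_index = latent_idx,
       associations = assoc)
}

#' End-to-end pipeline configuration
#'
#' Nested settings for a full run: cohort simulation (or paths to an
#' exported cohort), preprocessing, autoencoder training, embedding,
#' normative modelling and association screening. Every random operation
#' draws its seed from `seed` plus a fixed stage offset, so a config fully
#' determines the run.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()] (its seed is overridden by `seed`), or
#'   `NULL` together with `cohort_dir` to load an exported cohort.
#' @param cohort_dir Directory of an exported cohort (used when `sim` is
#'   `NULL`).
#' @param k_folds Subject-level folds; fold 0 is the held-out test fold.
#' @param epochs,lambda,batch_size Autoencoder training settings (the
#'   remaining architecture settings are [ae_config()] defaults).
#' @param n_neighbors,min_dist UMAP settings.
#' @param norm_cfg A [normative_config()] (its seed is overridden).
#' @param alpha Bonferroni level.
#' @param out_dir Output directory for stage artifacts (`NULL` = no
#'   files written).
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, cohort_dir = NULL,
                            k_folds = 5, epochs = 30, lambda = 0.05,
                            batch_size = 10, n_neighbors = 15,
                            min_dist = 0.1,
                            norm_cfg = normative_config(),
                            alpha = 0.05, out_dir = NULL) {
  if (is.null(sim) && is.null(cohort_dir))
    sim <- sim_config(seed = seed)
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  norm_cfg$seed <- as.integer(seed + 300L)
  structure(list(seed = as.integer(seed), sim = sim,
                 cohort_dir = cohort_dir, k_folds = as.integer(k_folds),
                 epochs = as.integer(epochs), lambda = lambda,
                 batch_size = as.integer(batch_size),
                 n_neighbors = n_neighbors, min_dist = min_dist,
                 norm_cfg = norm_cfg, alpha = alpha, out_dir = out_dir,
                 schema_version = 1L),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with fields matching the constructor arguments.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "cohort_dir", "k_folds", "epochs", "lambda",
             "batch_size", "n_neighbors", "min_dist", "alpha", "out_dir")
  bad <- setdiff(names(y), c(known, "sim", "normative"))
  if (length(bad) > 0)
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$normative))
    args$norm_cfg <- do.call(normative_config, y$normative)
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Executes simulate/load, preprocess (subject-level split and per-voxel
#' normalization fitted on the training fold only), autoencoder training,
#' encoding, and the downstream chain (UMAP, normative modelling,
#' association screening). Artifacts are returned in memory; when
#' `cfg$out_dir` is set, stage outputs (embedding coordinates, percentile
#' curves, association table, training history) and a run manifest with
#' file hashes are also written.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List with `cohort`, `split`, `normalizer`, `model`, `latents`,
#'   the [downstream_chain()] outputs, and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  stages <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    if (verbose) inform(paste0("[latentmap] stage: ", stage))
    out <- force(expr)
    stages[[stage]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  cohort <- tick("simulate", {
    if (!is.null(cfg$sim)) simulate_cohort(cfg$sim)
    else import_cohort(cfg$cohort_dir)
  })

  pre <- tick("preprocess", {
    split <- subject_level_split(cohort$demographics$subject_id,
                                 k = cfg$k_folds, seed = cfg$seed + 100L)
    test_subjects <- split$subject_id[split$fold == 0L]
    train_subjects <- setdiff(split$subject_id, test_subjects)
    train_scans <- cohort$scans[cohort$scans$subject_id %in%
                                  train_subjects, ]
    normalizer <- fit_normalizer(train_scans)
    list(split = split, train_subjects = train_subjects,
         test_subjects = test_subjects,
         scans_norm = apply_normalizer(normalizer, cohort$scans),
         normalizer = normalizer)
  })

  model <- tick("train", {
    shape <- dim(cohort$scans$volume[[1]]$voxels)
    acfg <- ae_config(input_shape = shape, lambda = cfg$lambda,
                      epochs = cfg$epochs, batch_size = cfg$batch_size,
                      seed = cfg$seed + 200L)
    m <- build_model(acfg)
    train_scans <- pre$scans_norm[pre$scans_norm$subject_id %in%
                                    pre$train_subjects, ]
    train_ae(m, train_scans, cohort$demographics,
             verbose = if (verbose) max(cfg$epochs %/% 5, 1) else 0)
  })

  latents <- tick("encode", encode_scans(model, pre$scans_norm))

  chain <- tick("downstream", downstream_chain(
    latents, cohort$demographics, cohort$nidps,
    nidp_meta = cohort$nidp_meta,
    train_subjects = pre$train_subjects,
    n_neighbors = cfg$n_neighbors, min_dist = cfg$min_dist,
    umap_seed = cfg$seed + 400L, norm_cfg = cfg$norm_cfg,
    alpha = cfg$alpha))

  manifest <- list(
    schema_version = cfg$schema_version,
    started = format(t0), finished = format(Sys.time()),
    seed = cfg$seed,
    stage_seconds = stages,
    n_scans = nrow(cohort$scans),
    n_train_subjects = length(pre$train_subjects),
    n_test_subjects = length(pre$test_subjects),
    package_version = as.character(utils::packageVersion("latentmap")))

  result <- c(list(cohort = cohort, split = pre$split,
                   normalizer = pre$normalizer, model = model,
                   latents = latents),
              chain, list(manifest = manifest))
  if (!is.null(cfg$out_dir)) write_run(result, cfg$out_dir)
  result
}

## Persist the tabular stage outputs plus a hashed manifest.
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    embeddings = file.path(out_dir, "embeddings.tsv"),
    latent_index = file.path(out_dir, "latent_index.tsv"),
    associations = file.path(out_dir, "associations.tsv"),
    history = file.path(out_dir, "training_history.csv"))
  readr::write_tsv(result$embeddings, paths["embeddings"])
  readr::write_tsv(result$latent_index, paths["latent_index"])
  readr::write_tsv(as_tibble(result$associations), paths["associations"])
  readr::write_csv(result$model$history, paths["history"])
  grid <- seq(result$normative_fits[[1]]$basis$bounds[1],
              result$normative_fits[[1]]$basis$bounds[2],
              length.out = 50)
  pc <- bind_rows(lapply(seq_along(result$normative_fits), function(i)
    mutate(percentile_curves(result$normative_fits[[i]], grid),
           component = i)))
  pc_path <- file.path(out_dir, "percentile_curves.csv")
  readr::write_csv(pc, pc_path)
  paths <- c(paths, percentile_curves = pc_path)
  result$manifest$files <- lapply(paths, function(p)
    list(path = unname(p), md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summary report of a completed run
#'
#' Collects the quantities a reader needs to judge a run: loss history
#' endpoints and the lambda setting, embedding silhouette by class,
#' normative convergence (max split-R-hat per component), calibration of
#' the deviation scores on held-out scans, and the top associations with
#' the Bonferroni threshold.
#'
#' @param result A [run_pipeline()] result.
#' @param top_n Number of top associations to list.
#' @return List (JSON-serialisable) with a `text` element for printing.
#' @export
report_run <- function(result, top_n = 10) {
  gl <- glance(result$model)
  labels <- result$embeddings$contrast_label
  sil <- tryCatch(embedding_silhouette(result$embeddings, labels),
                  error = function(e) NA_real_)
  rhats <- vapply(result$normative_fits, function(f)
    max(f$rhat$rhat, na.rm = TRUE), numeric(1))
  z_test <- result$latent_index$z[!result$latent_index$train]
  assoc <- as_tibble(result$associations)
  top <- utils::head(arrange(assoc, .data$p), top_n)
  rep <- list(
    lambda = result$model$config$lambda,
    epochs = result$model$epochs_trained,
    final_losses = as.list(gl[c("final_recon", "final_age_mae",
                                "final_sex_bce", "final_total")]),
    silhouette_by_class = sil,
    normative_max_rhat = as.list(setNames(rhats,
                                          paste0("component_",
                                                 seq_along(rhats)))),
    rhat_warning = any(rhats > 1.05),
    z_calibration = list(mean = mean(z_test), sd = sd(z_test),
                         n = length(z_test)),
    bonferroni = list(alpha = attr(result$associations, "alpha"),
                      n_tests = attr(result$associations, "n_tests"),
                      threshold = attr(result$associations, "threshold")),
    n_significant = sum(assoc$significant, na.rm = TRUE),
    top_associations = top,
    stage_seconds = result$manifest$stage_seconds)
  rep$text <- paste0(
    sprintf("latentmap run (lambda = %.3g, %d epochs)\n", rep$lambda,
            rep$epochs),
    sprintf("  final total loss %.4f (recon %.4f, age MAE %.2f)\n",
            gl$final_total, gl$final_recon, gl$final_age_mae),
    sprintf("  embedding silhouette by class: %.3f\n", sil),
    sprintf("  normative max R-hat: %s%s\n",
            paste(sprintf("%.3f", rhats), collapse = ", "),
            if (rep$rhat_warning) "  [WARNING > 1.05]" else ""),
    sprintf("  held-out z: mean %.3f, sd %.3f (n = %d)\n",
            rep$z_calibration$mean, rep$z_calibration$sd,
            rep$z_calibration$n),
    sprintf("  %d significant associations at Bonferroni %.2g\n",
            rep$n_significant, rep$bonferroni$threshold))
  rep
}

#' Reconstruction / supervision trade-off across lambda values
#'
#' Trains a short model per lambda on the same data and seed and reports
#' the final loss components, mirroring the calibration grid
#' `1, 0.995, 0.95, 0.5, 0.05, 0.005` used to pick the default.
#'
#' @param scans Normalized scan tibble.
#' @param demographics Demographics tibble.
#' @param input_shape Volume shape.
#' @param lambdas Lambda grid.
#' @param epochs Epochs per lambda (kept short; this is a comparison, not
#'   a final fit).
#' @param seed Seed shared by all runs.
#' @return Tibble with one row per lambda: final `recon`, `age`, `sex`,
#'   `total`.
#' @export
lambda_sweep <- function(scans, demographics, input_shape,
                         lambdas = c(1, 0.995, 0.95, 0.5, 0.05, 0.005),
                         epochs = 5, seed = 1L) {
  bind_rows(lapply(lambdas, function(lam) {
    cfg <- ae_config(input_shape = input_shape, lambda = lam,
                     epochs = epochs, seed = seed)
    m <- train_ae(build_model(cfg), scans, demographics)
    h <- m$history[nrow(m$history), ]
    tibble(lambda = lam, recon = h$recon, age = h$age, sex = h$sex,
           total = h$total)
  }))
}
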