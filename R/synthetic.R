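#' Configuration for a synthetic multi-contrast cohort
#'
#' The generator emulates the structure of a multi-contrast task-fMRI
#' cohort at desk scale: each contrast class has a smooth spatial template,
#' age and sex modulate dedicated spatial patterns, every subject carries a
#' scalar deviation score that scales their class templates, and non-imaging
#' phenotypes (nIDPs) are rank-coupled to that deviation score with a known
#' target Spearman correlation. All ground truth is retained so fitted
#' quantities can be compared against it.
#'
#' The per-scan generative model is
#' `voxels = template_c * (1 + subject_sd * d_s) +
#'  beta_age * (age - midpoint(age_range)) * age_map +
#'  delta_sex * sex * sex_map + noise`,
#' with `d_s ~ N(0, 1)` the subject deviation score and i.i.d. Gaussian
#' voxel noise. Planted nIDPs use a Gaussian copula on `d_s`: a bivariate
#' normal with Pearson correlation `2 sin(pi * rho / 6)` has Spearman
#' correlation `rho`, so the target is planted exactly in population.
#'
#' @param n_subjects Number of subjects (>= 2; default 300).
#' @param contrast_classes Character vector of contrast labels.
#' @param shape Integer triple; every axis must be >= 8 so distinct blobs
#'   fit (default `c(16, 16, 16)`).
#' @param age_range Numeric `(min, max)` in years; ages are uniform.
#' @param beta_age Amplitude of the age-modulated pattern per year.
#' @param delta_sex Additive amplitude of the sex pattern.
#' @param subject_sd Scale of the subject deviation term.
#' @param noise_sd I.i.d. voxel noise standard deviation (> 0).
#' @param nidp_specs Tibble with columns `name`, `rho` (target Spearman
#'   correlation with the deviation score), `missing_rate` in `[0, 1)` and
#'   `null` (logical; null measures are independent of everything).
#'   Defaults to 5 planted measures at `rho = 0.3` and 45 null measures, so
#'   that screening both embedding components performs 100 tests.
#' @param seed Integer seed; identical configs generate bitwise-identical
#'   cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 300,
                       contrast_classes = c("task_a", "task_b", "task_c"),
                       shape = c(16, 16, 16),
                       age_range = c(22, 36),
                       beta_age = 0.03,
                       delta_sex = 0.3,
                       subject_sd = 0.25,
                       noise_sd = 0.5,
                       nidp_specs = default_nidp_specs(),
                       seed = 1L) {
  stopifnot(n_subjects >= 2, length(contrast_classes) >= 1,
            length(shape) == 3, diff(age_range) > 0, noise_sd > 0,
            subject_sd >= 0)
  if (!all(c("name", "rho", "missing_rate", "null") %in% names(nidp_specs)))
    abort("nidp_specs needs columns name, rho, missing_rate, null")
  stopifnot(all(abs(nidp_specs$rho) <= 1),
            all(nidp_specs$missing_rate >= 0 & nidp_specs$missing_rate < 1))
  structure(list(n_subjects = as.integer(n_subjects),
                 contrast_classes = contrast_classes,
                 shape = as.integer(shape), age_range = age_range,
                 beta_age = beta_age, delta_sex = delta_sex,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 nidp_specs = as_tibble(nidp_specs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n_planted,n_null Counts of planted and null measures.
#' @param rho Target Spearman correlation of the planted measures.
#' @param missing_rate Fraction of values masked missing per measure.
#' @export
default_nidp_specs <- function(n_planted = 5, n_null = 45, rho = 0.3,
                               missing_rate = 0.05) {
  tibble(
    name = c(sprintf("planted_%02d", seq_len(n_planted)),
             sprintf("null_%02d", seq_len(n_null))),
    rho = c(rep(rho, n_planted), rep(0, n_null)),
    missing_rate = missing_rate,
    null = c(rep(FALSE, n_planted), rep(TRUE, n_null)))
}

## One smooth positive blob pattern: a sum of isotropic 3-D Gaussians.
gaussian_blob <- function(shape, centres, sigma, amplitude = 3) {
  ax <- lapply(shape, function(n) seq_len(n) - 1)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  val <- numeric(nrow(g))
  for (i in seq_len(nrow(centres))) {
    d2 <- (g$x - centres[i, 1])^2 + (g$y - centres[i, 2])^2 +
      (g$z - centres[i, 3])^2
    val <- val + amplitude * exp(-d2 / (2 * sigma^2))
  }
  array(val, shape)
}

#' Class-specific spatial templates
#'
#' Generates one smooth positive blob pattern (sum of 3-D Gaussians) per
#' contrast class, with centres redrawn until all pairwise Pearson
#' correlations are below 0.5 so the classes are spatially distinct.
#'
#' @param classes Character vector of class labels (>= 1).
#' @param shape Integer triple; every axis >= 8.
#' @param seed Integer seed.
#' @param max_tries Redraw attempts before giving up.
#' @return Named list of 3-D arrays, one per class.
#' @export
make_templates <- function(classes, shape, seed = 1L, max_tries = 200L) {
  stopifnot(length(classes) >= 1)
  shape <- as.integer(shape)
  if (any(shape < 8L))
    abort("shape too small to place distinct blobs (need >= 8 per axis)")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sigma <- min(shape) / 8
  draw <- function() {
    lapply(seq_along(classes), function(i) {
      centres <- cbind(runif(2, 0.15, 0.85) * (shape[1] - 1),
                       runif(2, 0.15, 0.85) * (shape[2] - 1),
                       runif(2, 0.15, 0.85) * (shape[3] - 1))
      gaussian_blob(shape, centres, sigma)
    })
  }
  for (try in seq_len(max_tries)) {
    tpl <- draw()
    if (length(tpl) == 1L) break
    cc <- cor(vapply(tpl, as.numeric, numeric(prod(shape))))
    if (max(abs(cc[upper.tri(cc)])) < 0.5) break
    if (try == max_tries)
      abort("could not place sufficiently distinct templates")
  }
  names(tpl) <- classes
  tpl
}

#' Simulate a synthetic cohort with known ground truth
#'
#' @param cfg A [sim_config()].
#' @param with_volumes Set `FALSE` to skip volume generation when only the
#'   tabular parts (demographics, deviation scores, nIDPs) are needed.
#' @return A `sim_cohort` list with elements `scans` (tibble with a
#'   `volume` list-column), `demographics`, `nidps`, `nidp_meta`,
#'   `templates`, `age_map`, `sex_map`, `deviation_scores` (named numeric)
#'   and `config`.
#' @export
simulate_cohort <- function(cfg, with_volumes = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  n <- cfg$n_subjects
  ids <- sprintf("sub-%04d", seq_len(n))
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- as.integer(runif(n) < 0.5)
  d_s <- rnorm(n)

  demographics <- tibble(subject_id = ids, age = age, sex = sex)

  ## nIDPs: Gaussian copula on the deviation score, then masking.
  specs <- cfg$nidp_specs
  nidps <- tibble(subject_id = ids)
  for (i in seq_len(nrow(specs))) {
    if (specs$null[i]) {
      v <- rnorm(n)
    } else {
      rho_g <- 2 * sin(pi * specs$rho[i] / 6)
      v <- rho_g * d_s + sqrt(1 - rho_g^2) * rnorm(n)
    }
    if (specs$missing_rate[i] > 0)
      v[runif(n) < specs$missing_rate[i]] <- NA_real_
    nidps[[specs$name[i]]] <- v
  }
  categories <- c("cognitive", "lifestyle", "mental_health", "physical",
                  "clinical", "sociodemographic", "early_life")
  nidp_meta <- mutate(specs,
                      category = categories[(seq_len(nrow(specs)) - 1) %%
                                              length(categories) + 1])

  templates <- make_templates(cfg$contrast_classes, cfg$shape,
                              seed = cfg$seed + 1L)
  age_map <- make_templates("age", cfg$shape, seed = cfg$seed + 2L)[[1]]
  sex_map <- make_templates("sex", cfg$shape, seed = cfg$seed + 3L)[[1]]
  age_mid <- mean(cfg$age_range)

  scans <- NULL
  if (with_volumes) {
    rows <- expand.grid(class = cfg$contrast_classes, subj = seq_len(n),
                        stringsAsFactors = FALSE)
    vols <- vector("list", nrow(rows))
    for (r in seq_len(nrow(rows))) {
      s <- rows$subj[r]; cl <- rows$class[r]
      arr <- templates[[cl]] * (1 + cfg$subject_sd * d_s[s]) +
        cfg$beta_age * (age[s] - age_mid) * age_map +
        cfg$delta_sex * sex[s] * sex_map +
        array(rnorm(prod(cfg$shape), sd = cfg$noise_sd), cfg$shape)
      vols[[r]] <- contrast_volume(arr, voxel_size_mm = 3,
                                   subject_id = ids[s],
                                   contrast_label = cl,
                                   cohort = "synthetic")
    }
    scans <- tibble(subject_id = ids[rows$subj],
                    contrast_label = rows$class,
                    cohort = "synthetic", volume = vols)
  }

  structure(list(scans = scans, demographics = demographics,
                 nidps = nidps, nidp_meta = nidp_meta,
                 templates = templates, age_map = age_map,
                 sex_map = sex_map,
                 deviation_scores = setNames(d_s, ids),
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d subjects x %d classes (%s), %d nIDP measures\n",
    x$config$n_subjects, length(x$config$contrast_classes),
    paste(x$config$shape, collapse = "x"), nrow(x$nidp_meta)))
  invisible(x)
}

#' Export / import a synthetic cohort on disk
#'
#' Writes one NIfTI per scan plus TSV demographics, TSV nIDP table, a TSV
#' scan manifest and a JSON ground-truth sidecar (templates, modulation
#' maps, deviation scores, config). [import_cohort()] reads the same layout
#' back losslessly.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(cohort$scans) || nrow(cohort$scans) == 0)
    abort("nothing to export: cohort has no volumes")
  dir.create(file.path(dir, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  rel <- sprintf("volumes/%s_%s.nii.gz", cohort$scans$subject_id,
                 cohort$scans$contrast_label)
  for (i in seq_len(nrow(cohort$scans)))
    write_volume(cohort$scans$volume[[i]], file.path(dir, rel[i]))
  readr::write_tsv(tibble(subject_id = cohort$scans$subject_id,
                          contrast_label = cohort$scans$contrast_label,
                          path = rel),
                   file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort$demographics, file.path(dir, "demographics.tsv"))
  readr::write_tsv(cohort$nidps, file.path(dir, "nidps.tsv"))
  readr::write_tsv(cohort$nidp_meta, file.path(dir, "nidp_meta.tsv"))
  gt <- list(
    shape = cohort$config$shape,
    templates = lapply(cohort$templates, as.numeric),
    age_map = as.numeric(cohort$age_map),
    sex_map = as.numeric(cohort$sex_map),
    deviation_scores = as.list(cohort$deviation_scores),
    config = unclass(cohort$config)[setdiff(names(cohort$config),
                                            "nidp_specs")])
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.tsv"))
}

#' @rdname export_cohort
#' @export
import_cohort <- function(dir) {
  scans <- read_scan_table(file.path(dir, "manifest.tsv"),
                           cohort = "synthetic")
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  shp <- as.integer(gt$shape)
  structure(list(
    scans = scans,
    demographics = read_demographics(file.path(dir, "demographics.tsv")),
    nidps = readr::read_tsv(file.path(dir, "nidps.tsv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(subject_id = "c")),
    nidp_meta = readr::read_tsv(file.path(dir, "nidp_meta.tsv"),
                                show_col_types = FALSE),
    templates = lapply(gt$templates, array, dim = shp),
    age_map = array(gt$age_map, shp),
    sex_map = array(gt$sex_map, shp),
    deviation_scores = unlist(gt$deviation_scores),
    config = gt$config), class = "sim_cohort")
}

#' Synthetic integer-label ROI atlas aligned to cohort templates
#'
#' Builds a toy atlas whose labels 1..n mark the strongest blob of each
#' class template (and the age map), with 0 as background -- enough to
#' exercise the region-of-interest baseline without any external atlas.
#'
#' @param cohort A `sim_cohort`.
#' @param threshold Fraction of each map's maximum defining its region.
#' @return A 3-D integer array (class labels in template order, then the
#'   age map), with attribute `labels`.
#' @export
synthetic_atlas <- function(cohort, threshold = 0.4) {
  maps <- c(cohort$templates, list(age_region = cohort$age_map))
  atlas <- array(0L, dim(maps[[1]]))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    atlas[m >= threshold * max(m) & atlas == 0L] <- i
  }
  attr(atlas, "labels") <- names(maps)
  atlas
}
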