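#' Filter non-imaging phenotype measures by availability and degeneracy
#'
#' Applies the standard phenome-screening inclusion rules: a measure is
#' kept only if it is available for *more than* `availability_min` of the
#' subjects (strict inequality, so exactly half is excluded) and its most
#' frequent non-missing value accounts for at most `mode_max` of the
#' non-missing entries (near-constant measures carry no rank information).
#'
#' @param nidps Tibble with a `subject_id` column and one column per
#'   measure (missing values allowed).
#' @param availability_min Availability threshold (default 0.5).
#' @param mode_max Maximum modal-value frequency among non-missing values
#'   (default 0.8; a measure constant in more than 80% of entries is
#'   dropped).
#' @return The filtered tibble; attribute `"dropped"` records each removed
#'   measure and the rule that removed it.
#' @export
filter_nidps <- function(nidps, availability_min = 0.5, mode_max = 0.8) {
  stopifnot(is.data.frame(nidps), "subject_id" %in% names(nidps))
  if (nrow(nidps) == 0) abort("empty nIDP table")
  measures <- setdiff(names(nidps), "subject_id")
  n <- nrow(nidps)
  dropped <- list()
  keep <- character(0)
  for (m in measures) {
    v <- nidps[[m]]
    avail <- mean(!is.na(v))
    if (!(avail > availability_min)) {
      dropped[[m]] <- sprintf("availability %.2f <= %.2f", avail,
                              availability_min)
      next
    }
    vv <- v[!is.na(v)]
    mode_frac <- max(table(vv)) / length(vv)
    if (mode_frac > mode_max) {
      dropped[[m]] <- sprintf("modal value frequency %.2f > %.2f",
                              mode_frac, mode_max)
      next
    }
    keep <- c(keep, m)
  }
  if (length(keep) == 0)
    warn("no measures survive the inclusion filters")
  out <- nidps[, c("subject_id", keep)]
  attr(out, "dropped") <- tibble(measure = names(dropped),
                                 reason = unlist(dropped, use.names = FALSE))
  out
}

#' Spearman rank correlation with pairwise deletion
#'
#' Computes Spearman's rho with average (mid-) ranks for ties on the
#' complete pairs, with the two-sided p-value from the t-approximation
#' (via [stats::cor.test()] with `exact = FALSE`).
#'
#' @param x,y Numeric vectors of equal length; missing values are removed
#'   pairwise.
#' @return Tibble with `rho`, `p`, `n_pairs`. If fewer than 3 complete
#'   pairs remain, or either vector is constant after deletion, the result
#'   is undefined and returned as `NA` with the pair count.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) < 1e-15 || sd(y[ok]) < 1e-15)
    return(tibble(rho = NA_real_, p = NA_real_, n_pairs = n))
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                  exact = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n_pairs = n)
}

#' Phenome-wide association of latent indices with nIDPs
#'
#' Correlates every (measure, component) pair by Spearman rank correlation
#' on pairwise-complete subject data and flags significance under the
#' Bonferroni threshold `alpha / M`, where `M` counts every executed test.
#' Scans are aggregated to one index per subject and component (mean over
#' contrasts) before matching against the subject-level nIDP table.
#'
#' @param latent_idx Tibble with `subject_id`, `component`, `z` (e.g. one
#'   row per scan and embedding component).
#' @param nidps Filtered nIDP tibble ([filter_nidps()]).
#' @param alpha Family-wise error level (default 0.05).
#' @param nidp_meta Optional tibble with `name` and `category` columns,
#'   carried through for Manhattan-style plotting.
#' @return Tibble of class `association_result` with one row per
#'   (measure, component): `measure`, `category`, `component`, `rho`, `p`,
#'   `n_pairs`, `neg_log10_p`, `significant`; attributes `alpha`,
#'   `n_tests` and `threshold`.
#' @export
associate <- function(latent_idx, nidps, alpha = 0.05, nidp_meta = NULL) {
  stopifnot(all(c("subject_id", "component", "z") %in% names(latent_idx)))
  measures <- setdiff(names(nidps), "subject_id")
  if (length(measures) == 0) abort("no nIDP measures to test")

  per_subj <- latent_idx |>
    group_by(.data$subject_id, .data$component) |>
    summarise(z = mean(.data$z), .groups = "drop")
  unmatched <- setdiff(per_subj$subject_id, nidps$subject_id)
  if (length(unmatched) > 0)
    abort(paste0("subjects missing from the nIDP table: ",
                 paste(utils::head(unmatched, 10), collapse = ", ")))

  rows <- list()
  for (comp in sort(unique(per_subj$component))) {
    zc <- filter(per_subj, .data$component == comp)
    idx <- match(zc$subject_id, nidps$subject_id)
    for (m in measures) {
      sc <- spearman_cor(zc$z, nidps[[m]][idx])
      rows[[length(rows) + 1]] <- mutate(sc, measure = m,
                                         component = comp)
    }
  }
  out <- bind_rows(rows)
  M <- sum(!is.na(out$p))
  thr <- alpha / max(M, 1)
  out <- mutate(out,
                neg_log10_p = -log10(.data$p),
                significant = !is.na(.data$p) & .data$p < thr)
  cat_tb <- if (!is.null(nidp_meta) &&
                all(c("name", "category") %in% names(nidp_meta))) {
    tibble(measure = nidp_meta$name, category = nidp_meta$category)
  } else {
    tibble(measure = measures, category = "uncategorised")
  }
  out <- left_join(out, cat_tb, by = "measure")
  out <- select(out, "measure", "category", "component", "rho", "p",
                "n_pairs", "neg_log10_p", "significant")
  structure(out, alpha = alpha, n_tests = M, threshold = thr,
            class = c("association_result", class(out)))
}

#' @method autoplot association_result
#' @export
autoplot.association_result <- function(object, ...) {
  thr <- attr(object, "threshold")
  d <- arrange(object, .data$category, .data$measure)
  d$pos <- seq_len(nrow(d))
  ggplot(d, aes(x = .data$pos, y = .data$neg_log10_p,
                colour = .data$category,
                shape = factor(.data$component))) +
    geom_point() +
    geom_hline(yintercept = -log10(thr), linetype = 2) +
    labs(x = "measure", y = expression(-log[10](p)),
         shape = "component", colour = NULL,
         title = "Latent index / nIDP associations") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
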