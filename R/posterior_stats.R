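#' Compare the marginals of two posteriors parameter by parameter
#'
#' Draws `n` samples per parameter from each posterior and applies a
#' two-sample Kolmogorov-Smirnov test; the direction of shift is the
#' sign of the difference of sample medians (B relative to A). p-values
#' are reported raw (an optional Holm correction can be switched on).
#' Posteriors carrying different MEA-batch labels are refused unless
#' `allow_cross_batch = TRUE`: posteriors should only be compared when
#' the measurements originate from the same MEA experiment.
#'
#' @param post_a,post_b `mea_posterior` handles over the same parameter
#'   set.
#' @param n Samples per side (default 50).
#' @param seed Integer seed (one seeded draw per comparison).
#' @param holm Apply a Holm multiple-testing correction.
#' @param allow_cross_batch Override the same-batch guard.
#' @return Tibble: `parameter`, `p_value`, `direction` (-1/0/1),
#'   `statistic`, and the handles' `id`/`batch` metadata.
#' @export
compare_marginals <- function(post_a, post_b, n = 50, seed = 1,
                              holm = FALSE, allow_cross_batch = FALSE) {
  stopifnot(inherits(post_a, "mea_posterior"),
            inherits(post_b, "mea_posterior"))
  pa <- post_a$model$ranges$parameter
  pb <- post_b$model$ranges$parameter
  if (!identical(pa, pb)) {
    stop("posteriors are over different parameter sets")
  }
  if (!allow_cross_batch &&
      !is.null(post_a$batch) && !is.null(post_b$batch) &&
      !identical(post_a$batch, post_b$batch)) {
    stop("posteriors come from different MEA batches (",
         post_a$batch, " vs ", post_b$batch,
         "); compare only within a batch, or set ",
         "`allow_cross_batch = TRUE` to override")
  }
  sa <- posterior_sample(post_a, n, seed = seed)
  sb <- posterior_sample(post_b, n, seed = seed + 1L)
  out <- purrr::map_dfr(pa, function(nm) {
    ks <- suppressWarnings(stats::ks.test(sa[[nm]], sb[[nm]]))
    tibble::tibble(parameter = nm,
                   p_value = ks$p.value,
                   statistic = unname(ks$statistic),
                   direction = sign(stats::median(sb[[nm]]) -
                                      stats::median(sa[[nm]])))
  })
  if (holm) out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$id_a <- if (is.null(post_a$id)) NA_character_ else post_a$id
  out$id_b <- if (is.null(post_b$id)) NA_character_ else post_b$id
  out$batch <- if (is.null(post_a$batch)) NA_character_ else post_a$batch
  out
}

#' Compare MEA features of two groups of recordings
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature.
#' Features are often non-normal across recordings, hence the
#' non-parametric default. A feature with all values tied across both
#' groups yields p = 1 with a warning.
#'
#' @param group_a,group_b Feature tibbles (one row per recording,
#'   matching columns), each with at least 3 rows.
#' @param features Feature columns to test (default: shared numeric
#'   columns).
#' @return Tibble: `feature`, `p_value`, `statistic`, `median_a`,
#'   `median_b`.
#' @export
compare_features <- function(group_a, group_b, features = NULL) {
  if (nrow(group_a) < 3 || nrow(group_b) < 3) {
    stop("each group needs at least 3 recordings")
  }
  if (is.null(features)) {
    features <- intersect(names(group_a), names(group_b))
    features <- features[vapply(group_a[features], is.numeric, logical(1))]
  }
  purrr::map_dfr(features, function(nm) {
    a <- group_a[[nm]]; b <- group_b[[nm]]
    if (length(unique(c(a, b))) == 1) {
      warning("feature ", nm, " is identical in both groups; p = 1")
      return(tibble::tibble(feature = nm, p_value = 1,
                            statistic = NA_real_,
                            median_a = stats::median(a),
                            median_b = stats::median(b)))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    tibble::tibble(feature = nm, p_value = wt$p.value,
                   statistic = unname(wt$statistic),
                   median_a = stats::median(a),
                   median_b = stats::median(b))
  })
}

#' One-sample t-test of correlation coefficients against zero
#'
#' Used on the per-pair conditional correlation coefficients; normality
#' is screened with a Shapiro-Wilk test whose p-value is reported
#' alongside.
#'
#' @param r_values Numeric vector of correlation coefficients (>= 3).
#' @return List with `p_value`, `t`, `mean_r`, `shapiro_p`.
#' @export
corr_vs_zero <- function(r_values) {
  r_values <- r_values[is.finite(r_values)]
  if (length(r_values) < 3) stop("need at least 3 correlation values")
  if (stats::sd(r_values) == 0) {
    # degenerate: all equal; decide from the sign
    return(list(p_value = if (r_values[1] == 0) 1 else 0,
                t = if (r_values[1] == 0) 0 else Inf * sign(r_values[1]),
                mean_r = r_values[1], shapiro_p = NA_real_))
  }
  sw <- tryCatch(stats::shapiro.test(r_values)$p.value,
                 error = function(e) NA_real_)
  tt <- stats::t.test(r_values, mu = 0)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       mean_r = mean(r_values), shapiro_p = sw)
}

#' Normalize features by their prior standard deviation
#'
#' Element-wise division of feature values by the standard deviation of
#' that feature over prior-sampled simulations, putting all features on
#' a common display scale.
#'
#' @param fv Feature tibble (rows = recordings).
#' @param prior_sd Named numeric vector of per-feature standard
#'   deviations (all positive).
#' @return Tibble of the same shape, in units of prior sd.
#' @export
normalize_features <- function(fv, prior_sd) {
  nm <- intersect(names(fv), names(prior_sd))
  bad <- nm[prior_sd[nm] <= 0 | !is.finite(prior_sd[nm])]
  if (length(bad)) {
    stop("non-positive prior sd for feature(s): ",
         paste(bad, collapse = ", "))
  }
  out <- fv
  for (f in nm) out[[f]] <- fv[[f]] / prior_sd[[f]]
  out
}

#' Average MEA features per cell line per MEA batch
#'
#' Wells from the same cell line measured on the same MEA (one
#' independent neuronal/astrocytic batch) are averaged into one row.
#'
#' @param features Feature tibble with label columns `line` and `mea`
#'   (plus any feature columns).
#' @param line,mea Names of the grouping columns.
#' @return Tibble: one row per (line, MEA) with averaged features and a
#'   `n_wells` count.
#' @export
aggregate_by_line <- function(features, line = "line", mea = "mea") {
  if (!all(c(line, mea) %in% names(features))) {
    stop("`features` must carry '", line, "' and '", mea, "' columns")
  }
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(line, mea)))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num), mean),
                     n_wells = dplyr::n(), .groups = "drop")
}
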