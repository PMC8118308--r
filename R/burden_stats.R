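# Reflectance crystal-burden quantification (crystal area as a percent of
# plaque area) and the two-group statistics used to compare plaque metrics:
# Mann-Whitney U and unpaired/paired t tests.

#' Crystal burden from a reflectance image
#'
#' Crystal pixels are those above threshold inside the plaque mask; the
#' burden is the crystal area as a percent of the plaque area. The default
#' threshold is Otsu's method restricted to plaque pixels, which makes the
#' burden invariant to uniform intensity scaling and keeps the dark exterior
#' out of the histogram.
#'
#' @param reflectance an [intensity_image] (channel REFLECTANCE).
#' @param plaque_mask logical matrix of the same shape, non-empty.
#' @param threshold `"otsu_plaque"` or a fixed numeric threshold.
#' @return object of class `burden_result`: `crystal_area_um2`,
#'   `plaque_area_um2`, `burden_percent`, `threshold`.
#' @export
compute_burden <- function(reflectance, plaque_mask, threshold = "otsu_plaque") {
  stop_if(!inherits(reflectance, "intensity_image"),
          "reflectance must be an intensity_image")
  stop_if(!is.matrix(plaque_mask) || !is.logical(plaque_mask) ||
            !all(dim(plaque_mask) == dim(reflectance$pixels)),
          "plaque_mask must be a logical matrix matching the image shape")
  stop_if(!any(plaque_mask), "plaque mask is empty")
  vals <- reflectance$pixels[plaque_mask]
  thr <- if (identical(threshold, "otsu_plaque")) {
    otsu_threshold(matrix(vals, nrow = 1L))$threshold
  } else {
    stop_if(!is_scalar_num(threshold), "threshold must be 'otsu_plaque' or a number")
    threshold
  }
  crystal <- plaque_mask & reflectance$pixels > thr
  px_um2 <- reflectance$pixel_size_um^2
  res <- list(crystal_area_um2 = sum(crystal) * px_um2,
              plaque_area_um2 = sum(plaque_mask) * px_um2,
              burden_percent = 100 * sum(crystal) / sum(plaque_mask),
              threshold = thr)
  class(res) <- "burden_result"
  res
}

#' @export
print.burden_result <- function(x, ...) {
  cat(fmt("<burden_result> %.3g%% (crystal %.4g um^2 / plaque %.4g um^2), threshold %.4g\n",
          x$burden_percent, x$crystal_area_um2, x$plaque_area_um2, x$threshold))
  invisible(x)
}

group_comparison <- function(method, statistic, p_value, n_per_group,
                             effect_direction) {
  structure(list(method = method, statistic = statistic,
                 p_value = min(max(p_value, 0), 1), n_per_group = n_per_group,
                 effect_direction = effect_direction),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(fmt("<group_comparison> %s: statistic %.4g, p = %.4g (n = %s), direction: %s\n",
          x$method, x$statistic, x$p_value,
          paste(x$n_per_group, collapse = " vs "), x$effect_direction))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midrank ties. For small samples
#' (`n1 + n2 <= 12`, or `exact = TRUE`) the two-sided p-value is computed by
#' exhaustive enumeration of all group labelings of the pooled sample (ties
#' handled exactly); otherwise by normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param sample_a,sample_b numeric samples (each size >= 1).
#' @param exact force (TRUE) or forbid (FALSE) exact enumeration; default
#'   `NULL` enumerates when `n1 + n2 <= 12`.
#' @return a `group_comparison`; `statistic` is U for `sample_a`
#'   (in `[0, n1 * n2]`).
#' @export
mann_whitney_u <- function(sample_a, sample_b, exact = NULL) {
  stop_if(length(sample_a) < 1L || length(sample_b) < 1L,
          "each sample must contain at least one value")
  stop_if(any(!is.finite(c(sample_a, sample_b))), "samples must be finite")
  n1 <- length(sample_a); n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                      # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  do_exact <- if (is.null(exact)) (n1 + n2) <= 12L else isTRUE(exact)
  if (do_exact) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2L, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    stop_if(sigma2 <= 0, "all values tied: Mann-Whitney variance is zero")
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
  }
  direction <- if (U > mu) "a_greater" else if (U < mu) "b_greater" else "none"
  group_comparison("MANN_WHITNEY_U", U, p, c(n1, n2), direction)
}

#' Two-sample t test
#'
#' Standard t statistic with two-sided p from the t distribution: pooled
#' variance by default (the study's stated unpaired test), Welch when
#' `equal_variance = FALSE`, or paired.
#'
#' @param sample_a,sample_b numeric samples, each of size >= 2; paired
#'   requires equal lengths.
#' @param paired paired test (default FALSE).
#' @param equal_variance pooled-variance test (default TRUE); ignored when
#'   paired.
#' @return a `group_comparison`.
#' @export
t_test_groups <- function(sample_a, sample_b, paired = FALSE,
                          equal_variance = TRUE) {
  stop_if(length(sample_a) < 2L || length(sample_b) < 2L,
          "t test requires n >= 2 per group")
  stop_if(paired && length(sample_a) != length(sample_b),
          "paired t test requires equal sample lengths")
  ht <- stats::t.test(sample_a, sample_b, paired = paired,
                      var.equal = equal_variance)
  method <- if (paired) "T_PAIRED" else "T_UNPAIRED"
  d <- mean(sample_a) - mean(sample_b)
  direction <- if (d > 0) "a_greater" else if (d < 0) "b_greater" else "none"
  group_comparison(method, unname(ht$statistic), ht$p.value,
                   c(length(sample_a), length(sample_b)), direction)
}

metric_value <- function(result, metric) {
  if (is.numeric(result)) return(result)
  switch(metric,
    density_per_mm2 = result$density_per_mm2,
    mean_length_um = result$length_summary$mean,
    burden_percent = result$burden_percent,
    stop(fmt("unknown metric '%s'", metric), call. = FALSE))
}

#' Compare a study metric between two groups
#'
#' Pools per-image metric values within each group (optionally averaging
#' within animal first, mirroring designs with several images per animal)
#' and applies the chosen two-sample test.
#'
#' @param group_results named list of exactly two groups; each group is a
#'   list of `morphometry_result` / `burden_result` objects (or plain
#'   numbers).
#' @param metric `"density_per_mm2"`, `"mean_length_um"` or
#'   `"burden_percent"`.
#' @param method `"mann_whitney"`, `"t_unpaired"` or `"t_paired"`.
#' @param animal_ids optional named list matching `group_results` giving an
#'   animal id per image; per-image values are averaged within animal before
#'   testing.
#' @return a `group_comparison`; `effect_direction` names the higher group.
#' @export
compare_study <- function(group_results, metric,
                          method = c("mann_whitney", "t_unpaired", "t_paired"),
                          animal_ids = NULL) {
  method <- match.arg(method)
  stop_if(!is.list(group_results) || length(group_results) != 2L ||
            is.null(names(group_results)),
          "group_results must be a named list of exactly two groups")
  metric <- match.arg(metric, c("density_per_mm2", "mean_length_um",
                                "burden_percent"))
  vals <- lapply(names(group_results), function(g) {
    v <- vapply(group_results[[g]], metric_value, numeric(1), metric = metric)
    if (!is.null(animal_ids)) {
      ids <- animal_ids[[g]]
      stop_if(length(ids) != length(v),
              fmt("animal_ids for group '%s' must match its image count", g))
      v <- as.numeric(tapply(v, ids, mean))
    }
    v
  })
  names(vals) <- names(group_results)
  a <- vals[[1L]]; b <- vals[[2L]]
  cmp <- switch(method,
    mann_whitney = mann_whitney_u(a, b),
    t_unpaired = t_test_groups(a, b, paired = FALSE),
    t_paired = t_test_groups(a, b, paired = TRUE))
  dir <- switch(cmp$effect_direction,
    a_greater = fmt("%s higher in %s", metric, names(vals)[1L]),
    b_greater = fmt("%s higher in %s", metric, names(vals)[2L]),
    "no difference")
  cmp$effect_direction <- dir
  cmp$metric <- metric
  cmp$group_values <- vals
  cmp
}
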