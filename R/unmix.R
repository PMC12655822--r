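#' Convert ratio designs to contribution fractions
#'
#' @param ratios Numeric vector of 5 non-negative mixing ratios, not all
#'   zero.
#' @return The ratios normalised to sum exactly 1 (names preserved).
#' @export
#' @examples
#' ratios_to_fractions(c(1, 6, 1, 1, 1))
ratios_to_fractions <- function(ratios) {
  if (length(ratios) != 5) abort("`ratios` must have length 5")
  if (!all(is.finite(ratios))) abort("`ratios` must be finite")
  if (any(ratios < 0)) abort("`ratios` must be non-negative")
  total <- sum(ratios)
  if (total == 0) abort("`ratios` must not be all zero")
  ratios / total
}

#' Classical least-squares deconvolution of a SERS spectrum
#'
#' Fits the linear mixture model `S_total = C1 S1 + ... + C5 S5 + delta`,
#' returning the weight factors `C1..C5` that minimise the L2 norm of the
#' residual `delta`. `mode = "nnls"` (default) constrains the weights to
#' be non-negative, reflecting their reading as physical signal
#' fractions; `mode = "ols"` solves the unconstrained problem.
#'
#' References are used exactly as supplied (not re-normalised), so the
#' weights are relative signal intensities against the reference spectra.
#'
#' @param spectrum A spectrum tibble on the library's axis (resample
#'   first if needed).
#' @param library A `ref_library` tibble.
#' @param mode `"nnls"` (default) or `"ols"`.
#' @return A `cls_fit` object: named weights, `residual_norm` (L2 norm of
#'   delta), `relative_residual` (residual norm over the spectrum norm)
#'   and the fit mode. Use [tidy()] for a per-reporter tibble.
#' @export
cls_unmix <- function(spectrum, library, mode = c("nnls", "ols")) {
  mode <- match.arg(mode)
  check_spectrum_tbl(spectrum)
  M <- library_matrix(library)
  x <- attr(M, "wavenumber")
  if (length(spectrum$wavenumber) != length(x) ||
      max(abs(spectrum$wavenumber - x)) > 1e-8) {
    abort("spectrum and reference library are on different axes; resample first")
  }
  sv <- svd(M, nu = 0, nv = 0)$d
  if (min(sv) == 0 || max(sv) / min(sv) > 1e8) {
    cm <- cor(M)
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "reference library is rank-deficient or ill-conditioned (reporters %s and %s are collinear)",
      colnames(M)[worst[[1]]], colnames(M)[worst[[2]]]))
  }
  y <- spectrum$intensity
  w <- if (mode == "ols") {
    drop(qr.coef(qr(M), y))
  } else {
    drop(pracma::lsqnonneg(M, y)$x)
  }
  names(w) <- colnames(M)
  resid <- y - drop(M %*% w)
  rn <- sqrt(sum(resid^2))
  yn <- sqrt(sum(y^2))
  structure(list(weights = w,
                 integrins = setNames(sers_integrins(), sers_reporters())[names(w)],
                 residual_norm = rn,
                 relative_residual = if (yn > 0) rn / yn else 0,
                 mode = mode, n = length(y)),
            class = "cls_fit")
}

#' @export
print.cls_fit <- function(x, ...) {
  cat(sprintf("<cls_fit> mode = %s, relative residual = %.3g\n",
              x$mode, x$relative_residual))
  print(round(x$weights, 4))
  invisible(x)
}

#' @rdname cls_unmix
#' @param x A `cls_fit`.
#' @param ... Unused.
#' @exportS3Method
tidy.cls_fit <- function(x, ...) {
  tibble::tibble(reporter = names(x$weights),
                 integrin = unname(x$integrins),
                 weight = unname(x$weights))
}

#' @rdname cls_unmix
#' @exportS3Method
glance.cls_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm,
                 relative_residual = x$relative_residual,
                 mode = x$mode, n = x$n)
}

#' @exportS3Method
autoplot.cls_fit <- function(object, ...) {
  d <- tidy(object)
  d$reporter <- factor(d$reporter, levels = sers_reporters())
  ggplot2::ggplot(d, ggplot2::aes(.data$reporter, .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Weight factor")
}

#' Unmix every spectrum of a mixture panel
#'
#' Runs [cls_unmix()] on each designed mixture and pairs the recovered
#' weights with the designed (theoretical) fractions. Recovered weights
#' are also renormalised to fractions (sum 1 within each design), the
#' form used for recovery-validation statistics.
#'
#' @param panel Output of [make_mixture_panel()].
#' @param library A `ref_library` tibble.
#' @param mode Passed to [cls_unmix()].
#' @return A tidy tibble with one row per (design, reporter):
#'   `true_fraction`, `recovered_weight`, `recovered_fraction`,
#'   `residual_norm`.
#' @export
unmix_panel <- function(panel, library, mode = "nnls") {
  stopifnot(all(c("design", "fractions", "spectrum") %in% names(panel)))
  purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    fit <- cls_unmix(panel$spectrum[[i]], library, mode = mode)
    w <- fit$weights
    tibble::tibble(design = panel$design[[i]],
                   reporter = names(w),
                   integrin = unname(fit$integrins),
                   true_fraction = unname(panel$fractions[[i]][names(w)]),
                   recovered_weight = unname(w),
                   recovered_fraction = unname(w / sum(w)),
                   residual_norm = fit$residual_norm)
  })
}

#' Pearson correlation with a slope test
#'
#' Ordinary least-squares line fit of `y` on `x` with the Pearson
#' correlation coefficient and the two-sided t-test p-value of the slope
#' (n - 2 degrees of freedom).
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return A `correlation_result`: `r`, `p`, `slope`, `intercept`, `n`.
#' @export
pearson_with_slope_p <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("at least 3 pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in `x` or `y`")
  n <- length(x)
  r <- cor(x, y)
  slope <- r * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  se <- sqrt((1 - r^2) / (n - 2)) * sd(y) / sd(x)
  p <- if (se == 0) 0 else 2 * pt(-abs(slope / se), df = n - 2)
  structure(list(r = r, p = p, slope = slope, intercept = intercept, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4f, p = %.3g, slope = %.4f, n = %d\n",
              x$r, x$p, x$slope, x$n))
  invisible(x)
}

#' @rdname pearson_with_slope_p
#' @param ... Unused.
#' @exportS3Method
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, slope = x$slope,
                 intercept = x$intercept, n = x$n)
}

#' @rdname pearson_with_slope_p
#' @exportS3Method
glance.correlation_result <- tidy.correlation_result

#' Recovery-validation correlation of a mixture panel
#'
#' Correlates the recovered contribution fractions against the designed
#' ones over all (design, reporter) pairs of an unmixed panel.
#'
#' @param panel_results Output of [unmix_panel()] (or any tibble with
#'   `true_fraction` and one of `recovered_fraction` /
#'   `recovered_weight`; weights are renormalised to fractions within
#'   each `design`).
#' @return A `correlation_result`.
#' @export
recovery_correlation <- function(panel_results) {
  stopifnot(is.data.frame(panel_results))
  if (!"true_fraction" %in% names(panel_results)) {
    abort("`panel_results` must have a `true_fraction` column")
  }
  if (!"recovered_fraction" %in% names(panel_results)) {
    if (!all(c("recovered_weight", "design") %in% names(panel_results))) {
      abort("`panel_results` needs `recovered_fraction`, or `recovered_weight` plus `design`")
    }
    panel_results <- panel_results |>
      dplyr::group_by(.data$design) |>
      dplyr::mutate(recovered_fraction =
                      .data$recovered_weight / sum(.data$recovered_weight)) |>
      dplyr::ungroup()
  }
  pearson_with_slope_p(panel_results$true_fraction,
                       panel_results$recovered_fraction)
}

#' Recovery scatter plot
#'
#' @param panel_results Output of [unmix_panel()].
#' @return A ggplot of recovered versus designed fractions with the
#'   identity line.
#' @export
plot_recovery <- function(panel_results) {
  ggplot2::ggplot(panel_results,
                  ggplot2::aes(.data$true_fraction, .data$recovered_fraction,
                               colour = .data$reporter)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Designed fraction", y = "Recovered fraction")
}
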