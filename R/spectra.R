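#' Wavenumber axis specification
#'
#' Describes a regular Raman-shift grid. The default reproduces the
#' acquisition grid used throughout the package: 250--3000 cm^-1 at a
#' resolution of 7 cm^-1, with axis values taken as bin centers.
#'
#' @param start,stop Axis limits in cm^-1 (`start < stop`).
#' @param step Grid spacing in cm^-1 (`> 0`).
#' @return An object of class `axis_spec`.
#' @export
#' @examples
#' axis_spec()
#' axis_points(axis_spec(400, 1800, 2))[1:5]
axis_spec <- function(start = 250, stop = 3000, step = 7) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    abort("`start`, `stop` and `step` must be numeric.")
  }
  if (start >= stop) abort("`start` must be strictly less than `stop`.")
  if (step <= 0) abort("`step` must be positive.")
  structure(list(start = start, stop = stop, step = step),
            class = "axis_spec")
}

#' @rdname axis_spec
#' @param spec An `axis_spec`.
#' @export
axis_points <- function(spec) {
  stopifnot(inherits(spec, "axis_spec"))
  seq(spec$start, spec$stop, by = spec$step)
}

#' @export
print.axis_spec <- function(x, ...) {
  cat(sprintf("<axis_spec> %g to %g cm^-1, step %g cm^-1 (%d points)\n",
              x$start, x$stop, x$step, length(axis_points(x))))
  invisible(x)
}

# A spectrum tibble has a `wavenumber` column, an `intensity` column and,
# for multi-spectrum tables, a `spectrum` id column. These checks are shared
# by every operation that consumes one.
check_spectrum_tbl <- function(df, arg = "spectrum") {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame.", arg))
  if (!all(c("wavenumber", "intensity") %in% names(df))) {
    abort(sprintf("`%s` must have `wavenumber` and `intensity` columns.", arg))
  }
  if (!all(is.finite(df$wavenumber)) || !all(is.finite(df$intensity))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  split_spectra(df) |> purrr::iwalk(function(s, id) {
    if (any(diff(s$wavenumber) <= 0)) {
      bad <- which(diff(s$wavenumber) <= 0)
      abort(sprintf(
        "wavenumber axis of spectrum '%s' is not strictly increasing at rows %s",
        id, paste(bad + 1L, collapse = ", ")))
    }
  })
  invisible(df)
}

# Split a (possibly multi-) spectrum tibble into a named list of
# single-spectrum tibbles.
split_spectra <- function(df) {
  if ("spectrum" %in% names(df)) {
    split(df, factor(df$spectrum, levels = unique(df$spectrum)))
  } else {
    list(intensity = df)
  }
}

# Apply `f` per spectrum and reassemble, preserving the id column.
map_spectra <- function(df, f) {
  pieces <- split_spectra(df)
  out <- purrr::imap(pieces, function(s, id) {
    res <- f(s)
    if ("spectrum" %in% names(df)) res$spectrum <- id
    res
  })
  res <- dplyr::bind_rows(out)
  cols <- intersect(c("wavenumber", "spectrum", "intensity"), names(res))
  res[cols]
}

#' Read a delimited spectrum table
#'
#' Reads one or more Raman spectra from delimited text: column 1 is the
#' wavenumber in cm^-1, columns 2..k are intensities (one spectrum per
#' column). The delimiter (comma or tab) is auto-detected; a header row is
#' recognised when its first cell is `"wavenumber"`.
#'
#' @param path Path to a delimited text file.
#' @param delim Optional delimiter; `NULL` (default) auto-detects.
#' @return A tibble with columns `wavenumber`, `intensity` and, when the
#'   file holds several spectra, `spectrum` (the column name or `s2`,
#'   `s3`, ... when no header is present).
#' @export
read_spectrum_table <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("file is empty: %s", path))
  if (is.null(delim)) delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[[1]])
    abort(sprintf("ragged rows in %s: row(s) %s have %s cells, expected %d",
                  path, paste(bad, collapse = ", "),
                  paste(unique(widths[bad]), collapse = "/"), widths[[1]]))
  }
  first <- trimws(cells[[1]])
  has_header <- tolower(first[[1]]) == "wavenumber"
  col_names <- if (has_header) first else
    c("wavenumber", if (widths[[1]] == 2) "intensity" else paste0("s", seq_len(widths[[1]] - 1) + 1L))
  body <- if (has_header) cells[-1] else cells
  if (length(body) == 0) abort(sprintf("no data rows in %s", path))
  mat <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(body))), nrow = length(body), byrow = TRUE))
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any)) + has_header
    abort(sprintf("non-numeric cells in %s at row(s) %s", path,
                  paste(bad, collapse = ", ")))
  }
  wn <- mat[, 1]
  if (any(diff(wn) <= 0)) {
    bad <- which(diff(wn) <= 0) + 1L + has_header
    abort(sprintf(
      "wavenumber column of %s is not strictly increasing at row(s) %s",
      path, paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(wavenumber = wn)
  if (ncol(mat) == 2) {
    out$intensity <- mat[, 2]
  } else {
    for (j in 2:ncol(mat)) out[[col_names[[j]]]] <- mat[, j]
    out <- tidyr::pivot_longer(out, -"wavenumber",
                               names_to = "spectrum", values_to = "intensity")
    out <- dplyr::arrange(out, .data$spectrum, .data$wavenumber)
  }
  check_spectrum_tbl(out, "file")
}

#' Write a spectrum table
#'
#' Writes spectra to delimited text in the same layout
#' [read_spectrum_table()] reads (wavenumber first, one intensity column
#' per spectrum, header row). Values are printed with 17 significant
#' digits so a read/write round trip is value-identical.
#'
#' @param df A spectrum tibble.
#' @param path Output path.
#' @param delim Delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(df, path, delim = ",") {
  check_spectrum_tbl(df)
  wide <- if ("spectrum" %in% names(df)) {
    tidyr::pivot_wider(df, names_from = "spectrum", values_from = "intensity")
  } else {
    df[c("wavenumber", "intensity")]
  }
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(names(wide), collapse = delim)
  rows <- apply(vapply(wide, fmt, character(nrow(wide))), 1, paste,
                collapse = delim)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Resample spectra onto a target axis
#'
#' Linear interpolation of each spectrum onto the grid of `spec`. Target
#' points outside the source range are set to 0; their count is recorded
#' in the `n_padded` attribute of the result.
#'
#' @param df A spectrum tibble.
#' @param spec An [axis_spec()] (or numeric vector of target wavenumbers).
#' @return A spectrum tibble on the target grid.
#' @export
resample_to_axis <- function(df, spec = axis_spec()) {
  check_spectrum_tbl(df)
  target <- if (inherits(spec, "axis_spec")) axis_points(spec) else
    as.numeric(spec)
  n_padded <- 0L
  out <- map_spectra(df, function(s) {
    if (max(s$wavenumber) < min(target) || min(s$wavenumber) > max(target)) {
      abort("spectrum axis does not overlap the target axis")
    }
    y <- approx(s$wavenumber, s$intensity, xout = target, rule = 1)$y
    pad <- is.na(y)
    n_padded <<- n_padded + sum(pad)
    y[pad] <- 0
    tibble::tibble(wavenumber = target, intensity = y)
  })
  attr(out, "n_padded") <- n_padded
  out
}

# Iterative ("modified polyfit") baseline of one segment: points sitting
# above the current polynomial fit by more than `k_dev` residual SDs are
# treated as peak points and dropped from the next fit, so peaks stop
# pulling the fit upward and the polynomial settles onto the continuum.
modpoly_segment <- function(x, y, degree, n_iterations, tol = 1e-6,
                            k_dev = 2) {
  if (length(x) < degree + 1) {
    abort(sprintf(
      "segment has %d points; at least %d needed for degree %d",
      length(x), degree + 1L, degree))
  }
  xs <- (x - mean(x)) / max(diff(range(x)) / 2, 1)  # scale for conditioning
  X <- outer(xs, 0:degree, `^`)
  mask <- rep(TRUE, length(y))
  fit_old <- NULL
  for (i in seq_len(max(1L, n_iterations))) {
    fit <- drop(X %*% qr.coef(qr(X[mask, , drop = FALSE]), y[mask]))
    if (!is.null(fit_old) &&
        sqrt(sum((fit - fit_old)^2)) <= tol * max(sqrt(sum(fit_old^2)), 1e-12)) {
      break
    }
    fit_old <- fit
    dev <- sd(y[mask] - fit[mask])
    if (is.na(dev)) break
    keep <- y <= fit + k_dev * dev
    if (sum(keep) > degree + 1) mask <- keep
  }
  fit
}

#' Multi-segment polynomial baseline correction
#'
#' Estimates and subtracts the broad continuum background of each spectrum
#' by iterative polynomial fitting in `n_segments` equal-width wavenumber
#' segments (neighbouring segments share a node and their baselines are
#' blended linearly over a 3-point overlap to avoid steps). Within each
#' segment, points above the current fit are progressively clipped so
#' peaks do not inflate the baseline.
#'
#' @param df A spectrum tibble.
#' @param n_segments Number of equal-width segments (default 4).
#' @param degree Polynomial degree per segment (default 3).
#' @param n_iterations Maximum clipping iterations (default 50); iteration
#'   stops early once the fitted baseline changes by less than `1e-6` in
#'   relative norm.
#' @param floor_zero Floor corrected intensities at 0 (default `TRUE`),
#'   consistent with reading weight factors as non-negative signal.
#' @return A spectrum tibble of baseline-corrected intensities.
#' @export
baseline_correct <- function(df, n_segments = 4, degree = 3,
                             n_iterations = 50, floor_zero = TRUE) {
  check_spectrum_tbl(df)
  if (n_segments < 1) abort("`n_segments` must be >= 1.")
  map_spectra(df, function(s) {
    x <- s$wavenumber
    y <- s$intensity
    n <- length(x)
    bounds <- seq(x[[1]], x[[n]], length.out = n_segments + 1)
    baseline <- numeric(n)
    weight <- numeric(n)
    for (k in seq_len(n_segments)) {
      core <- which(x >= bounds[[k]] & x <= bounds[[k + 1]])
      # one extra point each side -> 3-point overlap around the shared node
      idx <- seq(max(1L, min(core) - 1L), min(n, max(core) + 1L))
      fit <- modpoly_segment(x[idx], y[idx], degree, n_iterations)
      w <- rep(1, length(idx))
      if (min(idx) > 1) w[1:2] <- c(0, 0.5)
      if (max(idx) < n) w[(length(idx) - 1):length(idx)] <- c(0.5, 0)
      baseline[idx] <- baseline[idx] + w * fit
      weight[idx] <- weight[idx] + w
    }
    corrected <- y - baseline / pmax(weight, .Machine$double.eps)
    if (floor_zero) corrected <- pmax(corrected, 0)
    tibble::tibble(wavenumber = x, intensity = corrected)
  })
}

#' Boxcar smoothing
#'
#' Centered moving-average denoising. At the edges the window shrinks
#' symmetrically so the mean is always taken over a window centered on the
#' current point.
#'
#' @param df A spectrum tibble.
#' @param window_points Odd window width in points (default 5, i.e. 35
#'   cm^-1 on the default 7 cm^-1 grid).
#' @return A smoothed spectrum tibble.
#' @export
boxcar_smooth <- function(df, window_points = 5) {
  check_spectrum_tbl(df)
  w <- window_points
  if (length(w) != 1 || !is.finite(w) || w < 1 || w %% 2 != 1) {
    abort("`window_points` must be a positive odd integer.")
  }
  map_spectra(df, function(s) {
    y <- s$intensity
    n <- length(y)
    if (w > n) abort("`window_points` exceeds the spectrum length.")
    half <- (w - 1) / 2
    sm <- vapply(seq_len(n), function(i) {
      k <- min(half, i - 1, n - i)
      mean(y[(i - k):(i + k)])
    }, numeric(1))
    tibble::tibble(wavenumber = s$wavenumber, intensity = sm)
  })
}

#' Spectrum line plot
#'
#' @param df A spectrum tibble.
#' @return A ggplot object.
#' @export
plot_spectra <- function(df) {
  check_spectrum_tbl(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity))
  if ("spectrum" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$spectrum))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                    y = "Intensity (a.u.)")
}
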