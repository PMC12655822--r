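#' Default reporter peak models
#'
#' One row per Raman reporter with its integrin channel and peak list.
#' The strongest peak of each model sits at the reporter's characteristic
#' shift (SiNC 684, BHQ3 1094, QXL680 1140, QSY21 1496, DTDC 510 cm^-1);
#' the two or three minor peaks per reporter are synthetic fixtures placed
#' at fixed, non-overlapping positions so the five spectra are mutually
#' distinguishable. All positions, amplitudes and widths are overridable.
#'
#' @param line_shape `"lorentzian"` (default) or `"gaussian"`.
#' @return A tibble with columns `reporter`, `integrin`, `line_shape` and a
#'   `peaks` list-column of tibbles (`center`, `amplitude`, `fwhm`).
#' @export
#' @examples
#' reporter_models()
reporter_models <- function(line_shape = c("lorentzian", "gaussian")) {
  line_shape <- match.arg(line_shape)
  peak <- function(center, amplitude, fwhm = 18) {
    tibble::tibble(center = center, amplitude = amplitude, fwhm = fwhm)
  }
  peaks <- list(
    SiNC   = dplyr::bind_rows(peak(684, 1), peak(752, 0.35, 14),
                              peak(1338, 0.20, 14)),
    BHQ3   = dplyr::bind_rows(peak(1094, 1), peak(452, 0.20, 14),
                              peak(1242, 0.30, 14), peak(1730, 0.15, 14)),
    QXL680 = dplyr::bind_rows(peak(1140, 1), peak(592, 0.20, 14),
                              peak(938, 0.30, 14), peak(1562, 0.20, 14)),
    QSY21  = dplyr::bind_rows(peak(1496, 1), peak(642, 0.25, 14),
                              peak(1182, 0.25, 14)),
    DTDC   = dplyr::bind_rows(peak(510, 1), peak(558, 0.30, 14),
                              peak(852, 0.20, 14), peak(1622, 0.15, 14))
  )
  tbl <- channel_table()
  tbl$line_shape <- line_shape
  tbl$peaks <- unname(peaks[tbl$reporter])
  tbl
}

check_reporter_model <- function(model) {
  stopifnot(is.data.frame(model), nrow(model) == 1)
  pk <- model$peaks[[1]]
  if (any(pk$amplitude <= 0)) abort("all peak amplitudes must be positive")
  if (any(pk$fwhm <= 0)) abort("all peak widths must be positive")
  main <- pk$center[which.max(pk$amplitude)]
  if (!is.na(model$characteristic_shift) &&
      abs(main - model$characteristic_shift) > 1e-8) {
    abort(sprintf(
      "strongest peak of %s is at %g cm^-1, expected %g cm^-1",
      model$reporter, main, model$characteristic_shift))
  }
  invisible(model)
}

line_profile <- function(x, center, amplitude, fwhm, shape) {
  if (shape == "lorentzian") {
    amplitude / (1 + (2 * (x - center) / fwhm)^2)
  } else {
    amplitude * exp(-4 * log(2) * ((x - center) / fwhm)^2)
  }
}

#' Evaluate a reporter model on an axis
#'
#' Sums the model's line-shape profiles over the grid of `spec`. The
#' result is deterministic for a fixed model.
#'
#' @param model One row of [reporter_models()].
#' @param spec An [axis_spec()].
#' @return A spectrum tibble.
#' @export
make_reference <- function(model, spec = axis_spec()) {
  check_reporter_model(model)
  x <- axis_points(spec)
  pk <- model$peaks[[1]]
  main <- pk$center[which.max(pk$amplitude)]
  if (main < min(x) || main > max(x)) {
    abort(sprintf("characteristic peak of %s (%g cm^-1) lies outside the axis",
                  model$reporter, main))
  }
  y <- rowSums(mapply(function(c0, a, w) {
    line_profile(x, c0, a, w, model$line_shape[[1]])
  }, pk$center, pk$amplitude, pk$fwhm))
  tibble::tibble(wavenumber = x, intensity = y)
}

#' Simulate the five-reporter reference library
#'
#' Builds the pure-nanotag reference spectra S1..S5 shared by every
#' downstream deconvolution, all on one axis.
#'
#' @param models Reporter models, by default [reporter_models()].
#' @param spec An [axis_spec()].
#' @return A `ref_library` tibble with columns `reporter`, `integrin`,
#'   `wavenumber`, `intensity`.
#' @export
simulate_reference_library <- function(models = reporter_models(),
                                       spec = axis_spec()) {
  stopifnot(is.data.frame(models))
  missing <- setdiff(sers_reporters(), models$reporter)
  if (length(missing) > 0) {
    abort(sprintf("reference library is missing reporter(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
    s <- make_reference(models[i, ], spec)
    tibble::tibble(reporter = models$reporter[[i]],
                   integrin = models$integrin[[i]],
                   wavenumber = s$wavenumber,
                   intensity = s$intensity)
  })
  out$reporter <- factor(out$reporter, levels = sers_reporters())
  out <- dplyr::arrange(out, .data$reporter, .data$wavenumber)
  out$reporter <- as.character(out$reporter)
  class(out) <- c("ref_library", class(out))
  out
}

#' Reference library as a matrix
#'
#' @param library A `ref_library` tibble.
#' @return A numeric matrix (wavenumbers x 5 reporters) with the shared
#'   axis in attribute `wavenumber`.
#' @export
library_matrix <- function(library) {
  stopifnot(is.data.frame(library),
            all(c("reporter", "wavenumber", "intensity") %in% names(library)))
  wide <- tidyr::pivot_wider(
    library[c("wavenumber", "reporter", "intensity")],
    names_from = "reporter", values_from = "intensity")
  wide <- dplyr::arrange(wide, .data$wavenumber)
  reporters <- intersect(sers_reporters(), names(wide))
  M <- as.matrix(wide[reporters])
  if (anyNA(M)) abort("reference spectra do not share one axis")
  attr(M, "wavenumber") <- wide$wavenumber
  M
}

# Smooth random baseline: a random cubic in scaled wavenumber, normalised
# to a given peak amplitude.
random_baseline <- function(x, amplitude) {
  if (amplitude <= 0) return(numeric(length(x)))
  xs <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  co <- rnorm(4)
  b <- co[1] + co[2] * xs + co[3] * xs^2 + co[4] * xs^3
  b * amplitude / max(abs(b))
}

#' Forward mixture model
#'
#' Simulates the total SERS signal of a tag mixture,
#' `S_total = sum_i w_i S_i + noise + baseline`: the weighted sum of the
#' five reference spectra plus additive Gaussian noise (SD expressed as a
#' fraction of the library's global peak intensity) and a smooth random
#' baseline of the given relative amplitude.
#'
#' @param library A `ref_library` tibble.
#' @param weights Numeric vector of 5 weight factors (library reporter
#'   order, or named by reporter).
#' @param noise_sd Gaussian noise SD as a fraction of the global maximum
#'   of the reference library (default 0).
#' @param baseline_amp Amplitude of the smooth random baseline, same scale
#'   (default 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A spectrum tibble.
#' @export
mix_spectra <- function(library, weights, noise_sd = 0, baseline_amp = 0,
                        seed = NULL) {
  M <- library_matrix(library)
  if (length(weights) != ncol(M)) {
    abort(sprintf("`weights` must have length %d, got %d",
                  ncol(M), length(weights)))
  }
  if (!all(is.finite(weights))) abort("`weights` must be finite")
  if (!is.null(names(weights))) weights <- weights[colnames(M)]
  y <- drop(M %*% weights)
  x <- attr(M, "wavenumber")
  peak <- max(M)
  with_seed_or_ambient(seed, {
    if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd * peak)
    if (baseline_amp > 0) y <- y + random_baseline(x, baseline_amp * peak)
  })
  tibble::tibble(wavenumber = x, intensity = y)
}

#' Default mixture-panel ratio designs
#'
#' Eight five-tag ratio designs spanning equal, single-tag-dominant and
#' graded compositions; row 3 is the QXL680-dominant 1:6:1:1:1 design.
#'
#' @return A numeric matrix (designs x reporters).
#' @export
default_mixture_designs <- function() {
  m <- rbind(
    c(1, 1, 1, 1, 1),
    c(6, 1, 1, 1, 1),
    c(1, 1, 6, 1, 1),
    c(1, 6, 1, 1, 1),
    c(1, 1, 1, 6, 1),
    c(1, 1, 1, 1, 6),
    c(1, 2, 3, 2, 1),
    c(4, 2, 1, 0, 3)
  )
  colnames(m) <- sers_reporters()
  rownames(m) <- paste0("design", seq_len(nrow(m)))
  m
}

#' Build a designed mixture panel
#'
#' Normalises each ratio design to contribution fractions (sum 1) and
#' simulates the corresponding mixed spectrum with [mix_spectra()].
#'
#' @param library A `ref_library` tibble.
#' @param ratio_designs Matrix of non-negative ratios, one design per row
#'   (default [default_mixture_designs()]).
#' @param noise_sd,baseline_amp Passed to [mix_spectra()].
#' @param seed Optional integer seed; each design gets its own derived
#'   seed.
#' @return A tibble with one row per design: `design`, `fractions`
#'   (named-numeric list-column) and `spectrum` (list-column of spectrum
#'   tibbles).
#' @export
make_mixture_panel <- function(library, ratio_designs = default_mixture_designs(),
                               noise_sd = 0.015, baseline_amp = 0,
                               seed = NULL) {
  ratio_designs <- rbind(ratio_designs)
  seeds <- derive_seeds(seed, nrow(ratio_designs))
  rows <- purrr::map(seq_len(nrow(ratio_designs)), function(i) {
    fr <- ratios_to_fractions(ratio_designs[i, ])
    names(fr) <- colnames(ratio_designs) %||% sers_reporters()
    sp <- mix_spectra(library, fr, noise_sd = noise_sd,
                      baseline_amp = baseline_amp, seed = seeds[[i]])
    tibble::tibble(design = rownames(ratio_designs)[[i]] %||%
                     paste0("design", i),
                   fractions = list(fr), spectrum = list(sp))
  })
  dplyr::bind_rows(rows)
}

#' Synthetic cell-population configuration
#'
#' Per-cell-line truncated-normal models of the five integrin weight
#' factors. The default means are synthetic values chosen to match the
#' qualitative expression patterns of the three breast-cancer lines
#' (beta1 highest everywhere, beta4 near zero everywhere, beta5 elevated
#' in MCF7, beta3/beta4/beta5 near zero in SKBR3), with a common SD of
#' 0.06 and weights truncated to the observed range \[0, 0.79\].
#'
#' @param means Named list of per-line mean vectors (length 5, integrin
#'   order alpha3, beta1, beta3, beta4, beta5).
#' @param sd Common SD of the truncated normals (default 0.06).
#' @param bounds Truncation bounds (default `c(0, 0.79)`).
#' @param n_per_line Cells simulated per line (default 300).
#' @param noise_sd,baseline_amp Spectral noise model used when per-cell
#'   spectra are simulated (defaults 0.015 and 0).
#' @return A `population_config` list.
#' @export
population_config <- function(means = NULL, sd = 0.06, bounds = c(0, 0.79),
                              n_per_line = 300, noise_sd = 0.015,
                              baseline_amp = 0) {
  if (is.null(means)) {
    means <- list(
      MM231 = c(alpha3 = 0.45, beta1 = 0.55, beta3 = 0.02,
                beta4 = 0.05, beta5 = 0.25),
      MCF7  = c(alpha3 = 0.20, beta1 = 0.50, beta3 = 0.15,
                beta4 = 0.02, beta5 = 0.40),
      SKBR3 = c(alpha3 = 0.30, beta1 = 0.60, beta3 = 0.02,
                beta4 = 0.02, beta5 = 0.03)
    )
  }
  if (any(sd < 0)) abort("`sd` must be non-negative")
  if (bounds[[1]] < 0 || bounds[[2]] > 1 || bounds[[1]] >= bounds[[2]]) {
    abort("`bounds` must satisfy 0 <= lo < hi <= 1")
  }
  purrr::iwalk(means, function(m, line) {
    if (length(m) != 5) abort(sprintf("means for %s must have length 5", line))
    if (any(m < bounds[[1]] | m > bounds[[2]])) {
      abort(sprintf("means for %s fall outside the truncation bounds", line))
    }
  })
  if (n_per_line < 0) abort("`n_per_line` must be >= 0")
  structure(list(means = means, sd = sd, bounds = bounds,
                 n_per_line = n_per_line, noise_sd = noise_sd,
                 baseline_amp = baseline_amp),
            class = "population_config")
}

# Truncated-normal draws by rejection.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a labelled single-cell population
#'
#' Draws per-cell true weight factors from the per-line truncated normal
#' models of `config`, and optionally simulates each cell's measured
#' spectrum through the forward mixture model.
#'
#' @param config A [population_config()].
#' @param seed Optional integer seed; draws are bit-reproducible for a
#'   fixed seed.
#' @param library A `ref_library` tibble, required when `spectra = TRUE`.
#' @param spectra Also simulate per-cell spectra (default `FALSE`).
#' @param lines Cell lines to simulate (default all three).
#' @return A tibble with `cell_id`, `label`, the five weight columns by
#'   integrin name and, when requested, a `spectrum` list-column.
#' @export
simulate_cell_population <- function(config = population_config(), seed = NULL,
                                     library = NULL, spectra = FALSE,
                                     lines = names(config$means)) {
  stopifnot(inherits(config, "population_config"))
  if (spectra && is.null(library)) {
    abort("a reference `library` is needed to simulate spectra")
  }
  n <- config$n_per_line
  empty <- tibble::tibble(cell_id = character(), label = character())
  for (m in sers_integrins()) empty[[m]] <- numeric()
  if (n == 0 || length(lines) == 0) return(empty)
  seeds <- derive_seeds(seed, length(lines) + 1L)
  pop <- purrr::map_dfr(seq_along(lines), function(i) {
    line <- lines[[i]]
    w <- with_seed_or_ambient(seeds[[i]], {
      vapply(config$means[[line]], function(m) {
        rtruncnorm(n, m, config$sd, config$bounds[[1]], config$bounds[[2]])
      }, numeric(n))
    })
    out <- tibble::tibble(
      cell_id = sprintf("%s_%04d", line, seq_len(n)),
      label = line)
    for (j in seq_along(sers_integrins())) {
      out[[sers_integrins()[[j]]]] <- w[, j]
    }
    out
  })
  if (spectra) {
    cell_seeds <- derive_seeds(seeds[[length(seeds)]], nrow(pop))
    W <- as.matrix(pop[sers_integrins()])
    pop$spectrum <- purrr::map(seq_len(nrow(pop)), function(i) {
      mix_spectra(library, setNames(W[i, ], sers_reporters()),
                  noise_sd = config$noise_sd,
                  baseline_amp = config$baseline_amp,
                  seed = cell_seeds[[i]])
    })
  }
  pop
}
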