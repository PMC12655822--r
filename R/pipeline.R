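#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one nested list
#' that round-trips losslessly through YAML. Every default of the
#' package's design appears here explicitly.
#'
#' @param ... Named overrides of the defaults, nested lists merged
#'   recursively (e.g. `population = list(n_per_line = 50)`).
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' cfg <- pipeline_config(population = list(n_per_line = 30))
#' cfg$population$n_per_line
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    axis = list(start = 250, stop = 3000, step = 7),
    preprocess = list(n_segments = 4, degree = 3, n_iterations = 50,
                      floor_zero = TRUE, window_points = 5),
    references = list(path = NA, line_shape = "lorentzian"),
    panel = list(noise_sd = 0.015, baseline_amp = 0),
    population = list(n_per_line = 300, sd = 0.06,
                      bounds = c(0, 0.79), noise_sd = 0.015,
                      baseline_amp = 0, use_spectra = FALSE),
    unmix = list(mode = "nnls"),
    classify = list(train_fraction = 0.7, n_iterations = 200,
                    n_trees = 100, max_depth = NA),
    predict = list(n_mixed = 450),
    embed = list(perplexities = default_perplexities(), n_replicates = 5,
                 max_iter = 500, enabled = TRUE)
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  cfg <- merge_config(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' @rdname pipeline_config
#' @param path Path to a YAML config document.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_log <- function(lines, log_path, verbose = FALSE) {
  stamped <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), lines)
  cat(stamped, file = log_path, sep = "\n", append = TRUE)
  if (verbose) message(paste(stamped, collapse = "\n"))
}

null_if_na <- function(x) if (is.null(x) || (length(x) == 1 && is.na(x))) NULL else x

load_reference_library <- function(config, spec) {
  path <- null_if_na(config$references$path)
  if (is.null(path)) {
    return(simulate_reference_library(
      reporter_models(config$references$line_shape), spec))
  }
  if (!file.exists(path)) {
    abort(sprintf("reference spectrum file not found: %s", path))
  }
  tbl <- read_spectrum_table(path)
  if (!"spectrum" %in% names(tbl)) abort("reference file must hold 5 spectra")
  missing <- setdiff(sers_reporters(), unique(tbl$spectrum))
  if (length(missing) > 0) {
    abort(sprintf("reference file %s is missing reporter column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  lib <- tbl |>
    dplyr::rename(reporter = "spectrum") |>
    dplyr::left_join(channel_table()[c("reporter", "integrin")],
                     by = "reporter") |>
    resample_lib(spec)
  class(lib) <- c("ref_library", class(lib))
  lib
}

resample_lib <- function(lib, spec) {
  purrr::map_dfr(split(lib, lib$reporter), function(s) {
    r <- resample_to_axis(s[c("wavenumber", "intensity")], spec)
    tibble::tibble(reporter = s$reporter[[1]], integrin = s$integrin[[1]],
                   wavenumber = r$wavenumber, intensity = r$intensity)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates every stage on one seed: build (or load) the reference
#' library, simulate and unmix a designed mixture panel, simulate the
#' labelled cell population (optionally through spectra +
#' preprocessing + per-cell deconvolution), run the repeated
#' random-forest protocol, retrain on the full training data and predict
#' a fresh mixed population, and select a t-SNE embedding. Writes tidy
#' delimited-text artifacts plus a machine-readable YAML summary and a
#' timestamped, seed-stamped run log into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed (default `config$seed`); every stochastic
#'   stage derives its own seed from it and logs it.
#' @param verbose Also echo log lines to the console (default `FALSE`).
#' @return Invisibly, a list with every stage result and the paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = config$seed, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  say <- function(...) pipeline_log(sprintf(...), log_path, verbose)
  stage <- "setup"
  result <- tryCatch({
    say("run_pipeline start, top-level seed %d, serscyto %s", seed,
        as.character(utils::packageVersion("serscyto")))
    seeds <- derive_seeds(seed, 5)
    spec <- axis_spec(config$axis$start, config$axis$stop, config$axis$step)

    stage <- "references"
    lib <- load_reference_library(config, spec)
    ref_path <- file.path(out_dir, "reference_library.csv")
    write_spectrum_table(
      dplyr::rename(lib[c("wavenumber", "reporter", "intensity")],
                    spectrum = "reporter"), ref_path)
    say("stage references: wrote %s", ref_path)

    stage <- "mixture_panel"
    panel <- make_mixture_panel(lib, noise_sd = config$panel$noise_sd,
                                baseline_amp = config$panel$baseline_amp,
                                seed = seeds[[1]])
    recovery <- unmix_panel(panel, lib, mode = config$unmix$mode)
    rec_cor <- recovery_correlation(recovery)
    rec_path <- file.path(out_dir, "mixture_recovery.csv")
    utils::write.csv(recovery, rec_path, row.names = FALSE)
    say("stage mixture_panel: seed %d, r = %.4f, wrote %s",
        seeds[[1]], rec_cor$r, rec_path)

    stage <- "population"
    pop_cfg <- population_config(sd = config$population$sd,
                                 bounds = config$population$bounds,
                                 n_per_line = config$population$n_per_line,
                                 noise_sd = config$population$noise_sd,
                                 baseline_amp = config$population$baseline_amp)
    use_spectra <- isTRUE(config$population$use_spectra)
    pop <- simulate_cell_population(pop_cfg, seed = seeds[[2]], library = lib,
                                    spectra = use_spectra)
    if (use_spectra) {
      say("stage population: unmixing %d simulated spectra", nrow(pop))
      fits <- purrr::map(pop$spectrum, function(s) {
        s |>
          boxcar_smooth(config$preprocess$window_points) |>
          baseline_correct(config$preprocess$n_segments,
                           config$preprocess$degree,
                           config$preprocess$n_iterations,
                           config$preprocess$floor_zero) |>
          cls_unmix(lib, mode = config$unmix$mode)
      })
      W <- t(vapply(fits, function(f) f$weights, numeric(5)))
      for (j in seq_along(sers_integrins())) {
        pop[[sers_integrins()[[j]]]] <- W[, j]
      }
      pop$residual_norm <- purrr::map_dbl(fits, "residual_norm")
      pop$spectrum <- NULL
    } else {
      pop$residual_norm <- 0
    }
    say("stage population: seed %d, %d cells", seeds[[2]], nrow(pop))

    stage <- "classification"
    protocol <- repeat_training(pop,
                                n_iterations = config$classify$n_iterations,
                                train_fraction = config$classify$train_fraction,
                                n_trees = config$classify$n_trees,
                                max_depth = null_if_na(config$classify$max_depth),
                                seed = seeds[[3]])
    final_split <- split_train_test(pop, config$classify$train_fraction,
                                    seed = protocol$summary$split_seed[[1]])
    final_report <- protocol$reports[[1]]
    utils::write.csv(as.data.frame(final_report$confusion_counts),
                     file.path(out_dir, "confusion_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(final_report$confusion_fractions),
                     file.path(out_dir, "confusion_fractions.csv"),
                     row.names = FALSE)
    say("stage classification: seed %d, mean macro F1 = %.4f, mean accuracy = %.4f",
        seeds[[3]], protocol$mean_macro_f1, protocol$mean_accuracy)

    stage <- "profiles"
    pop$split <- final_split$split
    profile_path <- file.path(out_dir, "cell_profiles.csv")
    utils::write.csv(
      pop[c("cell_id", "label", "split", sers_integrins(), "residual_norm")],
      profile_path, row.names = FALSE)
    say("stage profiles: wrote %s", profile_path)

    stage <- "prediction"
    train <- final_split[final_split$split == "train", ]
    model <- train_forest(train, n_trees = config$classify$n_trees,
                          max_depth = null_if_na(config$classify$max_depth),
                          seed = seeds[[4]])
    mixed_cfg <- pop_cfg
    mixed_cfg$n_per_line <- ceiling(config$predict$n_mixed / 3)
    mixed <- simulate_cell_population(mixed_cfg, seed = seeds[[4]] + 1L)
    mixed <- head(mixed[with_seed_or_ambient(seeds[[4]],
                                             sample.int(nrow(mixed))), ],
                  config$predict$n_mixed)
    prediction <- predict_population(model, mixed)
    prof_cor <- profile_correlation(prediction, train)
    utils::write.csv(tidy(prediction),
                     file.path(out_dir, "prediction_summary.csv"),
                     row.names = FALSE)
    say("stage prediction: seed %d, counts %s, profile r = %.4f", seeds[[4]],
        paste(sprintf("%s=%d", names(prediction$counts), prediction$counts),
              collapse = " "), prof_cor$r)

    stage <- "embedding"
    selection <- NULL
    if (isTRUE(config$embed$enabled)) {
      perp <- config$embed$perplexities
      perp <- perp[perp < nrow(train)]
      selection <- select_perplexity(train, train$label, perplexities = perp,
                                     n_replicates = config$embed$n_replicates,
                                     seed = seeds[[5]],
                                     max_iter = config$embed$max_iter)
      utils::write.csv(selection$audit,
                       file.path(out_dir, "embedding_audit.csv"),
                       row.names = FALSE)
      say("stage embedding: seed %d, chosen perplexity %g (DBI %.4f)",
          seeds[[5]], selection$chosen_perplexity, selection$chosen_dbi)
    }

    stage <- "summary"
    summary <- list(
      seed = seed,
      stage_seeds = as.list(setNames(seeds, c("mixture_panel", "population",
                                              "classification", "prediction",
                                              "embedding"))),
      recovery = list(r = rec_cor$r, p = rec_cor$p, n = rec_cor$n),
      classification = list(mean_macro_f1 = protocol$mean_macro_f1,
                            mean_accuracy = protocol$mean_accuracy,
                            n_iterations = protocol$n_iterations),
      prediction = list(counts = as.list(prediction$counts),
                        n_total = prediction$n_total,
                        profile_r = prof_cor$r, profile_p = prof_cor$p),
      embedding = if (!is.null(selection)) {
        list(chosen_perplexity = selection$chosen_perplexity,
             chosen_dbi = selection$chosen_dbi)
      })
    yaml::write_yaml(summary, file.path(out_dir, "run_summary.yaml"))
    say("run_pipeline done")
    list(library = lib, panel_recovery = recovery,
         recovery_correlation = rec_cor, population = pop,
         protocol = protocol, prediction = prediction,
         profile_correlation = prof_cor, embedding = selection,
         summary = summary, out_dir = out_dir)
  }, error = function(e) {
    say("ERROR in stage %s: %s", stage, conditionMessage(e))
    abort(sprintf("pipeline failed in stage %s: %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
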