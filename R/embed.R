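# Exact (O(n^2)) t-SNE. Written for the population sizes this package
# works at (hundreds of cells, 5 features); no Barnes-Hut approximation.

# Conditional affinities p_{j|i} by per-point binary search on the
# Gaussian precision so each row's perplexity matches the target.
tsne_affinities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf
    hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(p), length(p)) else p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {           # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Fit one 2-D t-SNE embedding
#'
#' Exact t-SNE with a Student-t low-dimensional kernel, gradient descent
#' with momentum (0.5 for the first 250 iterations, 0.8 afterwards),
#' early exaggeration (factor 12 over the first 250 iterations), an
#' automatic learning rate (`max(n / 48, 50)`), and small random Gaussian
#' initialisation. Records the final Kullback-Leibler divergence of the
#' fit, the quantity used to pick the best replicate at a perplexity.
#'
#' @param profiles A tibble (or matrix) of per-cell features; by default
#'   the five integrin weight columns are used.
#' @param perplexity Target perplexity (must be < number of cells).
#' @param max_iter Gradient-descent iterations (default 500).
#' @param seed Optional integer seed; fits are reproducible under a
#'   fixed seed.
#' @param features Feature columns used when `profiles` is a data frame.
#' @return An `embedding_fit`: `coords` (tibble `tsne1`, `tsne2`),
#'   `kl_divergence`, `perplexity`, `seed`.
#' @export
tsne_fit <- function(profiles, perplexity = 30, max_iter = 500, seed = NULL,
                     features = sers_integrins()) {
  X <- as_feature_matrix(profiles, features)
  n <- nrow(X)
  if (n < 10) abort("at least 10 cells are required")
  if (perplexity >= n) {
    abort(sprintf("perplexity (%g) must be smaller than the number of cells (%d)",
                  perplexity, n))
  }
  D2 <- as.matrix(dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  exag_iter <- min(250L, max_iter)
  eta <- max(n / 48, 50)
  Y <- with_seed_or_ambient(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= exag_iter) P * 12 else P
    qnum <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(qnum) <- 0
    Q <- pmax(qnum / sum(qnum), 1e-12)
    L <- (Pe - Q) * qnum
    G <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    mom <- if (it <= 250) 0.5 else 0.8
    V <- mom * V - eta * gains * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  qnum <- 1 / (1 + as.matrix(dist(Y))^2)
  diag(qnum) <- 0
  Q <- pmax(qnum / sum(qnum), 1e-12)
  kl <- sum(P * log(P / Q))
  structure(list(coords = tibble::tibble(tsne1 = Y[, 1], tsne2 = Y[, 2]),
                 kl_divergence = kl, perplexity = perplexity,
                 seed = seed, n = n),
            class = "embedding_fit")
}

as_feature_matrix <- function(profiles, features) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.data.frame(profiles))
  present <- intersect(features, names(profiles))
  if (length(present) == 0) {
    present <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  }
  as.matrix(profiles[present])
}

#' @export
print.embedding_fit <- function(x, ...) {
  cat(sprintf("<embedding_fit> perplexity = %g, KL = %.4f, n = %d\n",
              x$perplexity, x$kl_divergence, x$n))
  invisible(x)
}

#' @exportS3Method
autoplot.embedding_fit <- function(object, labels = NULL, ...) {
  d <- object$coords
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$tsne1, .data$tsne2))
  if (!is.null(labels)) {
    d$label <- labels
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$tsne1, .data$tsne2,
                                         colour = .data$label))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}

#' Default perplexity grid
#'
#' Twelve values spanning 5--300; with five replicates per value this
#' yields the 60-fit sweep used by [select_perplexity()].
#'
#' @return A numeric vector of 12 perplexities.
#' @export
default_perplexities <- function() {
  c(5, 10, 20, 30, 45, 60, 90, 120, 150, 200, 250, 300)
}

#' t-SNE perplexity sweep
#'
#' Fits `n_replicates` embeddings at every perplexity, each replicate
#' with its own derived seed, recording the final KL divergence of every
#' fit.
#'
#' @inheritParams tsne_fit
#' @param perplexities Candidate perplexities (default
#'   [default_perplexities()]); all must be < number of cells.
#' @param n_replicates Replicate fits per perplexity (default 5).
#' @param seed Optional top-level seed.
#' @return A tibble with one row per fit: `perplexity`, `replicate`,
#'   `kl_divergence`, `seed` and the `fit` itself (list-column).
#' @export
tsne_sweep <- function(profiles, perplexities = default_perplexities(),
                       n_replicates = 5, seed = NULL, max_iter = 500,
                       features = sers_integrins()) {
  X <- as_feature_matrix(profiles, features)
  bad <- perplexities[perplexities >= nrow(X)]
  if (length(bad) > 0) {
    abort(sprintf("perplexity value(s) %s are not smaller than the number of cells (%d)",
                  paste(bad, collapse = ", "), nrow(X)))
  }
  grid <- tidyr::expand_grid(perplexity = perplexities,
                             replicate = seq_len(n_replicates))
  grid$seed <- derive_seeds(seed, nrow(grid))
  grid$fit <- purrr::pmap(grid, function(perplexity, replicate, seed) {
    tsne_fit(X, perplexity = perplexity, max_iter = max_iter, seed = seed)
  })
  grid$kl_divergence <- purrr::map_dbl(grid$fit, "kl_divergence")
  grid[c("perplexity", "replicate", "kl_divergence", "seed", "fit")]
}

#' Select the best replicate by KL divergence
#'
#' Among replicate fits at one perplexity, returns the fit with the
#' lowest final KL divergence (ties broken by lowest replicate index).
#'
#' @param fits A subset of [tsne_sweep()] rows, all at one perplexity.
#' @return The chosen `embedding_fit`, with its `replicate` attached.
#' @export
select_by_kl <- function(fits) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1,
            all(c("perplexity", "replicate", "kl_divergence", "fit") %in%
                  names(fits)))
  if (length(unique(fits$perplexity)) > 1) {
    abort("`fits` mixes several perplexities; select within one")
  }
  ord <- order(fits$kl_divergence, fits$replicate)
  best <- fits$fit[[ord[[1]]]]
  best$replicate <- fits$replicate[[ord[[1]]]]
  best
}

#' Davies-Bouldin index
#'
#' `DBI = (1/k) * sum_i max_{j != i} (sigma_i + sigma_j) / d(c_i, c_j)`,
#' where `c_i` is the Euclidean centroid of cluster i, `sigma_i` the mean
#' Euclidean distance of its members to the centroid, and `d` the
#' centroid distance. Lower is better.
#'
#' @param points A matrix or data frame of coordinates (e.g. the
#'   `coords` of an `embedding_fit`).
#' @param labels Cluster labels, one per point; at least 2 clusters.
#' @return The index (a single non-negative number).
#' @export
#' @examples
#' pts <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
#' davies_bouldin(pts, c("a", "a", "b", "b"))  # 0.2
davies_bouldin <- function(points, labels) {
  X <- as.matrix(as.data.frame(points))
  stopifnot(nrow(X) == length(labels))
  groups <- split(seq_len(nrow(X)), as.character(labels))
  k <- length(groups)
  if (k < 2) abort("at least 2 labelled clusters are required")
  cent <- t(vapply(groups, function(ix) colMeans(X[ix, , drop = FALSE]),
                   numeric(ncol(X))))
  sigma <- vapply(seq_len(k), function(i) {
    ix <- groups[[i]]
    mean(sqrt(rowSums((X[ix, , drop = FALSE] -
                         matrix(cent[i, ], length(ix), ncol(X),
                                byrow = TRUE))^2)))
  }, numeric(1))
  d <- as.matrix(dist(cent))
  if (any(d[upper.tri(d)] == 0)) {
    abort("two clusters have coincident centroids; DBI is undefined")
  }
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (sigma[[i]] + sigma[[j]]) / d[i, j]
    }, numeric(1)))
  }, numeric(1)))
}

#' Perplexity selection by KL divergence and Davies-Bouldin index
#'
#' The full embedding model-selection procedure: sweep perplexities with
#' replicate t-SNE fits, keep the lowest-KL replicate at each
#' perplexity, score each kept embedding with the Davies-Bouldin index
#' using the known labels, and choose the perplexity with the lowest
#' DBI. The complete audit trail (per-perplexity best replicate, KL and
#' DBI) is retained.
#'
#' @inheritParams tsne_sweep
#' @param labels Known class labels, one per cell.
#' @return An `embedding_selection`: `audit` tibble, `chosen_perplexity`,
#'   `chosen_fit`, `chosen_dbi` and the underlying `sweep`.
#' @export
select_perplexity <- function(profiles, labels,
                              perplexities = default_perplexities(),
                              n_replicates = 5, seed = NULL, max_iter = 500,
                              features = sers_integrins()) {
  X <- as_feature_matrix(profiles, features)
  stopifnot(length(labels) == nrow(X))
  sweep <- tsne_sweep(X, perplexities = perplexities,
                      n_replicates = n_replicates, seed = seed,
                      max_iter = max_iter)
  per_perp <- split(sweep, factor(sweep$perplexity, levels = perplexities))
  best <- purrr::map(per_perp, select_by_kl)
  audit <- purrr::map_dfr(best, function(fit) {
    tibble::tibble(perplexity = fit$perplexity,
                   best_replicate = fit$replicate,
                   kl_divergence = fit$kl_divergence,
                   dbi = davies_bouldin(fit$coords, labels))
  })
  chosen <- which.min(audit$dbi)
  structure(list(audit = audit,
                 chosen_perplexity = audit$perplexity[[chosen]],
                 chosen_fit = best[[chosen]],
                 chosen_dbi = audit$dbi[[chosen]],
                 labels = as.character(labels),
                 sweep = sweep),
            class = "embedding_selection")
}

#' @export
print.embedding_selection <- function(x, ...) {
  cat(sprintf("<embedding_selection> chosen perplexity = %g (DBI = %.4f) of %s\n",
              x$chosen_perplexity, x$chosen_dbi,
              paste(x$audit$perplexity, collapse = ", ")))
  invisible(x)
}

#' @rdname select_perplexity
#' @param x An `embedding_selection`.
#' @param ... Unused.
#' @exportS3Method
tidy.embedding_selection <- function(x, ...) x$audit

#' @rdname select_perplexity
#' @exportS3Method
glance.embedding_selection <- function(x, ...) {
  tibble::tibble(chosen_perplexity = x$chosen_perplexity,
                 chosen_dbi = x$chosen_dbi,
                 n_fits = nrow(x$sweep))
}

#' @exportS3Method
autoplot.embedding_selection <- function(object, ...) {
  autoplot(object$chosen_fit, labels = object$labels) +
    ggplot2::ggtitle(sprintf("perplexity %g (DBI %.3f)",
                             object$chosen_perplexity, object$chosen_dbi))
}
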