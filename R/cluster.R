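#' Horizontal-band initialization for echogram clustering
#'
#' Splits the depth bins into `k` contiguous horizontal bands of (near)
#' equal thickness, any remainder going to the deepest band, and computes
#' each band's mean spectrum in linear scale. This encodes the hypothesis
#' that scattering layers are stratified vertically.
#'
#' @param grid An [echogram_grid()].
#' @param k Number of bands (<= number of depth bins).
#' @return List with `assignment` (band id per depth bin) and `means`
#'   (k x n_freq matrix, dB).
#' @export
init_horizontal_bands <- function(grid, k) {
  stopifnot(inherits(grid, "echogram_grid"))
  if (k < 1) stop("'k' must be at least 1")
  if (k > grid$n_depth)
    stop("'k' exceeds the number of depth bins")
  base <- grid$n_depth %/% k
  sizes <- rep(base, k)
  sizes[k] <- grid$n_depth - base * (k - 1)
  assignment <- rep(seq_len(k), times = sizes)
  means <- t(vapply(seq_len(k), function(g) {
    sub <- grid$sv[, assignment == g, , drop = FALSE]
    lin <- apply(db_to_linear(sub), 3, mean)
    linear_to_db(lin)
  }, numeric(length(grid$frequencies))))
  list(assignment = assignment, means = means)
}

# direct diagonal-Gaussian MLE for the single-cluster case
single_cluster_fit <- function(x) {
  n <- nrow(x); d <- ncol(x)
  mu <- colMeans(x)
  v <- pmax(apply(x, 2, function(c) mean((c - mean(c))^2)), 1e-12)
  ll <- -0.5 * n * (d * log(2 * pi) + sum(log(v))) -
    0.5 * sum(sweep(sweep(x, 2, mu)^2, 2, v, "/"))
  list(z = matrix(1, n, 1), loglik = ll, df = 2 * d)
}

#' EM clustering of echo-integration cells
#'
#' Gaussian-mixture (diagonal covariance) expectation-maximization on the
#' standardized per-cell spectra, deterministically initialized from the
#' horizontal-band stratification ([init_horizontal_bands()]): each cell
#' starts fully assigned to its depth band and the first M-step recovers the
#' band means. Per-cluster median Sv spectra with 25/75% quantile bands are
#' computed from the raw (unstandardized) spectra; standardization is used
#' only for the feature space.
#'
#' @param grid An [echogram_grid()].
#' @param k Number of clusters.
#' @param bands A [transducer_bands()] object (feature-space definition).
#' @param include_cw Keep CW points in the feature space (default `TRUE`).
#' @param init Optional depth-bin band assignment (integer vector in `1..k`)
#'   overriding the equal-band initialization.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An object of class `"ssl_clusters"`: `k`, `labels` (ping x depth
#'   matrix), `z` (responsibilities), `means` (cluster means in feature
#'   space, dB), `medians` (per-cluster list with `frequencies`, `q25`,
#'   `q50`, `q75` from raw spectra), `loglik`, `df`, `bic` (the
#'   `-2 logL + df log n` form, smaller is better), `feature_frequencies`.
#' @export
em_cluster <- function(grid, k, bands = transducer_bands(),
                       include_cw = TRUE, init = NULL, tol = 1e-6,
                       max_iter = 500) {
  feats <- cluster_features(grid, bands, include_cw)
  x <- feats$features
  n <- nrow(x); d <- ncol(x)
  if (k > n) stop("'k' exceeds the number of cells")
  if (is.null(init)) {
    init <- init_horizontal_bands(grid, k)$assignment
  } else if (length(init) != grid$n_depth || !all(init %in% seq_len(k))) {
    stop("'init' must assign every depth bin to a band in 1..k")
  }
  cell_band <- rep(init, each = grid$n_ping)

  if (k == 1) {
    fit <- single_cluster_fit(x)
  } else {
    z0 <- matrix(0, n, k)
    z0[cbind(seq_len(n), cell_band)] <- 1
    fit <- mclust::meVVI(data = x, z = z0,
                         control = mclust::emControl(tol = tol,
                                                     itmax = max_iter))
    if (is.null(fit$z) || any(!is.finite(fit$z)) ||
        any(colSums(fit$z) < 0.5)) {
      # empty/degenerate cluster: re-seed it from the cells farthest from
      # their current centres and restart once
      message("em_cluster: degenerate cluster; re-seeding from farthest cells")
      mu0 <- t(vapply(seq_len(k), function(g)
        colMeans(x[cell_band == g, , drop = FALSE]),
        numeric(d)))
      dist2 <- vapply(seq_len(n), function(i)
        min(rowSums((mu0 - matrix(x[i, ], k, d, byrow = TRUE))^2)),
        numeric(1))
      far <- order(dist2, decreasing = TRUE)[seq_len(k)]
      z0 <- matrix(1 / k, n, k)
      z0[far, ] <- diag(k) * 0.9 + 0.1 / k
      z0 <- z0 / rowSums(z0)
      fit <- mclust::meVVI(data = x, z = z0,
                           control = mclust::emControl(tol = tol,
                                                       itmax = max_iter))
    }
    fit$df <- (k - 1) + k * d + mclust::nVarParams("VVI", d = d, G = k)
  }
  labels_vec <- apply(fit$z, 1, which.max)
  labels <- matrix(labels_vec, grid$n_ping, grid$n_depth)
  raw <- cell_matrix(grid)
  medians <- lapply(seq_len(k), function(g) {
    sub <- raw[labels_vec == g, , drop = FALSE]
    qs <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE)
    list(frequencies = grid$frequencies, q25 = qs[1, ], q50 = qs[2, ],
         q75 = qs[3, ], n_cells = nrow(sub))
  })
  means <- if (k == 1) matrix(colMeans(x), 1, d) else t(fit$parameters$mean)
  bic <- -2 * fit$loglik + fit$df * log(n)
  structure(list(k = k, labels = labels, z = fit$z, means = means,
                 medians = medians, loglik = fit$loglik, df = fit$df,
                 bic = bic, feature_frequencies = feats$frequencies),
            class = "ssl_clusters")
}

#' @export
print.ssl_clusters <- function(x, ...) {
  sizes <- vapply(x$medians, `[[`, numeric(1), "n_cells")
  cat(sprintf("EM segmentation: k = %d clusters (sizes %s), BIC = %.1f\n",
              x$k, paste(sizes, collapse = "/"), x$bic))
  invisible(x)
}

cluster_separation <- function(fit) {
  if (fit$k < 2) return(Inf)
  dmin <- Inf
  for (i in seq_len(fit$k - 1))
    for (j in seq(i + 1, fit$k))
      dmin <- min(dmin, max(abs(fit$means[i, ] - fit$means[j, ])))
  dmin
}

pooled_within_sd <- function(fit, feats) {
  lab <- as.vector(fit$labels)
  v <- unlist(lapply(seq_len(fit$k), function(g) {
    sub <- feats[lab == g, , drop = FALSE]
    if (nrow(sub) < 2) return(NULL)
    apply(sub, 2, stats::var)
  }))
  sqrt(mean(v))
}

#' Choose the number of clusters by spectral-shape diversity
#'
#' Runs [em_cluster()] over a range of `k` and selects the largest `k`
#' whose fitted cluster mean spectra are all pairwise distinct: every pair
#' must differ, at some feature frequency, by more than `sep_factor` times
#' the pooled within-cluster standard deviation. If no candidate qualifies
#' (a homogeneous grid), the smallest `k` in range is returned. This
#' operationalizes the segmentation rule of maximizing the diversity of
#' spectral shapes while minimizing the number of clusters: extra clusters
#' that only re-partition cell noise produce near-identical mean shapes and
#' are rejected. BIC is reported in the trace for reference but is not used
#' for the choice: on high-dimensional standardized spectra its penalty is
#' too weak against the common-mode noise that standardization induces, and
#' it systematically over-segments.
#'
#' @param grid An [echogram_grid()].
#' @param k_range Candidate cluster counts (default `2:5`).
#' @param sep_factor Multiple of the within-cluster SD that cluster mean
#'   shapes must exceed to count as distinct (default 2).
#' @param ... Passed to [em_cluster()].
#' @return List with `k` (the selected count), `trace` (data.frame of k,
#'   loglik, df, BIC, min_separation, within_sd, distinct) and `models`
#'   (the fitted `"ssl_clusters"` objects).
#' @export
select_k <- function(grid, k_range = 2:5, sep_factor = 2, ...) {
  fits <- lapply(k_range, function(k) em_cluster(grid, k, ...))
  feats <- cluster_features(grid)$features
  sep <- vapply(fits, cluster_separation, numeric(1))
  wsd <- vapply(fits, pooled_within_sd, numeric(1), feats = feats)
  distinct <- sep >= sep_factor * wsd
  trace <- data.frame(k = k_range,
                      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                      df = vapply(fits, `[[`, numeric(1), "df"),
                      bic = vapply(fits, `[[`, numeric(1), "bic"),
                      min_separation = sep, within_sd = wsd,
                      distinct = distinct)
  best <- if (any(distinct)) max(k_range[distinct]) else min(k_range)
  list(k = best, trace = trace,
       models = stats::setNames(fits, paste0("k", k_range)))
}
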