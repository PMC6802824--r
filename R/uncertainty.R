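#' Prior distribution for a scattering-model parameter
#'
#' Normal or lognormal prior used in the uncertainty analysis. For the
#' lognormal, `mu` and `sd` are the mean and SD on the log scale.
#'
#' @param name Parameter name; must match a tunable parameter of the model it
#'   will be propagated through (e.g. `"viscosity"`, `"g"`, `"R"`).
#' @param kind `"normal"` or `"lognormal"`.
#' @param mu Location (normal: mean; lognormal: log-scale mean).
#' @param sd Scale (same convention); non-negative, 0 meaning a point mass.
#' @param reference Optional reference (point-estimate) value.
#' @return An object of class `"param_dist"`.
#' @export
param_dist <- function(name, kind = c("normal", "lognormal"), mu, sd,
                       reference = NULL) {
  kind <- match.arg(kind)
  if (sd < 0) stop("'sd' must be non-negative")
  structure(list(name = name, kind = kind, mu = mu, sd = sd,
                 reference = reference),
            class = "param_dist")
}

# Tail-quantile convention: the 5% / 95% normal deviate is the rounded
# constant 1.645 used when intervals are reported; all other probabilities
# use the exact normal quantile.
z_tail <- function(p) {
  z <- stats::qnorm(p)
  z[abs(p - 0.05) < 1e-12] <- -1.645
  z[abs(p - 0.95) < 1e-12] <- 1.645
  z
}

#' Analytic quantiles of a parameter prior
#'
#' Exact analytic quantiles: `mu + z_q * sd` for the normal,
#' `exp(mu + z_q * sd)` for the lognormal. The 5% and 95% quantiles use the
#' conventional deviate 1.645, so reported intervals match tabulated
#' median / CI(0.05-0.95) values.
#'
#' @param x A [param_dist()].
#' @param probs Probabilities in (0, 1).
#' @param ... Unused.
#' @return Numeric vector of quantiles.
#' @examples
#' quantile(param_dist("viscosity", "lognormal", -2.3, 1), 0.5)  # 0.100
#' @export
quantile.param_dist <- function(x, probs = c(0.05, 0.5, 0.95), ...) {
  if (any(probs <= 0 | probs >= 1))
    stop("'probs' must lie strictly inside (0, 1)")
  q <- x$mu + z_tail(probs) * x$sd
  if (x$kind == "lognormal") q <- exp(q)
  q
}

#' Median and 5-95% interval of a prior, rounded half-up
#'
#' @param x A [param_dist()].
#' @param digits Decimal places for half-up rounding (default `NULL`: no
#'   rounding).
#' @return Named vector `c(q05, median, q95)`.
#' @export
prior_interval <- function(x, digits = NULL) {
  v <- quantile(x, c(0.05, 0.5, 0.95))
  if (!is.null(digits)) v <- round_half_up(v, digits)
  stats::setNames(v, c("q05", "median", "q95"))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' printed parameter tables, unlike R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# inverse-CDF transform of uniform draws (full-precision quantiles)
dist_transform <- function(dist, u) {
  switch(dist$kind,
         normal = stats::qnorm(u, dist$mu, dist$sd),
         lognormal = stats::qlnorm(u, dist$mu, dist$sd))
}

#' Latin hypercube sample of parameter priors
#'
#' Stratified inverse-CDF sampling: for each parameter, exactly one draw
#' falls in each probability stratum `[(i-1)/n, i/n)`, and strata are paired
#' randomly across parameters. Reproducible given `seed`.
#'
#' @param dists Named list of [param_dist()] objects (names default to each
#'   distribution's `name`).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed (required: every stochastic stage logs its seed).
#' @return An object of class `"lhs_design"`: list with `n`, `params`,
#'   `probs` (n x p uniform strata draws), `draws` (n x p parameter values)
#'   and `seed`.
#' @export
lhs_sample <- function(dists, n, seed) {
  if (n < 1) stop("'n' must be at least 1")
  if (missing(seed)) stop("'seed' is required")
  if (is.null(names(dists)) || any(!nzchar(names(dists))))
    names(dists) <- vapply(dists, `[[`, character(1), "name")
  set.seed(seed)
  u <- lhs::randomLHS(as.integer(n), length(dists))
  draws <- vapply(seq_along(dists),
                  function(j) dist_transform(dists[[j]], u[, j]),
                  numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, names(dists)))
  colnames(u) <- names(dists)
  structure(list(n = n, params = names(dists), probs = u, draws = draws,
                 seed = seed),
            class = "lhs_design")
}

# tunable (sampleable) parameters per scattering model
model_tunables <- list(
  fluid_like = c("g", "h", "length_to_radius"),
  elastic_shell = "R",
  gas_bearing = c("length_to_width_ratio", "viscosity", "surface_tension"))

eval_model_sigma <- function(model, pars, length_mm, medium, frequencies) {
  sp <- switch(model,
    fluid_like = ts_fluid_like(length_mm, do.call(fluid_params, pars),
                               medium, frequencies),
    elastic_shell = ts_elastic_shell(length_mm * pars$radius_fraction,
                                     elastic_params(pars$R), medium,
                                     frequencies),
    gas_bearing = ts_gas_bearing(length_mm,
                                 gas_params(pars$length_to_width_ratio,
                                            pars$viscosity,
                                            pars$surface_tension),
                                 medium, frequencies))
  db_to_linear(sp$ts)
}

clamp_draws <- function(model, draws) {
  cl <- draws
  if ("length_to_width_ratio" %in% colnames(cl))
    cl[, "length_to_width_ratio"] <- pmax(cl[, "length_to_width_ratio"], 1)
  if ("length_to_radius" %in% colnames(cl))
    cl[, "length_to_radius"] <- pmax(cl[, "length_to_radius"], 1e-3)
  for (nm in intersect(c("g", "h", "viscosity", "surface_tension"),
                       colnames(cl)))
    cl[, nm] <- pmax(cl[, nm], 1e-9)
  if ("R" %in% colnames(cl))
    cl[, "R"] <- pmin(pmax(cl[, "R"], 0), 1)
  cl
}

#' Predictive envelope of a TS spectrum under parameter uncertainty
#'
#' Propagates the parameter priors through a scattering model by Latin
#' hypercube sampling: for each length class, `n` TS spectra are evaluated at
#' the sampled parameter values, and the per-frequency 5%, 50% and 95%
#' quantiles of the simulated cross sections are taken in linear scale, then
#' converted to dB. Lengths are treated as measured and are never sampled;
#' for fluid-like models the orientation distribution is part of the model
#' itself and is likewise not sampled.
#'
#' @param model One of `"gas_bearing"`, `"fluid_like"`, `"elastic_shell"`.
#' @param dists Named list of [param_dist()] priors; every name must be a
#'   tunable parameter of `model`, otherwise a hard error is raised.
#' @param lengths Length classes (mm).
#' @param medium A [medium()] object.
#' @param frequencies Frequency grid (kHz).
#' @param n Simulations per length class (default 1000).
#' @param seed Integer seed (required).
#' @param base Named list of fixed model parameters completing the model
#'   (values for tunables not being sampled, orientation parameters, the
#'   elastic `radius_fraction`, ...).
#' @return An object of class `"ts_envelope"`: list of per-length envelopes,
#'   each with `length`, `frequencies`, `q05`, `q50`, `q95` (dB), plus the
#'   design metadata (`seed`, `n`).
#' @export
ts_envelope <- function(model = c("gas_bearing", "fluid_like",
                                  "elastic_shell"),
                        dists, lengths, medium = sslspectra::medium(),
                        frequencies, n = 1000, seed, base = list()) {
  model <- match.arg(model)
  if (is.null(names(dists)) || any(!nzchar(names(dists))))
    names(dists) <- vapply(dists, `[[`, character(1), "name")
  unknown <- setdiff(names(dists), model_tunables[[model]])
  if (length(unknown))
    stop(sprintf("prior(s) %s do not match any tunable parameter of the %s model",
                 paste0("'", unknown, "'", collapse = ", "), model))
  design <- lhs_sample(dists, n, seed)
  draws <- clamp_draws(model, design$draws)
  defaults <- switch(model,
    fluid_like = list(orientation_mean = 0, orientation_sd = 0,
                      shape = "bent_cylinder"),
    elastic_shell = list(radius_fraction = 0.5),
    gas_bearing = list())
  base <- utils::modifyList(defaults, base)
  envs <- lapply(lengths, function(len) {
    sig <- matrix(NA_real_, n, length(frequencies))
    for (i in seq_len(n)) {
      pars <- utils::modifyList(base, as.list(draws[i, , drop = TRUE]))
      sig[i, ] <- eval_model_sigma(model, pars, len, medium, frequencies)
    }
    qs <- apply(sig, 2, stats::quantile, probs = c(0.05, 0.5, 0.95),
                names = FALSE)
    list(length = len, frequencies = frequencies,
         q05 = linear_to_db(qs[1, ]), q50 = linear_to_db(qs[2, ]),
         q95 = linear_to_db(qs[3, ]))
  })
  structure(list(envelopes = envs, model = model, n = n, seed = seed,
                 params = names(dists)),
            class = "ts_envelope")
}

#' @export
print.ts_envelope <- function(x, ...) {
  cat(sprintf("TS envelope: %s model, %d length class(es), n = %d, seed = %d\n",
              x$model, length(x$envelopes), x$n, x$seed))
  invisible(x)
}

#' Write envelope quantiles to CSV
#'
#' One row per frequency and length class with `q05`, `q50`, `q95` columns.
#'
#' @param envelope A [ts_envelope()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  rows <- do.call(rbind, lapply(envelope$envelopes, function(e)
    data.frame(length_mm = e$length, frequency_khz = e$frequencies,
               q05 = e$q05, q50 = e$q50, q95 = e$q95)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
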