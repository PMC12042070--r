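#' @importFrom stats median quantile qnorm pnorm uniroot coef lm sd var cov cor
NULL

# taxon groups with density (Damuth-law) scaling data
PREY_GROUPS <- c("prokaryote", "protist", "invertebrate",
                 "ectotherm vertebrate", "mammal", "bird")
# taxon groups with metabolic (Kleiber-law) scaling data
PREDATOR_GROUPS <- c("protist", "invertebrate", "ectotherm vertebrate",
                     "mammal", "bird")

.jags_loglog_model <- "model {
  for (i in 1:N) {
    y[i] ~ dnorm(alpha + beta * x[i], tau)
  }
  alpha ~ dnorm(0, 1.0E-6)
  beta  ~ dnorm(0, 1.0E-6)
  sigma ~ dt(0, pow(2.5, -2), 3) T(0,)
  tau <- pow(sigma, -2)
}"

#' Fit a Bayesian log-log mass-scaling law
#'
#' Fits the model \eqn{\log_{10} y \sim N(\alpha + \beta \log_{10} x,
#' \sigma)} by MCMC (JAGS), with effectively flat normal priors on the
#' intercept and slope and a half-Student-t prior (df = 3, location 0,
#' scale 2.5) on the residual standard deviation. Defaults follow the
#' standard 4 chains x 1000 post-warmup draws after 1000 warmup iterations.
#' This is the workhorse for both Damuth-law (density on mass) and
#' Kleiber-law (metabolic rate on mass) fits.
#'
#' @param mass Positive masses, g.
#' @param response Positive response values (individuals/m^2 for density
#'   laws, kJ/day for metabolic laws).
#' @param group Optional taxon-group label stored with the fit.
#' @param chains,iter,warmup MCMC settings: number of chains, post-warmup
#'   draws per chain, warmup (adaptation + burn-in) iterations.
#' @param seed Integer seed; chain c uses RNG seed `seed + c`.
#' @return An object of class `scaling_law`: list with `group`, `intercept`,
#'   `slope`, `sigma` (posterior medians), `draws` (data.frame of posterior
#'   samples of `intercept`, `slope`, `sigma`), and `n_obs`.
#' @seealso [scaling_law()] for a deterministic plug-in law,
#'   [posterior_predictive_quantile()], [predict_median_demand()].
#' @export
fit_loglog <- function(mass, response, group = NULL,
                       chains = 4, iter = 1000, warmup = 1000, seed = 1L) {
  if (!is.numeric(mass) || !is.numeric(response)) {
    stop("mass and response must be numeric", call. = FALSE)
  }
  if (length(mass) != length(response)) {
    stop("mass and response must have the same length", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(!is.finite(response)) ||
      any(mass <= 0) || any(response <= 0)) {
    stop("mass and response must be finite and strictly positive", call. = FALSE)
  }
  if (length(mass) < 3) stop("need at least 3 observations to fit a scaling law", call. = FALSE)

  x <- log10(mass)
  y <- log10(response)
  ols <- stats::lm.fit(cbind(1, x), y)
  res_sd <- stats::sd(ols$residuals)
  if (!is.finite(res_sd) || res_sd < 1e-8) res_sd <- 1e-3  # near-noiseless data

  inits <- lapply(seq_len(chains), function(cc) {
    list(alpha = unname(ols$coefficients[1]),
         beta = unname(ols$coefficients[2]),
         sigma = res_sd,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + cc))
  })
  model <- rjags::jags.model(textConnection(.jags_loglog_model),
                             data = list(x = x, y = y, N = length(x)),
                             n.chains = chains, inits = inits,
                             n.adapt = max(100L, warmup %/% 2L), quiet = TRUE)
  stats::update(model, n.iter = max(0L, warmup - max(100L, warmup %/% 2L)),
                progress.bar = "none")
  samp <- rjags::coda.samples(model, c("alpha", "beta", "sigma"),
                              n.iter = iter, progress.bar = "none")
  draws <- as.data.frame(do.call(rbind, lapply(samp, unclass)))
  names(draws) <- c("intercept", "slope", "sigma")
  structure(list(group = group,
                 intercept = stats::median(draws$intercept),
                 slope = stats::median(draws$slope),
                 sigma = stats::median(draws$sigma),
                 draws = draws,
                 n_obs = length(x)),
            class = "scaling_law")
}

#' Construct a plug-in (deterministic) scaling law
#'
#' Builds a `scaling_law` with a single posterior draw at the given
#' parameters. Useful for closed-form checks and for running the prediction
#' pipeline with known generating laws: with a single draw, posterior
#' predictive quantiles reduce to the exact lognormal quantile
#' \eqn{10^{\alpha + \beta \log_{10} m + \sigma z_q}}.
#'
#' @param intercept Intercept \eqn{\alpha}, log10 response units at 1 g.
#' @param slope Scaling exponent \eqn{\beta}.
#' @param sigma Residual SD on the log10 scale; >= 0.
#' @param group Optional group label.
#' @return A `scaling_law`.
#' @export
scaling_law <- function(intercept, slope, sigma = 0, group = NULL) {
  stopifnot(is.numeric(intercept), is.numeric(slope), is.numeric(sigma),
            length(intercept) == 1, length(slope) == 1, length(sigma) == 1,
            is.finite(intercept), is.finite(slope), is.finite(sigma), sigma >= 0)
  structure(list(group = group, intercept = intercept, slope = slope,
                 sigma = sigma,
                 draws = data.frame(intercept = intercept, slope = slope,
                                    sigma = sigma),
                 n_obs = NA_integer_),
            class = "scaling_law")
}

#' @export
print.scaling_law <- function(x, ...) {
  cat("<scaling_law>", if (!is.null(x$group)) paste0(" [", x$group, "]"), "\n", sep = "")
  cat(sprintf("  log10(y) = %.3f %+.3f * log10(mass),  sigma = %.3f (log10 units)\n",
              x$intercept, x$slope, x$sigma))
  cat(sprintf("  %d posterior draw(s), n_obs = %s\n", nrow(x$draws),
              format(x$n_obs)))
  invisible(x)
}

.check_law <- function(law) {
  if (!inherits(law, "scaling_law")) stop("expected a 'scaling_law' object", call. = FALSE)
  if (is.null(law$draws) || nrow(law$draws) == 0) {
    stop("scaling law has no posterior draws; fit it first", call. = FALSE)
  }
}

#' Posterior-predictive quantile of a scaling law
#'
#' The posterior predictive distribution at mass m is the mixture over
#' posterior draws \eqn{(\alpha_i, \beta_i, \sigma_i)} of
#' \eqn{N(\alpha_i + \beta_i \log_{10} m, \sigma_i)} on the log10 scale. The
#' q-quantile is found as the root of the mixture CDF (deterministic; no
#' Monte Carlo resampling) and back-transformed to natural units. With a
#' single draw this reduces to the exact lognormal quantile. Since
#' \eqn{10^x} is monotone, quantiles computed on the log scale and
#' back-transformed equal quantiles of the back-transformed distribution.
#'
#' Low and high prey densities are obtained as the 0.10 and 0.90 predictive
#' quantiles of the prey group's density law evaluated at the prey mass.
#'
#' @param law A fitted [fit_loglog()] or plug-in [scaling_law()].
#' @param mass Positive mass (vectorised), g.
#' @param q Quantile level, a single number strictly in (0, 1).
#' @return Predictive quantile(s) in natural response units.
#' @export
posterior_predictive_quantile <- function(law, mass, q) {
  .check_law(law)
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    stop("q must be a single value strictly in (0, 1)", call. = FALSE)
  }
  d <- law$draws
  lm10 <- log10(mass)
  if (nrow(d) == 1L) {
    return(10^(d$intercept + d$slope * lm10 + d$sigma * stats::qnorm(q)))
  }
  z <- stats::qnorm(q)
  a <- d$intercept; b <- d$slope; s <- d$sigma
  vapply(lm10, function(lm) {
    mu <- a + b * lm
    lo <- min(mu + s * z)
    hi <- max(mu + s * z)
    if (hi - lo < 1e-14) return(10^lo)
    f <- function(t) mean(stats::pnorm(t, mean = mu, sd = s)) - q
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-10 * max(1, abs(hi)))$root
    10^root
  }, numeric(1))
}

#' Posterior-predictive median demand at a predator mass
#'
#' The point estimate of predator energetic demand D used by the prediction
#' pipeline: the median of the posterior predictive distribution of the
#' metabolic-rate scaling law at the predator's mass.
#'
#' @param law A metabolic `scaling_law` (kJ/day on mass in g).
#' @param predator_mass Positive mass (vectorised), g.
#' @return Median predicted metabolic rate, kJ/day.
#' @export
predict_median_demand <- function(law, predator_mass) {
  posterior_predictive_quantile(law, predator_mass, 0.5)
}

#' Read a mass-scaling table
#'
#' Expects a CSV with columns `group`, `mass_g`, `response_value`,
#' `response_type`, where `response_type` is `density_per_m2` (individuals
#' per aerial m^2) or `metabolic_kj_per_day`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the four columns, types checked.
#' @export
read_scaling_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "mass_g", "response_value", "response_type")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("scaling table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(tbl$response_type),
                      c("density_per_m2", "metabolic_kj_per_day"))
  if (length(bad_type)) {
    stop("unknown response_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(tbl[need])
}

#' Fit one scaling law per taxon group
#'
#' Splits a mass-scaling table by group for the requested response type and
#' fits [fit_loglog()] to each. Group labels are validated against the taxon
#' sets with known scaling data: density laws for prokaryotes, protists,
#' invertebrates, ectotherm vertebrates, mammals and birds; metabolic laws
#' for the same set minus prokaryotes. An unknown label is an error (no
#' fallback law is ever substituted).
#'
#' @param table A data frame as returned by [read_scaling_table()] (or the
#'   generator).
#' @param response_type `"density_per_m2"` or `"metabolic_kj_per_day"`.
#' @param ... Passed to [fit_loglog()] (`chains`, `iter`, `warmup`).
#' @param seed Integer seed; group g (in sorted order) uses `seed + 100*g`.
#' @return Named list of `scaling_law` objects, one per group present.
#' @export
fit_scaling_laws <- function(table, response_type = c("density_per_m2",
                                                      "metabolic_kj_per_day"),
                             ..., seed = 1L) {
  response_type <- match.arg(response_type)
  allowed <- if (response_type == "density_per_m2") PREY_GROUPS else PREDATOR_GROUPS
  sub <- table[table$response_type == response_type, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows with response_type '", response_type, "'", call. = FALSE)
  groups <- sort(unique(sub$group))
  unknown <- setdiff(groups, allowed)
  if (length(unknown)) {
    stop("no ", response_type, " scaling law is defined for group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  laws <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    rows <- sub[sub$group == g, ]
    fit_loglog(rows$mass_g, rows$response_value, group = g,
               seed = seed + 100L * i, ...)
  })
  names(laws) <- groups
  laws
}

#' Summarise a set of fitted scaling laws
#'
#' @param laws Named list of `scaling_law` objects.
#' @return A tibble with one row per law: group, posterior medians of
#'   intercept, slope and sigma, 95% credible bounds for the slope, and the
#'   number of observations.
#' @export
summarize_scaling_laws <- function(laws) {
  rows <- lapply(names(laws), function(g) {
    law <- laws[[g]]
    qs <- stats::quantile(law$draws$slope, c(0.025, 0.975), names = FALSE)
    qi <- stats::quantile(law$draws$intercept, c(0.025, 0.975), names = FALSE)
    tibble::tibble(group = g, intercept = law$intercept,
                   intercept_lo = qi[1], intercept_hi = qi[2],
                   slope = law$slope, slope_lo = qs[1], slope_hi = qs[2],
                   sigma = law$sigma, n_obs = law$n_obs)
  })
  do.call(rbind, rows)
}
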