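#' Read a functional-response experiment table
#'
#' Expects a CSV with the experiment-record schema used throughout the
#' pipeline: `study_id`, `predator_group`, `prey_group`, `predator_mass_g`,
#' `prey_mass_g`, `observed_a` (m^2/day), `observed_h` (days),
#' `prey_is_egg`, `prey_is_living`, `is_field_study`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the schema columns.
#' @export
read_forage_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(.check_forage_schema(tbl))
}

.forage_cols <- c("study_id", "predator_group", "prey_group",
                  "predator_mass_g", "prey_mass_g", "observed_a",
                  "observed_h", "prey_is_egg", "prey_is_living",
                  "is_field_study")

.check_forage_schema <- function(records) {
  missing_cols <- setdiff(.forage_cols, names(records))
  if (length(missing_cols)) {
    stop("experiment table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records
}

#' Apply the study exclusion filters
#'
#' Retains experiments that (i) used living, non-egg prey (mass-scaling laws
#' are not expected to apply to eggs), (ii) have handling time estimates
#' greater than 1e-6 days (smaller values flag poor type II fits), and
#' (iii) report both predator and prey masses (required to join the mass
#' scaling laws). A record failing several rules is attributed to the first
#' failing rule in that order; counts of records failing each rule
#' regardless of order are reported alongside. Filtering is idempotent.
#'
#' @param records Experiment-record data frame (see [read_forage_table()]).
#' @param handling_floor_days Exclusion threshold for handling time
#'   (default 1e-6 days).
#' @return List with `records` (retained rows), `log` (tibble: rule,
#'   n_excluded by first-match attribution, n_failing by any-match), and
#'   `n_retained`.
#' @export
apply_exclusion_filters <- function(records, handling_floor_days = 1e-6) {
  .check_forage_schema(records)
  if (nrow(records) == 0) {
    return(list(records = records,
                log = tibble::tibble(
                  rule = c("egg_or_nonliving_prey", "handling_time_floor",
                           "missing_mass"),
                  n_excluded = 0L, n_failing = 0L),
                n_retained = 0L))
  }
  fail_egg <- records$prey_is_egg | !records$prey_is_living
  fail_h <- !is.na(records$observed_h) & records$observed_h <= handling_floor_days
  fail_mass <- is.na(records$predator_mass_g) | is.na(records$prey_mass_g)
  fail_egg[is.na(fail_egg)] <- TRUE
  fail_h[is.na(records$observed_h)] <- TRUE
  drop <- fail_egg | fail_h | fail_mass
  first <- ifelse(fail_egg, "egg_or_nonliving_prey",
                  ifelse(fail_h, "handling_time_floor",
                         ifelse(fail_mass, "missing_mass", NA)))
  rules <- c("egg_or_nonliving_prey", "handling_time_floor", "missing_mass")
  log <- tibble::tibble(
    rule = rules,
    n_excluded = vapply(rules, function(r) sum(first == r, na.rm = TRUE),
                        integer(1), USE.NAMES = FALSE),
    n_failing = c(sum(fail_egg), sum(fail_h), sum(fail_mass)))
  list(records = records[!drop, , drop = FALSE], log = log,
       n_retained = sum(!drop))
}

#' Predict functional-response parameters for every experiment
#'
#' For each record, assembles an [energetic_context()] from the fitted
#' scaling laws — low and high prey densities as the `q_low`/`q_high`
#' posterior-predictive quantiles of the prey group's density law at the
#' prey mass, demand as the posterior-predictive median of the predator
#' group's metabolic law at the predator mass — and evaluates the two-rules
#' predictions. The full context is carried in the output for audit:
#' `demand_check()` on any row reproduces its `D` column.
#'
#' @param records Filtered experiment records (no missing masses).
#' @param density_laws Named list of density `scaling_law`s keyed by prey
#'   group.
#' @param demand_laws Named list of metabolic `scaling_law`s keyed by
#'   predator group.
#' @param E Prey energy density, kJ/g (default 5.6 kJ/g wet weight).
#' @param IS Degree of saturation at high prey density (default 0.9).
#' @param q_low,q_high Predictive quantiles defining the low and high prey
#'   densities (defaults 0.10 and 0.90).
#' @param assimilation Optional efficiency multiplier on `E` (default 1).
#' @return A predictions tibble: `study_id`, groups, `MP`, `MN`, `Nlow`,
#'   `Nhigh`, `D`, `E`, `IS`, `a_pred`, `h_pred`, `a_obs`, `h_obs`, and the
#'   low-density linearity diagnostic `ah_Nlow`.
#' @export
predict_all <- function(records, density_laws, demand_laws,
                        E = 5.6, IS = 0.9, q_low = 0.10, q_high = 0.90,
                        assimilation = 1) {
  .check_forage_schema(records)
  if (nrow(records) == 0) stop("no records to predict", call. = FALSE)
  if (any(is.na(records$predator_mass_g)) || any(is.na(records$prey_mass_g))) {
    stop("records contain missing masses; run apply_exclusion_filters() first",
         call. = FALSE)
  }
  miss_prey <- setdiff(unique(records$prey_group), names(density_laws))
  if (length(miss_prey)) {
    stop("no fitted density law for prey group(s): ",
         paste(miss_prey, collapse = ", "), call. = FALSE)
  }
  miss_pred <- setdiff(unique(records$predator_group), names(demand_laws))
  if (length(miss_pred)) {
    stop("no fitted demand law for predator group(s): ",
         paste(miss_pred, collapse = ", "), call. = FALSE)
  }

  n <- nrow(records)
  Nlow <- Nhigh <- D <- numeric(n)
  for (g in unique(records$prey_group)) {
    i <- records$prey_group == g
    Nlow[i] <- posterior_predictive_quantile(density_laws[[g]],
                                             records$prey_mass_g[i], q_low)
    Nhigh[i] <- posterior_predictive_quantile(density_laws[[g]],
                                              records$prey_mass_g[i], q_high)
  }
  for (g in unique(records$predator_group)) {
    i <- records$predator_group == g
    D[i] <- predict_median_demand(demand_laws[[g]], records$predator_mass_g[i])
  }
  ctx <- energetic_context(D, E, records$prey_mass_g, Nlow, Nhigh, IS,
                           assimilation = assimilation)
  fr <- predict_functional_response(ctx)
  tibble::tibble(
    study_id = records$study_id,
    predator_group = records$predator_group,
    prey_group = records$prey_group,
    MP = records$predator_mass_g, MN = records$prey_mass_g,
    Nlow = Nlow, Nhigh = Nhigh, D = D, E = E, IS = IS,
    a_pred = fr$a, h_pred = fr$h,
    a_obs = records$observed_a, h_obs = records$observed_h,
    ah_Nlow = low_density_linearity(fr, ctx))
}

.fit_m2 <- function(x, y, method) {
  switch(method, RMA = fit_rma(x, y), MA = fit_major_axis(x, y))
}

#' Compare observed and predicted functional-response parameters
#'
#' Model II regressions of log10 observed on log10 predicted values, for the
#' space clearance rate and the handling time separately. Reduced major axis
#' is the default for this comparison; major axis is available via `method`.
#'
#' @param predictions Output of [predict_all()].
#' @param method `"RMA"` (default) or `"MA"`.
#' @return List with elements `a` and `h`, each a `model2_fit` (slope,
#'   intercept, 95% CIs, correlation, R^2 about the 1:1 line) on the log10
#'   scale.
#' @export
compare_observed_predicted <- function(predictions, method = c("RMA", "MA")) {
  method <- match.arg(method)
  ok <- with(predictions, a_pred > 0 & a_obs > 0 & h_pred > 0 & h_obs > 0)
  p <- predictions[ok, , drop = FALSE]
  if (nrow(p) < 3) stop("need at least 3 complete positive predictions", call. = FALSE)
  list(a = .fit_m2(log10(p$a_pred), log10(p$a_obs), method),
       h = .fit_m2(log10(p$h_pred), log10(p$h_obs), method))
}

#' Observed versus predicted half-saturation density
#'
#' The theory predicts the half-saturation constant \eqn{1/(ah)} from the
#' high prey density alone: \eqn{(1-I_S) N_{high} / I_S}. This regresses the
#' observed log10 half-saturation density (from observed a and h) on the
#' predicted one with a model II fit (major axis by default). A
#' misconfigured saturation constant shifts the intercept but leaves the
#' slope at 1.
#'
#' @inheritParams compare_observed_predicted
#' @param method `"MA"` (default) or `"RMA"`.
#' @return A `model2_fit` on the log10 scale.
#' @export
auxiliary_half_saturation <- function(predictions, method = c("MA", "RMA")) {
  method <- match.arg(method)
  if (nrow(predictions) == 0) stop("empty predictions table", call. = FALSE)
  pred_c <- half_saturation_predicted(predictions$Nhigh, predictions$IS)
  obs_c <- 1 / (predictions$a_obs * predictions$h_obs)
  .fit_m2(log10(pred_c), log10(obs_c), method)
}

#' Observed versus predicted space clearance rate from handling time
#'
#' Tests the predicted inverse a-h relationship: the space clearance rate
#' implied by each observed handling time and high prey density,
#' \eqn{a = I_S/((1-I_S) N_{high} h)}, is compared with the observed space
#' clearance rate by model II regression on the log10 scale.
#'
#' @inheritParams auxiliary_half_saturation
#' @return A `model2_fit` on the log10 scale.
#' @export
auxiliary_a_h_relation <- function(predictions, method = c("MA", "RMA")) {
  method <- match.arg(method)
  if (nrow(predictions) == 0) stop("empty predictions table", call. = FALSE)
  a_from_h <- predicted_a_from_h(predictions$h_obs, predictions$Nhigh,
                                 predictions$IS)
  .fit_m2(log10(a_from_h), log10(predictions$a_obs), method)
}

#' Within-stratum space-clearance/handling-time slopes
#'
#' The inverse a-h relationship (log-log slope -1) holds among predators
#' whose prey reach similar high densities; pooled across very different
#' prey densities it is attenuated or absent. This bins records by log10
#' high prey density and fits an ordinary least squares slope of log10
#' observed a on log10 observed h within each bin.
#'
#' @inheritParams compare_observed_predicted
#' @param bin_width Width of the log10 Nhigh strata (default 0.25 decades).
#' @param min_n Minimum records per stratum to report a slope (default 30).
#' @return Tibble: stratum midpoint (log10 Nhigh), n, OLS slope and its
#'   standard error.
#' @export
stratified_a_h_slopes <- function(predictions, bin_width = 0.25, min_n = 30) {
  lN <- log10(predictions$Nhigh)
  bin <- floor(lN / bin_width)
  out <- lapply(split(seq_along(bin), bin), function(i) {
    if (length(i) < min_n) return(NULL)
    fit <- stats::lm(log10(predictions$a_obs[i]) ~ log10(predictions$h_obs[i]))
    sm <- summary(fit)$coefficients
    tibble::tibble(log10_Nhigh_mid = (mean(range(lN[i]))),
                   n = length(i), slope = sm[2, 1], slope_se = sm[2, 2])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) stop("no stratum reached min_n records", call. = FALSE)
  out
}

#' Observed and predicted allometric scaling of a and h
#'
#' Fits the observed allometries by ordinary least squares on the log10
#' scale — space clearance rate against predator mass, and prey-mass-specific
#' handling time (h / prey mass) against predator mass — with 95% confidence
#' intervals. If the underlying scaling exponents are supplied, the
#' theoretically composed exponents are computed with the allometry module
#' using the cohort's own prey-on-predator mass slope, and reported
#' alongside.
#'
#' @inheritParams compare_observed_predicted
#' @param e_density_low,e_density_high,e_demand Optional generating/fitted
#'   scaling exponents used to derive the predicted allometries.
#' @return List with `observed` (tibble: response, slope, 95% CI, intercept),
#'   `e_mn_mp` (cohort OLS slope of log10 prey mass on log10 predator mass),
#'   and, when exponents were supplied, `predicted` (the
#'   [allometry_derivation_table()]).
#' @export
auxiliary_allometry <- function(predictions, e_density_low = NULL,
                                e_density_high = NULL, e_demand = NULL) {
  if (nrow(predictions) < 3) stop("need at least 3 predictions", call. = FALSE)
  fit_a <- stats::lm(log10(a_obs) ~ log10(MP), data = predictions)
  fit_h <- stats::lm(log10(h_obs / MN) ~ log10(MP), data = predictions)
  ci_a <- stats::confint(fit_a)[2, ]
  ci_h <- stats::confint(fit_h)[2, ]
  observed <- tibble::tibble(
    response = c("log10_a_obs_vs_MP", "log10_h_over_MN_vs_MP"),
    slope = unname(c(coef(fit_a)[2], coef(fit_h)[2])),
    slope_lo = unname(c(ci_a[1], ci_h[1])),
    slope_hi = unname(c(ci_a[2], ci_h[2])),
    intercept = unname(c(coef(fit_a)[1], coef(fit_h)[1])))
  e_mn_mp <- unname(coef(stats::lm(log10(MN) ~ log10(MP), data = predictions))[2])
  out <- list(observed = observed, e_mn_mp = e_mn_mp)
  if (!is.null(e_density_low) && !is.null(e_density_high) && !is.null(e_demand)) {
    out$predicted <- allometry_derivation_table(e_density_low, e_density_high,
                                                e_demand, e_mn_mp)
  }
  out
}

#' Predict functional responses for field studies
#'
#' Direct evaluation of the two rules with system-specific information: each
#' field record carries its own demand, prey energy density, prey mass, and
#' the lowest/highest prey densities recorded during the study. If
#' `energy_density_kj_g` is missing for a record but percent protein/fat
#' composition is present, the energy density is computed with
#' [energy_density_from_composition()]. No records are excluded
#' automatically; circularity screening (kill rates derived from diet
#' proportions) is a data-curation flag (`diet_derived`) for the caller.
#'
#' @param records Field-study tibble with columns `study_id`,
#'   `demand_kj_day`, `energy_density_kj_g` (may be NA), `pct_protein`,
#'   `pct_fat` (used when energy density is NA), `prey_mass_g`,
#'   `density_low`, `density_high`, and optionally `observed_a`,
#'   `observed_h`.
#' @param E_override Optional single energy density overriding all records.
#' @param IS Degree of saturation (default 0.9).
#' @return The input tibble with columns `E_used`, `a_pred`, `h_pred`
#'   appended.
#' @export
predict_field_study <- function(records, E_override = NULL, IS = 0.9) {
  need <- c("study_id", "demand_kj_day", "prey_mass_g", "density_low",
            "density_high")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("field records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(E_override)) {
    E <- rep(E_override, nrow(records))
  } else {
    E <- if ("energy_density_kj_g" %in% names(records)) {
      records$energy_density_kj_g
    } else {
      rep(NA_real_, nrow(records))
    }
    fill <- is.na(E)
    if (any(fill)) {
      if (!all(c("pct_protein", "pct_fat") %in% names(records)) ||
          any(is.na(records$pct_protein[fill])) ||
          any(is.na(records$pct_fat[fill]))) {
        stop("record(s) ", paste(records$study_id[fill], collapse = ", "),
             " lack both energy density and body composition", call. = FALSE)
      }
      E[fill] <- energy_density_from_composition(records$pct_protein[fill],
                                                 records$pct_fat[fill])
    }
  }
  incomplete <- is.na(records$demand_kj_day) | is.na(records$prey_mass_g) |
    is.na(records$density_low) | is.na(records$density_high)
  if (any(incomplete)) {
    stop("incomplete field record(s): ",
         paste(records$study_id[incomplete], collapse = ", "), call. = FALSE)
  }
  ctx <- energetic_context(records$demand_kj_day, E, records$prey_mass_g,
                           records$density_low, records$density_high, IS)
  fr <- predict_functional_response(ctx)
  out <- tibble::as_tibble(records)
  out$E_used <- E
  out$a_pred <- fr$a
  out$h_pred <- fr$h
  out
}

#' Sensitivity sweep over saturation and density-quantile settings
#'
#' Re-runs [predict_all()] and [compare_observed_predicted()] for every
#' combination of the supplied saturation constants and (q_low, q_high)
#' pairs, collecting the comparison statistics. Supports the standard
#' sensitivity analysis showing that predictive performance is robust to
#' reasonable choices of I_S and of the density percentiles.
#'
#' @inheritParams predict_all
#' @param IS_values Numeric vector of saturation constants to try.
#' @param q_pairs List of `c(q_low, q_high)` pairs.
#' @param method Regression method for the comparison (default RMA).
#' @return Tibble with one row per combination and parameter (a, h):
#'   IS, q_low, q_high, parameter, slope, CI, r, r2_identity.
#' @export
sweep_predictions <- function(records, density_laws, demand_laws, E = 5.6,
                              IS_values = c(0.8, 0.9, 0.95),
                              q_pairs = list(c(0.10, 0.90), c(0.05, 0.95)),
                              method = c("RMA", "MA")) {
  method <- match.arg(method)
  rows <- list()
  for (IS in IS_values) {
    for (qp in q_pairs) {
      pred <- predict_all(records, density_laws, demand_laws, E = E, IS = IS,
                          q_low = qp[1], q_high = qp[2])
      cmp <- compare_observed_predicted(pred, method = method)
      for (par in c("a", "h")) {
        f <- cmp[[par]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          IS = IS, q_low = qp[1], q_high = qp[2], parameter = par,
          slope = f$slope, slope_lo = f$slope_ci[1], slope_hi = f$slope_ci[2],
          r = f$r, r2_identity = f$r2_identity)
      }
    }
  }
  do.call(rbind, rows)
}
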