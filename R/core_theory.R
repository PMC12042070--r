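#' Energetic context for functional-response prediction
#'
#' Bundles the right-hand-side quantities of the two energetic rules that
#' predict a Holling type II functional response: the predator's energetic
#' demand, the energy density and mass of its prey, the extremes of prey
#' density it is likely to experience, and the target degree of feeding-rate
#' saturation at high prey density.
#'
#' All fields are vectorised: scalars are recycled against the longest field,
#' so a single call can describe a whole cohort of predator-prey pairs.
#'
#' @param demand Predator energetic demand \eqn{D}, kJ/day.
#' @param energy_density Prey energy density \eqn{E}, kJ per g wet mass.
#' @param prey_mass Prey body mass \eqn{M_N}, g wet weight.
#' @param density_low Low prey density \eqn{N_{low}} the predator is likely to
#'   experience, individuals per m^2.
#' @param density_high High prey density \eqn{N_{high}}, individuals per m^2.
#'   Must satisfy `density_low <= density_high` elementwise.
#' @param saturation Target degree of feeding-rate saturation \eqn{I_S} at
#'   `density_high`, a fraction strictly between 0 and 1 (default 0.9, i.e.
#'   feeding saturated at 90% of its maximum).
#' @param assimilation Optional assimilation-efficiency multiplier applied to
#'   `energy_density` (fraction of ingested prey energy actually available to
#'   the predator). Default 1 (no losses).
#'
#' @return An object of class `energetic_context`: a list of numeric vectors
#'   `D`, `E`, `MN`, `Nlow`, `Nhigh`, `IS`, `assimilation`, all of common
#'   length.
#' @seealso [predict_functional_response()], [predict_space_clearance()],
#'   [predict_handling_time()]
#' @export
#' @examples
#' ctx <- energetic_context(demand = 5.6, energy_density = 5.6, prey_mass = 1,
#'                          density_low = 1, density_high = 9)
#' predict_space_clearance(ctx)  # 1 m^2/day
energetic_context <- function(demand, energy_density, prey_mass,
                              density_low, density_high,
                              saturation = 0.9, assimilation = 1) {
  fields <- list(D = demand, E = energy_density, MN = prey_mass,
                 Nlow = density_low, Nhigh = density_high,
                 IS = saturation, assimilation = assimilation)
  for (nm in names(fields)) {
    if (!is.numeric(fields[[nm]]) || length(fields[[nm]]) == 0) {
      stop("energetic_context: '", nm, "' must be a non-empty numeric vector",
           call. = FALSE)
    }
  }
  n <- max(lengths(fields))
  bad_len <- lengths(fields) != 1L & lengths(fields) != n
  if (any(bad_len)) {
    stop("energetic_context: fields must have length 1 or ", n, "; offending: ",
         paste(names(fields)[bad_len], collapse = ", "), call. = FALSE)
  }
  fields <- lapply(fields, rep_len, length.out = n)
  with(fields, {
    if (any(!is.finite(D)) || any(D <= 0)) stop("demand D must be finite and > 0", call. = FALSE)
    if (any(!is.finite(E)) || any(E <= 0)) stop("energy density E must be finite and > 0", call. = FALSE)
    if (any(!is.finite(MN)) || any(MN <= 0)) stop("prey mass MN must be finite and > 0", call. = FALSE)
    if (any(!is.finite(Nlow)) || any(Nlow <= 0)) stop("density_low must be finite and > 0", call. = FALSE)
    if (any(!is.finite(Nhigh)) || any(Nhigh <= 0)) stop("density_high must be finite and > 0", call. = FALSE)
    if (any(Nlow > Nhigh)) stop("density_low must not exceed density_high", call. = FALSE)
    if (any(IS <= 0 | IS >= 1)) stop("saturation I_S must lie strictly in (0, 1)", call. = FALSE)
    if (any(assimilation <= 0 | assimilation > 1)) {
      stop("assimilation efficiency must lie in (0, 1]", call. = FALSE)
    }
  })
  structure(fields, class = "energetic_context")
}

#' @export
print.energetic_context <- function(x, ...) {
  n <- length(x$D)
  cat("<energetic_context> ", n, if (n == 1) " record\n" else " records\n", sep = "")
  cat(sprintf("  D:     %s kJ/day\n", .fmt_range(x$D)))
  cat(sprintf("  E:     %s kJ/g (assimilation %s)\n", .fmt_range(x$E),
              .fmt_range(x$assimilation)))
  cat(sprintf("  MN:    %s g\n", .fmt_range(x$MN)))
  cat(sprintf("  Nlow:  %s /m^2\n", .fmt_range(x$Nlow)))
  cat(sprintf("  Nhigh: %s /m^2\n", .fmt_range(x$Nhigh)))
  cat(sprintf("  IS:    %s\n", .fmt_range(x$IS)))
  invisible(x)
}

.fmt_range <- function(v) {
  if (length(unique(v)) == 1L) format(v[1], digits = 4)
  else paste0("[", format(min(v), digits = 4), ", ", format(max(v), digits = 4), "]")
}

# effective prey energy density after assimilation losses
.energy_eff <- function(ctx) ctx$E * ctx$assimilation

#' Holling type II functional response
#'
#' Container for the two parameters of a Holling type II (saturating)
#' functional response \eqn{f(N) = aN / (1 + ahN)}: the space clearance rate
#' `a` (the slope at the origin; area effectively searched per predator per
#' day) and the handling time `h` (days per prey; the reciprocal of the
#' maximum feeding rate). The derived maximum feeding rate \eqn{f_{max}=1/h}
#' and half-saturation density \eqn{c = 1/(ah)} (the Michaelis-Menten
#' half-saturation constant) are stored alongside.
#'
#' @param space_clearance Space clearance rate \eqn{a}, m^2/day; > 0.
#' @param handling_time Handling time \eqn{h}, days per prey; > 0.
#' @return An object of class `functional_response` with fields `a`, `h`,
#'   `f_max`, `half_saturation` (vectorised, recycled to common length).
#' @export
#' @examples
#' fr <- functional_response(1, 0.5)
#' fr$f_max            # 2 prey/day
#' fr$half_saturation  # 2 prey/m^2
functional_response <- function(space_clearance, handling_time) {
  if (!is.numeric(space_clearance) || !is.numeric(handling_time)) {
    stop("space_clearance and handling_time must be numeric", call. = FALSE)
  }
  n <- max(length(space_clearance), length(handling_time))
  a <- rep_len(space_clearance, n)
  h <- rep_len(handling_time, n)
  if (any(!is.finite(a)) || any(a <= 0)) stop("space clearance rate a must be finite and > 0", call. = FALSE)
  if (any(!is.finite(h)) || any(h <= 0)) stop("handling time h must be finite and > 0", call. = FALSE)
  structure(list(a = a, h = h, f_max = 1 / h, half_saturation = 1 / (a * h)),
            class = "functional_response")
}

#' @export
print.functional_response <- function(x, ...) {
  cat("<functional_response> ", length(x$a), " record(s)\n", sep = "")
  cat(sprintf("  a (space clearance): %s m^2/day\n", .fmt_range(x$a)))
  cat(sprintf("  h (handling time):   %s days\n", .fmt_range(x$h)))
  cat(sprintf("  f_max = 1/h:         %s prey/day\n", .fmt_range(x$f_max)))
  cat(sprintf("  c = 1/(ah):          %s prey/m^2\n", .fmt_range(x$half_saturation)))
  invisible(x)
}

#' Linear (low-density) feeding rate
#'
#' Feeding rate under the linear approximation valid at low prey density,
#' \eqn{f = aN}. This is the regime in which the first rule (feeding meets
#' energetic demand) is imposed.
#'
#' @param a Space clearance rate, m^2/day; > 0.
#' @param N Prey density, individuals/m^2; >= 0.
#' @return Feeding rate, prey/day.
#' @export
feeding_rate_linear <- function(a, N) {
  if (!is.numeric(a) || any(!is.finite(a)) || any(a <= 0)) {
    stop("space clearance rate a must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 0)) {
    stop("prey density N must be finite and >= 0", call. = FALSE)
  }
  a * N
}

#' Holling type II feeding rate
#'
#' Saturating feeding rate \eqn{f(N) = aN/(1 + ahN)}: monotone increasing in
#' prey density and bounded above by the maximum feeding rate \eqn{1/h}.
#'
#' @param fr A [functional_response()].
#' @param N Prey density, individuals/m^2; >= 0.
#' @return Feeding rate, prey/day.
#' @export
feeding_rate_holling2 <- function(fr, N) {
  stopifnot(inherits(fr, "functional_response"))
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 0)) {
    stop("prey density N must be finite and >= 0", call. = FALSE)
  }
  fr$a * N / (1 + fr$a * fr$h * N)
}

#' Degree of feeding-rate saturation at a prey density
#'
#' The degree of saturation is the feeding rate expressed as a fraction of its
#' maximum, \eqn{f(N)\,h = ahN/(1+ahN) \in [0, 1)}. At steady state it is also
#' interpretable as the fraction of predators busy handling prey. The second
#' rule fixes this quantity to \eqn{I_S} at the high prey density.
#'
#' @inheritParams feeding_rate_holling2
#' @return Saturation fraction in \[0, 1).
#' @export
saturation_at_density <- function(fr, N) {
  feeding_rate_holling2(fr, N) * fr$h
}

#' Predicted space clearance rate from the first rule
#'
#' The first rule states that at low prey density the predator's feeding rate
#' (linear regime, \eqn{f_{low} = a N_{low}}) converts to exactly its
#' energetic demand: \eqn{D = a N_{low} E M_N}. Solving for the space
#' clearance rate gives \deqn{a = D / (N_{low} E M_N).}
#'
#' @param ctx An [energetic_context()].
#' @return Space clearance rate \eqn{a}, m^2/day.
#' @export
predict_space_clearance <- function(ctx) {
  stopifnot(inherits(ctx, "energetic_context"))
  ctx$D / (ctx$Nlow * .energy_eff(ctx) * ctx$MN)
}

#' Predicted handling time from the second rule
#'
#' The second rule states that the feeding rate reaches a saturation fraction
#' \eqn{I_S} at the high prey density: \eqn{I_S = f(N_{high})\,h}. Combined
#' with the first rule's space clearance rate this yields
#' \deqn{h = \frac{I_S\,N_{low}\,E\,M_N}{D\,N_{high}\,(1 - I_S)}.}
#'
#' @param ctx An [energetic_context()].
#' @return Handling time \eqn{h}, days per prey.
#' @export
predict_handling_time <- function(ctx) {
  stopifnot(inherits(ctx, "energetic_context"))
  ctx$IS * ctx$Nlow * .energy_eff(ctx) * ctx$MN /
    (ctx$D * ctx$Nhigh * (1 - ctx$IS))
}

#' Predict the full functional response from an energetic context
#'
#' Applies both rules: [predict_space_clearance()] and
#' [predict_handling_time()].
#'
#' @param ctx An [energetic_context()].
#' @return A [functional_response()].
#' @export
#' @examples
#' ctx <- energetic_context(5.6, 5.6, 1, 1, 9, saturation = 0.9)
#' fr <- predict_functional_response(ctx)
#' saturation_at_density(fr, ctx$Nhigh)  # 0.9, by construction
predict_functional_response <- function(ctx) {
  functional_response(predict_space_clearance(ctx), predict_handling_time(ctx))
}

#' Predicted half-saturation density
#'
#' Under the two rules the Michaelis-Menten half-saturation constant
#' \eqn{c = 1/(ah)} depends only on the high prey density and the saturation
#' target: \deqn{1/(ah) = (1 - I_S)\,N_{high} / I_S.} Predators experiencing
#' different prey-density ranges are therefore predicted to show the same
#' relative pattern of saturation across their own density range.
#'
#' @param Nhigh High prey density, individuals/m^2; > 0.
#' @param IS Degree of saturation at `Nhigh`, strictly in (0, 1).
#' @return Predicted half-saturation density, individuals/m^2.
#' @export
half_saturation_predicted <- function(Nhigh, IS) {
  if (!is.numeric(Nhigh) || any(!is.finite(Nhigh)) || any(Nhigh <= 0)) {
    stop("Nhigh must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(IS) || any(IS <= 0 | IS >= 1)) {
    stop("saturation I_S must lie strictly in (0, 1)", call. = FALSE)
  }
  (1 - IS) * Nhigh / IS
}

#' Space clearance rate implied by a handling time
#'
#' Eliminating the context between the two rules links the two functional
#' response parameters directly:
#' \deqn{a = \frac{I_S}{(1 - I_S)\,N_{high}\,h},} i.e. on the log scale
#' \eqn{\ln a = \ln[I_S / ((1-I_S) N_{high})] - \ln h}: an inverse
#' relationship (slope -1) among predators whose prey reach similar high
#' densities.
#'
#' @param h Handling time, days; > 0.
#' @param Nhigh High prey density, individuals/m^2; > 0.
#' @param IS Degree of saturation, strictly in (0, 1).
#' @return Space clearance rate, m^2/day.
#' @export
predicted_a_from_h <- function(h, Nhigh, IS) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0)) {
    stop("handling time h must be finite and > 0", call. = FALSE)
  }
  if (any(IS <= 0 | IS >= 1)) stop("saturation I_S must lie strictly in (0, 1)", call. = FALSE)
  if (any(!is.finite(Nhigh)) || any(Nhigh <= 0)) stop("Nhigh must be finite and > 0", call. = FALSE)
  IS / ((1 - IS) * Nhigh * h)
}

#' Energetic demand implied by a functional response
#'
#' Inverts the first rule: given a space clearance rate and the context's
#' low prey density, prey energy density and prey mass, returns the rate of
#' energy intake at low density, \eqn{a N_{low} E M_N} (kJ/day). When the
#' functional response was produced by [predict_functional_response()] on the
#' same context this reproduces the context's demand exactly, which makes it
#' a useful audit of any prediction table.
#'
#' @param fr A [functional_response()].
#' @param ctx An [energetic_context()].
#' @return Energy intake rate at low prey density, kJ/day.
#' @export
demand_check <- function(fr, ctx) {
  stopifnot(inherits(fr, "functional_response"), inherits(ctx, "energetic_context"))
  fr$a * ctx$Nlow * .energy_eff(ctx) * ctx$MN
}

#' Diagnostic for the linear low-density approximation
#'
#' The first rule evaluates feeding at low density with the linear form
#' \eqn{f_{low} = a N_{low}}; the approximation is good when
#' \eqn{a h N_{low} \ll 1}. This returns \eqn{a h N_{low}} so callers can
#' check how far each record is from that regime.
#'
#' @param fr A [functional_response()].
#' @param ctx An [energetic_context()].
#' @return Dimensionless \eqn{a h N_{low}} per record.
#' @export
low_density_linearity <- function(fr, ctx) {
  stopifnot(inherits(fr, "functional_response"), inherits(ctx, "energetic_context"))
  fr$a * fr$h * ctx$Nlow
}

#' Convert a volumetric clearance rate to an areal one
#'
#' Functional-response experiments in three-dimensional arenas report space
#' clearance in m^3/day. The theory's canonical units are areal (m^2/day, to
#' match aerial density compilations); dividing the volumetric rate by the
#' depth of the water column or arena over which prey are distributed gives
#' the areal equivalent. The choice of depth is the caller's: no per-study
#' guess is made here.
#'
#' @param a_m3_per_day Volumetric clearance rate, m^3/day; > 0.
#' @param depth_m Depth over which prey density is distributed, m; > 0.
#' @return Areal clearance rate, m^2/day.
#' @export
clearance_volume_to_area <- function(a_m3_per_day, depth_m) {
  if (any(!is.finite(a_m3_per_day)) || any(a_m3_per_day <= 0)) {
    stop("volumetric clearance rate must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(depth_m)) || any(depth_m <= 0)) {
    stop("depth must be finite and > 0", call. = FALSE)
  }
  a_m3_per_day / depth_m
}

#' Prey energy density from body composition
#'
#' When a species-specific energy density (kJ/g) is unavailable, it can be
#' computed from percent body composition using standard energetic
#' equivalents of 16.74 kJ/g for protein and 33.47 kJ/g for fat:
#' \eqn{E = 0.01 (p_{protein} \cdot 16.74 + p_{fat} \cdot 33.47)}.
#'
#' @param pct_protein Percent of wet body mass that is protein (0-100).
#' @param pct_fat Percent of wet body mass that is fat (0-100).
#' @return Energy density, kJ/g wet mass.
#' @export
#' @examples
#' energy_density_from_composition(20, 5)  # lean prey, ~5 kJ/g
energy_density_from_composition <- function(pct_protein, pct_fat) {
  if (any(pct_protein < 0) || any(pct_fat < 0) || any(pct_protein + pct_fat > 100)) {
    stop("composition percentages must be non-negative and sum to <= 100", call. = FALSE)
  }
  0.01 * (pct_protein * 16.74 + pct_fat * 33.47)
}
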