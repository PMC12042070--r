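#' Power-law scaling relationship
#'
#' A minimal container for a power law \eqn{y \propto M^{e}} in either prey
#' mass (`"prey_mass_MN"`) or predator mass (`"predator_mass_MP"`), used for
#' propagating scaling exponents through the two-rules predictions.
#'
#' @param base_variable `"prey_mass_MN"` or `"predator_mass_MP"`.
#' @param exponent Finite scaling exponent.
#' @param log10_prefactor Optional log10 prefactor (response units at 1 g).
#' @return An object of class `power_law`.
#' @export
power_law <- function(base_variable = c("prey_mass_MN", "predator_mass_MP"),
                      exponent, log10_prefactor = NA_real_) {
  base_variable <- match.arg(base_variable)
  stopifnot(is.numeric(exponent), length(exponent) == 1, is.finite(exponent))
  structure(list(base_variable = base_variable, exponent = exponent,
                 log10_prefactor = log10_prefactor),
            class = "power_law")
}

# accept a bare exponent or a power_law (optionally checking the variable)
.exponent_of <- function(x, variable) {
  if (inherits(x, "power_law")) {
    if (!missing(variable) && x$base_variable != variable) {
      stop("expected a power law in ", variable, ", got one in ",
           x$base_variable, call. = FALSE)
    }
    x$exponent
  } else {
    stopifnot(is.numeric(x), length(x) == 1, is.finite(x))
    x
  }
}

#' Predicted allometry of the space clearance rate
#'
#' Propagates power-law scalings through the first rule's prediction
#' \eqn{a = D/(N_{low} E M_N)}. With demand scaling \eqn{D \propto
#' M_P^{e_D}} and low prey density scaling \eqn{N_{low} \propto
#' M_N^{e_{N_{low}}}} (prey energy density and the saturation target treated
#' as mass-independent), the space clearance rate scales as
#' \deqn{a \propto M_P^{e_D}\, M_N^{-e_{N_{low}} - 1}.}
#'
#' @param e_density_low Exponent of the low-density (Damuth-law) scaling in
#'   prey mass, or a [power_law()] in `prey_mass_MN`.
#' @param e_demand Exponent of the demand (Kleiber-law) scaling in predator
#'   mass, or a [power_law()] in `predator_mass_MP`.
#' @return Named numeric vector `c(predator_mass_MP = ..., prey_mass_MN = ...)`.
#' @export
#' @examples
#' derive_a_scaling(-0.94, 0.87)  # c(MP = 0.87, MN = -0.06)
derive_a_scaling <- function(e_density_low, e_demand) {
  eN <- .exponent_of(e_density_low, "prey_mass_MN")
  eD <- .exponent_of(e_demand, "predator_mass_MP")
  c(predator_mass_MP = eD, prey_mass_MN = -eN - 1)
}

#' Predicted allometry of the handling time
#'
#' Propagates power-law scalings through the second rule's prediction
#' \eqn{h = I_S N_{low} E M_N / (D N_{high} (1 - I_S))}:
#' \deqn{h \propto M_N^{e_{N_{low}} + 1 - e_{N_{high}}}\, M_P^{-e_D}.}
#' When the low- and high-density exponents coincide, the densities cancel
#' and the prey-mass exponent is exactly 1.
#'
#' @param e_density_low,e_density_high Exponents of the low/high prey density
#'   scalings in prey mass (or [power_law()] objects).
#' @inheritParams derive_a_scaling
#' @return Named numeric vector `c(prey_mass_MN = ..., predator_mass_MP = ...)`.
#' @export
#' @examples
#' derive_h_scaling(-0.94, -0.9, 0.87)  # c(MN = 0.96, MP = -0.87)
derive_h_scaling <- function(e_density_low, e_density_high, e_demand) {
  eNl <- .exponent_of(e_density_low, "prey_mass_MN")
  eNh <- .exponent_of(e_density_high, "prey_mass_MN")
  eD <- .exponent_of(e_demand, "predator_mass_MP")
  c(prey_mass_MN = eNl + 1 - eNh, predator_mass_MP = -eD)
}

#' Compose a mixed (MP, MN) allometry onto predator mass alone
#'
#' Substitutes the predator-prey mass scaling \eqn{M_N \propto
#' M_P^{e_{M_N M_P}}} into a law with both predator- and prey-mass parts:
#' the total predator-mass exponent is
#' \eqn{e_{M_P} + e_{M_N} \cdot e_{M_N M_P}}. Composition is linear in the
#' exponents.
#'
#' @param exponents Named numeric vector with elements `predator_mass_MP`
#'   and `prey_mass_MN` (as returned by [derive_a_scaling()] or
#'   [derive_h_scaling()]).
#' @param e_mn_mp Exponent of prey mass on predator mass (or a [power_law()]).
#' @return Single numeric: the composed predator-mass exponent.
#' @export
#' @examples
#' compose_onto_predator_mass(derive_a_scaling(-0.94, 0.87), 0.79)  # 0.8226
compose_onto_predator_mass <- function(exponents, e_mn_mp) {
  if (!all(c("predator_mass_MP", "prey_mass_MN") %in% names(exponents))) {
    stop("exponents must be named with 'predator_mass_MP' and 'prey_mass_MN'",
         call. = FALSE)
  }
  e <- .exponent_of(e_mn_mp)
  unname(exponents[["predator_mass_MP"]] + exponents[["prey_mass_MN"]] * e)
}

#' Derivation table for the predicted allometries
#'
#' Assembles the full exponent-propagation table for the space clearance
#' rate, the handling time, and the prey-mass-specific handling time
#' \eqn{h/M_N} from the four input scalings. Two composed predator-mass
#' exponents are reported for \eqn{h/M_N}: the full composition (which
#' carries the small residual prey-mass exponent \eqn{e_{N_{low}} -
#' e_{N_{high}}} onto predator mass) and the predator-mass part alone
#' (i.e. treating \eqn{h/M_N} as depending on predator mass only, the form
#' usually quoted).
#'
#' @param e_density_low,e_density_high Prey-density scaling exponents in
#'   prey mass.
#' @param e_demand Demand scaling exponent in predator mass.
#' @param e_mn_mp Prey-mass-on-predator-mass scaling exponent.
#' @return A tibble with one row per derived quantity: its predator- and
#'   prey-mass exponents and the composed predator-mass exponent (full
#'   precision; round separately for display).
#' @export
#' @examples
#' allometry_derivation_table(-0.94, -0.9, 0.87, 0.79)
allometry_derivation_table <- function(e_density_low, e_density_high,
                                       e_demand, e_mn_mp) {
  ea <- derive_a_scaling(e_density_low, e_demand)
  eh <- derive_h_scaling(e_density_low, e_density_high, e_demand)
  eh_mn <- c(predator_mass_MP = unname(eh[["predator_mass_MP"]]),
             prey_mass_MN = unname(eh[["prey_mass_MN"]]) - 1)
  tibble::tibble(
    quantity = c("space_clearance_a", "handling_time_h",
                 "mass_specific_handling_h_over_MN"),
    exponent_MP = c(ea[["predator_mass_MP"]], eh[["predator_mass_MP"]],
                    eh_mn[["predator_mass_MP"]]),
    exponent_MN = c(ea[["prey_mass_MN"]], eh[["prey_mass_MN"]],
                    eh_mn[["prey_mass_MN"]]),
    composed_MP = c(compose_onto_predator_mass(ea, e_mn_mp),
                    compose_onto_predator_mass(eh, e_mn_mp),
                    compose_onto_predator_mass(eh_mn, e_mn_mp)),
    MP_part_only = c(ea[["predator_mass_MP"]], eh[["predator_mass_MP"]],
                     eh_mn[["predator_mass_MP"]])
  )
}
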