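#' Fluid material properties for thermoviscous acoustofluidics
#'
#' Bundles the ambient state and material constants of the working fluid
#' (culture medium, modelled as water) together with derived transport
#' scales: kinematic viscosity \eqn{\nu = \mu/\rho_0} and thermal
#' diffusivity \eqn{D_{th} = k/(\rho_0 C_p)}.
#'
#' Defaults are water at 37 degC as used for culture medium: density
#' 993.3 kg/m3, dynamic viscosity 6.92e-4 Pa s, bulk viscosity 2.4e-3 Pa s,
#' specific heat 4180 J/(kg K), thermal expansion 2.75e-4 1/K, isentropic
#' compressibility 4.48e-10 1/Pa and sound speed 1502 m/s.
#'
#' The viscosity ratio multiplying the dilatational stress term is taken as
#' \eqn{\beta = \mu_B/\mu + 1/3}, so that the compressible viscous stress
#' divergence equals the standard form
#' \eqn{\mu \nabla^2 V + (\mu_B + \mu/3)\nabla(\nabla\cdot V)}.
#'
#' @param rho0 density (kg/m3)
#' @param mu dynamic (shear) viscosity (Pa s)
#' @param muB bulk viscosity (Pa s)
#' @param Cp specific heat at constant pressure (J/(kg K))
#' @param alpha0 thermal expansion coefficient (1/K)
#' @param beta0 isentropic compressibility (1/Pa)
#' @param ca speed of sound (m/s)
#' @param T0 ambient temperature (K)
#' @param p0 ambient gauge pressure (Pa)
#' @param k_thermal thermal conductivity (W/(m K)); absent from the core
#'   parameter set, default 0.62 W/(m K) (water near 37 degC)
#' @param beta_ratio viscosity ratio; default \code{muB/mu + 1/3}
#' @return object of class \code{fluid_properties}
#' @export
fluid_properties <- function(rho0 = 993.3, mu = 6.92e-4, muB = 2.4e-3,
                             Cp = 4180, alpha0 = 2.75e-4, beta0 = 4.48e-10,
                             ca = 1502, T0 = 310.15, p0 = 0,
                             k_thermal = 0.62,
                             beta_ratio = muB / mu + 1 / 3) {
  stopifnot(rho0 > 0, mu > 0, muB > 0, Cp > 0, alpha0 > 0, beta0 > 0,
            ca > 0, T0 > 0)
  ca_from_beta <- 1 / sqrt(rho0 * beta0)
  if (abs(ca - ca_from_beta) / ca >= 0.01) {
    stop(sprintf(
      "inconsistent acoustic state: ca = %.1f m/s but 1/sqrt(rho0*beta0) = %.1f m/s (> 1%% apart)",
      ca, ca_from_beta))
  }
  out <- list(rho0 = rho0, mu = mu, muB = muB, Cp = Cp, alpha0 = alpha0,
              beta0 = beta0, ca = ca, T0 = T0, p0 = p0,
              k_thermal = k_thermal, beta_ratio = beta_ratio,
              nu = mu / rho0, Dth = k_thermal / (rho0 * Cp))
  class(out) <- "fluid_properties"
  out
}

#' Water properties at 25 degC
#'
#' Used by the rectangular-cavity streaming benchmark, which is specified at
#' an ambient temperature of 25 degC; the half-wave resonance of that cavity
#' matches its nominal drive frequency only with room-temperature sound speed.
#'
#' @return \code{fluid_properties} for water at 25 degC
#' @export
water_25C <- function() {
  fluid_properties(rho0 = 997, mu = 8.9e-4, muB = 2.47e-3,
                   Cp = 4181, alpha0 = 2.57e-4,
                   beta0 = 1 / (997 * 1497^2), ca = 1497,
                   T0 = 298.15, k_thermal = 0.603)
}

#' Viscous penetration depth
#'
#' Thickness \eqn{\delta = \sqrt{2\nu/\omega}} of the oscillatory viscous
#' boundary layer in which acoustic-streaming forcing concentrates.
#'
#' @param fluid a \code{fluid_properties} object
#' @param omega angular frequency (rad/s), positive
#' @return depth in metres
#' @export
viscous_penetration_depth <- function(fluid, omega) {
  if (!is.numeric(omega) || any(omega <= 0)) {
    stop("omega must be positive")
  }
  sqrt(2 * fluid$nu / omega)
}

#' Acoustic actuation of a vibrating wall
#'
#' Harmonic wall-normal displacement of amplitude \code{d0} at frequency
#' \code{f}, with the \eqn{e^{-i\omega t}} phase convention. The actuated
#' boundary oscillates with normal velocity amplitude \eqn{-i\omega d_0}.
#'
#' @param f frequency (Hz)
#' @param d0 displacement amplitude (m)
#' @param actuated_boundary boundary tag carrying the actuation
#' @return object of class \code{acoustic_actuation}
#' @export
acoustic_actuation <- function(f = 1e6, d0 = 0.5e-9,
                               actuated_boundary = "actuated_wall") {
  stopifnot(f > 0, d0 >= 0)
  out <- list(f = f, omega = 2 * pi * f, d0 = d0,
              actuated_boundary = actuated_boundary)
  class(out) <- "acoustic_actuation"
  out
}
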