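#' Water stopping-power table
#'
#' Collisional and radiative mass stopping powers of liquid water
#' (MeV cm^2/g) on a kinetic-energy grid from 0.5 to 300 MeV, rounded from
#' standard ICRU-37-style tabulations. The transport engine interpolates
#' log-log between grid points and clamps outside the range. The water
#' radiation length is 36.08 g/cm^2.
#'
#' These values define the engine's physics; they are a documented
#' stand-in for a general-purpose condensed-history code, adequate for
#' centimeter-scale depth-dose and scattering behaviour of 50-250 MeV
#' electrons in water-like media.
#'
#' @return data.frame with columns `energy` (MeV), `s_col`, `s_rad`
#'   (MeV cm^2/g).
#' @export
water_stopping_powers <- function() {
  data.frame(
    energy = c(0.5, 1, 2, 5, 10, 20, 50, 100, 150, 200, 250, 300),
    s_col  = c(2.034, 1.849, 1.795, 1.862, 1.942, 2.022,
               2.122, 2.193, 2.230, 2.254, 2.271, 2.285),
    s_rad  = c(0.0080, 0.0128, 0.0235, 0.0700, 0.183, 0.428,
               1.180, 2.400, 3.740, 5.120, 6.520, 7.940)
  )
}

#' Radiation length of water (g/cm^2)
#' @export
water_radiation_length <- function() 36.08

# MeV -> Gy conversion for a voxel: dose = E[MeV] * MEV_TO_J / mass[kg]
MEV_PER_G_TO_GY <- 1.602176634e-10

electron_rest_mass <- 0.510998946 # MeV

# beta*p*c (MeV) for kinetic energy E
beta_pc <- function(E) {
  etot <- E + electron_rest_mass
  (etot^2 - electron_rest_mass^2) / etot
}
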