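# Sedimentation-derived hydrodynamics: the downstream arithmetic of a
# sedimentation-velocity experiment (stoichiometry from the fitted molar
# mass, hydrodynamic radius from the frictional ratio, and the standard
# s20,w solvent correction). Units at the interface: kDa, Svedberg, cP,
# g/ml, ml/g, nm.

.AVOGADRO <- 6.02214076e23
.WATER20_VISCOSITY_CP <- 1.002
.WATER20_DENSITY <- 0.99823

#' Oligomeric stoichiometry from measured mass
#'
#' Ratio of the measured (solution) molar mass to the sequence-predicted
#' monomer mass, rounded to the nearest integer stoichiometry. A ratio more
#' than 0.15 away from an integer is flagged ambiguous.
#'
#' @param measured_mass_kda solution molar mass (kDa).
#' @param monomer_mass_kda monomer molar mass (kDa).
#' @return list: \code{ratio}, \code{stoichiometry}, \code{ambiguous}.
#' @export
oligomer_ratio <- function(measured_mass_kda, monomer_mass_kda) {
  if (measured_mass_kda <= 0 || monomer_mass_kda <= 0) {
    stop("masses must be > 0")
  }
  r <- measured_mass_kda / monomer_mass_kda
  s <- max(1L, as.integer(round(r)))
  list(ratio = r, stoichiometry = s, ambiguous = abs(r - round(r)) > 0.15)
}

#' Hydrodynamic radius from mass and frictional ratio
#'
#' \code{R_h = (f/f0) * (3 M vbar / (4 pi N_A))^(1/3)}: the anhydrous-sphere
#' radius of a particle of molar mass M and partial specific volume vbar,
#' inflated by the frictional ratio.
#'
#' @param mass_kda molar mass (kDa).
#' @param f_ratio frictional ratio f/f0 (>= 1 for physical particles).
#' @param vbar partial specific volume (ml/g); 0.73 is the canonical
#'   protein average and the documented default.
#' @return hydrodynamic radius in nm.
#' @export
hydrodynamic_radius <- function(mass_kda, f_ratio, vbar = 0.73) {
  if (mass_kda <= 0 || f_ratio <= 0 || vbar <= 0) stop("inputs must be > 0")
  m_g <- mass_kda * 1000                     # g/mol
  vol_cm3 <- m_g * vbar / .AVOGADRO          # anhydrous volume per particle
  r_cm <- (3 * vol_cm3 / (4 * pi))^(1 / 3)
  f_ratio * r_cm * 1e7                       # cm -> nm
}

#' Correct a sedimentation coefficient to standard conditions (s20,w)
#'
#' \code{s20w = s_obs * (eta_b / eta_20w) * (1 - vbar rho_20w) /
#' (1 - vbar rho_b)}: rescales the observed sedimentation coefficient from
#' the experimental buffer to water at 20 C.
#'
#' @param s_obs observed sedimentation coefficient (S).
#' @param vbar partial specific volume (ml/g).
#' @param buffer_viscosity_cp buffer viscosity (cP).
#' @param buffer_density buffer density (g/ml).
#' @param water20_viscosity_cp,water20_density reference values for water at
#'   20 C.
#' @return corrected sedimentation coefficient (S).
#' @export
s20w_correct <- function(s_obs, vbar = 0.73,
                         buffer_viscosity_cp, buffer_density,
                         water20_viscosity_cp = .WATER20_VISCOSITY_CP,
                         water20_density = .WATER20_DENSITY) {
  stopifnot(s_obs > 0, vbar > 0, buffer_viscosity_cp > 0, buffer_density > 0)
  buoy_b <- 1 - vbar * buffer_density
  buoy_w <- 1 - vbar * water20_density
  if (buoy_b <= 0) {
    stop("flotation regime: 1 - vbar * buffer_density <= 0, particle does not sediment")
  }
  s_obs * (buffer_viscosity_cp / water20_viscosity_cp) * buoy_w / buoy_b
}

#' Stokes-Einstein size-scaling factor for diffusion
#'
#' For particles of equal shape and density, the diffusion coefficient
#' scales with the inverse hydrodynamic radius, i.e. with
#' \code{mass^(-1/3)}; an m-fold mass increase slows diffusion by
#' \code{m^(1/3)} (an 8-fold increase: factor 2).
#'
#' @param mass_ratio ratio of particle masses (> 0).
#' @return factor by which the diffusion coefficient decreases.
#' @export
size_scaling_factor <- function(mass_ratio) {
  if (mass_ratio <= 0) stop("mass_ratio must be > 0")
  mass_ratio^(1 / 3)
}
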