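#' Mobile-water fraction of the reference ECM
#'
#' The compression experiments measure mobile water as a fraction of the
#' whole tissue block (0.375 for aortic media). Under the assumption that
#' all mobile water resides in the ECM, the mobile-water fraction per unit
#' reference ECM volume is
#' `w_ecm_ref = phi_w_block / (1 - phi_smc_ref)`.
#'
#' @param phi_w_block mobile-water fraction of the whole block, in (0, 1).
#' @param phi_smc_ref SMC volume fraction in the reference state.
#' @return the mobile-water fraction of the reference ECM.
#' @export
mobile_water_partition <- function(phi_w_block, phi_smc_ref) {
  if (phi_w_block <= 0 || phi_w_block >= 1) {
    abort("phi_w_block must lie in (0, 1)")
  }
  if (phi_smc_ref < 0 || phi_smc_ref >= 1) {
    abort("phi_smc_ref must lie in [0, 1)")
  }
  if (phi_w_block >= 1 - phi_smc_ref) {
    abort("more mobile water than ECM space: phi_w_block >= 1 - phi_smc_ref")
  }
  phi_w_block / (1 - phi_smc_ref)
}

#' Solid volume fraction at pressure
#'
#' The solid phase comprises the SMCs plus the non-mobile part of the ECM
#' (structural fibres and bound water):
#' `phi_s = phi_smc + (1 - phi_smc) * (1 - w_ecm_ref)`.
#' Pore closure enters through the pressure-dependent SMC fraction: as the
#' ECM compacts, `phi_smc` rises and with it `phi_s`.
#'
#' @param phi_smc_p SMC volume fraction measured at some pressure, in
#'   (0, 1).
#' @param w_ecm_ref mobile-water fraction of the ECM (treated as constant
#'   across pressures), in (0, 1).
#' @return the solid volume fraction `phi_s`.
#' @export
solid_fraction_at_pressure <- function(phi_smc_p, w_ecm_ref) {
  if (any(phi_smc_p <= 0) || any(phi_smc_p >= 1)) {
    abort("phi_smc_p must lie in (0, 1)")
  }
  if (w_ecm_ref <= 0 || w_ecm_ref > 1) abort("w_ecm_ref must lie in (0, 1]")
  phi_smc_p + (1 - phi_smc_p) * (1 - w_ecm_ref)
}

#' Volumetric ratio from solid fractions
#'
#' Both phases are intrinsically incompressible, so the solid volume is
#' conserved and any volume change is fluid entering or leaving:
#' `J = phi_s_ref / phi_s_p`.
#'
#' @param phi_s_p solid fraction in the deformed state, in (0, 1).
#' @param phi_s_ref solid fraction in the reference (0 mmHg) state.
#' @return the volumetric ratio `J` (deformed volume over reference
#'   volume).
#' @export
volumetric_ratio <- function(phi_s_p, phi_s_ref) {
  if (any(phi_s_p <= 0)) abort("phi_s_p must be > 0")
  if (phi_s_ref <= 0 || phi_s_ref >= 1) abort("phi_s_ref must lie in (0, 1)")
  phi_s_ref / phi_s_p
}

#' Assemble a biphasic mixture state
#'
#' Bundles the volume-fraction bookkeeping at one pressure into a single
#' row: SMC/ECM fractions from imaging, the solid and fluid fractions
#' (which satisfy the saturation condition `phi_s + phi_f = 1` exactly),
#' and the volumetric ratio relative to the reference state.
#'
#' @param pressure transmural pressure, mmHg.
#' @param phi_smc SMC fraction at this pressure.
#' @param w_ecm_ref mobile-water fraction of the ECM (see
#'   [mobile_water_partition()]).
#' @param phi_s_ref reference-state solid fraction (sigmoid extrapolation
#'   to 0 mmHg).
#' @return a one-row tibble: pressure, phi_smc, phi_ecm, phi_s, phi_f, J.
#' @export
mixture_state <- function(pressure, phi_smc, w_ecm_ref, phi_s_ref) {
  phi_s <- solid_fraction_at_pressure(phi_smc, w_ecm_ref)
  tibble(pressure = pressure, phi_smc = phi_smc, phi_ecm = 1 - phi_smc,
         phi_s = phi_s, phi_f = 1 - phi_s,
         J = volumetric_ratio(phi_s, phi_s_ref))
}
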