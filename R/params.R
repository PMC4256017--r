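#' Simulation parameters for the ductal Potts model
#'
#' Collects every model parameter in one list: the contact-adhesion
#' hierarchy between luminal epithelial (LEP) and myoepithelial (MEP)
#' cells, the volume and surface constraints that give each cell a target
#' size and a roughly circular resting shape, the contractile spring links
#' between neighbouring cells' centers of mass, the Metropolis temperature
#' (intrinsic cell motility), and the rules of the biological event layer
#' (mitosis cadence, division-axis mode, crowding-gated apoptosis,
#' distance-gated necrosis).
#'
#' Lengths are in pixels at a scale of 1 pixel = 1 micron, so a typical
#' epithelial cell has a 10-pixel diameter, a target volume of
#' `pi * 5^2 = 78.5` pixels and a target surface of `pi * 10 = 31.4`
#' pixel faces. Adhesion coefficients are energies per unit contact face
#' and are negative (binding lowers the energy), with
#' `J_LEP,LEP < J_LEP,MEP < J_MEP,MEP < 0` modelling differential
#' E-cadherin expression. Spring targets are shorter than the typical
#' resting center-to-center distance, so the links are contractile; the
#' more contractile MEP layer has the shortest target length.
#'
#' @param ... named overrides of any default listed below.
#' @param preset optional named parameter preset: `"low_adhesion"`
#'   (adhesion and spring coefficients all zero), `"high_adhesion"`
#'   (J = -100, -50, -25), `"low_contractility"` (`lambda_V` MEP/LEP =
#'   2/1, spring coefficients 1/0.1 homotypic/heterotypic) or
#'   `"high_contractility"` (`lambda_V` MEP/LEP = 50/25, spring
#'   coefficients 100/10). Presets are applied before `...` overrides.
#'
#' @section Defaults:
#' * `J_lep_lep = -20`, `J_lep_mep = -10`, `J_mep_mep = -5`: contact
#'   adhesion (pairs involving medium or necrotic debris are always zero);
#' * `Vt_lep = Vt_mep = 78.5`, `lambda_V_lep = 5`, `lambda_V_mep = 10`:
#'   target volume and stiffness (MEP are twice as stiff as LEP);
#' * `St_lep = St_mep = 31.4`, `lambda_S_lep = lambda_S_mep = 1`:
#'   target surface and membrane elasticity;
#' * `fpp_L_lep_lep = 8`, `fpp_L_lep_mep = 8`, `fpp_L_mep_mep = 5`,
#'   `fpp_lambda_lep_lep = 50`, `fpp_lambda_lep_mep = 5`,
#'   `fpp_lambda_mep_mep = 50`: spring-link target lengths and constants
#'   (homotypic constants 10-fold the heterotypic one);
#' * `temperature = 20`: Metropolis temperature;
#' * `mitosis_interval = 50` MCS between mitosis rounds,
#'   `division_fraction = 0.25` of LEP dividing per round,
#'   `axis_mode = "perpendicular"` (also `"parallel"`, `"random"`);
#' * `apoptosis_prob = 0.01` per overcrowded-cell check per MCS,
#'   `crowding_radius = 25` pixels (2.5 cell diameters),
#'   `crowding_threshold = 10` neighbours;
#' * `necrosis_dist = 100` pixels (10 cell diameters) from the MEP layer;
#' * `preferential_proliferation = FALSE`, `preferential_weight = 2`:
#'   double the sampling weight of end-region cells when on;
#' * `protect_luminal_progeny = FALSE`: exempt luminally placed daughters
#'   from apoptosis checks;
#' * `link_max_range = 20`: capture range (pixels) within which unlinked
#'   neighbouring cells form a spring link and beyond which a stretched
#'   link breaks;
#' * `cell_px = 10`: nominal cell diameter in pixels.
#'
#' @return An object of class `cpm_params` (a named list).
#' @examples
#' p <- cpm_params(apoptosis_prob = 0.005, axis_mode = "parallel")
#' p$J_lep_lep
#' cpm_params(preset = "high_adhesion")$J_lep_lep
#' @export
cpm_params <- function(..., preset = NULL) {
  p <- list(
    J_lep_lep = -20, J_lep_mep = -10, J_mep_mep = -5,
    Vt_lep = 78.5, Vt_mep = 78.5, lambda_V_lep = 5, lambda_V_mep = 10,
    St_lep = 31.4, St_mep = 31.4, lambda_S_lep = 1, lambda_S_mep = 1,
    fpp_L_lep_lep = 8, fpp_L_lep_mep = 8, fpp_L_mep_mep = 5,
    fpp_lambda_lep_lep = 50, fpp_lambda_lep_mep = 5, fpp_lambda_mep_mep = 50,
    temperature = 20,
    mitosis_interval = 50, division_fraction = 0.25,
    axis_mode = "perpendicular",
    apoptosis_prob = 0.01, crowding_radius = 25, crowding_threshold = 10,
    necrosis_dist = 100,
    preferential_proliferation = FALSE, preferential_weight = 2,
    protect_luminal_progeny = FALSE,
    link_max_range = 20,
    cell_px = 10
  )
  if (!is.null(preset)) p <- modifyList(p, cpm_preset(preset))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    p <- modifyList(p, dots)
  }
  stopifnot(
    p$axis_mode %in% c("perpendicular", "parallel", "random"),
    p$apoptosis_prob >= 0, p$apoptosis_prob <= 1,
    p$mitosis_interval >= 1, p$division_fraction > 0, p$division_fraction <= 1,
    p$crowding_radius >= 0, p$crowding_threshold >= 0, p$necrosis_dist >= 0
  )
  structure(p, class = "cpm_params")
}

#' Named parameter presets for the adhesion / contractility experiments
#'
#' @param name one of `"default"`, `"low_adhesion"`, `"high_adhesion"`,
#'   `"low_contractility"`, `"high_contractility"`.
#' @return A named list of parameter overrides (empty for `"default"`).
#' @export
cpm_preset <- function(name) {
  switch(match.arg(name, c("default", "low_adhesion", "high_adhesion",
                           "low_contractility", "high_contractility")),
    default = list(),
    low_adhesion = list(
      J_lep_lep = 0, J_lep_mep = 0, J_mep_mep = 0,
      fpp_lambda_lep_lep = 0, fpp_lambda_lep_mep = 0, fpp_lambda_mep_mep = 0
    ),
    high_adhesion = list(J_lep_lep = -100, J_lep_mep = -50, J_mep_mep = -25),
    low_contractility = list(
      lambda_V_mep = 2, lambda_V_lep = 1,
      fpp_lambda_lep_lep = 1, fpp_lambda_mep_mep = 1, fpp_lambda_lep_mep = 0.1
    ),
    high_contractility = list(
      lambda_V_mep = 50, lambda_V_lep = 25,
      fpp_lambda_lep_lep = 100, fpp_lambda_mep_mep = 100, fpp_lambda_lep_mep = 10
    )
  )
}

#' @export
print.cpm_params <- function(x, ...) {
  cat("<cpm_params>\n")
  cat(sprintf("  adhesion J (LL, LM, MM): %g, %g, %g\n",
              x$J_lep_lep, x$J_lep_mep, x$J_mep_mep))
  cat(sprintf("  volume: Vt %g/%g, lambda_V %g/%g (LEP/MEP)\n",
              x$Vt_lep, x$Vt_mep, x$lambda_V_lep, x$lambda_V_mep))
  cat(sprintf("  springs: L %g/%g/%g, lambda %g/%g/%g (LL/LM/MM)\n",
              x$fpp_L_lep_lep, x$fpp_L_lep_mep, x$fpp_L_mep_mep,
              x$fpp_lambda_lep_lep, x$fpp_lambda_lep_mep, x$fpp_lambda_mep_mep))
  cat(sprintf("  temperature %g; mitosis every %d MCS (%s axis); apoptosis %g%%\n",
              x$temperature, x$mitosis_interval, x$axis_mode,
              100 * x$apoptosis_prob))
  invisible(x)
}

# 4x4 type-indexed matrices for the engine (medium, LEP, MEP, necrotic)
param_matrices <- function(p) {
  J <- matrix(0, 4, 4)
  J[2, 2] <- p$J_lep_lep
  J[2, 3] <- J[3, 2] <- p$J_lep_mep
  J[3, 3] <- p$J_mep_mep
  lam <- matrix(0, 4, 4)
  lam[2, 2] <- p$fpp_lambda_lep_lep
  lam[2, 3] <- lam[3, 2] <- p$fpp_lambda_lep_mep
  lam[3, 3] <- p$fpp_lambda_mep_mep
  L <- matrix(0, 4, 4)
  L[2, 2] <- p$fpp_L_lep_lep
  L[2, 3] <- L[3, 2] <- p$fpp_L_lep_mep
  L[3, 3] <- p$fpp_L_mep_mep
  list(J = J, fpp_lambda = lam, fpp_L = L)
}
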