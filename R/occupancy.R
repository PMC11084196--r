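#' Equilibrium occupancy, excess-ligand isotherm
#'
#' Fractional occupancy of a binding-site class from the Langmuir isotherm
#' `theta = K*L / (1 + K*L)`, with `K` the equilibrium association constant
#' and `L` the free (here: total) ligand concentration. Valid when ligand is
#' in large excess over binding sites, so depletion is negligible.
#'
#' @param K Association constant, 1/M.
#' @param ligand_conc Ligand concentration, M. Vectorised.
#' @return Fraction in `[0, 1]`.
#' @seealso [occupancy_depletion()] for the exact mass-balance solution.
#' @export
#' @examples
#' occupancy_simple(1e3, 2.5e-3)   # ~0.71, prednisone at 2.5 mM
#' occupancy_simple(5e4, 1e-3)     # ~0.98, warfarin's weaker site at 1 mM
occupancy_simple <- function(K, ligand_conc) {
  check_number(K, "K", min = 0, strict_min = TRUE)
  if (any(ligand_conc < 0)) stopf("'ligand_conc' must be >= 0")
  K * ligand_conc / (1 + K * ligand_conc)
}

#' Equilibrium occupancy with ligand depletion
#'
#' Exact single-class mass balance for `n_sites` equivalent sites per HSA
#' molecule: with total site concentration `S = n_sites * hsa_conc`,
#' dissociation constant `Kd = 1/K` and total ligand `L`, the bound
#' concentration is the smaller root of the binding quadratic,
#' `b = ((S + L + Kd) - sqrt((S + L + Kd)^2 - 4*S*L)) / 2`, and the
#' occupancy is `b/S`. Needed when the ligand is not in excess (e.g. a
#' poorly soluble ligand over tens of micromolar HSA); reduces to
#' [occupancy_simple()] as `L/S` grows.
#'
#' @param K Association constant, 1/M.
#' @param ligand_conc Total ligand concentration, M.
#' @param hsa_conc Total HSA concentration, M.
#' @param n_sites Equivalent sites per HSA molecule.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' # sparingly soluble ligand: 15 uM over 40 uM HSA with 4 sites
#' occupancy_depletion(1e5, 15e-6, 40e-6, n_sites = 4)  # ~0.088
occupancy_depletion <- function(K, ligand_conc, hsa_conc, n_sites = 1L) {
  check_number(K, "K", min = 0, strict_min = TRUE)
  check_number(ligand_conc, "ligand_conc", min = 0)
  check_number(hsa_conc, "hsa_conc", min = 0, strict_min = TRUE)
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  S <- n_sites * hsa_conc
  L <- ligand_conc
  Kd <- 1 / K
  disc <- (S + L + Kd)^2 - 4 * S * L
  stopifnot(disc >= 0)  # guaranteed for non-negative S, L, Kd
  b <- ((S + L + Kd) - sqrt(disc)) / 2
  b / S
}

#' Occupancy range over an HSA concentration interval
#'
#' Evaluates the depletion-corrected occupancy at both endpoints of an HSA
#' concentration range (occupancy is monotone in HSA concentration at fixed
#' total ligand, so the endpoints bound the range) and returns the sorted
#' pair.
#'
#' @inheritParams occupancy_depletion
#' @param hsa_range Length-2 numeric, HSA concentration interval in M.
#' @return Named numeric `c(min = , max = )`, fractions.
#' @export
#' @examples
#' occupancy_over_range(1e5, 15e-6, c(2.5e-6, 40e-6), n_sites = 4)
occupancy_over_range <- function(K, ligand_conc, hsa_range, n_sites = 1L) {
  if (length(hsa_range) != 2L) stopf("'hsa_range' must have two endpoints")
  th <- vapply(hsa_range, function(h)
    occupancy_depletion(K, ligand_conc, h, n_sites), numeric(1))
  c(min = min(th), max = max(th))
}

#' Tabulate occupancies for a panel of ligand/site specifications
#'
#' Batch wrapper mirroring the screen's occupancy table: one row per
#' site class with its association constant and ligand concentration;
#' rows with an `hsa_conc` (and optionally `n_sites`) column get the
#' depletion-corrected value, the rest the excess-ligand isotherm.
#'
#' @param specs `data.frame` with columns `K` (1/M), `ligand_conc` (M) and
#'   optionally `hsa_conc` (M, `NA` for excess-ligand rows) and `n_sites`.
#' @return The input with `occupancy` (fraction), `percent` (rounded to the
#'   nearest percent, half away from zero) and `model` columns appended.
#' @export
occupancy_table <- function(specs) {
  stopifnot(is.data.frame(specs), all(c("K", "ligand_conc") %in% names(specs)))
  if (!"hsa_conc" %in% names(specs)) specs$hsa_conc <- NA_real_
  if (!"n_sites" %in% names(specs)) specs$n_sites <- 1L
  occ <- vapply(seq_len(nrow(specs)), function(i) {
    if (is.na(specs$hsa_conc[i])) {
      occupancy_simple(specs$K[i], specs$ligand_conc[i])
    } else {
      occupancy_depletion(specs$K[i], specs$ligand_conc[i],
                          specs$hsa_conc[i], specs$n_sites[i])
    }
  }, numeric(1))
  specs$occupancy <- occ
  specs$percent <- round_half_up(100 * occ)
  specs$model <- ifelse(is.na(specs$hsa_conc), "excess-ligand isotherm",
                        "mass-balance quadratic")
  specs
}
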