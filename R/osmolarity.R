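#' Osmotic coefficient table
#'
#' Milliosmoles contributed per millimole of solute when fully
#' dissolved: NaCl dissociates into two particles (assumed fully
#' ionized at working concentrations), glycerol and sorbitol stay
#' single particles. Extend by passing additional named coefficients.
#'
#' @param ... Additional or overriding coefficients, e.g. `KCl = 2`.
#' @return Named numeric vector of mOsm per mM.
#' @export
osmotic_coefficients <- function(...) {
  base <- c(NaCl = 2, glycerol = 1, sorbitol = 1)
  extra <- c(...)
  if (length(extra)) base[names(extra)] <- extra
  base
}

#' Calculate solution osmolarity from a recipe
#'
#' Additive model: total osmolarity is the sum of each solute's
#' concentration times its osmotic coefficient. Interactions among
#' solutes are ignored (they are small at working concentrations; see
#' [reconcile_measured()] for validation against osmometer readings).
#'
#' @param recipe Named numeric vector of solute concentrations in mM,
#'   e.g. `c(NaCl = 50, glycerol = 300)`.
#' @param coefficients Osmotic coefficient table; see
#'   [osmotic_coefficients()].
#' @return Osmolarity in mOsm.
#' @export
#' @examples
#' calc_osmolarity(c(NaCl = 50, glycerol = 300)) # 400 mOsm
calc_osmolarity <- function(recipe, coefficients = osmotic_coefficients()) {
  if (length(recipe) == 0) return(0)
  stopifnot(is.numeric(recipe), !is.null(names(recipe)))
  if (any(recipe < 0)) stop("concentrations must be >= 0")
  missing <- setdiff(names(recipe), names(coefficients))
  if (length(missing)) {
    stop("no osmotic coefficient for solute(s): ",
         paste(missing, collapse = ", "))
  }
  sum(recipe * coefficients[names(recipe)])
}

#' Build a standard testing-solution recipe
#'
#' Every testing solution carries 50 mM NaCl (controlling for the salt
#' response) and is brought to the target osmolarity with a balancing
#' solute.
#'
#' @param target_mosm Target osmolarity (mOsm).
#' @param balancing_solute `"glycerol"`, `"sorbitol"`, or `"NaCl"`.
#' @param nacl_mm Base NaCl concentration (mM, default 50).
#' @param coefficients Osmotic coefficient table.
#' @return Named numeric recipe (mM) whose [calc_osmolarity()] equals
#'   `target_mosm`.
#' @export
#' @examples
#' solution_recipe(400, "glycerol") # 50 mM NaCl + 300 mM glycerol
solution_recipe <- function(target_mosm,
                            balancing_solute = c("glycerol", "sorbitol",
                                                 "NaCl"),
                            nacl_mm = 50,
                            coefficients = osmotic_coefficients()) {
  balancing_solute <- match.arg(balancing_solute)
  base_mosm <- nacl_mm * coefficients[["NaCl"]]
  if (target_mosm < base_mosm) {
    stop("target osmolarity below the contribution of the base NaCl")
  }
  need <- (target_mosm - base_mosm) / coefficients[[balancing_solute]]
  recipe <- c(NaCl = nacl_mm)
  if (balancing_solute == "NaCl") {
    recipe["NaCl"] <- recipe["NaCl"] + need
  } else if (need > 0) {
    recipe[balancing_solute] <- need
  }
  recipe
}

#' Osmometer validation chart for the testing solutions
#'
#' Calculated versus vapor-pressure-osmometer-measured osmolarity for
#' the glycerol-, NaCl-, and sorbitol-balanced testing solutions.
#'
#' @return A tibble of `balancing_solute`, `calculated_mosm`,
#'   `measured_mosm`.
#' @export
testing_solutions <- function() {
  tibble::tibble(
    balancing_solute = c("glycerol", "glycerol", "glycerol", "glycerol",
                         "NaCl", "NaCl", "sorbitol", "sorbitol"),
    calculated_mosm = c(150, 400, 600, 800, 150, 400, 150, 400),
    measured_mosm = c(144, 415, 621, 838, 144, 369, 141, 373)
  )
}

#' Reconcile calculated against measured osmolarity
#'
#' Per solution: calculated value, measured value, absolute and
#' relative deviation, and a flag for deviations beyond the tolerance.
#'
#' @param calculated Named numeric vector of calculated osmolarities
#'   (mOsm), or a list of recipes (then [calc_osmolarity()] is applied).
#' @param measured Named numeric vector of measured osmolarities keyed
#'   identically to `calculated`.
#' @param tolerance Relative deviation above which a solution is
#'   flagged (default 0.10).
#' @return A tibble of `solution`, `calculated_mosm`, `measured_mosm`,
#'   `abs_deviation_mosm`, `rel_deviation`, `flagged`.
#' @export
reconcile_measured <- function(calculated, measured, tolerance = 0.10) {
  if (is.list(calculated)) {
    calculated <- vapply(calculated, calc_osmolarity, numeric(1))
  }
  if (is.null(names(calculated)) || is.null(names(measured)) ||
      !setequal(names(calculated), names(measured))) {
    stop("`calculated` and `measured` must be keyed identically")
  }
  measured <- measured[names(calculated)]
  rel <- abs(measured - calculated) / calculated
  tibble::tibble(
    solution = names(calculated),
    calculated_mosm = unname(calculated),
    measured_mosm = unname(measured),
    abs_deviation_mosm = unname(abs(measured - calculated)),
    rel_deviation = unname(rel),
    flagged = unname(rel > tolerance)
  )
}
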