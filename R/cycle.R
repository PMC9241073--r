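RESIDUE_CHARGES <- c(
  ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0, GLU = -1,
  GLY = 0, HIS = 0, ILE = 0, LEU = 0, LYS = 1, MET = 0, PHE = 0,
  PRO = 0, SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0
)

#' Formal side-chain charge change of a point mutation
#'
#' Uses the standard pH-7 formal charges (ASP/GLU -1, LYS/ARG +1,
#' histidine neutral, all others 0) and returns target minus source. The
#' sign convention means D38A (removing an aspartate) gives +1 and K135Q
#' (removing a lysine) gives -1.
#'
#' @param source_residue,target_residue Standard 3-letter residue codes.
#' @return Integer charge change in elementary charges.
#' @export
residue_charge_delta <- function(source_residue, target_residue) {
  src <- toupper(source_residue)
  tgt <- toupper(target_residue)
  for (code in c(src, tgt)) {
    if (!code %in% names(RESIDUE_CHARGES)) {
      rlang::abort(sprintf("Unknown residue code '%s'.", code))
    }
  }
  as.integer(RESIDUE_CHARGES[[tgt]] - RESIDUE_CHARGES[[src]])
}

#' Plan the alchemical co-ion counter-transformation
#'
#' Charge-changing mutations would alter the simulation box's net charge;
#' the co-ion approach keeps it constant by transforming a Na+ ion into a
#' water molecule whenever a unit of negative charge is annealed or of
#' positive charge created (net protein charge change +1), and a water
#' molecule into Na+ for the opposite case (-1). The plan is bookkeeping
#' metadata for simulation setup; no energy term is computed here.
#'
#' @param charge_delta Integer protein charge change (target minus
#'   source), |delta| <= 1. Larger changes do not occur among standard
#'   single-point mutations at fixed protonation and are rejected.
#' @return A tibble with columns `action` (`none`, `na_to_water`, or
#'   `water_to_na`) and `protein_charge_delta`.
#' @export
plan_coion <- function(charge_delta) {
  if (!is.numeric(charge_delta) || length(charge_delta) != 1L ||
      charge_delta != round(charge_delta)) {
    rlang::abort("`charge_delta` must be a single integer.")
  }
  if (abs(charge_delta) > 1) {
    rlang::abort(sprintf(
      "Unsupported transformation: |charge change| = %d > 1.",
      abs(charge_delta)
    ))
  }
  action <- switch(as.character(as.integer(charge_delta)),
    "1" = "na_to_water",
    "-1" = "water_to_na",
    "0" = "none"
  )
  tibble::tibble(action = action,
                 protein_charge_delta = as.integer(charge_delta))
}

#' Estimate one transformation leg from its window series
#'
#' Runs the per-window statistics (equilibration discard, statistical
#' inefficiency, uncorrelated subsampling) followed by the TI quadrature
#' and its error propagation.
#'
#' @param windows List of `dvdl_series`, one per schedule node, in node
#'   order.
#' @param schedule The leg's `lambda_schedule`.
#' @param equilibration_fraction Per-window discard fraction.
#' @return A list with `delta_g`, `sigma`, `n_windows`, `window_stats`
#'   (tibble) and `schedule`.
#' @export
estimate_leg <- function(windows, schedule, equilibration_fraction = 0.1) {
  validate_schedule(schedule)
  if (length(windows) != nrow(schedule)) {
    rlang::abort(sprintf(
      "Leg has %d window series for a %d-node schedule.",
      length(windows), nrow(schedule)
    ))
  }
  ws <- purrr::map_dfr(windows, window_stats,
                       equilibration_fraction = equilibration_fraction)
  ws$lambda <- schedule$lambda
  list(
    delta_g = ti_integrate(schedule, ws$mean),
    sigma = ti_error(schedule, ws$sem),
    n_windows = nrow(schedule),
    window_stats = ws,
    schedule = schedule
  )
}

#' Compute a thermodynamic-cycle relative binding free energy
#'
#' Runs the full pipeline for one mutation: read each leg's schedule and
#' window files, discard equilibration, summarize each window, integrate
#' each leg by TI, and form the cycle difference
#' \eqn{\Delta\Delta G_b = \Delta G(\mathrm{complex}) -
#' \Delta G(\mathrm{apo})} with combined error
#' \eqn{\sigma^2 = \sigma_\mathrm{complex}^2 + \sigma_\mathrm{apo}^2}.
#' A co-ion plan is attached from the mutation's formal charge change
#' (unless the manifest's `coion_policy` overrides it).
#'
#' @param manifest A `cycle_manifest` (from [read_cycle_manifest()]), a
#'   path to one, or an equivalent named list whose legs carry in-memory
#'   `schedule` (`lambda_schedule`) and `windows` (list of `dvdl_series`)
#'   instead of paths.
#' @param n_chunks Number of points in the forward/reverse convergence
#'   profile (0 to skip it).
#' @return A `fep_cycle` object: fields `mutation_label`, `ddg`, `sigma`,
#'   `legs` (complex/apo leg estimates), `coion`, `convergence`.
#' @export
compute_cycle <- function(manifest, n_chunks = 10) {
  if (is.character(manifest)) manifest <- read_cycle_manifest(manifest)
  legs <- purrr::map(manifest$legs[c("complex", "apo")], function(leg) {
    sched <- if (is.character(leg$schedule)) {
      read_schedule(leg$schedule)
    } else {
      validate_schedule(leg$schedule)
    }
    wins <- if (is.character(leg$windows)) {
      purrr::map(leg$windows, read_dvdl_window)
    } else {
      leg$windows
    }
    list(schedule = sched, windows = wins)
  })
  if (!isTRUE(all.equal(legs$complex$schedule$lambda,
                        legs$apo$schedule$lambda))) {
    rlang::warn("Complex and apo legs use different lambda schedules.")
  }
  frac <- manifest$equilibration_fraction %||% 0.1
  est <- purrr::map(legs, function(l) {
    estimate_leg(l$windows, l$schedule, equilibration_fraction = frac)
  })

  coion <- switch(manifest$coion_policy %||% "auto",
    auto = plan_coion(residue_charge_delta(manifest$source_residue,
                                           manifest$target_residue)),
    none = tibble::tibble(action = "none", protein_charge_delta = 0L),
    tibble::tibble(
      action = manifest$coion_policy,
      protein_charge_delta = as.integer(
        residue_charge_delta(manifest$source_residue,
                             manifest$target_residue))
    )
  )

  conv <- if (n_chunks >= 1) {
    convergence_profile(legs$complex$windows, legs$apo$windows,
                        legs$complex$schedule, n_chunks = n_chunks,
                        direction = "both", equilibration_fraction = frac)
  } else {
    tibble::tibble(direction = character(), fraction = numeric(),
                   ddg = numeric(), sigma = numeric())
  }

  structure(
    list(
      mutation_label = manifest$mutation_label %||% NA_character_,
      ddg = est$complex$delta_g - est$apo$delta_g,
      sigma = sqrt(est$complex$sigma^2 + est$apo$sigma^2),
      legs = est,
      coion = coion,
      convergence = conv,
      temperature = manifest$temperature %||% NA_real_
    ),
    class = "fep_cycle"
  )
}

#' @export
print.fep_cycle <- function(x, ...) {
  cat(sprintf("<fep_cycle> %s\n", x$mutation_label))
  cat(sprintf("  ddG(bind) = %+.3f +/- %.3f kcal/mol\n", x$ddg, x$sigma))
  cat(sprintf("  complex leg: %+.3f +/- %.3f over %d windows\n",
              x$legs$complex$delta_g, x$legs$complex$sigma,
              x$legs$complex$n_windows))
  cat(sprintf("  apo leg:     %+.3f +/- %.3f over %d windows\n",
              x$legs$apo$delta_g, x$legs$apo$sigma, x$legs$apo$n_windows))
  cat(sprintf("  co-ion: %s (protein charge delta %+d)\n",
              x$coion$action, x$coion$protein_charge_delta))
  invisible(x)
}

#' Tidy the per-window statistics of a cycle result
#'
#' @param x A `fep_cycle`.
#' @param ... Unused.
#' @return A tibble with one row per (leg, lambda window): columns
#'   `environment`, `lambda`, `n`, `mean`, `sem`, `g`, `n_eff`.
#' @method tidy fep_cycle
#' @export
tidy.fep_cycle <- function(x, ...) {
  purrr::map_dfr(c("complex", "apo"), function(env) {
    dplyr::mutate(x$legs[[env]]$window_stats, environment = env,
                  .before = 1)
  })
}

#' One-row summary of a cycle result
#'
#' @param x A `fep_cycle`.
#' @param ... Unused.
#' @return A one-row tibble: `mutation_label`, `ddg`, `sigma`,
#'   per-leg estimates, and the co-ion action.
#' @method glance fep_cycle
#' @export
glance.fep_cycle <- function(x, ...) {
  tibble::tibble(
    mutation_label = x$mutation_label,
    ddg = x$ddg,
    sigma = x$sigma,
    dg_complex = x$legs$complex$delta_g,
    sigma_complex = x$legs$complex$sigma,
    dg_apo = x$legs$apo$delta_g,
    sigma_apo = x$legs$apo$sigma,
    n_windows = x$legs$complex$n_windows,
    coion_action = x$coion$action
  )
}
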