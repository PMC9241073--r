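#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.9872e-3

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G_b = RT \ln K_d} with the Kd expressed in molar units
#' (standard state 1 M), R = 1.9872e-3 kcal/(mol K).
#'
#' @param kd Dissociation constant in molar units (> 0).
#' @param temperature Temperature in kelvin (default 298.15).
#' @return Binding free energy in kcal/mol.
#' @export
dg_from_kd <- function(kd, temperature = 298.15) {
  if (any(!is.finite(kd) | kd <= 0)) {
    rlang::abort("`kd` must be positive and finite.")
  }
  if (any(!is.finite(temperature) | temperature <= 0)) {
    rlang::abort("`temperature` must be positive.")
  }
  R_KCAL * temperature * log(kd)
}

#' Experimental relative binding free energy from two Kd values
#'
#' \eqn{\Delta\Delta G_b = RT \ln (K_d^{mut} / K_d^{wt})}; the Kd unit
#' cancels, so nanomolar values can be passed directly. The default
#' 298.15 K reproduces published experimental ddG tables derived from
#' room-temperature Kd measurements (a 303 K simulation temperature does
#' not, and is available through the `temperature` argument).
#'
#' @param kd_mut,kd_wt Mutant and wild-type dissociation constants (same
#'   unit, > 0).
#' @param temperature Temperature in kelvin.
#' @return Relative binding free energy in kcal/mol (positive =
#'   destabilizing mutation).
#' @export
ddg_exp <- function(kd_mut, kd_wt, temperature = 298.15) {
  if (any(!is.finite(kd_mut) | kd_mut <= 0) ||
      any(!is.finite(kd_wt) | kd_wt <= 0)) {
    rlang::abort("Dissociation constants must be positive.")
  }
  R_KCAL * temperature * log(kd_mut / kd_wt)
}

#' First-order error of an experimental ddG
#'
#' Propagates the variant's Kd uncertainty only:
#' \eqn{\sigma_{\Delta\Delta G} = RT \, \sigma_{K_d} / K_d}. This
#' convention (no wild-type contribution) reproduces published
#' experimental error columns entry by entry and is documented as
#' inferred from them.
#'
#' @param kd The variant's Kd (> 0, any unit).
#' @param kd_sd Its standard deviation (same unit, >= 0).
#' @param temperature Temperature in kelvin.
#' @return One standard deviation in kcal/mol.
#' @export
ddg_exp_error <- function(kd, kd_sd, temperature = 298.15) {
  if (any(!is.finite(kd) | kd <= 0)) {
    rlang::abort("`kd` must be positive.")
  }
  if (any(kd_sd < 0, na.rm = TRUE)) {
    rlang::abort("`kd_sd` must be non-negative.")
  }
  R_KCAL * temperature * kd_sd / kd
}

#' Mean absolute error between computed and experimental values
#'
#' @param exp,comp Numeric vectors of equal length (kcal/mol).
#' @return Mean of |comp - exp| in kcal/mol.
#' @export
mae <- function(exp, comp) {
  if (length(exp) == 0L) rlang::abort("Cannot take the MAE of zero pairs.")
  if (length(exp) != length(comp)) {
    rlang::abort("`exp` and `comp` must have equal length.")
  }
  mean(abs(comp - exp))
}

#' Pearson correlation between computed and experimental values
#'
#' A thin wrapper over [stats::cor()] that rejects degenerate inputs
#' (fewer than two pairs, or zero variance on either side) instead of
#' returning NA.
#'
#' @inheritParams mae
#' @return Sample Pearson correlation coefficient.
#' @export
pearson <- function(exp, comp) {
  if (length(exp) != length(comp)) {
    rlang::abort("`exp` and `comp` must have equal length.")
  }
  if (length(exp) < 2L) {
    rlang::abort("Pearson correlation needs >= 2 pairs.")
  }
  if (stats::sd(exp) == 0 || stats::sd(comp) == 0) {
    rlang::abort("Pearson correlation undefined: zero variance.")
  }
  stats::cor(exp, comp)
}

#' Score computed ddG values against the experimental benchmark
#'
#' Fills the experimental ddG (and its error) for every record from its
#' Kd relative to the wild-type Kd; lower-bound Kd rows are converted at
#' the bound value and flagged. When the table carries a printed
#' experimental column (`ddg_exp_print`), statistics use it (it is the
#' published reference, and one record's printed value is inconsistent
#' with its printed Kd); otherwise the Kd-derived values are used. The
#' wild-type self-row is excluded from the statistics by default.
#'
#' @param records A benchmark tibble (see [read_benchmark_table()] /
#'   [cdc42_pak1_benchmark()]).
#' @param comp Bare name of the computed-ddG column to score (default
#'   `ddg_comp_kcal`).
#' @param temperature Kd-to-ddG conversion temperature in kelvin.
#' @param subset Optional character vector of mutation labels to keep.
#' @param include_wildtype Keep the wild-type control row in the
#'   statistics (default FALSE).
#' @param wt_label Label of the wild-type row (default "wild-type").
#' @param subset_label Free-text label stored with the statistics.
#' @return A `fep_benchmark` object: `table` (per-record tibble with
#'   `ddg_exp`, `ddg_exp_sd`, `ddg_comp`, `abs_error` columns) and
#'   `stats` (one-row tibble: `n`, `mae`, `pearson_r`, `subset_label`).
#'   `pearson_r` is NA (with a warning) when fewer than two scorable
#'   records remain.
#' @export
run_benchmark <- function(records, comp = ddg_comp_kcal,
                          temperature = 298.15, subset = NULL,
                          include_wildtype = FALSE,
                          wt_label = "wild-type",
                          subset_label = "all") {
  comp_quo <- rlang::enquo(comp)
  wt <- records[records$mutation == wt_label, ]
  if (nrow(wt) != 1L) {
    rlang::abort(sprintf("Expected exactly one '%s' row.", wt_label))
  }
  kd_wt <- wt$kd_nM

  tab <- records |>
    dplyr::mutate(
      ddg_exp_kd = ddg_exp(.data$kd_nM, kd_wt, temperature),
      ddg_exp_sd_kd = ddg_exp_error(.data$kd_nM, .data$kd_sd_nM,
                                    temperature),
      ddg_comp = !!comp_quo
    )
  has_printed <- "ddg_exp_print" %in% names(records)
  tab <- dplyr::mutate(
    tab,
    ddg_exp = if (has_printed) {
      dplyr::coalesce(.data$ddg_exp_print, .data$ddg_exp_kd)
    } else {
      .data$ddg_exp_kd
    },
    ddg_exp_sd = if (has_printed && "ddg_exp_sd_print" %in% names(records)) {
      dplyr::coalesce(.data$ddg_exp_sd_print, .data$ddg_exp_sd_kd)
    } else {
      .data$ddg_exp_sd_kd
    },
    abs_error = abs(.data$ddg_comp - .data$ddg_exp)
  )

  scor <- tab
  if (!include_wildtype) scor <- scor[scor$mutation != wt_label, ]
  if (!is.null(subset)) {
    missing <- setdiff(subset, scor$mutation)
    if (length(missing)) {
      rlang::abort(sprintf("Subset label(s) not in table: %s",
                           paste(missing, collapse = ", ")))
    }
    scor <- scor[scor$mutation %in% subset, ]
  }
  scor <- scor[!is.na(scor$ddg_comp) & !is.na(scor$ddg_exp), ]
  if (nrow(scor) == 0L) rlang::abort("No scorable records remain.")

  r <- if (nrow(scor) >= 2L &&
           stats::sd(scor$ddg_exp) > 0 && stats::sd(scor$ddg_comp) > 0) {
    pearson(scor$ddg_exp, scor$ddg_comp)
  } else {
    rlang::warn("Pearson r undefined for this subset; reporting NA.")
    NA_real_
  }
  stats_row <- tibble::tibble(
    n = nrow(scor),
    mae = mae(scor$ddg_exp, scor$ddg_comp),
    pearson_r = r,
    subset_label = subset_label
  )
  structure(
    list(table = tab, scored = scor$mutation, stats = stats_row,
         temperature = temperature),
    class = "fep_benchmark"
  )
}

#' @export
print.fep_benchmark <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<fep_benchmark> %s: n = %d\n", s$subset_label, s$n))
  cat(sprintf("  MAE = %.1f kcal/mol (full precision %.4f)\n",
              round(s$mae, 1), s$mae))
  if (is.na(s$pearson_r)) {
    cat("  Pearson r: undefined for this subset\n")
  } else {
    cat(sprintf("  Pearson r = %.2f\n", s$pearson_r))
  }
  invisible(x)
}

#' Per-record table of a benchmark run
#'
#' @param x A `fep_benchmark`.
#' @param ... Unused.
#' @return The per-record tibble with experimental and computed ddG
#'   columns, absolute errors, and a `scored` flag marking rows that
#'   entered the statistics.
#' @method tidy fep_benchmark
#' @export
tidy.fep_benchmark <- function(x, ...) {
  dplyr::mutate(x$table, scored = .data$mutation %in% x$scored)
}

#' One-row statistics of a benchmark run
#'
#' @param x A `fep_benchmark`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `mae`, `pearson_r`, `subset_label`.
#' @method glance fep_benchmark
#' @export
glance.fep_benchmark <- function(x, ...) {
  x$stats
}
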