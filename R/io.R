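#' Read a lambda schedule from a two-column text file
#'
#' The on-disk dialect is two whitespace-separated columns (lambda,
#' weight); lines starting with `#` are comments. Energies are kcal/mol
#' and temperatures kelvin everywhere on disk; no unit autodetection is
#' attempted. Malformed input is rejected, never repaired.
#'
#' @param path Path to the schedule file.
#' @return A `lambda_schedule` tibble (columns `lambda`, `weight`).
#' @export
read_schedule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    rlang::abort(sprintf("Schedule file '%s' has no data lines.", path))
  }
  parse_row <- function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 2L || any(is.na(vals))) {
      rlang::abort(sprintf(
        "Malformed schedule line %d in '%s': '%s'", i, path, lines[i]
      ))
    }
    vals
  }
  m <- vapply(keep, parse_row, numeric(2))
  sched <- tibble::tibble(lambda = m[1, ], weight = m[2, ])
  validate_schedule(sched)
  new_lambda_schedule(sched)
}

#' Write a lambda schedule
#'
#' @param schedule A `lambda_schedule` (columns `lambda`, `weight`).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  lines <- c(
    "# lambda  weight",
    sprintf("%.17g %.17g", schedule$lambda, schedule$weight)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read one window's dV/dlambda series
#'
#' Window files carry a `# lambda=<value>` header line followed by two
#' whitespace-separated columns: step (or time) and dV/dlambda in
#' kcal/mol.
#'
#' @param path Path to the window file.
#' @return A `dvdl_series`.
#' @export
read_dvdl_window <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#\\s*lambda\\s*=", lines, value = TRUE)
  if (length(hdr) == 0L) {
    rlang::abort(sprintf("Window file '%s' lacks a '# lambda=' header.", path))
  }
  lam <- suppressWarnings(as.numeric(sub("^#\\s*lambda\\s*=\\s*", "", hdr[1])))
  if (is.na(lam)) {
    rlang::abort(sprintf("Unparseable lambda header in '%s'.", path))
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    rlang::abort(sprintf("Window file '%s' has no samples.", path))
  }
  vals <- vapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (length(v) != 2L || any(is.na(v))) {
      rlang::abort(sprintf(
        "Malformed sample line %d in '%s': '%s'", i, path, lines[i]
      ))
    }
    v[2]
  }, numeric(1))
  dvdl_series(vals, lambda = lam)
}

#' Write one window's dV/dlambda series
#'
#' @param series A `dvdl_series`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_dvdl_window <- function(series, path) {
  lines <- c(
    sprintf("# lambda=%.17g", series_lambda(series)),
    sprintf("%d %.17g", series$step, series$dvdl)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Extract dV/dlambda samples from an MD engine log
#'
#' Scans a free-form text log for lines containing the literal token
#' `DV/DL` and takes the last numeric field on each matching line, in file
#' order. Engine logs usually end with average/RMS summary blocks that
#' repeat the token; `skip_last` drops that many trailing matches (default
#' 0, i.e. take everything).
#'
#' @param path Path to the log file.
#' @param lambda Lambda value to attach to the extracted series.
#' @param skip_last Number of trailing matched lines to discard.
#' @return A `dvdl_series`.
#' @export
extract_dvdl_from_engine_log <- function(path, lambda = NA_real_,
                                         skip_last = 0) {
  lines <- readLines(path, warn = FALSE)
  hits <- grep("DV/DL", lines, fixed = TRUE, value = TRUE)
  if (skip_last > 0 && skip_last < length(hits)) {
    hits <- hits[seq_len(length(hits) - skip_last)]
  } else if (skip_last >= length(hits)) {
    hits <- character(0)
  }
  if (length(hits) == 0L) {
    rlang::abort(sprintf("No 'DV/DL' samples found in '%s'.", path))
  }
  vals <- vapply(hits, function(ln) {
    nums <- regmatches(ln, gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", ln))[[1]]
    if (length(nums) == 0L) {
      rlang::abort(sprintf("No numeric field on DV/DL line: '%s'", ln))
    }
    as.numeric(nums[length(nums)])
  }, numeric(1), USE.NAMES = FALSE)
  dvdl_series(vals, lambda = lambda)
}

#' Read an experimental benchmark table
#'
#' Reads a CSV with mandatory columns `mutation`, `kd_nM`, `kd_sd_nM`,
#' `kd_is_lower_bound` and optional per-row computed columns
#' (`ddg_comp_kcal`, `ddg_comp_sd_kcal`, plus any further `ddg_*`
#' columns, which are carried through untouched). Unicode en-dash and
#' minus signs are normalized to ASCII minus before parsing. Lower-bound
#' rows (Kd reported as "> x") carry the bound in `kd_nM`, no `kd_sd_nM`,
#' and `kd_is_lower_bound = TRUE`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per record.
#' @export
read_benchmark_table <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- gsub("–|−|—", "-", raw)
  df <- utils::read.csv(text = raw, stringsAsFactors = FALSE,
                        check.names = TRUE)
  mandatory <- c("mutation", "kd_nM", "kd_sd_nM", "kd_is_lower_bound")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "Benchmark table '%s' lacks mandatory column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  df$kd_is_lower_bound <- as.logical(df$kd_is_lower_bound)
  df$kd_is_lower_bound[is.na(df$kd_is_lower_bound)] <- FALSE
  if (any(!is.finite(df$kd_nM) | df$kd_nM <= 0)) {
    rlang::abort(sprintf(
      "Benchmark table '%s' contains non-positive or missing Kd values.", path
    ))
  }
  if (any(df$kd_is_lower_bound & !is.na(df$kd_sd_nM))) {
    rlang::abort("Lower-bound Kd rows must not carry a Kd standard deviation.")
  }
  tibble::as_tibble(df)
}

#' Packaged CDC42/PAK1 mutation benchmark table
#'
#' Returns the packaged benchmark of 16 single-point CDC42 mutations (plus
#' the wild-type control row) at the CDC42/PAK1 interface: experimental
#' dissociation constants with uncertainties or lower bounds, the printed
#' experimental ddG column, final and superseded-initial alchemical ddG
#' estimates, and MM/GBSA direct and alanine-scanning values where
#' reported.
#'
#' @return A tibble with 17 rows (see [read_benchmark_table()] for the
#'   column dialect).
#' @export
cdc42_pak1_benchmark <- function() {
  read_benchmark_table(
    system.file("extdata", "cdc42_pak1_table1.csv", package = "alchemr",
                mustWork = TRUE)
  )
}

#' Read a thermodynamic-cycle manifest
#'
#' Manifests are YAML documents describing one mutation's pair of
#' transformation legs. Required fields: `mutation_label`, `position`,
#' `source_residue`, `target_residue`, `temperature` (kelvin), `legs`
#' (exactly two entries named `complex` and `apo`, each with `schedule`
#' and `windows` paths). Optional: `equilibration_fraction` (default 0.1)
#' and `coion_policy` (`auto`, `none`, or an explicit action; default
#' `auto`). Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the YAML manifest.
#' @return A named list of class `cycle_manifest`.
#' @export
read_cycle_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path, mustWork = TRUE))
  required <- c("mutation_label", "position", "source_residue",
                "target_residue", "temperature", "legs")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "Manifest '%s' lacks field(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  if (!setequal(names(m$legs), c("complex", "apo"))) {
    rlang::abort("Manifest must define exactly two legs: 'complex' and 'apo'.")
  }
  m$equilibration_fraction <- m$equilibration_fraction %||% 0.1
  m$coion_policy <- m$coion_policy %||% "auto"
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (leg in c("complex", "apo")) {
    m$legs[[leg]]$schedule <- resolve(m$legs[[leg]]$schedule)
    m$legs[[leg]]$windows <- resolve(unlist(m$legs[[leg]]$windows))
  }
  class(m) <- "cycle_manifest"
  m
}

#' Write a thermodynamic-cycle manifest
#'
#' @param manifest A `cycle_manifest`-shaped named list (see
#'   [read_cycle_manifest()] for the fields).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cycle_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  yaml::write_yaml(m, path)
  invisible(path)
}

#' Write a cycle or benchmark result document
#'
#' Serializes a `fep_cycle` or `fep_benchmark` result to a structured
#' JSON document that round-trips every numeric field (full double
#' precision) and can be re-read with [read_results()].
#'
#' @param result A `fep_cycle` or `fep_benchmark` object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  payload <- if (inherits(result, "fep_cycle")) {
    list(
      kind = "cycle",
      mutation_label = result$mutation_label,
      ddg = result$ddg,
      sigma = result$sigma,
      coion = result$coion,
      legs = purrr::map(result$legs, function(l) list(
        delta_g = l$delta_g,
        sigma = l$sigma,
        n_windows = l$n_windows,
        window_stats = as.list(l$window_stats)
      )),
      convergence = as.list(result$convergence %||% tibble::tibble())
    )
  } else if (inherits(result, "fep_benchmark")) {
    list(
      kind = "benchmark",
      stats = as.list(result$stats),
      table = as.list(result$table)
    )
  } else {
    rlang::abort("`result` must be a fep_cycle or fep_benchmark object.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result document written by [write_results()]
#'
#' @param path Path to the JSON document.
#' @return A list mirroring the serialized structure; tabular sections are
#'   restored as tibbles.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$kind, "cycle")) {
    x$legs <- purrr::map(x$legs, function(l) {
      l$window_stats <- tibble::as_tibble(l$window_stats)
      l
    })
    x$convergence <- tibble::as_tibble(x$convergence)
  } else if (identical(x$kind, "benchmark")) {
    x$stats <- tibble::as_tibble(x$stats)
    x$table <- tibble::as_tibble(x$table)
  }
  x
}
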