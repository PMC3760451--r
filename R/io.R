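# File input/output: compound definitions, contact angles, liquid constants,
# parameter tables.

#' Read compound definitions
#'
#' Reads a compound table from JSON (one object per molecule with keys
#' `name`, `formula`, `density` or `molar_volume`, `groups` (label -> count),
#' `symmetry_planes`, `role`; either a top-level array or an object with a
#' `compounds` array) or from CSV (columns `name`, `formula`,
#' `molar_volume` and/or `density`, `symmetry_planes`, `role`, plus one
#' column per structural group label holding counts).
#'
#' Validation is record-level and aggregated: every offending record is
#' listed in a single error, none is silently dropped.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @param include_supplementary Keep records flagged `supplementary` in the
#'   file. Default `FALSE`.
#' @return A compounds tibble suitable for [hansen_parameters()].
#' @export
read_compounds <- function(path, include_supplementary = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "phytosol_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext == "json") read_compounds_json(path)
          else read_compounds_csv(path)
  if (!length(recs)) {
    warn(paste0("no compound records in ", path))
    return(empty_compounds())
  }
  problems <- character()
  rows <- purrr::imap(recs, function(rec, i) {
    label <- rec$name %||% paste0("record ", i)
    errs <- character()
    if (is.null(rec$name) || !nzchar(rec$name)) errs <- c(errs, "missing name")
    if (is.null(rec$molar_volume) && is.null(rec$density)) {
      errs <- c(errs, "needs molar_volume or density")
    }
    groups <- tryCatch(as_group_counts(rec$groups),
                       error = function(e) {
                         errs <<- c(errs, conditionMessage(e))
                         NULL
                       })
    if (length(errs)) {
      problems <<- c(problems,
                     paste0(label, " (record ", i, "): ",
                            paste(errs, collapse = "; ")))
      return(NULL)
    }
    tibble::tibble(
      name = rec$name,
      formula = rec$formula %||% NA_character_,
      molar_volume = rec$molar_volume %||% NA_real_,
      density = rec$density %||% NA_real_,
      role = rec$role %||% "other",
      symmetry_planes = rec$symmetry_planes %||% 0,
      supplementary = isTRUE(rec$supplementary),
      groups = list(groups)
    )
  })
  if (length(problems)) {
    abort(paste0("invalid compound records in ", path, ":\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "phytosol_io_error")
  }
  out <- dplyr::bind_rows(rows)
  if (!include_supplementary) out <- out[!out$supplementary, ]
  out
}

empty_compounds <- function() {
  tibble::tibble(name = character(), formula = character(),
                 molar_volume = numeric(), density = numeric(),
                 role = character(), symmetry_planes = numeric(),
                 supplementary = logical(), groups = list())
}

read_compounds_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$compounds)) raw <- raw$compounds
  purrr::map(raw, function(rec) {
    rec$groups <- unlist(rec$groups)
    rec
  })
}

read_compounds_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(df)) return(list())
  meta <- c("name", "formula", "molar_volume", "density", "role",
            "symmetry_planes", "supplementary", "activity", "notes")
  group_cols <- setdiff(names(df), meta)
  purrr::map(seq_len(nrow(df)), function(i) {
    counts <- unlist(df[i, group_cols])
    counts <- counts[!is.na(counts) & counts > 0]
    rec <- as.list(df[i, intersect(meta, names(df))])
    rec$groups <- counts
    rec
  })
}

#' Write a solubility parameter table to CSV
#'
#' Numbers are written at full precision by default; `digits` adds
#' display-rounded copies of the delta columns (`*_rounded`), mirroring the
#' 0.1 reference precision when `digits = 1`.
#'
#' @param params A `hansen_tbl` (or any data frame).
#' @param path Output path.
#' @param digits Optional rounding for display columns.
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(params, path, digits = NULL) {
  df <- tibble::as_tibble(params)
  df <- df[!purrr::map_lgl(df, is.list)]
  if (!is.null(digits)) {
    for (col in intersect(c("delta_d", "delta_p", "delta_h", "delta_total"),
                          names(df))) {
      df[[paste0(col, "_rounded")]] <- round(df[[col]], digits)
    }
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a contact angle table
#'
#' @param path CSV with columns `surface`, `liquid`, `theta_mean_deg` and
#'   optionally `theta_sd_deg`, `n`.
#' @return A validated tibble.
#' @export
read_contact_angles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("surface", "liquid", "theta_mean_deg")
  if (!all(need %in% names(df))) {
    abort(paste0("contact angle file must have columns ",
                 paste(need, collapse = ", ")),
          class = "phytosol_io_error")
  }
  check_angle(df$theta_mean_deg)
  if ("theta_sd_deg" %in% names(df) &&
      any(df$theta_sd_deg < 0, na.rm = TRUE)) {
    abort("theta_sd_deg must be non-negative", class = "phytosol_io_error")
  }
  if ("n" %in% names(df) && any(df$n < 1, na.rm = TRUE)) {
    abort("n must be >= 1", class = "phytosol_io_error")
  }
  tibble::as_tibble(df)
}

#' Read probe liquid constants
#'
#' JSON (top-level array or a `liquids` array) or YAML keyed by liquid name;
#' each record needs `gamma_total`, `gamma_lw`, `gamma_plus`, `gamma_minus`.
#' The result is merged over the defaults and validated by
#' [probe_liquids()].
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A probe liquid tibble.
#' @export
read_liquids <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML liquid files requires the 'yaml' package",
            class = "phytosol_io_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (!is.null(raw$liquids)) raw <- raw$liquids
  if (!is.null(names(raw)) && all(nzchar(names(raw)))) {
    raw <- purrr::imap(raw, function(rec, nm) c(list(liquid = nm), rec))
  }
  override <- purrr::map_dfr(raw, tibble::as_tibble)
  probe_liquids(override = override)
}

#' Run configuration
#'
#' Bundles and validates the knobs shared across the pipeline.
#'
#' @param symmetry_mode See [delta_polar()].
#' @param negative_roots See [solve_acid_base()].
#' @param miscible_limit,immiscible_limit See [classify_miscibility()].
#' @param n_draws,seed Contact-angle resampling control.
#' @param digits Display precision (decimal places, >= 1).
#' @return A named list of class `phytosol_config`.
#' @export
run_config <- function(symmetry_mode = c("on_delta_p", "on_squared_sum"),
                       negative_roots = c("square", "clamp"),
                       miscible_limit = 7, immiscible_limit = 10,
                       n_draws = 10000, seed = 20121114, digits = 1) {
  stopifnot(miscible_limit > 0, immiscible_limit > miscible_limit,
            n_draws >= 1, digits >= 1)
  structure(list(symmetry_mode = match.arg(symmetry_mode),
                 negative_roots = match.arg(negative_roots),
                 miscible_limit = miscible_limit,
                 immiscible_limit = immiscible_limit,
                 n_draws = n_draws, seed = seed, digits = digits),
            class = "phytosol_config")
}
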