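#' Read an analyte registry
#'
#' The registry records each antioxidant's identity and assessment inputs:
#' CAS number, chemical class, log Kow, specific migration limits
#' (substance-specific and/or recommended), NOAEL, RfD and Cramer class.
#' The file is a YAML (or JSON) document with a top-level `analytes` list;
#' see `system.file("extdata", "antioxidants.yaml", package = "migrisk")`
#' for the documented schema. Unknown keys raise a warning, never pass
#' silently.
#'
#' @param path Path to a YAML/JSON registry file.
#' @return A data frame of class `"ao_registry"`, one row per analyte, with
#'   columns `analyte_id`, `name`, `cas`, `chem_class`, `log_kow`,
#'   `sml_specific`, `sml_recommended`, `noael`, `rfd`, `cramer_class`.
#'   Optional fields absent from the file are `NA`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || is.null(doc$analytes)) {
    if (is.null(doc)) return(empty_registry())
    stop("registry file has no 'analytes' list", call. = FALSE)
  }
  known <- c("analyte_id", "name", "cas", "chem_class", "log_kow",
             "sml_specific", "sml_recommended", "noael", "rfd",
             "cramer_class", "provenance")
  rows <- lapply(seq_along(doc$analytes), function(i) {
    rec <- doc$analytes[[i]]
    extra <- setdiff(names(rec), known)
    if (length(extra))
      warning("registry record ", i, ": ignoring unknown field(s) ",
              paste(extra, collapse = ", "), call. = FALSE)
    for (f in c("analyte_id", "name"))
      if (is.null(rec[[f]]))
        stop("registry record ", i, ": missing mandatory field '", f, "'",
             call. = FALSE)
    num <- function(f) if (is.null(rec[[f]])) NA_real_ else {
      v <- as.numeric(rec[[f]])
      if (!is.finite(v) || v <= 0)
        stop("registry record '", rec$analyte_id, "': field '", f,
             "' must be strictly positive", call. = FALSE)
      v
    }
    chr <- function(f) if (is.null(rec[[f]])) NA_character_ else
      as.character(rec[[f]])
    data.frame(analyte_id = as.character(rec$analyte_id),
               name = as.character(rec$name),
               cas = chr("cas"),
               chem_class = chr("chem_class"),
               log_kow = if (is.null(rec$log_kow)) NA_real_ else
                 as.numeric(rec$log_kow),
               sml_specific = num("sml_specific"),
               sml_recommended = num("sml_recommended"),
               noael = num("noael"),
               rfd = num("rfd"),
               cramer_class = chr("cramer_class"),
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  if (is.null(reg)) return(empty_registry())
  if (anyDuplicated(reg$analyte_id))
    stop("duplicated analyte_id in registry: ",
         paste(unique(reg$analyte_id[duplicated(reg$analyte_id)]),
               collapse = ", "), call. = FALSE)
  bad_cc <- !is.na(reg$chem_class) & !reg$chem_class %in% .chem_classes
  if (any(bad_cc))
    stop("unknown chem_class: ",
         paste(unique(reg$chem_class[bad_cc]), collapse = ", "),
         call. = FALSE)
  bad_cr <- !is.na(reg$cramer_class) &
    !reg$cramer_class %in% c("I", "II", "III")
  if (any(bad_cr))
    stop("unknown cramer_class: ",
         paste(unique(reg$cramer_class[bad_cr]), collapse = ", "),
         call. = FALSE)
  class(reg) <- c("ao_registry", "data.frame")
  reg
}

empty_registry <- function() {
  structure(data.frame(analyte_id = character(), name = character(),
                       cas = character(), chem_class = character(),
                       log_kow = numeric(), sml_specific = numeric(),
                       sml_recommended = numeric(), noael = numeric(),
                       rfd = numeric(), cramer_class = character(),
                       stringsAsFactors = FALSE),
            class = c("ao_registry", "data.frame"))
}

.measurement_cols <- c("sample_id", "material_class", "product_type",
                       "medium", "temperature_c", "duration_h", "analyte_id",
                       "concentration_mg_per_kg", "censored", "lod", "loq")

#' Read a migration measurement table
#'
#' Measurements are stored as comma-separated text with one row per
#' sample x analyte x medium, columns `sample_id, material_class,
#' product_type, medium, temperature_c, duration_h, analyte_id,
#' concentration_mg_per_kg, censored, lod, loq`. Concentrations are in
#' mg/kg throughout (the 10^-3 mg/kg scale common in migration tables is a
#' display convention only). Censored rows (below the limit of detection)
#' carry `censored = TRUE`; their concentration cell may be empty and is
#' ignored downstream, where an explicit non-detect convention is applied
#' instead. LOD and LOQ are stored per row because detection limits differ
#' across media.
#'
#' @param path Path to the CSV file.
#' @param registry Optional `"ao_registry"`; when supplied, every
#'   `analyte_id` must resolve in it.
#' @return A data frame of class `"migration_data"`.
#' @seealso [write_measurements()], [summarize_migration()]
#' @export
read_measurements <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("measurements file not found: ", path,
                               call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.measurement_cols, names(x))
  if (length(missing_cols))
    stop("measurements file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- x[.measurement_cols]
  x$censored <- as.logical(x$censored)
  as_migration_data(x, registry = registry)
}

#' Validate a migration measurement table
#'
#' Checks the closed vocabularies (material class, medium), non-negative
#' concentrations, `lod <= loq` and (optionally) that analytes resolve in a
#' registry, then stamps the `"migration_data"` class.
#'
#' @param x A data frame with the measurement columns (see
#'   [read_measurements()]).
#' @param registry Optional `"ao_registry"` used to resolve `analyte_id`.
#' @return `x`, validated, of class `"migration_data"`.
#' @export
as_migration_data <- function(x, registry = NULL) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.measurement_cols, names(x))
  if (length(missing_cols))
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !x$material_class %in% .material_classes
  if (any(bad))
    stop("unknown material_class: ",
         paste(unique(x$material_class[bad]), collapse = ", "),
         call. = FALSE)
  bad <- !x$medium %in% .media
  if (any(bad))
    stop("unknown medium: ", paste(unique(x$medium[bad]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(x$censored)))
    stop("'censored' must be TRUE/FALSE for every row", call. = FALSE)
  conc <- x$concentration_mg_per_kg
  if (any(!x$censored & (is.na(conc) | conc < 0)))
    stop("detected rows need a non-negative concentration_mg_per_kg",
         call. = FALSE)
  if (any(!is.na(conc) & conc < 0))
    stop("negative concentration_mg_per_kg", call. = FALSE)
  if (any(is.na(x$lod) | is.na(x$loq) | x$lod > x$loq))
    stop("every row needs lod <= loq", call. = FALSE)
  if (!is.null(registry)) {
    unknown <- setdiff(x$analyte_id, registry$analyte_id)
    if (length(unknown))
      stop("analyte_id not in registry: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!inherits(x, "migration_data"))
    class(x) <- c("migration_data", class(x))
  x
}

#' Write a migration measurement table
#'
#' Inverse of [read_measurements()]: writes the documented CSV layout so
#' that a read/write round trip reproduces the table cell for cell.
#'
#' @param x A `"migration_data"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  stopifnot(inherits(x, "migration_data"))
  utils::write.csv(as.data.frame(x)[.measurement_cols], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Resolve the specific migration limit for each analyte
#'
#' Applies the regulatory fallback chain: the substance-specific limit when
#' one exists, else the recommended limit, else the default limit (60 mg/kg
#' unless overridden in [exposure_constants()]). The provenance of the
#' chosen limit is reported alongside the value.
#'
#' @param registry An `"ao_registry"` data frame (or one row of it).
#' @param constants An [exposure_constants()] object.
#' @return Data frame with columns `analyte_id`, `sml` (mg/kg) and
#'   `sml_source` (`"specific"`, `"recommended"` or `"default"`).
#' @examples
#' reg <- read_registry(system.file("extdata", "antioxidants.yaml",
#'                                  package = "migrisk"))
#' resolve_sml(reg[reg$analyte_id == "irganox_1076", ])
#' @export
resolve_sml <- function(registry, constants = exposure_constants()) {
  stopifnot(is.data.frame(registry))
  sml <- ifelse(!is.na(registry$sml_specific), registry$sml_specific,
                ifelse(!is.na(registry$sml_recommended),
                       registry$sml_recommended, constants$sml_default))
  src <- ifelse(!is.na(registry$sml_specific), "specific",
                ifelse(!is.na(registry$sml_recommended), "recommended",
                       "default"))
  data.frame(analyte_id = registry$analyte_id, sml = sml, sml_source = src,
             stringsAsFactors = FALSE)
}

#' Read an exposure parameter configuration
#'
#' Parses a YAML document describing the Monte Carlo exposure parameter
#' distributions (`fc`, `ef`, `ed`, `bw`, optionally a per-analyte `c`
#' block) and the iteration count. Each parameter entry is a mapping with a
#' `family` key (`point`, `uniform`, `triangular`, `normal`, `lognormal`,
#' `empirical`) and family-specific parameters, plus an optional
#' `truncation: [low, high]`; see [dist_spec()]. Unknown parameter names
#' warn.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `n_iter` and `parameters` (named list of
#'   [dist_spec()] objects), plus `c` (named list per analyte) if present.
#' @export
read_exposure_config <- function(path) {
  if (!file.exists(path)) stop("exposure config not found: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  known <- c("schema", "n_iter", "parameters", "c")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning("exposure config: ignoring unknown key(s) ",
            paste(extra, collapse = ", "), call. = FALSE)
  parse_spec <- function(entry, what) {
    if (is.null(entry$family))
      stop("exposure config: '", what, "' needs a 'family' key",
           call. = FALSE)
    args <- entry[setdiff(names(entry), c("family", "truncation"))]
    tr <- if (!is.null(entry$truncation)) as.numeric(entry$truncation)
    do.call(dist_spec, c(list(family = entry$family, truncation = tr), args))
  }
  pars <- lapply(names(doc$parameters), function(nm)
    parse_spec(doc$parameters[[nm]], nm))
  names(pars) <- names(doc$parameters)
  out <- list(n_iter = if (is.null(doc$n_iter)) 10000L else
                as.integer(doc$n_iter),
              parameters = pars)
  if (!is.null(doc$c)) {
    out$c <- lapply(names(doc$c), function(nm)
      parse_spec(doc$c[[nm]], paste0("c/", nm)))
    names(out$c) <- names(doc$c)
  }
  out
}

#' Read FDA consumption-factor weights
#'
#' Parses a YAML document with a scalar `cf` (consumption factor, fraction
#' of the diet contacting the packaging type, in (0, 1]) and an `ft`
#' mapping giving the food-type distribution over the four regulatory food
#' classes `aqueous`, `acidic`, `alcoholic`, `fatty` (must sum to 1).
#'
#' @param path Path to the YAML file.
#' @return An object of class `"fda_weights"`; see [fda_weights()].
#' @export
read_fda_weights <- function(path) {
  if (!file.exists(path)) stop("FDA weights file not found: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$cf) || is.null(doc$ft))
    stop("FDA weights file needs 'cf' and 'ft' keys", call. = FALSE)
  fda_weights(cf = as.numeric(doc$cf), ft = unlist(doc$ft))
}
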