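#' Run the full migration-to-exposure pipeline
#'
#' Orchestrates an end-to-end assessment: group summaries under an
#' explicit non-detect convention, a specific-migration-limit screen,
#' deterministic EU and FDA risk tables, and per-analyte Monte Carlo
#' exposure profiles. Each report is written as delimited text (units in
#' the header) alongside a JSON run manifest recording package version,
#' seed and conventions, so that re-running an identical configuration
#' reproduces the bundle file for file.
#'
#' A framework lacking its required inputs is skipped with a warning, not
#' an error: FDA needs `weights`, the Monte Carlo stage needs an exposure
#' parameter config plus, per analyte, a log Kow and an RfD (or Cramer
#' class) in the registry.
#'
#' @param measurements A `"migration_data"` data frame or path to a
#'   measurements CSV.
#' @param registry An `"ao_registry"` or path to a registry YAML.
#' @param out_dir Output directory (created if needed).
#' @param convention Non-detect convention for the summary tables (see
#'   [summarize_migration()]).
#' @param frameworks Subset of `c("eu", "fda", "mc")` to run.
#' @param weights Optional [fda_weights()] (or path to a weights YAML).
#' @param exposure_config Optional result of [read_exposure_config()] (or
#'   a path). Its `parameters` block supplies `fc`, `ef`, `ed`, `bw`; the
#'   dietary concentration C is taken from its `c` block when present,
#'   else from the empirical distribution of the measurements
#'   (non-detects as zero).
#' @param constants An [exposure_constants()] object.
#' @param seed Integer seed for the Monte Carlo stage.
#' @param verbose Print progress messages.
#' @return Invisibly, a list of the report tables
#'   (`summary`, `sml_screen`, `eu`, `fda`, `mc`, `manifest`).
#' @export
run_pipeline <- function(measurements, registry, out_dir,
                         convention = "nd_as_zero",
                         frameworks = c("eu", "fda", "mc"),
                         weights = NULL, exposure_config = NULL,
                         constants = exposure_constants(), seed = 1,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(measurements))
    measurements <- read_measurements(measurements, registry)
  measurements <- as_migration_data(as.data.frame(measurements), registry)
  if (is.character(weights)) weights <- read_fda_weights(weights)
  if (is.character(exposure_config))
    exposure_config <- read_exposure_config(exposure_config)
  frameworks <- match.arg(frameworks, c("eu", "fda", "mc"),
                          several.ok = TRUE)
  convention <- resolve_convention(convention)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE,
                     quote = FALSE, na = "")
  }
  skipped <- character()

  say("summarising migration data (", convention, ")")
  summ <- summarize_migration(measurements,
                              by = c("material_class", "analyte_id"),
                              convention = convention)
  names(summ)[names(summ) %in% c("mean", "sd", "median", "max")] <-
    c("mean_mg_per_kg", "sd_mg_per_kg", "median_mg_per_kg", "max_mg_per_kg")
  emit(summ, "migration_summary.csv")

  overall <- summarize_migration(measurements, by = "analyte_id",
                                 convention = convention)
  screen <- sml_screen(overall, registry, constants)
  names(screen)[names(screen) %in% c("max", "sml", "margin")] <-
    c("max_mg_per_kg", "sml_mg_per_kg", "margin_mg_per_kg")
  emit(screen, "sml_screen.csv")

  results <- list(summary = summ, sml_screen = screen)
  max_mig <- stats::setNames(ifelse(is.na(overall$max), 0, overall$max),
                             overall$analyte_id)

  if ("eu" %in% frameworks) {
    say("EU deterministic assessment (worst-case migration)")
    eu <- tryCatch(assess_eu(max_mig, registry, constants),
                   error = function(e) {
                     warning("EU framework skipped: ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    if (!is.null(eu)) {
      names(eu)[names(eu) == "m_max"] <- "m_max_mg_per_kg"
      names(eu)[names(eu) == "edi"] <- "edi_mg_per_kg_bw_day"
      emit(eu, "exposure_eu.csv")
      results$eu <- eu
    } else skipped <- c(skipped, "eu")
  }

  if ("fda" %in% frameworks) {
    if (is.null(weights)) {
      warning("FDA framework skipped: no CF/f_T weights supplied",
              call. = FALSE)
      skipped <- c(skipped, "fda")
    } else {
      say("FDA deterministic assessment")
      by_med <- summarize_migration(measurements,
                                    by = c("analyte_id", "medium"),
                                    convention = convention)
      m_list <- lapply(split(by_med, by_med$analyte_id), function(g)
        stats::setNames(ifelse(is.na(g$max), 0, g$max), g$medium))
      fda <- withCallingHandlers(
        tryCatch(assess_fda(m_list, weights, registry, constants),
                 error = function(e) {
                   warning("FDA framework skipped: ", conditionMessage(e),
                           call. = FALSE)
                   NULL
                 }),
        warning = function(w) {
          if (grepl("treated as 0", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      if (!is.null(fda)) {
        names(fda)[names(fda) == "m_weighted"] <- "m_weighted_mg_per_kg"
        names(fda)[names(fda) == "edi"] <- "edi_mg_per_kg_bw_day"
        emit(fda, "exposure_fda.csv")
        results$fda <- fda
      } else skipped <- c(skipped, "fda")
    }
  }

  if ("mc" %in% frameworks) {
    if (is.null(exposure_config)) {
      warning("Monte Carlo framework skipped: no exposure config supplied",
              call. = FALSE)
      skipped <- c(skipped, "mc")
    } else {
      say("Monte Carlo assessment (", exposure_config$n_iter,
          " iterations)")
      pars <- exposure_config$parameters
      need <- setdiff(c("fc", "ef", "bw"), names(pars))
      if (length(need)) {
        warning("Monte Carlo framework skipped: exposure config lacks ",
                paste(need, collapse = ", "), call. = FALSE)
        skipped <- c(skipped, "mc")
      } else {
        mc_rows <- list()
        for (a in sort(unique(measurements$analyte_id))) {
          rec <- registry[registry$analyte_id == a, ]
          nl <- resolve_noael(rec[1L, ])
          if (is.na(rec$log_kow[1L]) || is.na(nl$noael)) {
            say("  ", a, ": no log Kow or RfD; skipped")
            next
          }
          c_spec <- if (!is.null(exposure_config$c[[a]]))
            exposure_config$c[[a]]
          else {
            g <- measurements[measurements$analyte_id == a, ]
            dist_spec("empirical",
                      values = ifelse(g$censored, 0,
                                      g$concentration_mg_per_kg))
          }
          fit <- mc_exposure(c_spec = c_spec, fc_spec = pars$fc,
                             ef_spec = pars$ef, bw_spec = pars$bw,
                             ed_spec = pars$ed,
                             log_kow = rec$log_kow[1L], rfd = nl$noael,
                             n_iter = exposure_config$n_iter, seed = seed)
          for (metric in c("edi", "hq"))
            mc_rows[[paste(a, metric)]] <- cbind(
              data.frame(analyte_id = a, metric = metric,
                         rfd_mg_per_kg_bw_day = nl$noael,
                         fabs = fit$fabs, stringsAsFactors = FALSE),
              as.data.frame(as.list(fit$profile[metric, ])))
        }
        if (length(mc_rows)) {
          mc <- do.call(rbind, mc_rows)
          rownames(mc) <- NULL
          emit(mc, "exposure_mc.csv")
          results$mc <- mc
        } else {
          warning("Monte Carlo framework produced no analyte profile",
                  call. = FALSE)
          skipped <- c(skipped, "mc")
        }
      }
    }
  }

  manifest <- list(
    package = "migrisk",
    version = as.character(utils::packageVersion("migrisk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    convention = convention,
    frameworks_requested = frameworks,
    frameworks_skipped = skipped,
    n_measurements = nrow(measurements),
    constants = unclass(constants))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  say("report bundle written to ", out_dir)
  invisible(results)
}
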