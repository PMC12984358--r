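#' EU single-point estimated daily intake
#'
#' EDI = M x fc / BW, with the EU conventions fc = 1 kg food/day and the
#' configured body weight (default 60.95 kg). M is the migration level in
#' mg/kg food under the 1 L simulant = 1 kg food equivalence, so the EDI is
#' in mg/kg bw/day. Linear in M.
#'
#' @param m Migration level(s), mg/kg, non-negative.
#' @param constants An [exposure_constants()] object.
#' @return EDI in mg/kg bw/day.
#' @examples
#' edi_eu(0.3708)  # worst-case 2,4-DTBP migration
#' @export
edi_eu <- function(m, constants = exposure_constants()) {
  stopifnot(is.numeric(m))
  if (any(is.na(m) | m < 0)) stop("migration level must be >= 0",
                                  call. = FALSE)
  m * constants$fc_eu / constants$bw
}

#' FDA consumption-factor weights
#'
#' The FDA framework weights migration by the consumption factor CF (the
#' fraction of the diet contacting the packaging type) and the food-type
#' distribution factors f_T over the four regulatory food classes. The f_T
#' values must sum to 1.
#'
#' @param cf Consumption factor in (0, 1].
#' @param ft Named numeric vector with entries `aqueous`, `acidic`,
#'   `alcoholic`, `fatty`, each >= 0, summing to 1 (tolerance 1e-9).
#' @return An object of class `"fda_weights"`.
#' @examples
#' fda_weights(cf = 0.05,
#'             ft = c(aqueous = 0.49, acidic = 0.16,
#'                    alcoholic = 0.01, fatty = 0.34))
#' @export
fda_weights <- function(cf, ft) {
  food_classes <- c("aqueous", "acidic", "alcoholic", "fatty")
  stopifnot(is.numeric(cf), length(cf) == 1L)
  if (!is.finite(cf) || cf <= 0 || cf > 1)
    stop("cf must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(ft) || is.null(names(ft)))
    stop("ft must be a named numeric vector", call. = FALSE)
  missing_ft <- setdiff(food_classes, names(ft))
  if (length(missing_ft))
    stop("ft lacks food class(es): ", paste(missing_ft, collapse = ", "),
         call. = FALSE)
  ft <- ft[food_classes]
  if (any(ft < 0)) stop("ft entries must be >= 0", call. = FALSE)
  if (abs(sum(ft) - 1) > 1e-9)
    stop("ft must sum to 1 (got ", format(sum(ft)), ")", call. = FALSE)
  structure(list(cf = cf, ft = ft), class = "fda_weights")
}

# Regulatory food class -> the simulant standing in for it.
.food_class_medium <- c(aqueous = "ethanol_10", alcoholic = "ethanol_50",
                        fatty = "ethanol_95", acidic = "acetic_3pct")

#' FDA consumption-factor-weighted estimated daily intake
#'
#' Computes the food-type-weighted mean migration
#' <M> = sum over food classes of f_T(class) x M(simulant of that class),
#' with the class-to-simulant mapping aqueous -> 10% ethanol, alcoholic ->
#' 50% ethanol, fatty -> 95% ethanol, acidic -> 3% acetic acid, then
#' EDI = <M> x fc x CF / BW with fc = 3 kg food/day. Simulants missing
#' from `m_by_simulant` but carrying nonzero f_T weight are treated as zero
#' migration with a warning.
#'
#' @param m_by_simulant Named numeric vector of migration levels (mg/kg)
#'   keyed by medium token (`ethanol_10`, `ethanol_50`, `ethanol_95`,
#'   `acetic_3pct`).
#' @param weights An [fda_weights()] object.
#' @param constants An [exposure_constants()] object.
#' @return EDI in mg/kg bw/day.
#' @examples
#' w <- fda_weights(0.1, c(aqueous = 0.25, acidic = 0.25,
#'                         alcoholic = 0.25, fatty = 0.25))
#' edi_fda(c(ethanol_10 = 0.4, ethanol_50 = 0.2, ethanol_95 = 0.1,
#'           acetic_3pct = 0.1), w)
#' @export
edi_fda <- function(m_by_simulant, weights,
                    constants = exposure_constants()) {
  stopifnot(inherits(weights, "fda_weights"), is.numeric(m_by_simulant),
            !is.null(names(m_by_simulant)))
  if (any(m_by_simulant < 0)) stop("migration level must be >= 0",
                                   call. = FALSE)
  m <- numeric(4L)
  names(m) <- names(.food_class_medium)
  for (fc_class in names(.food_class_medium)) {
    med <- .food_class_medium[[fc_class]]
    if (med %in% names(m_by_simulant)) {
      m[fc_class] <- m_by_simulant[[med]]
    } else if (weights$ft[[fc_class]] > 0) {
      warning("no migration value for simulant '", med,
              "' (food class ", fc_class, "); treated as 0", call. = FALSE)
    }
  }
  m_bar <- sum(weights$ft[names(m)] * m)
  m_bar * constants$fc_fda * weights$cf / constants$bw
}

#' Margin of exposure
#'
#' MOE = NOAEL / EDI, compared against a target margin that depends on how
#' the NOAEL was obtained: 100 for database (study-derived) NOAELs, 1 for
#' TTC-derived surrogate NOAELs, whose generic thresholds already embed the
#' uncertainty factors. A zero EDI gives an infinite MOE and low risk.
#' Risk-class comparison uses the unrounded MOE; rounding to integer is a
#' report-layer convention (see `moe_report`).
#'
#' @param noael NOAEL in mg/kg bw/day, > 0.
#' @param edi EDI in mg/kg bw/day, >= 0.
#' @param noael_source `"database"` or `"ttc"`.
#' @param constants An [exposure_constants()] object (supplies the database
#'   target margin).
#' @return List with `moe`, `moe_report` (rounded to integer), `target`,
#'   `noael_source` and `risk_class` (`"low"` when `moe >= target`, else
#'   `"attention"`).
#' @examples
#' moe(noael = 0.03, edi = edi_eu(0.3708), noael_source = "ttc")
#' @export
moe <- function(noael, edi, noael_source = c("database", "ttc"),
                constants = exposure_constants()) {
  noael_source <- match.arg(noael_source)
  stopifnot(is.numeric(noael), is.numeric(edi), length(noael) == 1L,
            length(edi) == 1L)
  if (!is.finite(noael) || noael <= 0)
    stop("NOAEL must be > 0", call. = FALSE)
  if (is.na(edi) || edi < 0) stop("EDI must be >= 0", call. = FALSE)
  m <- if (edi == 0) Inf else noael / edi
  target <- if (noael_source == "ttc") 1 else constants$moe_threshold
  list(moe = m, moe_report = round(m), target = target,
       noael_source = noael_source,
       risk_class = if (m >= target) "low" else "attention")
}

# NOAEL fallback chain for one registry row: direct NOAEL, then RfD
# (both "database"), then the TTC surrogate from the Cramer class.
resolve_noael <- function(rec) {
  if (!is.na(rec$noael)) list(noael = rec$noael, source = "database")
  else if (!is.na(rec$rfd)) list(noael = rec$rfd, source = "database")
  else if (!is.na(rec$cramer_class))
    list(noael = ttc_rfd(rec$cramer_class), source = "ttc")
  else list(noael = NA_real_, source = NA_character_)
}

#' Deterministic EU-framework risk table
#'
#' Worst-case single-point assessment: for each analyte the maximum
#' observed migration is converted to an EDI by [edi_eu()] and to a margin
#' of exposure by [moe()], with the NOAEL taken from the registry (direct
#' NOAEL, else RfD, else the TTC surrogate from the Cramer class).
#' Analytes without any resolvable NOAEL are dropped with a warning.
#'
#' @param max_migration Named numeric vector: worst-case migration per
#'   analyte, mg/kg.
#' @param registry An `"ao_registry"` data frame.
#' @param constants An [exposure_constants()] object.
#' @return Data frame `analyte_id`, `m_max`, `edi`, `noael`,
#'   `noael_source`, `moe`, `moe_report`, `target`, `risk_class`.
#' @export
assess_eu <- function(max_migration, registry,
                      constants = exposure_constants()) {
  stopifnot(is.numeric(max_migration), !is.null(names(max_migration)))
  rows <- lapply(names(max_migration), function(a) {
    rec <- registry[registry$analyte_id == a, ]
    if (!nrow(rec)) stop("analyte not in registry: ", a, call. = FALSE)
    nl <- resolve_noael(rec[1L, ])
    if (is.na(nl$noael)) {
      warning("no NOAEL/RfD/Cramer class for '", a, "'; skipped",
              call. = FALSE)
      return(NULL)
    }
    edi <- edi_eu(max_migration[[a]], constants)
    res <- moe(nl$noael, edi, nl$source, constants)
    data.frame(analyte_id = a, m_max = max_migration[[a]], edi = edi,
               noael = nl$noael, noael_source = res$noael_source,
               moe = res$moe, moe_report = res$moe_report,
               target = res$target, risk_class = res$risk_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no analyte with a resolvable NOAEL",
                         call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Deterministic FDA-framework risk table
#'
#' As [assess_eu()], but the exposure side uses the consumption-factor
#' weighted intake of [edi_fda()], requiring per-simulant migration levels
#' for each analyte.
#'
#' @param m_by_analyte Named list: for each analyte id, a named numeric
#'   vector of migration levels by medium token (mg/kg).
#' @param weights An [fda_weights()] object.
#' @param registry An `"ao_registry"` data frame.
#' @param constants An [exposure_constants()] object.
#' @return Data frame as in [assess_eu()], with `m_weighted` (the
#'   f_T-weighted mean migration) in place of `m_max`.
#' @export
assess_fda <- function(m_by_analyte, weights, registry,
                       constants = exposure_constants()) {
  stopifnot(is.list(m_by_analyte), !is.null(names(m_by_analyte)))
  rows <- lapply(names(m_by_analyte), function(a) {
    rec <- registry[registry$analyte_id == a, ]
    if (!nrow(rec)) stop("analyte not in registry: ", a, call. = FALSE)
    nl <- resolve_noael(rec[1L, ])
    if (is.na(nl$noael)) {
      warning("no NOAEL/RfD/Cramer class for '", a, "'; skipped",
              call. = FALSE)
      return(NULL)
    }
    edi <- edi_fda(m_by_analyte[[a]], weights, constants)
    m_bar <- edi * constants$bw / (constants$fc_fda * weights$cf)
    res <- moe(nl$noael, edi, nl$source, constants)
    data.frame(analyte_id = a, m_weighted = m_bar, edi = edi,
               noael = nl$noael, noael_source = res$noael_source,
               moe = res$moe, moe_report = res$moe_report,
               target = res$target, risk_class = res$risk_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no analyte with a resolvable NOAEL",
                         call. = FALSE)
  rownames(out) <- NULL
  out
}
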