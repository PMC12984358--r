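resolve_convention <- function(convention) {
  convention <- match.arg(convention,
                          c("nd_as_zero", "detected_only",
                            "table2_style", "table3_style"))
  switch(convention,
         table2_style = "nd_as_zero",
         table3_style = "detected_only",
         convention)
}

#' Summarise migration measurements under an explicit non-detect convention
#'
#' Group summaries of left-censored migration data. Two conventions are
#' supported and must be chosen explicitly, because survey tables routinely
#' mix them: `"nd_as_zero"` substitutes 0 for every non-detect and computes
#' mean/SD/median/max over all n (the usual whole-survey table convention;
#' alias `"table2_style"`), while `"detected_only"` computes the statistics
#' over detected values only (the usual convention for "average migration
#' of the detected analyte"; alias `"table3_style"`). The detection rate is
#' the share of detected measurements and does not depend on the
#' convention.
#'
#' @param measurements A `"migration_data"` data frame.
#' @param by Character vector of grouping columns, e.g.
#'   `c("analyte_id")`, `c("material_class", "analyte_id")`.
#' @param convention `"nd_as_zero"`/`"table2_style"` or
#'   `"detected_only"`/`"table3_style"`.
#' @return A data frame of class `"migration_summary"`: the grouping
#'   columns plus `n`, `n_detected`, `mean`, `sd`, `median`, `max`
#'   (mg/kg), `detection_rate` (percent) and `convention`. Under
#'   `detected_only`, groups with no detection have `NA` statistics and a
#'   detection rate of 0.
#' @examples
#' oil <- read_measurements(system.file("extdata",
#'   "soybean_oil_migration.csv", package = "migrisk"))
#' summarize_migration(oil, by = "analyte_id", convention = "detected_only")
#' @export
summarize_migration <- function(measurements, by = "analyte_id",
                                convention = c("nd_as_zero", "detected_only",
                                               "table2_style",
                                               "table3_style")) {
  measurements <- as_migration_data(as.data.frame(measurements))
  convention <- resolve_convention(convention)
  if (!nrow(measurements)) stop("empty measurement table", call. = FALSE)
  missing_by <- setdiff(by, names(measurements))
  if (length(missing_by))
    stop("unknown grouping column(s): ", paste(missing_by, collapse = ", "),
         call. = FALSE)
  key <- interaction(measurements[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(measurements)), key)
  rows <- lapply(groups, function(idx) {
    g <- measurements[idx, ]
    det <- !g$censored
    vals <- if (convention == "nd_as_zero")
      ifelse(det, g$concentration_mg_per_kg, 0)
    else g$concentration_mg_per_kg[det]
    stats <- if (length(vals))
      c(mean = mean(vals), sd = if (length(vals) > 1L) stats::sd(vals) else 0,
        median = stats::median(vals), max = max(vals))
    else c(mean = NA_real_, sd = NA_real_, median = NA_real_, max = NA_real_)
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = nrow(g), n_detected = sum(det),
                     mean = stats[["mean"]], sd = stats[["sd"]],
                     median = stats[["median"]], max = stats[["max"]],
                     detection_rate = 100 * sum(det) / nrow(g),
                     convention = convention, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("migration_summary", "data.frame")
  out
}

#' Pool group means into an overall mean
#'
#' Sample-size-weighted average of disjoint group means (e.g. class-level
#' means pooled over material classes), matching the "total" column of a
#' stratified survey table. All groups must share one non-detect
#' convention; under `nd_as_zero` the weight is the full group size `n`,
#' under `detected_only` the number of detections.
#'
#' @param summaries A `"migration_summary"` data frame (or any data frame
#'   with `mean`, `n`, `n_detected`, `convention` and an `analyte_id`
#'   column).
#' @return Data frame with one row per analyte: `analyte_id`, `n`, `mean`.
#' @examples
#' s <- data.frame(analyte_id = "irganox_1010",
#'                 mean = c(0.3529, 0.5305, 0), n = c(10, 15, 14),
#'                 n_detected = c(2, 11, 0), convention = "nd_as_zero")
#' pooled_mean(s)  # 0.2945 mg/kg
#' @export
pooled_mean <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("analyte_id", "mean", "n", "convention") %in%
                  names(summaries)))
  if (length(unique(summaries$convention)) > 1L)
    stop("cannot pool summaries computed under different conventions",
         call. = FALSE)
  conv <- summaries$convention[1L]
  w <- if (conv == "detected_only") summaries$n_detected else summaries$n
  rows <- lapply(split(seq_len(nrow(summaries)), summaries$analyte_id),
                 function(idx) {
    wi <- w[idx]; mi <- summaries$mean[idx]
    keep <- wi > 0
    data.frame(analyte_id = summaries$analyte_id[idx[1L]],
               n = sum(wi),
               mean = if (any(keep))
                 sum(wi[keep] * mi[keep]) / sum(wi) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection rate
#'
#' Share of units with at least one detection, in percent. With
#' `by = "sample"` a unit is a sample (a sample counts as positive when any
#' of its analytes is detected); with `by = "cell"` each sample x analyte
#' measurement is a unit.
#'
#' @param measurements A `"migration_data"` data frame.
#' @param by `"sample"` or `"cell"`.
#' @return Detection rate in percent (unrounded; report layers typically
#'   round to integer).
#' @examples
#' oil <- read_measurements(system.file("extdata",
#'   "soybean_oil_migration.csv", package = "migrisk"))
#' detection_rate(oil[oil$analyte_id == "antioxidant_jx35", ], by = "cell")
#' @export
detection_rate <- function(measurements, by = c("sample", "cell")) {
  by <- match.arg(by)
  measurements <- as.data.frame(measurements)
  if (!nrow(measurements)) stop("empty measurement table", call. = FALSE)
  if (by == "cell") return(100 * mean(!measurements$censored))
  pos <- tapply(!measurements$censored, measurements$sample_id, any)
  100 * mean(pos)
}

#' Composition shares of total migration
#'
#' Each analyte's share of the summed migration level, in percent. Shares
#' computed from per-analyte means or per-analyte sums are identical for a
#' fixed sample count; means are the expected input.
#'
#' @param means Named numeric vector (or data frame with `analyte_id` and
#'   `mean`) of non-negative per-analyte migration levels.
#' @return Data frame `analyte_id`, `share_pct`, ordered by decreasing
#'   share. Shares sum to 100 before any report-layer rounding.
#' @examples
#' composition_shares(c(irganox_1010 = 0.2945, irgafos_168 = 0.2586))
#' @export
composition_shares <- function(means) {
  if (is.data.frame(means)) {
    stopifnot(all(c("analyte_id", "mean") %in% names(means)))
    means <- stats::setNames(means$mean, means$analyte_id)
  }
  stopifnot(is.numeric(means), !is.null(names(means)))
  if (any(is.na(means) | means < 0))
    stop("means must be non-negative and non-missing", call. = FALSE)
  tot <- sum(means)
  if (tot == 0) stop("all migration levels are zero", call. = FALSE)
  out <- data.frame(analyte_id = names(means),
                    share_pct = 100 * unname(means) / tot,
                    stringsAsFactors = FALSE)
  out[order(-out$share_pct), , drop = FALSE]
}

#' Screen group maxima against specific migration limits
#'
#' Compares the maximum observed migration of each analyte with its
#' resolved specific migration limit. A group passes when its maximum is
#' at or below the limit (inclusive); the compliance margin
#' (SML - max) is reported.
#'
#' @param summaries A `"migration_summary"` data frame with `analyte_id`
#'   and `max` columns (mg/kg).
#' @param registry An `"ao_registry"` data frame.
#' @param constants An [exposure_constants()] object (supplies the default
#'   limit).
#' @return Data frame `analyte_id`, `max`, `sml`, `sml_source`,
#'   `margin`, `pass`.
#' @export
sml_screen <- function(summaries, registry,
                       constants = exposure_constants()) {
  stopifnot(is.data.frame(summaries),
            all(c("analyte_id", "max") %in% names(summaries)))
  lim <- resolve_sml(registry, constants)
  out <- merge(summaries[c("analyte_id", "max")], lim, by = "analyte_id")
  out$margin <- out$sml - out$max
  out$pass <- is.na(out$max) | out$max <= out$sml
  out
}

#' Pairwise Pearson correlation of analyte migration levels
#'
#' Builds a sample x analyte matrix of migration levels (non-detects as 0
#' under the default convention, or pairwise complete detected values) and
#' returns the Pearson correlation of every analyte pair with a two-sided
#' p-value from the t transform `t = r * sqrt((n - 2) / (1 - r^2))`.
#' Pairs with fewer than 3 paired observations, or zero variance in either
#' vector, yield `NA` and are flagged.
#'
#' @param measurements A `"migration_data"` data frame (one medium).
#' @param analytes Character vector of analyte ids to correlate; default
#'   all analytes present.
#' @param convention `"nd_as_zero"` (default) or `"detected_only"` (uses
#'   jointly detected pairs only).
#' @param adjust If `TRUE`, Benjamini-Hochberg adjust the p-values across
#'   the upper triangle.
#' @return List of matrices `r`, `p`, `n` (pairs used), plus a logical
#'   matrix `flagged` for undefined entries. `r` is symmetric with unit
#'   diagonal.
#' @export
correlate_analytes <- function(measurements, analytes = NULL,
                               convention = c("nd_as_zero", "detected_only"),
                               adjust = FALSE) {
  convention <- match.arg(convention)
  measurements <- as.data.frame(measurements)
  if (is.null(analytes)) analytes <- sort(unique(measurements$analyte_id))
  k <- length(analytes)
  wide <- function(a) {
    g <- measurements[measurements$analyte_id == a, ]
    v <- ifelse(g$censored, if (convention == "nd_as_zero") 0 else NA_real_,
                g$concentration_mg_per_kg)
    stats::setNames(v, g$sample_id)
  }
  cols <- lapply(analytes, wide)
  samples <- sort(unique(measurements$sample_id))
  m <- sapply(cols, function(v) v[samples])
  dimnames(m) <- list(samples, analytes)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(analytes, analytes))
  nmat <- matrix(0L, k, k, dimnames = list(analytes, analytes))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(m[, i], m[, j])
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 3L) next
    xi <- m[ok, i]; xj <- m[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    rij <- stats::cor(xi, xj)
    r[i, j] <- rij
    if (abs(rij) < 1) {
      tt <- rij * sqrt((sum(ok) - 2) / (1 - rij^2))
      p[i, j] <- 2 * stats::pt(-abs(tt), df = sum(ok) - 2)
    } else p[i, j] <- 0
  }
  diag(r)[!is.na(diag(r))] <- 1
  if (adjust) {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  list(r = r, p = p, n = nmat, flagged = is.na(r))
}
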