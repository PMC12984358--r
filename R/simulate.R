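#' Configure the synthetic migration-data generator
#'
#' Describes the statistical structure the analysis assumes in real
#' migration surveys: detection is class- and analyte-specific
#' (Bernoulli), positive concentrations are lognormal on the mg/kg scale
#' (migration tables show SD well above the mean, i.e. strong right skew),
#' analytes that share a formulation cluster are correlated on the log
#' scale through one shared latent factor per sample, and values below the
#' limit of detection are re-censored to non-detects.
#'
#' @param n_samples Named integer vector: samples per material class
#'   (names from `PLA`, `starch`, `fiber`).
#' @param analytes Character vector of analyte ids.
#' @param detect_prob Matrix `[class x analyte]` of detection
#'   probabilities in `[0, 1]` (dimnames required).
#' @param mean_log,sd_log Matrices `[class x analyte]`: mean and sd of the
#'   natural log of positive concentrations (mg/kg scale); `sd_log >= 0`.
#' @param lod,loq Named numeric vectors per analyte, mg/kg, `lod <= loq`.
#' @param cluster Named vector assigning analytes to correlation clusters
#'   (`NA` = uncorrelated).
#' @param latent_correlation Shared-factor correlation rho in `[0, 1)`
#'   between log concentrations of analytes in the same cluster.
#' @param medium Medium token for the generated rows.
#' @param temperature_c,duration_h Migration test conditions recorded in
#'   the rows.
#' @return An object of class `"generator_config"`.
#' @seealso [simulate_migration()], [tableware_generator_config()]
#' @export
generator_config <- function(n_samples, analytes, detect_prob, mean_log,
                             sd_log, lod, loq, cluster = NULL,
                             latent_correlation = 0,
                             medium = "ethanol_95", temperature_c = 70,
                             duration_h = 2) {
  stopifnot(is.numeric(n_samples), !is.null(names(n_samples)),
            all(names(n_samples) %in% .material_classes),
            is.character(analytes), length(analytes) >= 1L)
  check_mat <- function(m, nm) {
    if (!is.matrix(m) ||
        !identical(rownames(m), names(n_samples)) ||
        !identical(colnames(m), analytes))
      stop("'", nm, "' must be a [class x analyte] matrix with dimnames ",
           "matching n_samples and analytes", call. = FALSE)
    m
  }
  detect_prob <- check_mat(detect_prob, "detect_prob")
  mean_log <- check_mat(mean_log, "mean_log")
  sd_log <- check_mat(sd_log, "sd_log")
  if (any(detect_prob < 0 | detect_prob > 1))
    stop("detect_prob entries must lie in [0, 1]", call. = FALSE)
  if (any(sd_log < 0)) stop("sd_log entries must be >= 0", call. = FALSE)
  lod <- lod[analytes]; loq <- loq[analytes]
  if (any(is.na(lod) | is.na(loq) | lod > loq))
    stop("every analyte needs lod <= loq", call. = FALSE)
  if (is.null(cluster))
    cluster <- stats::setNames(rep(NA_character_, length(analytes)),
                               analytes)
  cluster <- cluster[analytes]
  if (latent_correlation < 0 || latent_correlation >= 1)
    stop("latent_correlation must lie in [0, 1)", call. = FALSE)
  stopifnot(medium %in% .media)
  structure(list(n_samples = n_samples, analytes = analytes,
                 detect_prob = detect_prob, mean_log = mean_log,
                 sd_log = sd_log, lod = lod, loq = loq, cluster = cluster,
                 latent_correlation = latent_correlation, medium = medium,
                 temperature_c = temperature_c, duration_h = duration_h),
            class = "generator_config")
}

#' Simulate a migration measurement table
#'
#' Draws one dataset from a [generator_config()]: per sample x analyte,
#' detection is Bernoulli(detect_prob); a detected value is
#' `exp(mean_log + sd_log * (sqrt(rho) * z_shared + sqrt(1 - rho) * z_own))`
#' with standard-normal factors, `z_shared` common to all analytes of the
#' sample's cluster (inducing log-scale correlation exactly rho), and
#' values below the analyte's LOD re-censored to non-detects. Byte-identical
#' for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A `"migration_data"` data frame (censored rows have `NA`
#'   concentration).
#' @export
simulate_migration <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  analytes <- config$analytes
  k <- length(analytes)
  clusters <- unique(stats::na.omit(config$cluster))
  rho <- config$latent_correlation
  blocks <- list()
  for (cls in names(config$n_samples)) {
    n <- config$n_samples[[cls]]
    if (n < 1L) next
    # latent structure per sample: one shared factor per cluster
    z_shared <- matrix(stats::rnorm(n * max(length(clusters), 1L)), n)
    colnames(z_shared) <- if (length(clusters)) clusters else "none"
    detected <- matrix(stats::runif(n * k), n, k) <
      matrix(config$detect_prob[cls, ], n, k, byrow = TRUE)
    z_own <- matrix(stats::rnorm(n * k), n, k)
    z <- z_own
    for (j in seq_len(k)) {
      cl <- config$cluster[[analytes[j]]]
      if (!is.na(cl))
        z[, j] <- sqrt(rho) * z_shared[, cl] + sqrt(1 - rho) * z_own[, j]
    }
    conc <- exp(matrix(config$mean_log[cls, ], n, k, byrow = TRUE) +
                  matrix(config$sd_log[cls, ], n, k, byrow = TRUE) * z)
    # re-censor below the LOD
    detected <- detected & conc >= matrix(config$lod, n, k, byrow = TRUE)
    conc[!detected] <- NA_real_
    blocks[[cls]] <- data.frame(
      sample_id = rep(sprintf("%s_%05d", cls, seq_len(n)), each = k),
      material_class = cls, product_type = "synthetic",
      medium = config$medium, temperature_c = config$temperature_c,
      duration_h = config$duration_h,
      analyte_id = rep(analytes, times = n),
      concentration_mg_per_kg = as.vector(t(conc)),
      censored = !as.vector(t(detected)),
      lod = rep(unname(config$lod), times = n),
      loq = rep(unname(config$loq), times = n),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  as_migration_data(out)
}

#' Recover generator parameters from a simulated dataset
#'
#' Moment estimates of the generating quantities: empirical detection
#' probability per class x analyte, mean and sd of the log of detected
#' concentrations, and pairwise Pearson correlation of log concentrations
#' over jointly detected sample pairs (which estimates the shared-factor
#' rho). Cells with fewer than 3 detections are flagged unstable and
#' reported as `NA`.
#'
#' @param data A `"migration_data"` data frame from
#'   [simulate_migration()].
#' @param config The generating [generator_config()] (defines the
#'   class/analyte grid and clusters).
#' @return List with matrices `detect_prob`, `mean_log`, `sd_log`,
#'   `unstable`, and `log_correlation` (analyte x analyte, pooled over
#'   classes).
#' @export
recover_parameters <- function(data, config) {
  stopifnot(inherits(config, "generator_config"))
  data <- as.data.frame(data)
  classes <- names(config$n_samples)
  analytes <- config$analytes
  dims <- list(classes, analytes)
  dp <- ml <- sl <- matrix(NA_real_, length(classes), length(analytes),
                           dimnames = dims)
  unstable <- matrix(FALSE, length(classes), length(analytes),
                     dimnames = dims)
  for (cls in classes) for (a in analytes) {
    g <- data[data$material_class == cls & data$analyte_id == a, ]
    if (!nrow(g)) next
    dp[cls, a] <- mean(!g$censored)
    v <- g$concentration_mg_per_kg[!g$censored]
    if (length(v) < 3L) {
      unstable[cls, a] <- TRUE
      next
    }
    ml[cls, a] <- mean(log(v))
    sl[cls, a] <- stats::sd(log(v))
  }
  # pairwise log-scale correlation over jointly detected samples
  k <- length(analytes)
  rmat <- matrix(NA_real_, k, k, dimnames = list(analytes, analytes))
  diag(rmat) <- 1
  wide <- stats::reshape(
    data[c("sample_id", "analyte_id", "concentration_mg_per_kg")],
    idvar = "sample_id", timevar = "analyte_id", direction = "wide")
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    xi <- wide[[paste0("concentration_mg_per_kg.", analytes[i])]]
    xj <- wide[[paste0("concentration_mg_per_kg.", analytes[j])]]
    ok <- !is.na(xi) & !is.na(xj) & xi > 0 & xj > 0
    if (sum(ok) < 3L) next
    rmat[i, j] <- rmat[j, i] <- stats::cor(log(xi[ok]), log(xj[ok]))
  }
  list(detect_prob = dp, mean_log = ml, sd_log = sl, unstable = unstable,
       log_correlation = rmat)
}

#' Generate a calibration fixture
#'
#' Responses on a straight line plus optional Gaussian noise; with
#' `noise_sd = 0`, [fit_calibration()] recovers the coefficients exactly.
#'
#' @param slope,intercept Line coefficients (response units per mg/kg and
#'   response units).
#' @param noise_sd Standard deviation of the additive response noise.
#' @param levels Numeric vector of concentration levels, mg/kg (>= 2
#'   distinct values).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Data frame `concentration`, `response`.
#' @examples
#' simulate_calibration(134213.1, 3118.8, 0,
#'                      c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8))
#' @export
simulate_calibration <- function(slope, intercept, noise_sd, levels,
                                 seed = 1) {
  stopifnot(is.numeric(levels), length(unique(levels)) >= 2L,
            noise_sd >= 0)
  noise <- if (noise_sd > 0) {
    set.seed(as.integer(seed))
    stats::rnorm(length(levels), 0, noise_sd)
  } else 0
  data.frame(concentration = levels,
             response = slope * levels + intercept + noise)
}

#' Bundled generator configuration for a tableware migration survey
#'
#' An approximate, survey-shaped default configuration: 10 PLA, 15 starch
#' and 14 fiber samples; ten antioxidants with class-level detection
#' probabilities and nd-as-zero class means typical of a biodegradable
#' tableware survey in 95% ethanol (fiber products all non-detect; starch
#' products carry the most analytes); a five-analyte correlation cluster
#' (Irganox 1310, Antioxidant JX-35, Irgafos 168, Irganox 1010, 2,4-DTBP
#' migrate together, rho = 0.7); lognormal positives with `sd_log = 1.2`.
#' `mean_log` is moment-matched so that
#' `detect_prob * E[positive] = class mean`. The targets are marginal
#' summaries only — the configuration makes no claim of sample-level
#' fidelity to any real survey.
#'
#' @return A [generator_config()].
#' @export
tableware_generator_config <- function() {
  analytes <- c("irganox_1010", "irgafos_168", "irganox_1076", "dtbp_24",
                "antioxidant_dltp", "irganox_1310", "antioxidant_jx35",
                "irganox_3114", "irganox_330", "irganox_245")
  n_samples <- c(PLA = 10L, starch = 15L, fiber = 14L)
  # class-level detection probabilities (approximate survey targets)
  dp <- rbind(
    PLA    = c(0.20, 0.30, 0.50, 0.10, 0.10, 0.20, 0.10, 0.00, 0.00, 0.00),
    starch = c(0.73, 0.60, 0.73, 0.27, 0.00, 0.93, 0.73, 0.20, 0.13, 0.07),
    fiber  = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00))
  colnames(dp) <- analytes
  # nd-as-zero class mean migration, mg/kg (approximate survey targets)
  cm <- rbind(
    PLA    = c(0.3529, 0.4234, 0.0468, 0.0371, 0.0674, 0.0073, 0.0011,
               0, 0, 0),
    starch = c(0.5305, 0.3900, 0.1322, 0.0273, 0, 0.0185, 0.0140,
               0.0029, 0.0003, 0.00004),
    fiber  = rep(0, 10))
  colnames(cm) <- analytes
  sd_log <- matrix(1.2, 3, 10, dimnames = dimnames(dp))
  # moment matching: detected-only mean = class mean / detect_prob
  mean_log <- matrix(NA_real_, 3, 10, dimnames = dimnames(dp))
  pos <- dp > 0 & cm > 0
  mean_log[pos] <- log(cm[pos] / dp[pos]) - sd_log[pos]^2 / 2
  mean_log[!pos] <- log(1e-6)  # irrelevant: detect_prob or mean is 0
  lod <- stats::setNames(rep(1e-5, 10), analytes)
  loq <- stats::setNames(rep(3e-5, 10), analytes)
  cluster <- stats::setNames(rep(NA_character_, 10), analytes)
  cluster[c("irganox_1310", "antioxidant_jx35", "irgafos_168",
            "irganox_1010", "dtbp_24")] <- "comigration"
  generator_config(n_samples = n_samples, analytes = analytes,
                   detect_prob = dp, mean_log = mean_log, sd_log = sd_log,
                   lod = lod, loq = loq, cluster = cluster,
                   latent_correlation = 0.7)
}
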