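#' Exposure assessment constants
#'
#' Bundle of the fixed point-estimate constants used by the deterministic
#' exposure frameworks and the compliance screen. Defaults follow the common
#' regulatory conventions: the EU single-point method assumes 1 kg of food
#' per person per day packed in 6 dm^2 of material, the FDA method assumes
#' 3 kg/day, and migration is expressed under the 1 L food simulant = 1 kg
#' food equivalence.
#'
#' @param fc_eu Daily food consumption for the EU method, kg food/day.
#' @param fc_fda Daily food consumption for the FDA method, kg food/day.
#' @param bw Body weight, kg.
#' @param moe_threshold Target margin of exposure for NOAELs taken from a
#'   toxicological database. TTC-derived NOAELs use a target of 1 instead
#'   (the TTC value already embeds the uncertainty factors).
#' @param hq_threshold Hazard-quotient threshold flagging potential concern.
#' @param sml_default Default specific migration limit, mg/kg, applied to
#'   analytes without a substance-specific or recommended limit.
#'
#' @return An object of class `"exposure_constants"` (a named list).
#' @examples
#' exposure_constants()
#' exposure_constants(bw = 60)  # plain 60-kg adult convention
#' @export
exposure_constants <- function(fc_eu = 1, fc_fda = 3, bw = 60.95,
                               moe_threshold = 100, hq_threshold = 1,
                               sml_default = 60) {
  for (nm in c("fc_eu", "fc_fda", "bw", "moe_threshold", "hq_threshold",
               "sml_default")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  structure(list(fc_eu = fc_eu, fc_fda = fc_fda, bw = bw,
                 moe_threshold = moe_threshold, hq_threshold = hq_threshold,
                 sml_default = sml_default),
            class = "exposure_constants")
}

#' @export
print.exposure_constants <- function(x, ...) {
  cat("Exposure constants:\n")
  cat(sprintf("  fc (EU / FDA): %g / %g kg food/day\n", x$fc_eu, x$fc_fda))
  cat(sprintf("  body weight:   %g kg\n", x$bw))
  cat(sprintf("  target MOE:    %g (database NOAEL), 1 (TTC)\n",
              x$moe_threshold))
  cat(sprintf("  HQ threshold:  %g\n", x$hq_threshold))
  cat(sprintf("  default SML:   %g mg/kg\n", x$sml_default))
  invisible(x)
}

# Closed vocabularies shared across the package.
.material_classes <- c("PLA", "starch", "fiber")
.media <- c("acetic_3pct", "ethanol_10", "ethanol_50", "ethanol_95",
            "soybean_oil")
.chem_classes <- c("hindered_phenol", "phosphite", "thioester",
                   "hindered_amine", "other")

#' Threshold of toxicological concern (TTC) by Cramer class
#'
#' Generic exposure thresholds used as surrogate NOAEL/RfD values for
#' analytes lacking compound-specific toxicology: Cramer class I
#' (low structural concern) 0.03, class II 0.009, class III 0.0015
#' mg/kg bw/day.
#'
#' @param cramer_class Character vector with elements `"I"`, `"II"` or
#'   `"III"`.
#' @return Numeric vector of thresholds in mg/kg bw/day.
#' @examples
#' ttc_rfd(c("I", "II", "III"))
#' @export
ttc_rfd <- function(cramer_class) {
  tab <- c(I = 0.03, II = 0.009, III = 0.0015)
  cramer_class <- as.character(cramer_class)
  bad <- !is.na(cramer_class) & !cramer_class %in% names(tab)
  if (any(bad))
    stop("unknown Cramer class: ",
         paste(unique(cramer_class[bad]), collapse = ", "), call. = FALSE)
  unname(tab[cramer_class])
}
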