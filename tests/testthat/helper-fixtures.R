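# Shared fixture builders: everything is constructed in code.

extdata <- function(file) system.file("extdata", file, package = "migrisk")

fixture_registry <- function() read_registry(extdata("antioxidants.yaml"))

fixture_oil <- function(registry = fixture_registry())
  read_measurements(extdata("soybean_oil_migration.csv"), registry)

fixture_ethanol_summary <- function() {
  x <- utils::read.csv(extdata("ethanol95_summary.csv"),
                       stringsAsFactors = FALSE)
  x
}

# minimal hand-built measurement table
make_measurements <- function(conc, censored, analyte_id = "irganox_1010",
                              material_class = "starch",
                              medium = "ethanol_95",
                              sample_id = sprintf("s%02d", seq_along(conc)),
                              lod = 1e-5, loq = 3e-5) {
  as_migration_data(data.frame(
    sample_id = sample_id, material_class = material_class,
    product_type = "box", medium = medium, temperature_c = 70,
    duration_h = 2, analyte_id = analyte_id,
    concentration_mg_per_kg = ifelse(censored, NA_real_, conc),
    censored = censored, lod = lod, loq = loq, stringsAsFactors = FALSE))
}

# all-point Monte Carlo model around a single concentration
point_model <- function(c_value = 0.1, rfd = 1, fabs = 1, n_iter = 100,
                        seed = 1, ...) {
  mc_exposure(c_spec = dist_spec("point", value = c_value),
              fc_spec = dist_spec("point", value = 1),
              ef_spec = dist_spec("point", value = 365),
              bw_spec = dist_spec("point", value = 60.95),
              fabs = fabs, rfd = rfd, n_iter = n_iter, seed = seed, ...)
}

# small single-class generator config for recovery tests
recovery_config <- function(n = 10000L, p = 0.5, mu = log(0.1), sig = 0.8,
                            rho = 0.7) {
  analytes <- c("a1", "a2", "a3")
  dims <- list("starch", analytes)
  generator_config(
    n_samples = c(starch = n), analytes = analytes,
    detect_prob = matrix(p, 1, 3, dimnames = dims),
    mean_log = matrix(mu, 1, 3, dimnames = dims),
    sd_log = matrix(sig, 1, 3, dimnames = dims),
    lod = stats::setNames(rep(1e-12, 3), analytes),
    loq = stats::setNames(rep(3e-12, 3), analytes),
    cluster = stats::setNames(rep("c1", 3), analytes),
    latent_correlation = rho)
}
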