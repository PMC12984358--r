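# Example Monte Carlo exposure parameter configuration.
#
# NON-AUTHORITATIVE: the distribution families and parameters below are
# documented stand-ins chosen to look like a plausible adult dietary
# exposure scenario. Real assessments must supply their own, sourced
# parameter file with this schema (exposure_config/1):
#
#   n_iter       iterations per simulation
#   parameters:  fc (food consumption, kg/day), ef (exposure frequency,
#                days/year), ed (exposure duration, years; cancels in the
#                model but may be recorded), bw (body weight, kg)
#   c:           optional per-analyte dietary concentration C (mg/kg);
#                when absent the pipeline uses the empirical distribution
#                of the measurement table (non-detects as 0)
#
# Each entry: family (point|uniform|triangular|normal|lognormal|empirical),
# family-specific parameters, optional truncation: [low, high].
schema: exposure_config/1
n_iter: 10000
parameters:
  fc:
    family: triangular
    min: 0.5
    mode: 1.0
    max: 2.0
  ef:
    family: point
    value: 350
  ed:
    family: point
    value: 30
  bw:
    family: normal
    mean: 60.95
    sd: 10
    truncation: [40, 120]
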