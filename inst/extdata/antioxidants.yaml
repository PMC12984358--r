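# Analyte registry: 20 polymer antioxidants monitored in food-contact
# tableware. Schema (ao_registry/1):
#   analyte_id        short unique token (mandatory)
#   name              display name (mandatory)
#   cas               CAS registry number
#   chem_class        hindered_phenol | phosphite | thioester |
#                     hindered_amine | other
#   log_kow           log10 octanol/water partition coefficient.
#                     PLACEHOLDER values, user-supplied for real use:
#                     look each compound up in a curated property
#                     database before relying on the absorption model.
#   sml_specific      substance-specific migration limit, mg/kg
#   sml_recommended   recommended migration limit, mg/kg
#   noael             NOAEL, mg/kg bw/day (database-derived)
#   rfd               reference dose, mg/kg bw/day (database-derived)
#   cramer_class      I | II | III (drives the TTC surrogate when no
#                     NOAEL/RfD is given)
# All numeric fields strictly positive when present; concentrations are
# mg/kg everywhere.
schema: ao_registry/1
analytes:
  - analyte_id: irganox_1010
    name: Irganox 1010
    cas: 6683-19-8
    chem_class: hindered_phenol
    log_kow: 19.6          # placeholder - user-supplied
    cramer_class: II
  - analyte_id: irgafos_168
    name: Irgafos 168
    cas: 31570-04-4
    chem_class: phosphite
    log_kow: 16.2          # placeholder - user-supplied
    sml_recommended: 10
    rfd: 1.0
  - analyte_id: irganox_1076
    name: Irganox 1076
    cas: 2082-79-3
    chem_class: hindered_phenol
    log_kow: 13.3          # placeholder - user-supplied
    sml_specific: 6
    cramer_class: II
  - analyte_id: dtbp_24
    name: 2,4-DTBP
    cas: 96-76-4
    chem_class: hindered_phenol
    log_kow: 4.9           # placeholder - user-supplied
    cramer_class: I
  - analyte_id: antioxidant_dltp
    name: Antioxidant DLTP
    cas: 123-28-4
    chem_class: thioester
    log_kow: 10.2          # placeholder - user-supplied
    sml_specific: 5
    cramer_class: I
  - analyte_id: irganox_1310
    name: Irganox 1310
    cas: 20170-32-5
    chem_class: hindered_phenol
    log_kow: 3.9           # placeholder - user-supplied
    cramer_class: II
  - analyte_id: antioxidant_jx35
    name: Antioxidant JX-35
    cas: 6386-38-5
    chem_class: hindered_phenol
    log_kow: 4.5           # placeholder - user-supplied
    cramer_class: II
  - analyte_id: irganox_3114
    name: Irganox 3114
    cas: 27676-62-6
    chem_class: hindered_phenol
    log_kow: 11.1          # placeholder - user-supplied
    sml_specific: 5
    cramer_class: III
  - analyte_id: irganox_330
    name: Irganox 330
    cas: 1709-70-2
    chem_class: hindered_amine
    log_kow: 13.7          # placeholder - user-supplied
    cramer_class: III
  - analyte_id: irganox_245
    name: Irganox 245
    cas: 36443-68-2
    chem_class: hindered_phenol
    log_kow: 5.8           # placeholder - user-supplied
    sml_specific: 9
    cramer_class: I
  - analyte_id: irganox_80
    name: Irganox 80
    cas: 90498-90-1
    chem_class: hindered_phenol
    sml_specific: 0.05
  - analyte_id: irganox_1222
    name: Irganox 1222
    cas: 976-56-7
    chem_class: hindered_phenol
  - analyte_id: irganox_3052
    name: Irganox 3052
    cas: 61167-58-6
    chem_class: hindered_phenol
    sml_specific: 6
  - analyte_id: irganox_1024
    name: Irganox 1024
    cas: 32687-78-8
    chem_class: hindered_phenol
    sml_specific: 15
  - analyte_id: irganox_565
    name: Irganox 565
    cas: 991-84-4
    chem_class: hindered_phenol
    sml_specific: 30
  - analyte_id: irganox_1098
    name: Irganox 1098
    cas: 23128-74-7
    chem_class: hindered_phenol
    sml_specific: 45
  - analyte_id: irganox_1035
    name: Irganox 1035
    cas: 41484-35-9
    chem_class: hindered_phenol
    sml_specific: 2.4
  - analyte_id: irganox_697
    name: Irganox 697
    cas: 70331-94-1
    chem_class: hindered_phenol
  - analyte_id: antioxidant_300
    name: Antioxidant 300
    cas: 96-69-5
    chem_class: hindered_phenol
    sml_specific: 0.48
  - analyte_id: antioxidant_2246
    name: Antioxidant 2246
    cas: 119-47-1
    chem_class: hindered_phenol
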