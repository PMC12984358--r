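# Example FDA consumption-factor weights (fda_weights/1).
#
# ILLUSTRATIVE ONLY: cf depends on the packaging category under
# assessment and must be supplied by the user; the f_T split below is the
# widely cited general polymer food-type distribution (aqueous 49%,
# acidic 16%, alcoholic 1%, fatty 34%). f_T must sum to 1.
schema: fda_weights/1
cf: 0.05
ft:
  aqueous: 0.49
  acidic: 0.16
  alcoholic: 0.01
  fatty: 0.34
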