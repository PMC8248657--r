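# Canonical factor order used throughout the package: the cohort CSV, the
# categorization scheme and the knowledge base all use these 12 columns.
hd_factors <- c(
  "age", "mmsetotal", "indepscl", "fiscore", "tfcscore", "motscore",
  "exfscore", "aptscore", "irascore", "depscore", "psyscore", "sdmt1"
)

# Finite upper bound of each clinical scale, used when an open-ended top
# category ("> 12", "age >= 70", ...) has to be sampled or serialized.
hd_factor_caps <- c(
  age = 90, mmsetotal = 30, indepscl = 100, fiscore = 25, tfcscore = 13,
  motscore = 124, exfscore = 20, aptscore = 20, irascore = 20, depscore = 20,
  psyscore = 20, sdmt1 = 110
)
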