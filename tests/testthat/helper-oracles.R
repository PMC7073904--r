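# shared fixtures and small independent oracles

# a vector with exactly the requested mean and sd, for cross-checking
# summary-statistic tests against stats::t.test on raw data
vector_with_moments <- function(m, s, n) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}

# strip order and attributes so structurally identical models compare equal
canonical_model <- function(model) {
  model$reactions <- lapply(model$reactions[order(names(model$reactions))],
                            function(r) {
                              r$stoichiometry <-
                                r$stoichiometry[order(names(r$stoichiometry))]
                              r
                            })
  model$metabolites <- model$metabolites[order(names(model$metabolites))]
  attributes(model) <- attributes(model)[c("names", "class")]
  model
}

toy_thy <- function(b = 0.7, ...) {
  phase_plane(gen_toy_model(b, "auxotroph", ...), build_medium("thy"))
}
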