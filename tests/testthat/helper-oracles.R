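# Independent brute-force oracles used against the package implementation.

# PAF over an unweighted exposure sample: 1 - n / sum(theta^x).
oracle_paf <- function(x, theta) 1 - length(x) / sum(theta^x)

# Weighted mean-RR PAF, written out longhand.
oracle_paf_weighted <- function(x, w, theta) {
  w <- w / sum(w)
  1 - 1 / sum(w * theta^x)
}

# Category masses by directly classifying each point against the cutoffs.
oracle_category_masses <- function(points, weights, cutoffs) {
  bounds <- c(-Inf, cutoffs, Inf)
  m <- vapply(seq_len(length(bounds) - 1L), function(k) {
    sum(weights[points >= bounds[k] & points < bounds[k + 1]])
  }, numeric(1))
  names(m) <- c("normal", names(cutoffs))
  m
}

# A one-stratum, one-disease toy input set with hand-settable parameters.
toy_inputs <- function(theta = 1.37, servings = 1, se = 0,
                       population = 1e5, mortality = 100) {
  kt <- generate_known_truth(1 - 1 / theta, population = population)
  kt$inputs$consumption$mean_servings <- servings
  kt$inputs$consumption$se_servings <- se
  kt$inputs$disease_epi$mortality_rate <- mortality
  kt$inputs
}
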