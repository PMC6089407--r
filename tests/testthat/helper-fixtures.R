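# Shared fixtures: all data are generated in code.

# Paired frequencies from an all-defaults synthetic experiment.
make_paired <- function(seed = 1) {
  paired_frequencies(paper_like_dataset(seed = seed))
}

# Noise-free paired data: offspring counts set to the exact beta-binomial
# mean under a given cost (rounded to the nearest integer at large n, so
# the MLE of c is pinned very close to the truth).
noiseless_paired <- function(c_true = 2, n = 10000,
                             q_t = seq(0.1, 0.6, length.out = 24)) {
  q1 <- next_frequency(q_t, c_true)
  data.frame(
    year = rep(2012:2015, each = 6),
    mesocosm_id = seq_along(q_t),
    q_t = q_t,
    offspring_k = round(n * q1),
    offspring_n = n
  )
}

# One hand-built raw record for arithmetic checks.
one_record <- function(...) {
  base <- list(
    year = 2012, mesocosm_id = "M1",
    parent_flow_triploid = 30, parent_flow_diploid = 30,
    dissected_males = 50, dissected_females = 50,
    offspring_flow_triploid = 37, offspring_flow_diploid = 37,
    infected_males = 0, infected_females = 0, infected_offspring = 0
  )
  override <- list(...)
  base[names(override)] <- override
  as.data.frame(base)
}
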