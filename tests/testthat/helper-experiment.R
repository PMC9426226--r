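# One full default experiment shared across test files (memoized so the
# 384-session run happens once per test session).
.exp_cache <- new.env(parent = emptyenv())

default_experiment <- function() {
  if (is.null(.exp_cache$exp))
    .exp_cache$exp <- run_experiment(seed = 42L)
  .exp_cache$exp
}

# Analytic standard error of the mean of per-session o_ac values under the
# two-option guessing model: o_ac = 2 * o_ae with o_ae binomial(n, g^2/4)/n.
oac_mean_se <- function(g, n_items) {
  p <- g^2 / 4
  sqrt(sum(4 * p * (1 - p) / n_items)) / length(g)
}
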