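# irrsim

Simulation-based evaluation of interrater reliability indices against a
behavioral golden standard.

## The problem

When two raters assign items to nominal categories, how should the quality
of the rating be scored? Percent agreement `a_o` ignores the agreements
produced by random rating; the chance-corrected indices — Bennett et al.'s
S, Perreault–Leigh I_r, Gwet's AC1, Scott's π, Cohen's κ, Krippendorff's α
— all apply the shared correction

    r_i = (a_o − a_c) / (1 − a_c)

but each embodies a different model of the chance agreement `a_c`: `1/C`
for S and I_r, pooled-marginal concentration for π (and α, with a
finite-sample correction), per-rater marginals for κ, and
`Σ p̄ₖ(1−p̄ₖ)/(C−1)` for AC1. Whether any of these models matches how
raters actually misbehave is an empirical question. `irrsim` makes it
testable: it simulates truth-labeled two-rater sessions in which random
rating is *involuntary and difficulty-dependent* — confined to the two
confusable categories, with guess probability `g(d_f)` rising with task
difficulty — so the *observed* chance agreement `o_ac = 2·o_ae` (twice the
erroneous agreement) and *observed* reliability `o_ri = a_o − o_ac` are
available as golden standards, and every index and every chance estimator
can be scored against its estimand with directional r² (`dr² = r·|r|`),
mean of errors `m_e`, error of means `e_m`, and benchmark verdicts
(`dr² > .8` primary, `dr² > .67` tentative, `m_e < .2` secondary).

The package is aimed at methodologists studying agreement statistics —
the kappa paradoxes, category and skew dependence, and the behavioral
assumptions behind chance correction — and at anyone who wants a
reproducible factorial test bench for a new index.

## Worked example

Simulate one hard session (C = 4 declared categories, 75–25 skew,
difficulty 6/7) and score it:

```r
library(irrsim)
s <- simulate_session(C = 4, s_k = 0.75, d_f = 6/7, seed = 42)
golden_standard(s)
#> Golden standard (100 items)
#> o_ar o_ae  a_o  d_o o_ac o_ri  t_h
#> 0.49 0.09 0.58 0.42 0.18 0.40 0.30
agreement(s)
#> Interrater reliability estimates (100 items, C = 4)
#>
#>           a_o    S   I_r   AC1    pi kappa alpha
#> estimate 0.58 0.44 0.663 0.499 0.138 0.147 0.142
#> chance   0.00 0.25 0.250 0.162 0.513 0.508 0.510
```

Read: the raters agreed on 58% of items, but 9% of items were agreements
on a *wrong* category, so the observed chance agreement is 0.18 and the
true reliability 0.40. An index would need a chance estimate of exactly
`t_h = 0.30` to recover 0.40; S and I_r assume 0.25 and overestimate,
while π, κ and α assume ≈ 0.51 — intentional maximum random rating — and
report ≈ 0.14, less than half the observed reliability.

The full factorial experiment (4 category levels × 8 difficulty levels ×
3 skews × 4 replicate sessions = 384 sessions of 100 items):

```r
exp <- run_experiment(seed = 1)
exp
#> Interrater reliability experiment: 384 sessions (seed 1)
#> Observed: mean o_ri = 0.539, mean o_ac = 0.134
#>
#> Index ranking by predictive accuracy (dr2 vs estimand):
#>  index dr2_reliability dr2_chance
#>    a_o           0.861         NA
#>    AC1           0.587      0.007
#>      S           0.586      0.000
#>    I_r           0.470      0.000
#>  kappa           0.396     -0.176
#>     pi           0.393     -0.173
#>  alpha           0.393     -0.173
#>
#> Meta dr2 (chance vs reliability accuracy, 6 adjusted indices): 0.808
```

Uncorrected percent agreement predicts the observed reliability best;
the skew-based trio π/κ/α predicts it worst, and their chance estimators
correlate *negatively* with the observed chance agreement. `summary(exp)`
prints the full evaluation (m_e, e_m, CIs, benchmark verdicts) and the
factor-effect table (dr² of every estimator against category, skew and
difficulty); `exp$means` holds the cell means by factor level, `plot(exp)`
draws the accuracy ranking, and `exp$records` has the 384 per-session
records. `write_sessions()` / `read_sessions()` round-trip sessions as
plain CSV, and `read_config()` loads a YAML design configuration.

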