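test_that("percent agreement is the diagonal proportion", {
  expect_equal(percent_agreement(contingency_table(rep(1, 100), rep(1, 100), C = 2)), 1)
  r1 <- rep(c(1L, 2L), c(60, 40))
  r2 <- c(rep(1L, 50), rep(2L, 10), rep(1L, 22), rep(2L, 18))
  expect_equal(percent_agreement(contingency_table(r1, r2, C = 2)), 0.68)
  # diagonal (50, 18), off-diagonal (20, 12), n = 100
  tab <- contingency_table(rep(c(1L, 1L, 2L, 2L), c(50, 20, 12, 18)),
                           rep(c(1L, 2L, 1L, 2L), c(50, 20, 12, 18)), C = 2)
  expect_equal(percent_agreement(tab), 0.68)
  expect_error(contingency_table(integer(0), integer(0), C = 2), "no rated items")
})

test_that("uniform-category chance model gives 1/C", {
  expect_equal(chance_S(2), 0.500)
  expect_equal(chance_S(4), 0.250)
  expect_equal(chance_S(8), 0.125)
  expect_error(chance_S(1), "two categories")
})

test_that("pooled- and per-rater-marginal chance models match hand arithmetic", {
  # pooled marginals (.5, .5)
  tab <- contingency_table(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L), C = 2)
  expect_equal(chance_pi(tab), 0.5)
  # pooled marginals (.75, .25): rater1 all 1, rater2 half-half
  tab <- contingency_table(rep(1L, 4), c(1L, 1L, 2L, 2L), C = 2)
  expect_equal(chance_pi(tab), 0.75^2 + 0.25^2)
  expect_equal(chance_pi(contingency_table(rep(1L, 5), rep(1L, 5), C = 2)), 1)
  # per-rater marginals (.7, .3) and (.6, .4)
  r1 <- rep(c(1L, 2L), c(7, 3))
  r2 <- rep(c(1L, 2L), c(6, 4))
  expect_equal(chance_kappa(contingency_table(r1, r2, C = 2)), 0.7 * 0.6 + 0.3 * 0.4)
  # disjoint support: marginals (1, 0) and (0, 1)
  expect_equal(chance_kappa(contingency_table(rep(1L, 4), rep(2L, 4), C = 2)), 0)
})

test_that("Krippendorff chance model carries the finite-sample correction", {
  r1 <- rep(c(1L, 2L), 50)
  r2 <- rep(c(2L, 1L), 50) # pooled counts (100, 100)
  tab <- contingency_table(r1, r2, C = 2)
  expect_equal(chance_alpha(tab), 2 * (100 * 99) / (200 * 199))
  expect_equal(chance_alpha(contingency_table(rep(1L, 5), rep(1L, 5), C = 2)), 1)
  # converges to the pooled-marginal (pi) model from below as n grows
  set.seed(7)
  n <- 1e4
  r1 <- sample(1:3, n, replace = TRUE, prob = c(.5, .3, .2))
  r2 <- sample(1:3, n, replace = TRUE, prob = c(.4, .4, .2))
  big <- contingency_table(r1, r2, C = 3)
  expect_lt(abs(chance_alpha(big) - chance_pi(big)), 1e-3)
  expect_lte(chance_alpha(big), chance_pi(big))
})

test_that("AC1 chance model reacts to category and reversed skew", {
  tab <- contingency_table(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L), C = 2)
  expect_equal(chance_AC1(tab), 0.5)
  # pooled (.99, .01): tiny chance estimate under extreme skew
  r1 <- rep(c(1L, 2L), c(99, 1))
  r2 <- rep(c(1L, 2L), c(99, 1))
  expect_equal(chance_AC1(contingency_table(r1, r2, C = 2)), 2 * 0.99 * 0.01)
  # C = 4 uniform pooled marginals
  tab4 <- contingency_table(1:4, 1:4, C = 4)
  expect_equal(chance_AC1(tab4), (1 / 3) * 4 * 0.25 * 0.75)
})

test_that("chance correction behaves at its edges", {
  expect_equal(chance_correct(0.685, 0), 0.685)
  expect_equal(chance_correct(0.8, 0.5), 0.6)
  expect_equal(chance_correct(0.3, 0.3), 0)
  expect_true(is.na(chance_correct(1, 1)))
  expect_error(chance_correct(1.2, 0.5), "lie in")
})

test_that("Ir is the square root of a non-negative S and zero below", {
  expect_equal(index_Ir(0.64), 0.8)
  expect_equal(index_Ir(-0.1), 0)
  expect_equal(index_Ir(0), 0)
  expect_equal(index_Ir(1), 1)
  expect_true(is.na(index_Ir(NA_real_)))
})

test_that("agreement() assembles all estimators, flags degenerate chance", {
  # perfect balanced 2x2: every index 1
  perfect <- contingency_table(rep(c(1L, 2L), each = 50),
                               rep(c(1L, 2L), each = 50), C = 2)
  fit <- agreement(perfect)
  expect_equal(unname(coef(fit)), rep(1, 7))
  expect_equal(fit$chance[["ao_ac"]], 0)
  expect_equal(fit$chance[["Ir_ac"]], fit$chance[["S_ac"]])
  # ground-zero-like table: all chance estimates at 0.5, alpha within .005
  gz <- contingency_table(rep(c(1L, 1L, 2L, 2L), each = 25),
                          rep(c(1L, 2L, 1L, 2L), each = 25), C = 2)
  ch <- agreement(gz)$chance
  expect_equal(unname(ch[c("S_ac", "Ir_ac", "AC_ac", "pi_ac", "kappa_ac")]),
               rep(0.5, 5))
  expect_lt(abs(ch[["alpha_ac"]] - 0.5), 0.005)
  # both raters glued to one category: pi/kappa/alpha chance hits 1, flagged
  degen <- agreement(contingency_table(rep(1L, 10), rep(1L, 10), C = 2))
  expect_true(all(is.na(coef(degen)[c("pi", "kappa", "alpha")])))
  expect_equal(coef(degen)[["a_o"]], 1)
  expect_false(is.na(coef(degen)[["S"]]))
})

test_that("estimators match the brute-force oracle on all small 2x2 tables", {
  for (tb in enumerate_2x2(12)) {
    fit <- agreement(tb$r1, tb$r2, C = 2)
    ref <- oracle_all(tb$r1, tb$r2, 2)
    for (nm in names(ref)) {
      if (is.na(ref[[nm]])) {
        expect_true(is.na(coef(fit)[[nm]]))
      } else {
        expect_equal(coef(fit)[[nm]], ref[[nm]], tolerance = 1e-12)
      }
    }
  }
})

test_that("alpha equals its direct 1 - Do/De form", {
  set.seed(11)
  for (rep in 1:25) {
    C <- sample(2:5, 1)
    n <- sample(5:60, 1)
    r1 <- sample(seq_len(C), n, replace = TRUE)
    r2 <- sample(seq_len(C), n, replace = TRUE)
    a_pkg <- coef(agreement(r1, r2, C = C))[["alpha"]]
    a_ref <- oracle_alpha_direct(r1, r2, C)
    if (is.na(a_ref)) expect_true(is.na(a_pkg))
    else expect_equal(a_pkg, a_ref, tolerance = 1e-12)
  }
})

test_that("kappa matches scikit-learn's reference implementation", {
  set.seed(3)
  r1 <- sample(1:3, 60, replace = TRUE)
  r2 <- sample(1:3, 60, replace = TRUE)
  code <- sprintf(
    "from sklearn.metrics import cohen_kappa_score; print(repr(cohen_kappa_score([%s],[%s])))",
    paste(r1, collapse = ","), paste(r2, collapse = ","))
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  expect_equal(coef(agreement(r1, r2, C = 3))[["kappa"]],
               as.numeric(out), tolerance = 1e-10)
})

test_that("estimates are invariant to category relabeling", {
  set.seed(21)
  for (rep in 1:20) {
    C <- sample(2:6, 1)
    n <- sample(10:80, 1)
    r1 <- sample(seq_len(C), n, replace = TRUE)
    r2 <- sample(seq_len(C), n, replace = TRUE)
    perm <- sample(seq_len(C))
    a <- coef(agreement(r1, r2, C = C))
    b <- coef(agreement(perm[r1], perm[r2], C = C))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("estimator orderings hold: pi <= kappa, S <= Ir, alpha >= pi", {
  set.seed(5)
  for (rep in 1:50) {
    C <- sample(2:5, 1)
    n <- sample(4:60, 1)
    r1 <- sample(seq_len(C), n, replace = TRUE)
    r2 <- sample(seq_len(C), n, replace = TRUE)
    fit <- agreement(r1, r2, C = C)
    est <- coef(fit)
    expect_gte(fit$chance[["pi_ac"]] + 1e-12, fit$chance[["kappa_ac"]])
    if (!is.na(est[["pi"]]) && !is.na(est[["kappa"]]))
      expect_lte(est[["pi"]], est[["kappa"]] + 1e-12)
    if (!is.na(est[["S"]]) && est[["S"]] >= 0)
      expect_lte(est[["S"]], est[["I_r"]] + 1e-12)
    if (!is.na(est[["pi"]]) && !is.na(est[["alpha"]]) && est[["pi"]] < 1)
      expect_gte(est[["alpha"]] + 1e-12, est[["pi"]])
    expect_true(all(est[!is.na(est)] <= 1 + 1e-12))
  }
})

test_that("alpha - pi gap shrinks at rate 1/n", {
  # same joint distribution scaled up: gap should fall ~10x from n to 10n
  gap_at <- function(scale) {
    r1 <- rep(c(1L, 1L, 2L, 2L), c(4, 2, 1, 3) * scale)
    r2 <- rep(c(1L, 2L, 1L, 2L), c(4, 2, 1, 3) * scale)
    fit <- agreement(r1, r2, C = 2)
    coef(fit)[["alpha"]] - coef(fit)[["pi"]]
  }
  g10 <- gap_at(1)
  g100 <- gap_at(10)
  g1000 <- gap_at(100)
  expect_gt(g10, 0)
  expect_equal(g100 / g10, 0.1, tolerance = 0.06)
  expect_equal(g1000 / g100, 0.1, tolerance = 0.06)
})
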