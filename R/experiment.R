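index_names <- c("a_o", "S", "I_r", "AC1", "pi", "kappa", "alpha")
chance_names <- c("ao_ac", "S_ac", "Ir_ac", "AC_ac", "pi_ac", "kappa_ac",
                  "alpha_ac")

#' Score sessions: golden standards and index estimates per session
#'
#' For every truth-labeled session computes the golden-standard
#' observations and all seven index estimates plus their chance estimates,
#' returning one record per session — the unit of analysis of the
#' experiment.
#'
#' @param sessions list of `rating_session` objects (see
#'   [simulate_design()] / [read_sessions()]).
#' @return data frame with design columns (`session`, `C`, `s_k`, `d_f`,
#'   `replicate`, `n_items`), golden-standard columns (`o_ar`, `o_ae`,
#'   `a_o`, `d_o`, `o_ac`, `o_ri`, `t_h`) and the 13 estimator columns
#'   (`S` ... `alpha`, `ao_ac` ... `alpha_ac`).
#' @export
score_sessions <- function(sessions) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    gs <- golden_standard(s)
    fit <- agreement(s)
    data.frame(session = i, C = s$C, s_k = s$s_k, d_f = s$d_f,
               replicate = s$replicate, n_items = s$n_items,
               o_ar = gs$o_ar, o_ae = gs$o_ae, a_o = gs$a_o, d_o = gs$d_o,
               o_ac = gs$o_ac, o_ri = gs$o_ri, t_h = gs$t_h,
               as.list(fit$estimates[setdiff(index_names, "a_o")]),
               as.list(fit$chance))
  })
  do.call(rbind, rows)
}

#' Evaluate index estimates against the golden standards
#'
#' Across sessions, scores every reliability estimator against the
#' observed reliability `o_ri` and every chance estimator against the
#' observed chance agreement `o_ac`: directional r squared (with pretest
#' p-value), mean of errors (with sd and 95% CI), error of means (with
#' 95% CI), the number of sessions used (undefined estimates excluded, the
#' excluded count reported) and benchmark verdicts.
#'
#' @param records per-session records from [score_sessions()].
#' @param benchmarks list with `primary`, `tentative`, `secondary`
#'   thresholds (see [benchmark_verdicts()]).
#' @return object of class `"irr_evaluation"`: list with data frames
#'   `reliability` and `chance` (one row per estimator) and the
#'   `benchmarks` used.
#' @export
evaluate_indices <- function(records,
                             benchmarks = list(primary = 0.8,
                                               tentative = 0.67,
                                               secondary = 0.2)) {
  eval_block <- function(estimators, target) {
    rows <- lapply(estimators, function(nm) {
      x <- records[[nm]]
      y <- records[[target]]
      dr2 <- directional_r2(x, y)
      me <- mean_of_errors(x, y)
      em <- error_of_means(x, y)
      v <- benchmark_verdicts(as.numeric(dr2), as.numeric(me),
                              primary = benchmarks$primary,
                              tentative = benchmarks$tentative,
                              secondary = benchmarks$secondary)
      me_ci <- attr(me, "conf.int")
      em_ci <- attr(em, "conf.int")
      data.frame(estimator = nm, target = target,
                 dr2 = as.numeric(dr2), p_pretest = attr(dr2, "p.value"),
                 m_e = as.numeric(me), m_e_sd = attr(me, "sd"),
                 m_e_lo = me_ci[1], m_e_hi = me_ci[2],
                 e_m = as.numeric(em), e_m_lo = em_ci[1], e_m_hi = em_ci[2],
                 mean_est = mean(x, na.rm = TRUE),
                 min_est = min(x, na.rm = TRUE),
                 max_est = max(x, na.rm = TRUE),
                 n_used = attr(me, "n"),
                 n_excluded = sum(!is.finite(x) | !is.finite(y)),
                 primary = v[["primary"]], tentative = v[["tentative"]],
                 secondary = v[["secondary"]])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  structure(list(reliability = eval_block(index_names, "o_ri"),
                 chance = eval_block(chance_names, "o_ac"),
                 benchmarks = benchmarks),
            class = "irr_evaluation")
}

#' @export
print.irr_evaluation <- function(x, digits = 3, ...) {
  cat("Index evaluation against golden standards\n\n")
  cat("Reliability estimators vs observed reliability (o_ri):\n")
  rel <- x$reliability
  rel$stars <- vapply(rel$p_pretest, pretest_stars, character(1))
  print(format_eval(rel, digits), row.names = FALSE)
  cat("\nChance estimators vs observed chance agreement (o_ac):\n")
  ch <- x$chance
  ch$stars <- vapply(ch$p_pretest, pretest_stars, character(1))
  print(format_eval(ch, digits), row.names = FALSE)
  invisible(x)
}

format_eval <- function(df, digits) {
  out <- df[, c("estimator", "dr2", "stars", "m_e", "e_m", "n_used",
                "primary", "tentative", "secondary")]
  for (nm in c("dr2", "m_e", "e_m")) out[[nm]] <- round(out[[nm]], digits)
  out
}

#' Factor effects on estimators and estimands
#'
#' Directional r squared of each dependent variable (the observed and
#' estimated reliabilities, and the observed and estimated chance
#' agreements) against each independent variable (its estimand, category
#' `C`, skew `s_k`, difficulty `d_f`), with pretest stars — the
#' estimand-vs-factor reliance profile of every estimator.
#'
#' @param records per-session records from [score_sessions()].
#' @return object of class `"irr_factor_effects"`: list of two data frames
#'   (`reliability`, `chance`), rows = independent variables, columns =
#'   dependent variables; matching `*_p` data frames of pretest p-values.
#' @export
factor_effects <- function(records) {
  block <- function(dvs, estimand) {
    ivs <- c(estimand, "C", "s_k", "d_f")
    dr2 <- matrix(NA_real_, nrow = length(ivs), ncol = length(dvs),
                  dimnames = list(ivs, dvs))
    pval <- dr2
    for (iv in ivs) for (dv in dvs) {
      d <- directional_r2(records[[dv]], records[[iv]])
      dr2[iv, dv] <- as.numeric(d)
      pval[iv, dv] <- attr(d, "p.value")
    }
    list(dr2 = as.data.frame(dr2), p = as.data.frame(pval))
  }
  rel <- block(c("o_ri", index_names), "o_ri")
  ch <- block(c("o_ac", chance_names), "o_ac")
  structure(list(reliability = rel$dr2, reliability_p = rel$p,
                 chance = ch$dr2, chance_p = ch$p),
            class = "irr_factor_effects")
}

#' @export
print.irr_factor_effects <- function(x, digits = 3, ...) {
  starred <- function(dr2, p) {
    out <- dr2
    for (j in seq_along(out))
      out[[j]] <- paste0(format(round(dr2[[j]], digits), nsmall = digits),
                         vapply(p[[j]], pretest_stars, character(1)))
    out
  }
  cat("Effects on reliability observations & estimates (dr2):\n")
  print(starred(x$reliability, x$reliability_p))
  cat("\nEffects on chance-agreement observations & estimates (dr2):\n")
  print(starred(x$chance, x$chance_p))
  invisible(x)
}

#' Cell means of observations and estimates by factor level
#'
#' Means of every observed and estimated quantity at the reference
#' condition ("ground zero": two categories, even truth distribution) and
#' at each level of category, skew and difficulty, plus the grand mean —
#' the factor-profile table of the experiment.
#'
#' @param records per-session records from [score_sessions()].
#' @return data frame, one row per condition (`block`, `level`, `n`, then
#'   the mean of each quantity; undefined estimates dropped from their
#'   cell mean).
#' @export
cell_means <- function(records) {
  qty <- c("o_ri", index_names[-1], "o_ac", chance_names)
  qty <- c("o_ri", "a_o", setdiff(qty, c("o_ri", "a_o")))
  row_for <- function(block, level, idx) {
    sub <- records[idx, , drop = FALSE]
    means <- vapply(qty, function(nm) mean(sub[[nm]], na.rm = TRUE),
                    numeric(1))
    cbind(data.frame(block = block, level = level, n = sum(idx)),
          as.data.frame(as.list(means)))
  }
  rows <- list(row_for("ground zero", "C=2, s_k=0.5",
                       records$C == 2 & records$s_k == 0.5))
  for (v in sort(unique(records$C)))
    rows[[length(rows) + 1]] <- row_for("category", as.character(v),
                                        records$C == v)
  for (v in sort(unique(records$s_k)))
    rows[[length(rows) + 1]] <- row_for("skew", format(v), records$s_k == v)
  for (v in sort(unique(records$d_f)))
    rows[[length(rows) + 1]] <- row_for("difficulty", format(round(v, 3)),
                                        records$d_f == v)
  rows[[length(rows) + 1]] <- row_for("mean", "all", rep(TRUE, nrow(records)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank indices by predictive accuracy
#'
#' Per index, directional r squared against observed reliability and (for
#' its chance estimator) against observed chance agreement, sorted by
#' reliability dr2 — the accuracy ranking. A meta-correlation (dr2 between
#' the chance-prediction and reliability-prediction accuracies over the
#' six chance-adjusted indices) is attached as attribute `meta_dr2`.
#'
#' @param evaluation an [evaluate_indices()] result.
#' @return data frame (`index`, `dr2_reliability`, `dr2_chance`) sorted
#'   decreasing by `dr2_reliability`.
#' @export
index_ranking <- function(evaluation) {
  stopifnot(inherits(evaluation, "irr_evaluation"))
  rel <- evaluation$reliability
  ch <- evaluation$chance
  out <- data.frame(index = rel$estimator,
                    dr2_reliability = rel$dr2,
                    dr2_chance = ch$dr2)
  out <- out[order(-out$dr2_reliability), ]
  rownames(out) <- NULL
  adjusted <- out$index != "a_o"
  meta <- directional_r2(out$dr2_chance[adjusted],
                         out$dr2_reliability[adjusted])
  attr(out, "meta_dr2") <- as.numeric(meta)
  out
}

#' Run the full factorial reliability experiment
#'
#' Simulates every session of the design, computes golden standards and
#' index estimates per session, evaluates all estimators against their
#' estimands, and assembles the factor-effect, cell-mean and ranking
#' tables. Deterministic under `seed`.
#'
#' @param design a [design_grid()] (default: the full 4 x 8 x 3 design
#'   with 4 replicates, 100 items per session — 384 sessions).
#' @param model a [behavior_model()] (default: [default_calibration()]).
#' @param seed master integer seed.
#' @param benchmarks benchmark thresholds, see [evaluate_indices()].
#' @return object of class `"irr_experiment"`: list with `records`,
#'   `evaluation`, `effects`, `means`, `ranking`, `design`, `seed`.
#' @examples
#' \donttest{
#' exp <- run_experiment(seed = 1)
#' exp
#' }
#' @export
run_experiment <- function(design = design_grid(),
                           model = default_calibration(),
                           seed = 1L,
                           benchmarks = list(primary = 0.8,
                                             tentative = 0.67,
                                             secondary = 0.2)) {
  sessions <- simulate_design(design, model, seed)
  records <- score_sessions(sessions)
  evaluation <- evaluate_indices(records, benchmarks)
  structure(list(records = records,
                 evaluation = evaluation,
                 effects = factor_effects(records),
                 means = cell_means(records),
                 ranking = index_ranking(evaluation),
                 design = design,
                 seed = seed),
            class = "irr_experiment")
}

#' @export
print.irr_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("Interrater reliability experiment: %d sessions (seed %d)\n",
              nrow(x$records), x$seed))
  cat(sprintf("Observed: mean o_ri = %.3f, mean o_ac = %.3f\n\n",
              mean(x$records$o_ri), mean(x$records$o_ac)))
  cat("Index ranking by predictive accuracy (dr2 vs estimand):\n")
  rk <- x$ranking
  rk$dr2_reliability <- round(rk$dr2_reliability, digits)
  rk$dr2_chance <- round(rk$dr2_chance, digits)
  print(rk, row.names = FALSE)
  cat(sprintf(
    "\nMeta dr2 (chance vs reliability accuracy, 6 adjusted indices): %.3f\n",
    attr(x$ranking, "meta_dr2")))
  invisible(x)
}

#' @export
summary.irr_experiment <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$evaluation)
  cat("\n")
  print(object$effects)
  invisible(object)
}

#' @export
plot.irr_experiment <- function(x, ...) {
  rk <- x$ranking
  m <- rbind(reliability = rk$dr2_reliability, chance = rk$dr2_chance)
  colnames(m) <- rk$index
  graphics::barplot(m, beside = TRUE, ylim = c(min(0, min(m)) - 0.1, 1),
                    legend.text = c("dr2 vs o_ri", "dr2 vs o_ac"),
                    ylab = "directional r squared",
                    main = "Accuracy of interrater reliability indices", ...)
  graphics::abline(h = 0.8, lty = 2)
  invisible(x)
}
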