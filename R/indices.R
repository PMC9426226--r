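#' Percent agreement
#'
#' Raw proportion of items on which the two raters chose the same category;
#' the oldest reliability index, with no chance correction (its implicit
#' chance-agreement estimate is the constant 0).
#'
#' @param table a [contingency_table()] (or a `rating_session`).
#' @return proportion in `[0, 1]`.
#' @export
percent_agreement <- function(table) {
  tab <- as_table(table)
  if (tab$n_items < 1L) stop("no rated items")
  sum(diag(tab$counts)) / tab$n_items
}

#' Chance-agreement estimators of the six chance-corrected indices
#'
#' Each chance-corrected index embodies a different model of how much
#' agreement two randomly rating raters would produce:
#'
#' * `chance_S()`: Bennett et al.'s uniform-category model, `1 / C`. It
#'   depends only on the declared number of categories; Perreault and
#'   Leigh's Ir adopts the same estimator.
#' * `chance_pi()`: Scott's pooled-marginal model, `sum(p_k^2)` with `p_k`
#'   the category proportions pooled over both raters.
#' * `chance_kappa()`: Cohen's per-rater marginal model,
#'   `sum(p_k1 * p_k2)`.
#' * `chance_alpha()`: Krippendorff's finite-sample pooled model for
#'   nominal data, two raters, no missing values:
#'   `sum(n_k (n_k - 1)) / (n (n - 1))` with `n_k` the pooled category
#'   counts and `n = 2 * n_items`. Converges to `chance_pi()` from below
#'   as the number of items grows.
#' * `chance_AC1()`: Gwet's model,
#'   `(1 / (C - 1)) * sum(p_k (1 - p_k))` on the pooled marginals — a
#'   function of both category count and skew, decreasing in skew.
#'
#' @param table a [contingency_table()] (or a `rating_session`).
#' @param C number of admissible categories (>= 2), for `chance_S()`.
#' @return a chance-agreement proportion in `[0, 1]`.
#' @seealso [chance_correct()], [agreement()]
#' @export
chance_S <- function(C) {
  if (inherits(C, "contingency_table") || inherits(C, "rating_session"))
    C <- as_table(C)$C
  if (length(C) != 1L || !is.finite(C) || C < 2)
    stop("at least two categories required")
  1 / C
}

#' @rdname chance_S
#' @export
chance_pi <- function(table) {
  tab <- as_table(table)
  p <- pooled_marginals(tab)
  sum(p^2)
}

#' @rdname chance_S
#' @export
chance_kappa <- function(table) {
  tab <- as_table(table)
  p1 <- rowSums(tab$counts) / tab$n_items
  p2 <- colSums(tab$counts) / tab$n_items
  sum(p1 * p2)
}

#' @rdname chance_S
#' @export
chance_alpha <- function(table) {
  tab <- as_table(table)
  nk <- rowSums(tab$counts) + colSums(tab$counts)
  n <- 2 * tab$n_items
  if (n < 2) stop("need at least one rated item")
  sum(nk * (nk - 1)) / (n * (n - 1))
}

#' @rdname chance_S
#' @export
chance_AC1 <- function(table) {
  tab <- as_table(table)
  if (tab$C < 2) stop("at least two categories required")
  p <- pooled_marginals(tab)
  sum(p * (1 - p)) / (tab$C - 1)
}

pooled_marginals <- function(tab) {
  (rowSums(tab$counts) + colSums(tab$counts)) / (2 * tab$n_items)
}

#' Chance correction of observed agreement
#'
#' The correction shared by all chance-corrected indices:
#' `r = (a_o - a_c) / (1 - a_c)`. When the chance estimate reaches 1 the
#' denominator vanishes and the index is undefined; `NA` is returned (a
#' flag, never a silent convention such as "define the index as 1").
#'
#' @param a_o observed percent agreement in `[0, 1]`.
#' @param a_c estimated chance agreement in `[0, 1]`.
#' @return reliability estimate `<= 1`, or `NA` when `a_c == 1`.
#' @examples
#' chance_correct(0.8, 0.5) # 0.6
#' @export
chance_correct <- function(a_o, a_c) {
  stopifnot(is.numeric(a_o), is.numeric(a_c))
  if (is.na(a_o) || is.na(a_c)) return(NA_real_)
  if (a_o < 0 || a_o > 1 || a_c < 0 || a_c > 1)
    stop("a_o and a_c must lie in [0, 1]")
  if (a_c == 1) return(NA_real_)
  (a_o - a_c) / (1 - a_c)
}

#' Perreault and Leigh's Ir from Bennett's S
#'
#' `Ir = sqrt(S)` for `S >= 0` and `Ir = 0` for `S < 0`, so Ir lives on
#' `[0, 1]` and always sits at or above a non-negative S.
#'
#' @param S Bennett's S (any value `<= 1`), possibly `NA`.
#' @return Ir in `[0, 1]`, `NA` if `S` is `NA`.
#' @export
index_Ir <- function(S) {
  if (is.na(S)) return(NA_real_)
  if (S >= 0) sqrt(S) else 0
}

#' Estimate all seven interrater reliability indices
#'
#' The central estimator: from a two-rater cross-classification it computes
#' percent agreement `a_o`, Bennett's `S`, Perreault-Leigh `I_r`, Gwet's
#' `AC1`, Scott's `pi`, Cohen's `kappa` and Krippendorff's `alpha`,
#' together with each index's chance-agreement estimate (`ao_ac` is the
#' constant 0 by construction). Undefined estimates (degenerate
#' denominator, e.g. both raters using a single category throughout) are
#' carried as `NA`.
#'
#' @param x a [contingency_table()], a `rating_session`, or an integer
#'   vector of rater-1 labels (then `rater2` and `C` are required).
#' @param ... passed to methods.
#' @return An object of class `"irr_estimates"`: a list with named numeric
#'   vectors `estimates` (`a_o`, `S`, `I_r`, `AC1`, `pi`, `kappa`,
#'   `alpha`) and `chance` (`ao_ac`, `S_ac`, `Ir_ac`, `AC_ac`, `pi_ac`,
#'   `kappa_ac`, `alpha_ac`), plus `n_items` and `C`.
#' @examples
#' tab <- contingency_table(rep(1:2, c(60, 40)),
#'                          rep(c(1, 2, 1, 2), c(50, 10, 8, 32)), C = 2)
#' fit <- agreement(tab)
#' coef(fit)
#' @export
agreement <- function(x, ...) UseMethod("agreement")

#' @rdname agreement
#' @export
agreement.contingency_table <- function(x, ...) {
  a_o <- percent_agreement(x)
  chance <- c(ao_ac = 0,
              S_ac = chance_S(x$C),
              Ir_ac = chance_S(x$C),
              AC_ac = chance_AC1(x),
              pi_ac = chance_pi(x),
              kappa_ac = chance_kappa(x),
              alpha_ac = chance_alpha(x))
  S <- chance_correct(a_o, chance[["S_ac"]])
  est <- c(a_o = a_o,
           S = S,
           I_r = index_Ir(S),
           AC1 = chance_correct(a_o, chance[["AC_ac"]]),
           pi = chance_correct(a_o, chance[["pi_ac"]]),
           kappa = chance_correct(a_o, chance[["kappa_ac"]]),
           alpha = chance_correct(a_o, chance[["alpha_ac"]]))
  structure(list(estimates = est, chance = chance,
                 n_items = x$n_items, C = x$C),
            class = "irr_estimates")
}

#' @rdname agreement
#' @export
agreement.rating_session <- function(x, ...) {
  agreement(as_table(x))
}

#' @rdname agreement
#' @param rater2 rater-2 labels (default method only).
#' @param C declared number of categories (default method only).
#' @export
agreement.default <- function(x, rater2, C, ...) {
  agreement(contingency_table(x, rater2, C))
}

#' @export
coef.irr_estimates <- function(object, ...) object$estimates

#' @export
print.irr_estimates <- function(x, digits = 3, ...) {
  cat(sprintf("Interrater reliability estimates (%d items, C = %d)\n\n",
              x$n_items, x$C))
  m <- rbind(estimate = x$estimates, chance = x$chance)
  colnames(m) <- names(x$estimates)
  print(round(m, digits))
  if (anyNA(x$estimates))
    cat("NA: estimate undefined (chance estimate equals 1)\n")
  invisible(x)
}

#' @export
summary.irr_estimates <- function(object, ...) {
  object
}
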