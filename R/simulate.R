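## Difficulty levels of the factorial design: the two confusable stimuli
## differ by p_x = 8..1 pixels, mapped to d_f = (8 - p_x) / 7.
design_difficulties <- function() (8 - (8:1)) / 7

## Per-session mean erroneous-chance agreement observed at each difficulty
## level, used to calibrate the guessing curve (hardest level last).
calibration_oac <- c(0.020, 0.021, 0.036, 0.062, 0.116, 0.168, 0.236, 0.380)

#' Rater behavior model: involuntary, difficulty-dependent guessing
#'
#' Raters are assumed honest but fallible: with probability `g(d_f)` a
#' rating decision is an involuntary uniform guess between the two
#' confusable categories (the longest and second-longest bars), otherwise
#' the truth is reported. Optionally, with probability `eps(C)` a decision
#' lands uniformly on one of the `C - 2` non-confusable ("short bar")
#' categories. `g` must be monotone non-decreasing over the eight design
#' difficulties and map into `[0, 1]`.
#'
#' @param guess_rate function of difficulty `d_f` in `[0, 1]` returning the
#'   involuntary guess probability.
#' @param short_bar_rate function of the category count `C` returning the
#'   probability a decision lands on a short-bar category (0 when `C == 2`
#'   regardless).
#' @return an object of class `"behavior_model"`.
#' @seealso [default_calibration()]
#' @export
behavior_model <- function(guess_rate,
                           short_bar_rate = function(C) 0) {
  stopifnot(is.function(guess_rate), is.function(short_bar_rate))
  d <- design_difficulties()
  g <- vapply(d, guess_rate, numeric(1))
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
    stop("guess_rate must map [0, 1] into [0, 1]")
  if (any(diff(g) < -1e-12))
    stop("guess_rate must be monotone non-decreasing over the design difficulties")
  structure(list(guess_rate = guess_rate, short_bar_rate = short_bar_rate),
            class = "behavior_model")
}

#' Default calibrated behavior model
#'
#' The guess probability at the eight design difficulties is obtained by
#' inverting the closed form `E[o_ac] = g^2 / 2` at the per-level mean
#' observed chance agreements (0.020, 0.021, 0.036, 0.062, 0.116, 0.168,
#' 0.236, 0.380), giving `g ≈ (0.200, 0.205, 0.268, 0.352, 0.482, 0.580,
#' 0.687, 0.872)`, with piecewise-linear interpolation between levels.
#' Short-bar noise is off by default; with `short_bars = TRUE` the
#' short-bar decision rates are set to the observed 1.11%, 1.93% and 5.53%
#' for C = 4, 6 and 8.
#'
#' @param short_bars logical; enable short-bar decision noise.
#' @return a [behavior_model()].
#' @export
default_calibration <- function(short_bars = FALSE) {
  g_fun <- stats::approxfun(design_difficulties(), sqrt(2 * calibration_oac),
                            rule = 2)
  eps_fun <- if (short_bars) {
    function(C) {
      rates <- c("2" = 0, "4" = 0.0111, "6" = 0.0193, "8" = 0.0553)
      key <- as.character(C)
      if (key %in% names(rates)) unname(rates[key]) else 0
    }
  } else {
    function(C) 0
  }
  behavior_model(g_fun, eps_fun)
}

#' Enumerate the factorial design
#'
#' Cross-product of category counts, skews and difficulties, each cell
#' replicated `replicates` times; at the defaults this is the
#' 4 x 8 x 3 design with 4 sessions per cell, 384 sessions in all.
#'
#' @param categories admissible category counts (each >= 2).
#' @param skews true-category skews in `[0.5, 1)`: probability that an
#'   item's truth is the majority confusable category.
#' @param difficulties difficulty levels in `[0, 1]`.
#' @param replicates sessions per design cell.
#' @param n_items rated items per session.
#' @return data frame of class `"irr_design"`, one row per session, with
#'   columns `session`, `C`, `s_k`, `d_f`, `replicate`, `n_items`.
#' @examples
#' nrow(design_grid()) # 384
#' @export
design_grid <- function(categories = c(2, 4, 6, 8),
                        skews = c(0.5, 0.75, 0.99),
                        difficulties = design_difficulties(),
                        replicates = 4,
                        n_items = 100) {
  if (length(categories) == 0 || length(skews) == 0 || length(difficulties) == 0)
    stop("every design factor needs at least one level")
  if (any(categories < 2)) stop("at least two categories required")
  if (any(skews < 0.5 | skews >= 1)) stop("skews must lie in [0.5, 1)")
  if (any(difficulties < 0 | difficulties > 1))
    stop("difficulties must lie in [0, 1]")
  if (replicates < 1 || n_items < 1)
    stop("replicates and n_items must be positive")
  cells <- expand.grid(replicate = seq_len(replicates),
                       d_f = difficulties,
                       s_k = skews,
                       C = categories,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("C", "s_k", "d_f", "replicate")]
  cells$n_items <- as.integer(n_items)
  cells <- cbind(session = seq_len(nrow(cells)), cells)
  class(cells) <- c("irr_design", "data.frame")
  cells
}

#' Simulate one truth-labeled rating session
#'
#' Each item's true category is the first confusable category with
#' probability `s_k`, otherwise the second (truth never falls on short-bar
#' categories; they are empty by design). Each rater, independently per
#' item: with probability `eps(C)` reports a uniformly chosen short-bar
#' category (only possible when `C > 2`); otherwise with probability
#' `g(d_f)` guesses uniformly between the two confusable categories;
#' otherwise reports the truth. Deterministic given `seed`.
#'
#' @param C declared category count (>= 2).
#' @param s_k skew of the true distribution.
#' @param d_f task difficulty in `[0, 1]`.
#' @param n_items items per session.
#' @param model a [behavior_model()].
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param replicate replicate label carried into the session record.
#' @return object of class `"rating_session"`: list with `items`
#'   (data frame `truth`, `rater1`, `rater2`), `C`, `s_k`, `d_f`,
#'   `n_items`, `replicate`, `seed`.
#' @export
simulate_session <- function(C, s_k, d_f, n_items = 100,
                             model = default_calibration(),
                             seed = NULL, replicate = 1L) {
  stopifnot(inherits(model, "behavior_model"),
            C >= 2, s_k >= 0, s_k < 1, d_f >= 0, d_f <= 1, n_items >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- model$guess_rate(d_f)
  eps <- if (C > 2) model$short_bar_rate(C) else 0
  truth <- ifelse(stats::runif(n_items) < s_k, 1L, 2L)
  rate_one <- function() {
    r <- truth
    guess <- stats::runif(n_items) < g
    n_g <- sum(guess)
    if (n_g > 0)
      r[guess] <- sample(c(1L, 2L), n_g, replace = TRUE)
    if (eps > 0) {
      short <- stats::runif(n_items) < eps
      n_s <- sum(short)
      if (n_s > 0)
        r[short] <- sample(seq.int(3L, C), n_s, replace = TRUE)
    }
    r
  }
  items <- data.frame(truth = truth, rater1 = rate_one(), rater2 = rate_one())
  structure(list(items = items, C = as.integer(C), s_k = s_k, d_f = d_f,
                 n_items = as.integer(n_items),
                 replicate = as.integer(replicate), seed = seed),
            class = "rating_session")
}

#' @export
print.rating_session <- function(x, ...) {
  cat(sprintf(
    "Rating session: %d items, C = %d, skew = %.2f, difficulty = %.3f (replicate %d)\n",
    x$n_items, x$C, x$s_k, x$d_f, x$replicate))
  invisible(x)
}

#' Simulate every session of a design
#'
#' One master seed drives the whole experiment: per-session seeds are drawn
#' once from the master stream, so sessions are independent yet the full
#' set is bit-reproducible under the same master seed.
#'
#' @param design a [design_grid()].
#' @param model a [behavior_model()].
#' @param seed master integer seed.
#' @return list of `rating_session` objects, one per design row.
#' @export
simulate_design <- function(design = design_grid(),
                            model = default_calibration(),
                            seed = 1L) {
  stopifnot(inherits(design, "data.frame"), nrow(design) >= 1)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, nrow(design))
  lapply(seq_len(nrow(design)), function(i) {
    simulate_session(C = design$C[i], s_k = design$s_k[i],
                     d_f = design$d_f[i], n_items = design$n_items[i],
                     model = model, seed = seeds[i],
                     replicate = design$replicate[i])
  })
}
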