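#' Golden-standard observation of a truth-labeled rating session
#'
#' With the true category of every item known, agreement splits into
#' right agreement (both raters equal the truth, `o_ar`) and erroneous
#' agreement (raters agree with each other on a wrong category, `o_ae`).
#' Because involuntary guessing here is confined to two confusable
#' categories, a chance agreement lands on the truth and on the wrong
#' alternative equally often, so the observed ("true") chance agreement is
#' twice the erroneous agreement, `o_ac = 2 * o_ae`, and the observed
#' reliability is `o_ri = a_o - o_ac` (equivalently `o_ar - o_ae`). These
#' observed quantities are the estimands the index estimates are judged
#' against.
#'
#' `o_ac` is a model-based estimate rather than a probability: in the
#' extreme all-agree-wrong session it reaches 2 (and `o_ri` reaches -1).
#' `o_ri` is never clamped.
#'
#' @param session a `rating_session` whose items carry a non-missing
#'   `truth` column (see [simulate_session()] / [read_sessions()]).
#' @return An object of class `"golden_standard"`: list with `o_ar`,
#'   `o_ae`, `a_o`, `d_o`, `o_ac`, `o_ri`, `t_h` (the accuracy threshold,
#'   `Inf` when `o_ri == 1`) and `n_items`.
#' @seealso [reliability_threshold()]
#' @export
golden_standard <- function(session) {
  if (!inherits(session, "rating_session"))
    stop("expected a 'rating_session'")
  items <- session$items
  if (is.null(items$truth) || anyNA(items$truth))
    stop("golden standard requires truth")
  o_ar <- mean(items$rater1 == items$truth & items$rater2 == items$truth)
  o_ae <- mean(items$rater1 == items$rater2 & items$rater1 != items$truth)
  a_o <- o_ar + o_ae
  o_ac <- 2 * o_ae
  o_ri <- a_o - o_ac
  structure(list(o_ar = o_ar, o_ae = o_ae, a_o = a_o, d_o = 1 - a_o,
                 o_ac = o_ac, o_ri = o_ri,
                 t_h = reliability_threshold(o_ac, o_ri),
                 n_items = nrow(items)),
            class = "golden_standard")
}

#' @export
print.golden_standard <- function(x, digits = 3, ...) {
  cat(sprintf("Golden standard (%d items)\n", x$n_items))
  v <- unlist(x[c("o_ar", "o_ae", "a_o", "d_o", "o_ac", "o_ri", "t_h")])
  print(round(v, digits))
  invisible(x)
}

#' Chance-agreement threshold for exact reliability recovery
#'
#' Setting the chance-corrected estimate equal to the observed reliability
#' and solving for the chance estimate gives `t_h = o_ac / (1 - o_ri)`. An
#' index whose chance estimate equals `t_h` on a session reproduces `o_ri`
#' exactly through the chance correction; a chance estimate above `t_h`
#' underestimates reliability, one below it overestimates. Since
#' `t_h >= o_ac` whenever `o_ri > 0`, an index can recover the observed
#' reliability exactly only by *over*estimating the observed chance
#' agreement; conversely, plugging the exactly observed chance agreement
#' into the correction returns `o_ri / (1 - o_ac)`, an overestimate — the
#' chance-removal paradox.
#'
#' @param o_ac observed chance agreement (>= 0).
#' @param o_ri observed reliability (< 1 for a finite threshold).
#' @return `t_h >= 0`; `Inf` when `o_ri == 1` (flagged infinite, no finite
#'   chance value can reproduce a perfect observed reliability unless
#'   `o_ac` is 0 too, in which case any `a_c` works).
#' @examples
#' reliability_threshold(0.13, 0.555) # 0.292
#' @export
reliability_threshold <- function(o_ac, o_ri) {
  stopifnot(is.numeric(o_ac), is.numeric(o_ri), o_ac >= 0)
  if (o_ri >= 1) return(Inf)
  o_ac / (1 - o_ri)
}
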