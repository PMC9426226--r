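#' Cross-classification of two raters' categorical judgements
#'
#' Builds the C x C table of joint counts (cell \[j, k\] = number of items
#' rater 1 assigned to category j and rater 2 to category k) that every
#' agreement index is computed from. The number of admissible categories `C`
#' is always the *declared* category set, never inferred from the labels
#' actually used: categories that no rater touched still count, and this is
#' what drives the category dependence of Bennett's S, Perreault-Leigh Ir
#' and Gwet's AC1.
#'
#' @param rater1,rater2 integer vectors of category labels in `1:C`, one
#'   element per rated item.
#' @param C number of admissible categories (>= 2). Must be declared
#'   explicitly; empty categories are meaningful.
#' @return An object of class `"contingency_table"`: a list with elements
#'   `counts` (C x C integer matrix), `n_items` and `C`.
#' @examples
#' tab <- contingency_table(c(1, 1, 2, 2), c(1, 2, 2, 2), C = 2)
#' tab$counts
#' @export
contingency_table <- function(rater1, rater2, C) {
  if (length(C) != 1L || !is.finite(C) || C < 2 || C != round(C))
    stop("at least two categories required")
  C <- as.integer(C)
  rater1 <- as.integer(rater1)
  rater2 <- as.integer(rater2)
  if (length(rater1) != length(rater2))
    stop("rater1 and rater2 must have the same length")
  if (length(rater1) == 0L)
    stop("no rated items")
  if (anyNA(rater1) || anyNA(rater2))
    stop("missing ratings are not supported")
  if (any(rater1 < 1L | rater1 > C) || any(rater2 < 1L | rater2 > C))
    stop("category labels must lie in 1..C")
  counts <- table(factor(rater1, levels = seq_len(C)),
                  factor(rater2, levels = seq_len(C)))
  counts <- matrix(as.integer(counts), nrow = C, ncol = C)
  structure(list(counts = counts, n_items = length(rater1), C = C),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Two-rater contingency table: %d items, C = %d categories\n",
              x$n_items, x$C))
  print(x$counts)
  invisible(x)
}

## Coerce the objects the index functions accept into a contingency_table.
as_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (inherits(x, "rating_session"))
    return(contingency_table(x$items$rater1, x$items$rater2, C = x$C))
  stop("expected a 'contingency_table' or 'rating_session'")
}
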