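#' Read and write rating sessions as delimited text
#'
#' The on-disk carrier is a plain CSV with a header and one row per rated
#' item: `session, C, s_k, d_f, replicate, item, truth, rater1, rater2`.
#' Categories are 1-based integers; the `truth` column may be empty (such
#' files are accepted for index computation but rejected by
#' [golden_standard()]). Writing then reading reproduces the sessions
#' exactly.
#'
#' @param sessions list of `rating_session` objects.
#' @param path file path.
#' @return `read_sessions()` returns a list of `rating_session` objects;
#'   `write_sessions()` returns `path` invisibly.
#' @export
write_sessions <- function(sessions, path) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    data.frame(session = i, C = s$C, s_k = s$s_k, d_f = s$d_f,
               replicate = s$replicate, item = seq_len(s$n_items),
               truth = s$items$truth, rater1 = s$items$rater1,
               rater2 = s$items$rater2)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path)
  required <- c("session", "C", "s_k", "d_f", "replicate", "item",
                "rater1", "rater2")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("malformed session file: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$truth)) df$truth <- NA_integer_
  check_cat <- function(col) {
    bad <- which(!is.na(df[[col]]) &
                   (df[[col]] < 1 | df[[col]] > df$C |
                      df[[col]] != round(df[[col]])))
    if (length(bad) > 0)
      stop(sprintf("malformed %s at line %d: category out of 1..C",
                   col, bad[1] + 1L))
  }
  for (col in c("truth", "rater1", "rater2")) check_cat(col)
  lapply(split(df, df$session), function(s) {
    structure(list(items = data.frame(truth = as.integer(s$truth),
                                      rater1 = as.integer(s$rater1),
                                      rater2 = as.integer(s$rater2)),
                   C = as.integer(s$C[1]), s_k = s$s_k[1], d_f = s$d_f[1],
                   n_items = nrow(s), replicate = as.integer(s$replicate[1]),
                   seed = NULL),
              class = "rating_session")
  })
}

#' Read an experiment configuration file
#'
#' YAML configuration selecting the design factors, replicate and item
#' counts, behavior model and benchmarks; unspecified entries fall back to
#' the defaults of [design_grid()], [default_calibration()] and
#' [evaluate_indices()]. Recognised keys: `categories`, `skews`,
#' `difficulties`, `replicates`, `n_items`, `seed`, `short_bars`,
#' `benchmarks` (with `primary`, `tentative`, `secondary`).
#'
#' @param path path to a YAML file.
#' @return list with elements `design` (a [design_grid()]), `model`
#'   (a [behavior_model()]), `seed` and `benchmarks`, ready to splice into
#'   [run_experiment()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  known <- c("categories", "skews", "difficulties", "replicates", "n_items",
             "seed", "short_bars", "benchmarks")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  design_args <- cfg[intersect(names(cfg),
                               c("categories", "skews", "difficulties",
                                 "replicates", "n_items"))]
  bench <- utils::modifyList(list(primary = 0.8, tentative = 0.67,
                                  secondary = 0.2),
                             if (is.null(cfg$benchmarks)) list()
                             else cfg$benchmarks)
  list(design = do.call(design_grid, design_args),
       model = default_calibration(short_bars = isTRUE(cfg$short_bars)),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       benchmarks = bench)
}
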