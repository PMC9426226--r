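# Independent brute-force oracle: every quantity recomputed from raw rating
# lists with explicit loops, no contingency tables, no shared code with the
# package internals.

oracle_ao <- function(r1, r2) {
  hits <- 0L
  for (i in seq_along(r1)) if (r1[i] == r2[i]) hits <- hits + 1L
  hits / length(r1)
}

oracle_counts <- function(r, C) {
  out <- numeric(C)
  for (v in r) out[v] <- out[v] + 1
  out
}

oracle_chance_pi <- function(r1, r2, C) {
  pooled <- oracle_counts(c(r1, r2), C) / (2 * length(r1))
  total <- 0
  for (p in pooled) total <- total + p * p
  total
}

oracle_chance_kappa <- function(r1, r2, C) {
  p1 <- oracle_counts(r1, C) / length(r1)
  p2 <- oracle_counts(r2, C) / length(r2)
  total <- 0
  for (k in seq_len(C)) total <- total + p1[k] * p2[k]
  total
}

oracle_chance_alpha <- function(r1, r2, C) {
  nk <- oracle_counts(c(r1, r2), C)
  n <- 2 * length(r1)
  total <- 0
  for (k in seq_len(C)) total <- total + nk[k] * (nk[k] - 1)
  total / (n * (n - 1))
}

oracle_chance_AC1 <- function(r1, r2, C) {
  pooled <- oracle_counts(c(r1, r2), C) / (2 * length(r1))
  total <- 0
  for (p in pooled) total <- total + p * (1 - p)
  total / (C - 1)
}

oracle_correct <- function(a_o, a_c) {
  if (a_c == 1) return(NA_real_)
  (a_o - a_c) / (1 - a_c)
}

# Krippendorff's alpha by its own route: 1 - D_o/D_e from the coincidence
# matrix, not via the chance-correction form the package uses.
oracle_alpha_direct <- function(r1, r2, C) {
  n <- 2 * length(r1)
  coin <- matrix(0, C, C)
  for (i in seq_along(r1)) {
    coin[r1[i], r2[i]] <- coin[r1[i], r2[i]] + 1
    coin[r2[i], r1[i]] <- coin[r2[i], r1[i]] + 1
  }
  nk <- rowSums(coin)
  d_o <- 0
  d_e <- 0
  for (a in seq_len(C)) for (b in seq_len(C)) if (a != b) {
    d_o <- d_o + coin[a, b]
    d_e <- d_e + nk[a] * nk[b]
  }
  d_o <- d_o / n
  d_e <- d_e / (n * (n - 1))
  if (d_e == 0) return(NA_real_)
  1 - d_o / d_e
}

oracle_all <- function(r1, r2, C) {
  a_o <- oracle_ao(r1, r2)
  S <- oracle_correct(a_o, 1 / C)
  list(a_o = a_o,
       S = S,
       I_r = if (is.na(S)) NA_real_ else if (S >= 0) sqrt(S) else 0,
       AC1 = oracle_correct(a_o, oracle_chance_AC1(r1, r2, C)),
       pi = oracle_correct(a_o, oracle_chance_pi(r1, r2, C)),
       kappa = oracle_correct(a_o, oracle_chance_kappa(r1, r2, C)),
       alpha = oracle_correct(a_o, oracle_chance_alpha(r1, r2, C)))
}

# All 2x2 tables (a, b, c, d) with a+b+c+d = n, as raw rating lists.
enumerate_2x2 <- function(n_max) {
  out <- list()
  for (n in 1:n_max) for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    out[[length(out) + 1]] <- list(
      r1 = rep(c(1L, 1L, 2L, 2L), times = c(a, b, cc, d)),
      r2 = rep(c(1L, 2L, 1L, 2L), times = c(a, b, cc, d)))
  }
  out
}

# Hand-built truth-labeled session for fixtures.
make_session <- function(truth, r1, r2, C, s_k = 0.5, d_f = 0) {
  structure(list(items = data.frame(truth = as.integer(truth),
                                    rater1 = as.integer(r1),
                                    rater2 = as.integer(r2)),
                 C = as.integer(C), s_k = s_k, d_f = d_f,
                 n_items = length(truth), replicate = 1L, seed = NULL),
            class = "rating_session")
}
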