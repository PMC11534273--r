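# Shared fixtures: tiny banks and hand-built response tables.

tiny_bank <- function(n = 4, keys = rep(c(TRUE, FALSE), length.out = n)) {
  item_bank(sprintf("q%d", seq_len(n)),
            sprintf("Statement %d.", seq_len(n)),
            keys)
}

# One participant-phase worth of records from a choice vector (one choice
# per bank item, in bank order).
records_for <- function(bank, pid, phase, choices, time = 0) {
  response_records(
    participant_id = rep(pid, nrow(bank)),
    phase = rep(phase, nrow(bank)),
    attempt_time = rep(time, nrow(bank)),
    item_id = bank$item_id,
    choice = choices,
    bank = bank
  )
}

# Paired records for several participants: choices_pre/choices_post are
# lists (one choice vector per participant).
paired_records <- function(bank, choices_pre, choices_post) {
  n <- length(choices_pre)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(
      records_for(bank, sprintf("p%d", i), "pre", choices_pre[[i]], time = 0),
      records_for(bank, sprintf("p%d", i), "post", choices_post[[i]], time = 1)
    )
  }))
}

# The choice that is correct (or not) in the keyed direction, at a given
# confidence.
choice_for <- function(key, correct, confident) {
  n <- max(length(key), length(correct), length(confident))
  key <- rep_len(as.logical(key), n)
  correct <- rep_len(as.logical(correct), n)
  confident <- rep_len(as.logical(confident), n)
  dir <- ifelse(correct, key, !key)
  ifelse(dir,
         ifelse(confident, "sure_true", "unsure_true"),
         ifelse(confident, "sure_false", "unsure_false"))
}

# Exact permutation distribution of the signed-rank statistic: enumerate
# all 2^n sign assignments of |d| and return the two-sided mid-p for the
# observed W+ (half the observed point mass counted; the mid-p is the
# quantity the uncorrected normal approximation estimates on a lattice).
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  t_obs <- abs(w_obs - e_w)
  mean(abs(w_all - e_w) > t_obs) + 0.5 * mean(abs(w_all - e_w) == t_obs)
}

# Random choice matrix for property tests.
random_choices <- function(n_items) {
  sample(c("sure_true", "unsure_true", "unsure_false", "sure_false"),
         n_items, replace = TRUE)
}

# Independent type-7 quantile arithmetic (sort-based), kept free of
# stats::quantile.
sort_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
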