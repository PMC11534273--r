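# Paired pre-post inference: tie-corrected Wilcoxon signed-rank with a
# normal approximation, Rosenthal effect sizes, and McNemar tests on paired
# binary correctness.

#' Wilcoxon signed-rank test for paired pre/post values
#'
#' Normal-approximation signed-rank test on the paired differences
#' `post - pre`. Pairs with a missing member are dropped, zero differences
#' are discarded (classic Wilcoxon; configurable in principle but Pratt's
#' rule is not implemented), absolute differences are ranked with midranks,
#' and the variance carries the tie correction `sum(t^3 - t)/48`. No
#' continuity correction is applied.
#'
#' Sign convention: `z` is negative when post systematically exceeds pre, so
#' an improvement after an intervention reports a negative statistic (the
#' convention used in pre-post evaluation tables where all gains print
#' negative z).
#'
#' @param pre,post Equal-length numeric vectors of paired values.
#' @return An object of class `ctf_wilcoxon`: list with `z`, `p` (two-sided),
#'   `n_effective` (pairs with nonzero difference), `n_pairs` (pairs entering
#'   the test after NA removal), `w_plus` (sum of ranks of positive
#'   differences).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  keep <- !(is.na(pre) | is.na(post))
  pre <- pre[keep]; post <- post[keep]
  n_pairs <- length(pre)
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L)
    stop("fewer than 5 nonzero paired differences (", n,
         "); the normal approximation is unreliable - use an exact test",
         call. = FALSE)
  r <- rank(abs(d))                       # midranks for ties
  w_plus <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4
  ties <- table(r)
  v_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z_raw <- (w_plus - e_w) / sqrt(v_w)
  z <- -z_raw                             # improvement (post > pre) => z < 0
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(z = z, p = p, n_effective = n, n_pairs = n_pairs, w_plus = w_plus),
    class = "ctf_wilcoxon"
  )
}

#' @export
print.ctf_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (normal approx., tie-corrected)\n  z = %.3f, p = %s, n = %d pairs (%d nonzero)\n",
    x$z, format_p(x$p), x$n_pairs, x$n_effective))
  invisible(x)
}

#' Rosenthal effect size r = z / sqrt(N)
#'
#' Converts a standardized rank-test statistic into the Rosenthal
#' correlation, with a qualitative label: `|r| < 0.30` weak, `0.30 - 0.59`
#' moderate, `>= 0.60` strong.
#'
#' @param z Standard-normal-scale test statistic (signed).
#' @param n_pairs Number of pairs actually analyzed.
#' @return An object of class `ctf_effect_size`: list with `r` and `label`.
#' @examples
#' rosenthal_r(-9.41, 307)   # r = -0.54, moderate
#' @export
rosenthal_r <- function(z, n_pairs) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  r <- z / sqrt(n_pairs)
  structure(list(r = r, label = effect_label(r)), class = "ctf_effect_size")
}

effect_label <- function(r) {
  a <- abs(r)
  ifelse(a < 0.30, "weak", ifelse(a < 0.60, "moderate", "strong"))
}

#' @export
print.ctf_effect_size <- function(x, ...) {
  cat(sprintf("Rosenthal r = %.2f (%s)\n", x$r, x$label))
  invisible(x)
}

#' McNemar test on paired binary correctness
#'
#' Chi-square test of marginal homogeneity on the discordant cells of the
#' paired pre/post 2x2 correctness table: `(b - c)^2 / (b + c)` on 1 df,
#' where `b` counts pre-correct/post-incorrect pairs and `c` the reverse.
#' No continuity correction. With no discordant pairs the statistic is 0 and
#' p = 1.
#'
#' @param pre_correct,post_correct Equal-length logical vectors.
#' @return An object of class `ctf_mcnemar`: list with `statistic`, `p`,
#'   `discordant = list(b, c)`.
#' @examples
#' mcnemar_test(rep(c(TRUE, FALSE), c(10, 10)), rep(c(TRUE, FALSE), c(15, 5)))
#' @export
mcnemar_test <- function(pre_correct, post_correct) {
  if (length(pre_correct) != length(post_correct))
    stop("pre and post must have equal length", call. = FALSE)
  keep <- !(is.na(pre_correct) | is.na(post_correct))
  pre_correct <- as.logical(pre_correct)[keep]
  post_correct <- as.logical(post_correct)[keep]
  b <- sum(pre_correct & !post_correct)
  c_ <- sum(!pre_correct & post_correct)
  if (b + c_ == 0) {
    stat <- 0; p <- 1
  } else {
    stat <- (b - c_)^2 / (b + c_)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p = p, discordant = list(b = b, c = c_)),
            class = "ctf_mcnemar")
}

#' @export
print.ctf_mcnemar <- function(x, ...) {
  cat(sprintf("McNemar chi-square = %.2f (1 df), p = %s  [b = %d, c = %d]\n",
              x$statistic, format_p(x$p), x$discordant$b, x$discordant$c))
  invisible(x)
}

format_p <- function(p, digits = 3) {
  ifelse(p < 10^-digits, paste0("<.", paste(rep("0", digits - 1), collapse = ""), "1"),
         sub("^0", "", sprintf(paste0("%.", digits, "f"), p)))
}

# The seven pre/post summary rows and where each lives.
summary_measures <- data.frame(
  score = c("ctf_sum", "binary_pct", "ac", "bs", "ccp", "cip", "dis"),
  label = c("CTF overall score", "Binary true/false score",
            "Absolute accuracy of confidence judgments",
            "Bias of confidence judgments",
            "Confident correct probability",
            "Confident incorrect probability",
            "Discrimination between correct and incorrect decisions"),
  source = c("scores", "scores", rep("profiles", 5)),
  stringsAsFactors = FALSE
)

#' Pre/post summary table of scores and metacognitive indices
#'
#' Builds the seven-row evaluation table — CTF sum, binary percent correct,
#' AC, BS, CCP, CIP, DIS — with per-phase median, IQR and range, the
#' tie-corrected Wilcoxon z and p, and the Rosenthal effect size with its
#' qualitative label. Participants with an undefined index value in either
#' phase are excluded pairwise for that row only (`n_excluded` reports how
#' many). Rows where the signed-rank test is degenerate (post identical to
#' pre, or fewer than 5 nonzero differences) carry `NA` statistics and a
#' `note`.
#'
#' @param scores Output of [score_cohort()].
#' @param profiles Output of [profile_cohort()].
#' @return Data frame with one row per measure: `score`, `label`,
#'   `median_pre`, `q1_pre`, `q3_pre`, `min_pre`, `max_pre`, the same for
#'   post, `n`, `n_excluded`, `z`, `p`, `r`, `effect_label`, `note`.
#' @export
prepost_summary <- function(scores, profiles) {
  rows <- lapply(seq_len(nrow(summary_measures)), function(i) {
    meas <- summary_measures[i, ]
    tab <- if (meas$source == "scores") scores else profiles
    wide <- align_phases(tab, meas$score)
    keep <- !(is.na(wide$pre) | is.na(wide$post))
    pre <- wide$pre[keep]; post <- wide$post[keep]
    n <- length(pre)
    wt <- tryCatch(wilcoxon_signed_rank(pre, post),
                   error = function(e) conditionMessage(e))
    if (is.character(wt)) {
      z <- NA_real_; p <- NA_real_; r <- NA_real_; lab <- NA_character_
      note <- wt
    } else {
      z <- wt$z; p <- wt$p
      es <- rosenthal_r(z, n)
      r <- es$r; lab <- es$label
      note <- NA_character_
    }
    data.frame(
      score = meas$score, label = meas$label,
      median_pre = stats::median(pre), q1_pre = unname(stats::quantile(pre, 0.25)),
      q3_pre = unname(stats::quantile(pre, 0.75)),
      min_pre = min(pre), max_pre = max(pre),
      median_post = stats::median(post), q1_post = unname(stats::quantile(post, 0.25)),
      q3_post = unname(stats::quantile(post, 0.75)),
      min_post = min(post), max_post = max(post),
      n = n, n_excluded = sum(!keep),
      z = z, p = p, r = r, effect_label = lab, note = note,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# participant-aligned pre/post columns for one measure
align_phases <- function(tab, column) {
  pre <- tab[tab$phase == "pre", c("participant_id", column)]
  post <- tab[tab$phase == "post", c("participant_id", column)]
  m <- merge(pre, post, by = "participant_id", suffixes = c("_pre", "_post"))
  data.frame(participant_id = m$participant_id,
             pre = m[[paste0(column, "_pre")]],
             post = m[[paste0(column, "_post")]],
             stringsAsFactors = FALSE)
}
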