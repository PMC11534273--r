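# Synthetic paired pre-post CTF cohorts with known latent structure.
#
# Generative model, per participant i and item j:
#   pretest  P(correct) = plogis(qlogis(p_i) + delta_j)
#   posttest P(correct) = plogis(qlogis(p_i) + delta_j + knowledge_effect)
# with per-participant ability p_i ~ Beta(a, b) and per-item difficulty
# offsets delta_j ~ Normal(0, item_difficulty_sd) on the log-odds scale.
# The chosen direction is the keyed one iff correct; confidence is then
# drawn conditionally on correctness alone (gamma_cc when correct, gamma_ci
# when incorrect, each with its own pre/post value) — item-independent
# confidence is the simplest structure that exercises every index the
# pipeline computes. Posttest dropout and biased retakes (later attempts
# get a correctness bonus, so only the chronologically first attempt is
# unbiased) are optional.

#' Simulation configuration
#'
#' Defaults mirror the assessment shape this package targets: a cohort of
#' 307 learners on a 20-item bank with 13 false-keyed items, pretest binary
#' accuracy around 60% rising to about 72%, and confidence that rises after
#' the intervention for correct and incorrect answers alike
#' (`gamma_cc` 0.35 to 0.85, `gamma_ci` 0.20 to 0.70).
#'
#' @param n_participants Cohort size before dropout.
#' @param n_items Number of items.
#' @param frac_false_keyed Fraction of items keyed false.
#' @param knowledge_pre Length-2 `c(a, b)` Beta parameters for per-
#'   participant pretest probability of a correct direction.
#' @param knowledge_effect Additive posttest shift on the log-odds of
#'   correctness.
#' @param conf_given_correct_pre,conf_given_correct_post Probability of a
#'   confident (`sure_*`) choice when correct (gamma_cc), per phase.
#' @param conf_given_incorrect_pre,conf_given_incorrect_post Probability of
#'   a confident choice when incorrect (gamma_ci), per phase.
#' @param item_difficulty_sd SD of per-item log-odds offsets.
#' @param dropout_post Probability a participant has no posttest.
#' @param extra_attempts_max Maximum number of additional posttest attempts;
#'   each later attempt gains `attempt_bonus` log-odds of correctness, so
#'   using any attempt but the first inflates scores measurably.
#' @param attempt_bonus Log-odds correctness bonus per later attempt.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 307, n_items = 20,
                       frac_false_keyed = 13 / 20,
                       knowledge_pre = c(6, 4), knowledge_effect = 0.5,
                       conf_given_correct_pre = 0.35,
                       conf_given_correct_post = 0.85,
                       conf_given_incorrect_pre = 0.20,
                       conf_given_incorrect_post = 0.70,
                       item_difficulty_sd = 1, dropout_post = 0,
                       extra_attempts_max = 0, attempt_bonus = 0.75,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_items = as.integer(n_items),
    frac_false_keyed = frac_false_keyed, knowledge_pre = knowledge_pre,
    knowledge_effect = knowledge_effect,
    conf_given_correct_pre = conf_given_correct_pre,
    conf_given_correct_post = conf_given_correct_post,
    conf_given_incorrect_pre = conf_given_incorrect_pre,
    conf_given_incorrect_post = conf_given_incorrect_post,
    item_difficulty_sd = item_difficulty_sd, dropout_post = dropout_post,
    extra_attempts_max = as.integer(extra_attempts_max),
    attempt_bonus = attempt_bonus, seed = as.integer(seed)
  )
  probs <- cfg[c("frac_false_keyed", "conf_given_correct_pre",
                 "conf_given_correct_post", "conf_given_incorrect_pre",
                 "conf_given_incorrect_post", "dropout_post")]
  bad <- names(probs)[vapply(probs, function(p)
    !is.numeric(p) || is.na(p) || p < 0 || p > 1, logical(1))]
  if (length(bad))
    stop("sim_config: not a probability in [0,1]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  if (cfg$n_items < 1L) stop("n_items must be >= 1", call. = FALSE)
  if (length(cfg$knowledge_pre) != 2L || any(cfg$knowledge_pre <= 0))
    stop("knowledge_pre must be positive Beta parameters c(a, b)", call. = FALSE)
  if (cfg$item_difficulty_sd < 0) stop("item_difficulty_sd must be >= 0", call. = FALSE)
  if (cfg$extra_attempts_max < 0L) stop("extra_attempts_max must be >= 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

choice_from <- function(direction_true, confident) {
  ifelse(direction_true,
         ifelse(confident, "sure_true", "unsure_true"),
         ifelse(confident, "sure_false", "unsure_false"))
}

#' Simulate a paired pre-post CTF cohort
#'
#' Draws a full response table (plus its item bank and the latent truth)
#' from the generative model described in [sim_config()]. The output always
#' passes the package's own validation and, in the absence of dropout,
#' yields a paired cohort of exactly `n_participants`.
#'
#' @param config A [sim_config()].
#' @return List with
#'   \describe{
#'     \item{bank}{an [item_bank] of `n_items` synthetic statements}
#'     \item{responses}{a `ctf_responses` data frame; pretest at
#'       `attempt_time` 0, posttest attempts at 1, 2, ...}
#'     \item{truth}{list: `p_pre`, `p_post` (participant x item correctness
#'       probability matrices for the first attempt), `theta` (participant
#'       ability log-odds), `delta` (item offsets), `config`}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  k <- config$n_items
  ids <- sprintf("p%03d", seq_len(n))
  n_false <- round(config$frac_false_keyed * k)
  key <- rep(TRUE, k)
  if (n_false > 0) key[seq_len(n_false)] <- FALSE
  bank <- item_bank(
    item_id = sprintf("q%02d", seq_len(k)),
    statement = sprintf("Synthetic statement %d (keyed %s).", seq_len(k),
                        ifelse(key, "true", "false")),
    answer_key = key
  )
  theta <- stats::qlogis(stats::rbeta(n, config$knowledge_pre[1],
                                      config$knowledge_pre[2]))
  delta <- stats::rnorm(k, 0, config$item_difficulty_sd)
  lin <- outer(theta, delta, "+")
  p_pre <- stats::plogis(lin)
  p_post <- stats::plogis(lin + config$knowledge_effect)

  draw_phase <- function(p_correct, g_cc, g_ci) {
    correct <- matrix(stats::runif(n * k) < p_correct, n, k)
    keymat <- matrix(key, n, k, byrow = TRUE)
    direction <- ifelse(correct, keymat, !keymat)
    confident <- matrix(stats::runif(n * k), n, k) <
      ifelse(correct, g_cc, g_ci)
    choice_from(direction, confident)
  }

  pre_choice <- draw_phase(p_pre, config$conf_given_correct_pre,
                           config$conf_given_incorrect_pre)
  has_post <- stats::runif(n) >= config$dropout_post
  extra <- if (config$extra_attempts_max > 0)
    sample(0:config$extra_attempts_max, n, replace = TRUE) else integer(n)

  blocks <- list(data.frame(
    participant_id = rep(ids, each = k),
    phase = "pre", attempt_time = 0,
    item_id = rep(bank$item_id, n),
    choice = as.vector(t(pre_choice)),
    stringsAsFactors = FALSE
  ))
  max_attempt <- if (any(has_post)) max(1L, 1L + max(extra[has_post])) else 0L
  for (a in seq_len(max_attempt)) {
    in_attempt <- has_post & (1L + extra) >= a
    if (!any(in_attempt)) next
    p_a <- stats::plogis(lin + config$knowledge_effect +
                           (a - 1) * config$attempt_bonus)
    ch <- draw_phase(p_a, config$conf_given_correct_post,
                     config$conf_given_incorrect_post)
    idx <- which(in_attempt)
    blocks[[length(blocks) + 1L]] <- data.frame(
      participant_id = rep(ids[idx], each = k),
      phase = "post", attempt_time = a,
      item_id = rep(bank$item_id, length(idx)),
      choice = as.vector(t(ch[idx, , drop = FALSE])),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, blocks)
  responses <- response_records(tab$participant_id, tab$phase,
                                tab$attempt_time, tab$item_id, tab$choice,
                                bank = bank)
  truth <- list(p_pre = p_pre, p_post = p_post, theta = theta, delta = delta,
                has_post = has_post, extra_attempts = extra, config = config)
  list(bank = bank, responses = responses, truth = truth)
}

#' Recover confidence-calibration parameters from a simulated cohort
#'
#' Checks that the pipeline's cohort-mean CCP and CIP estimate the
#' generator's `gamma_cc` and `gamma_ci`: runs the simulated responses
#' through [select_first_posttest()], [build_paired_cohort()] and
#' [profile_cohort()], then compares phase-wise participant means of CCP/CIP
#' against the configured truth.
#'
#' @param sim A [simulate_cohort()] result.
#' @return Data frame with one row per phase x index: `phase`, `index`
#'   (`ccp`/`cip`), `truth`, `estimate` (cohort mean, undefined values
#'   dropped), `bias`, `rmse` (participant-level root-mean-square error
#'   around the truth), `n_defined`.
#' @export
recover_parameters <- function(sim) {
  cfg <- sim$truth$config
  cohort <- build_paired_cohort(select_first_posttest(sim$responses), sim$bank)
  prof <- profile_cohort(cohort, sim$bank)
  truth_of <- list(
    pre = c(ccp = cfg$conf_given_correct_pre, cip = cfg$conf_given_incorrect_pre),
    post = c(ccp = cfg$conf_given_correct_post, cip = cfg$conf_given_incorrect_post)
  )
  rows <- list()
  for (ph in phase_levels) {
    sub <- prof[prof$phase == ph, ]
    for (index in c("ccp", "cip")) {
      v <- sub[[index]]
      v <- v[!is.na(v)]
      tru <- truth_of[[ph]][[index]]
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, index = index, truth = tru,
        estimate = mean(v), bias = mean(v) - tru,
        rmse = sqrt(mean((v - tru)^2)), n_defined = length(v),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
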