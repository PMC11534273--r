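# Metacognitive calibration indices from (confident, correct)
# classifications of CTF responses.
#
# With per-phase counts cc (confident correct), uc (unconfident correct),
# ci (confident incorrect), ui (unconfident incorrect), n = cc+uc+ci+ui:
#   AC  = (cc + ui) / n        match between confidence and outcome
#   BS  = (ci - uc) / n        confidence rate minus accuracy rate;
#                              positive = overconfident, negative = under
#   CCP = cc / (cc + uc)       P(confident | correct), undefined if no corrects
#   CIP = ci / (ci + ui)       P(confident | incorrect), undefined if no errors
#   DIS = CCP - CIP            undefined when either conditional is
# Undefined components are NA, never imputed: clamping them to 0 or 1 would
# manufacture bias in exactly the indices under study.

#' Classify a response as (confident, correct)
#'
#' @inheritParams ctf_points
#' @return Data frame with logical columns `confident` (a `sure_*` choice)
#'   and `correct` (direction matches the key).
#' @export
classify_response <- function(choice, answer_key) {
  choice <- normalize_choice(choice)
  data.frame(
    confident = choice_confident(choice),
    correct = binary_correct(choice, answer_key)
  )
}

metacog_from_counts <- function(cc, uc, ci, ui) {
  n <- cc + uc + ci + ui
  ccp <- ifelse(cc + uc > 0, cc / (cc + uc), NA_real_)
  cip <- ifelse(ci + ui > 0, ci / (ci + ui), NA_real_)
  data.frame(
    ac = (cc + ui) / n,
    bs = (ci - uc) / n,
    ccp = ccp,
    cip = cip,
    dis = ccp - cip,
    cc = cc, uc = uc, ci = ci, ui = ui
  )
}

#' Metacognitive profile from classified responses
#'
#' Computes the five calibration indices — absolute accuracy (AC), bias
#' (BS), confident-correct probability (CCP), confident-incorrect
#' probability (CIP) and discrimination (DIS = CCP − CIP) — from one
#' participant-phase's `(confident, correct)` classifications.
#'
#' @param classified Data frame with logical columns `confident` and
#'   `correct` (one row per item), as produced by [classify_response()].
#' @return One-row data frame `ac`, `bs`, `ccp`, `cip`, `dis`, `cc`, `uc`,
#'   `ci`, `ui`. Undefined conditional probabilities (no correct answers for
#'   CCP, no incorrect for CIP) are `NA`.
#' @examples
#' cls <- classify_response(rep(c("sure_true", "unsure_false"), c(15, 5)), TRUE)
#' metacog_profile(cls)
#' @export
metacog_profile <- function(classified) {
  if (NROW(classified) == 0L)
    stop("cannot compute a metacognitive profile from zero responses",
         call. = FALSE)
  conf <- classified$confident
  corr <- classified$correct
  if (anyNA(conf) || anyNA(corr))
    stop("classified responses contain missing values", call. = FALSE)
  metacog_from_counts(
    cc = sum(conf & corr), uc = sum(!conf & corr),
    ci = sum(conf & !corr), ui = sum(!conf & !corr)
  )
}

#' Metacognitive profiles for a paired cohort
#'
#' @param cohort A [build_paired_cohort()] result.
#' @param bank The [item_bank].
#' @return Data frame with one row per participant x phase:
#'   `participant_id`, `phase`, then the [metacog_profile()] columns.
#'   `NA` components propagate to downstream inference, where those
#'   participants are excluded pairwise.
#' @export
profile_cohort <- function(cohort, bank) {
  validate_item_bank(bank)
  out <- lapply(phase_levels, function(ph) {
    m <- choice_matrix(cohort, bank, ph)
    keymat <- matrix(bank$answer_key, nrow = cohort$n, ncol = nrow(bank),
                     byrow = TRUE)
    conf <- m == 1L | m == 4L
    corr <- (m == 1L | m == 2L) == keymat
    prof <- metacog_from_counts(
      cc = rowSums(conf & corr), uc = rowSums(!conf & corr),
      ci = rowSums(conf & !corr), ui = rowSums(!conf & !corr)
    )
    cbind(
      data.frame(participant_id = cohort$participants,
                 phase = factor(ph, levels = phase_levels),
                 stringsAsFactors = FALSE),
      prof
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$phase), ]
  rownames(res) <- NULL
  res
}
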