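# Published reference values from a metacognitive evaluation of a
# naloxone-coprescription continuing-education course (paired cohort,
# N = 307, 20-item CTF assessment). The participant-level data behind these
# summaries are not public; the printed summary statistics serve as worked-
# example inputs for effect-size and item-change computations and as
# cross-checks for the test statistics this package implements.

#' Published summary-table reference values
#'
#' The seven score rows of the published evaluation: Wilcoxon z, Rosenthal
#' effect size and qualitative label, for a paired cohort of 307.
#'
#' @return Data frame with columns `score`, `z`, `r`, `effect_label`, `n`.
#' @examples
#' ref <- ctf_reference_summary()
#' rosenthal_r(ref$z[ref$score == "ctf_sum"], 307)
#' @export
ctf_reference_summary <- function() {
  data.frame(
    score = c("ctf_sum", "binary_pct", "ac", "bs", "ccp", "cip", "dis"),
    z = c(-9.41, -9.41, -9.42, -13.08, -13.59, -12.82, 2.85),
    r = c(-0.54, -0.54, -0.54, -0.75, -0.78, -0.73, 0.16),
    effect_label = c("moderate", "moderate", "moderate", "strong", "strong",
                     "strong", "weak"),
    n = 307L,
    stringsAsFactors = FALSE
  )
}

#' Published item-level reference values
#'
#' Per item of the published 20-item assessment: the answer key, the
#' McNemar statistic printed for the pre/post binary comparison, the
#' confident-incorrect category percentage at each phase, and the printed
#' percent-change column. `change_consistent` flags the items whose printed
#' change agrees with the confident-incorrect definition
#' (`100 * (post - pre) / pre` at integer rounding); for the others the
#' printed column does not match that definition (nor, with one sign
#' exception, the total-incorrect variant) and is kept only for the record.
#' Items 7, 12 and 15 form the `riosord` concept group.
#'
#' @return Data frame with columns `item_id`, `answer_key`,
#'   `concept_group`, `mcnemar_stat`, `conf_incorrect_pre`,
#'   `conf_incorrect_post`, `printed_change`, `change_consistent`.
#' @export
ctf_reference_items <- function() {
  df <- data.frame(
    item_id = sprintf("q%02d", 1:20),
    answer_key = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                   TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, FALSE),
    concept_group = NA_character_,
    mcnemar_stat = c(2.47, 26.18, 1.25, 0.91, 16.20, 13.23, 0.81, 19.76,
                     0.02, 0.15, 0.38, 8.56, 18.67, 9.14, 4.41, 6.86,
                     14.29, 10.12, 2.06, 6.88),
    conf_incorrect_pre = c(11, 7, 11, 6, 7, 17, 8, 9, 1, 16,
                           7, 29, 3, 2, 22, 11, 2, 1, 3, 22),
    conf_incorrect_post = c(22, 5, 18, 14, 18, 31, 36, 16, 4, 35,
                            21, 63, 2, 1, 64, 16, 3, 1, 5, 38),
    printed_change = c(100, -28.5, 64, 5, 129, 82, 350, -32, 300, 4,
                       -6, 117, -33, -50, 191, 45, 50, 0, 67, 73),
    stringsAsFactors = FALSE
  )
  df$concept_group[df$item_id %in% c("q07", "q12", "q15")] <- "riosord"
  clean <- c(1, 3, 6, 7, 9, 12, 13, 14, 15, 16, 17, 18, 19, 20)
  df$change_consistent <- seq_len(20) %in% clean
  df
}
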