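# Per-item CTF distribution tables, binary aggregation, McNemar change
# tests and the confident-incorrect change metric.

# Category order worst-to-best relative to the key: the confident wrong
# answer first, the confident right answer last. For a false-keyed item
# that is sure_true .. sure_false; for a true-keyed item the reverse.
category_order <- function(answer_key) {
  if (answer_key) rev(ctf_levels) else ctf_levels
}

confident_incorrect_category <- function(answer_key) {
  if (answer_key) "sure_false" else "sure_true"
}

#' Per-item CTF response distribution
#'
#' Percentage of the paired cohort choosing each CTF category for one item
#' in one phase, on the paired-cohort denominator (same n pre and post).
#' Categories are ordered from confident-incorrect to confident-correct
#' relative to the answer key.
#'
#' @param cohort A [build_paired_cohort()] result.
#' @param bank The [item_bank].
#' @param item Item id.
#' @param phase `"pre"` or `"post"`.
#' @return Named numeric vector of percentages (sums to 100) in
#'   worst-to-best category order, with attributes `item_id`, `phase`,
#'   `answer_key`.
#' @export
ctf_distribution <- function(cohort, bank, item, phase) {
  validate_item_bank(bank)
  pos <- match(item, bank$item_id)
  if (is.na(pos)) stop("unknown item: ", item, call. = FALSE)
  phase <- as.character(normalize_phase(phase))
  resp <- cohort$responses
  ch <- resp$choice[resp$item_id == item & resp$phase == phase]
  counts <- table(factor(as.character(ch), levels = ctf_levels))
  pct <- 100 * as.numeric(counts) / cohort$n
  names(pct) <- ctf_levels
  ord <- category_order(bank$answer_key[pos])
  structure(pct[ord], item_id = item, phase = phase,
            answer_key = bank$answer_key[pos])
}

#' Relative change in confident-incorrect answers
#'
#' Percent change from pre to post in the share of the cohort that was
#' confidently wrong on an item: `100 * (post - pre) / pre`. Undefined
#' (`NA`) when the pretest share is zero. Scale-invariant: proportions and
#' percentages give the same result.
#'
#' @param pre_pct,post_pct Confident-incorrect category percentages (or
#'   proportions) at pre and post.
#' @return Percent change (unrounded; report tables round to integers), or
#'   `NA` when `pre_pct` is 0.
#' @examples
#' confident_incorrect_change(11, 22)  # 100
#' confident_incorrect_change(8, 36)   # 350
#' @export
confident_incorrect_change <- function(pre_pct, post_pct) {
  ifelse(pre_pct == 0, NA_real_, 100 * (post_pct - pre_pct) / pre_pct)
}

#' Item-level change report
#'
#' One row per bank item: the four CTF category percentages at pre and post
#' (paired-cohort denominator), the binary true/false aggregation, the
#' McNemar test on binary correctness, and the confident-incorrect change.
#' A `total_incorrect_change` variant (relative change in all wrong-direction
#' answers, confident or not) is included alongside the confident-only
#' definition.
#'
#' @param cohort A [build_paired_cohort()] result.
#' @param bank The [item_bank].
#' @return Data frame of class `ctf_item_report`, one row per item, columns
#'   `item_id`, `answer_key`, `concept_group`,
#'   `pre_sure_true` .. `pre_sure_false`, `post_sure_true` ..
#'   `post_sure_false`, `pre_true_pct`, `pre_false_pct`, `post_true_pct`,
#'   `post_false_pct`, `pre_correct_pct`, `post_correct_pct`,
#'   `mcnemar_stat`, `mcnemar_p`, `mcnemar_b`, `mcnemar_c`,
#'   `conf_incorrect_pre`, `conf_incorrect_post`, `conf_incorrect_change`,
#'   `total_incorrect_change`. Percentages are unrounded; rounding is a
#'   report-time concern.
#' @export
item_report <- function(cohort, bank) {
  validate_item_bank(bank)
  pre_m <- choice_matrix(cohort, bank, "pre")
  post_m <- choice_matrix(cohort, bank, "post")
  n <- cohort$n
  rows <- lapply(seq_len(nrow(bank)), function(j) {
    key <- bank$answer_key[j]
    pre <- pre_m[, j]; post <- post_m[, j]
    pre_pct <- 100 * tabulate(pre, 4L) / n
    post_pct <- 100 * tabulate(post, 4L) / n
    names(pre_pct) <- names(post_pct) <- ctf_levels
    pre_corr <- (pre == 1L | pre == 2L) == key
    post_corr <- (post == 1L | post == 2L) == key
    mc <- mcnemar_test(pre_corr, post_corr)
    ci_cat <- confident_incorrect_category(key)
    wrong_cats <- if (key) c("sure_false", "unsure_false") else c("sure_true", "unsure_true")
    data.frame(
      item_id = bank$item_id[j],
      answer_key = key,
      concept_group = bank$concept_group[j],
      pre_sure_true = pre_pct[["sure_true"]],
      pre_unsure_true = pre_pct[["unsure_true"]],
      pre_unsure_false = pre_pct[["unsure_false"]],
      pre_sure_false = pre_pct[["sure_false"]],
      post_sure_true = post_pct[["sure_true"]],
      post_unsure_true = post_pct[["unsure_true"]],
      post_unsure_false = post_pct[["unsure_false"]],
      post_sure_false = post_pct[["sure_false"]],
      pre_true_pct = pre_pct[["sure_true"]] + pre_pct[["unsure_true"]],
      pre_false_pct = pre_pct[["sure_false"]] + pre_pct[["unsure_false"]],
      post_true_pct = post_pct[["sure_true"]] + post_pct[["unsure_true"]],
      post_false_pct = post_pct[["sure_false"]] + post_pct[["unsure_false"]],
      pre_correct_pct = 100 * mean(pre_corr),
      post_correct_pct = 100 * mean(post_corr),
      mcnemar_stat = mc$statistic,
      mcnemar_p = mc$p,
      mcnemar_b = mc$discordant$b,
      mcnemar_c = mc$discordant$c,
      conf_incorrect_pre = pre_pct[[ci_cat]],
      conf_incorrect_post = post_pct[[ci_cat]],
      conf_incorrect_change = confident_incorrect_change(pre_pct[[ci_cat]],
                                                         post_pct[[ci_cat]]),
      total_incorrect_change = confident_incorrect_change(sum(pre_pct[wrong_cats]),
                                                          sum(post_pct[wrong_cats])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ctf_item_report", "data.frame")
  out
}

#' Range of confident-incorrect change within a concept group
#'
#' Minimum and maximum of the defined confident-incorrect change values
#' among the items tagged with one concept group (e.g. the items probing a
#' single clinical risk tool).
#'
#' @param reports An [item_report()] data frame.
#' @param group Concept-group tag, matched against `concept_group`; or a
#'   character vector of item ids via `items`.
#' @param items Optional explicit item ids overriding the group lookup.
#' @return List with `min_change` and `max_change`.
#' @export
concept_group_change <- function(reports, group = NULL, items = NULL) {
  if (is.null(items)) {
    if (is.null(group)) stop("give either group or items", call. = FALSE)
    items <- reports$item_id[!is.na(reports$concept_group) &
                               reports$concept_group == group]
  }
  sel <- reports[reports$item_id %in% items, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no items in group", call. = FALSE)
  ch <- sel$conf_incorrect_change
  ch <- ch[!is.na(ch)]
  if (length(ch) == 0L)
    stop("no defined confident-incorrect change values in group", call. = FALSE)
  list(min_change = min(ch), max_change = max(ch))
}
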