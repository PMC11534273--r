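# Content-knowledge scores for CTF assessments.
#
# Point mapping (default): confident correct 4, unconfident correct 3,
# unconfident incorrect 1, confident incorrect 0. Only the endpoints are
# fixed by the CTF construct; the intermediate values form the simplest
# symmetric, strictly monotone mapping on the 0-4 scale, and can be swapped
# for another published mapping via the `points` argument.

default_ctf_points <- c(confident_correct = 4, unconfident_correct = 3,
                        unconfident_incorrect = 1, confident_incorrect = 0)

check_points <- function(points) {
  if (length(points) != 4L || anyNA(points) || !is.numeric(points))
    stop("points must be a numeric 4-vector: (confident correct, ",
         "unconfident correct, unconfident incorrect, confident incorrect)",
         call. = FALSE)
  as.numeric(points)
}

choice_direction <- function(choice) {
  # TRUE if the choice asserts the statement is true
  as.integer(choice) %in% c(1L, 2L)
}

choice_confident <- function(choice) {
  as.integer(choice) %in% c(1L, 4L)
}

#' CTF points for one response
#'
#' Scores a single CTF choice against the answer key: a confident response in
#' the correct direction earns the maximum (4 by default), a confident
#' response in the wrong direction the minimum (0), with unsure responses in
#' between (3 correct / 1 incorrect by default).
#'
#' @param choice A CTF choice (`sure_true`, `unsure_true`, `unsure_false`,
#'   `sure_false`), or a vector of them.
#' @param answer_key Logical; `TRUE` if the statement is true. Recycled
#'   against `choice`.
#' @param points Numeric 4-vector `(confident correct, unconfident correct,
#'   unconfident incorrect, confident incorrect)`.
#' @return Numeric vector of per-item points.
#' @examples
#' ctf_points("sure_true", TRUE)   # 4
#' ctf_points("sure_true", FALSE)  # 0
#' @export
ctf_points <- function(choice, answer_key, points = default_ctf_points) {
  points <- check_points(points)
  choice <- normalize_choice(choice)
  correct <- binary_correct(choice, answer_key)
  confident <- choice_confident(choice)
  idx <- ifelse(correct, ifelse(confident, 1L, 2L), ifelse(confident, 4L, 3L))
  points[idx]
}

#' Binary correctness of one response
#'
#' `TRUE` iff the true/false direction of the choice matches the answer key,
#' regardless of confidence.
#'
#' @inheritParams ctf_points
#' @return Logical vector.
#' @export
binary_correct <- function(choice, answer_key) {
  choice <- normalize_choice(choice)
  choice_direction(choice) == rep_len(as.logical(answer_key), length(choice))
}

#' Score one participant-phase
#'
#' Computes the three content-knowledge scores from one phase of one
#' participant's responses: the summed CTF score (0 to 4 x items), the
#' percent CTF score (share of the maximum), and the binary percent correct.
#'
#' @param responses A `ctf_responses` data frame (or any data frame with
#'   `item_id` and `choice`) holding exactly one response per bank item.
#' @param bank The [item_bank].
#' @param points CTF point mapping, see [ctf_points()].
#' @return A one-row data frame with `ctf_sum`, `ctf_pct`, `binary_pct`,
#'   `n_items`.
#' @export
score_participant <- function(responses, bank, points = default_ctf_points) {
  validate_item_bank(bank)
  if (anyDuplicated(responses$item_id) ||
      !setequal(responses$item_id, bank$item_id))
    stop("scoring requires exactly one response per bank item", call. = FALSE)
  key <- bank$answer_key[match(responses$item_id, bank$item_id)]
  pts <- ctf_points(responses$choice, key, points)
  corr <- binary_correct(responses$choice, key)
  n <- nrow(bank)
  data.frame(
    ctf_sum = sum(pts),
    ctf_pct = 100 * sum(pts) / (max(check_points(points)) * n),
    binary_pct = 100 * sum(corr) / n,
    n_items = n
  )
}

#' Score every participant-phase in a paired cohort
#'
#' @param cohort A [build_paired_cohort()] result.
#' @param bank The [item_bank].
#' @param points CTF point mapping, see [ctf_points()].
#' @return Data frame with one row per participant x phase:
#'   `participant_id`, `phase`, `ctf_sum`, `ctf_pct`, `binary_pct`,
#'   `n_items`.
#' @export
score_cohort <- function(cohort, bank, points = default_ctf_points) {
  points <- check_points(points)
  validate_item_bank(bank)
  pmax_ <- max(points)
  n_items <- nrow(bank)
  out <- lapply(phase_levels, function(ph) {
    m <- choice_matrix(cohort, bank, ph)                 # participants x items
    keymat <- matrix(bank$answer_key, nrow = cohort$n, ncol = n_items,
                     byrow = TRUE)
    dir <- m == 1L | m == 2L                             # asserts "true"
    conf <- m == 1L | m == 4L
    correct <- dir == keymat
    idx <- ifelse(correct, ifelse(conf, 1L, 2L), ifelse(conf, 4L, 3L))
    pts <- matrix(points[idx], nrow = cohort$n)
    data.frame(
      participant_id = cohort$participants,
      phase = factor(ph, levels = phase_levels),
      ctf_sum = rowSums(pts),
      ctf_pct = 100 * rowSums(pts) / (pmax_ * n_items),
      binary_pct = 100 * rowSums(correct) / n_items,
      n_items = n_items,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$phase), ]
  rownames(res) <- NULL
  res
}
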