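# Long-format CTF response tables: loading, normalization, attempt
# deduplication and paired complete-case cohort construction.

ctf_levels <- c("sure_true", "unsure_true", "unsure_false", "sure_false")
phase_levels <- c("pre", "post")

normalize_phase <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("pre", "pretest"), "pre",
                ifelse(x %in% c("post", "posttest"), "post", NA))
  if (anyNA(out))
    stop("unrecognized phase label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected pre/pretest or post/posttest)", call. = FALSE)
  factor(out, levels = phase_levels)
}

normalize_choice <- function(x) {
  x <- tolower(trimws(as.character(x)))
  bad <- unique(x[!x %in% ctf_levels])
  if (length(bad))
    stop("unrecognized CTF choice label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(ctf_levels, collapse = ", "), ")",
         call. = FALSE)
  factor(x, levels = ctf_levels)
}

# Attempt times: ISO-8601 strings or numeric attempt indices, compared after
# parsing (never lexically).
parse_attempt_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  t <- suppressWarnings(as.POSIXct(x, tz = "UTC",
                                   tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                  "%Y-%m-%d %H:%M:%S",
                                                  "%Y-%m-%d")))
  if (anyNA(t))
    stop("unparseable attempt_time value(s): ",
         paste(unique(x[is.na(t)]), collapse = ", "), call. = FALSE)
  as.numeric(t)
}

#' Assemble a table of CTF response records
#'
#' Validates and normalizes one response record per participant x phase x
#' attempt x item: phase labels are normalized case-insensitively from
#' pre/pretest and post/posttest, choices must be one of the four CTF levels
#' (`sure_true`, `unsure_true`, `unsure_false`, `sure_false`), and attempt
#' times may be ISO-8601 timestamps or numeric attempt indices.
#'
#' @param participant_id,phase,attempt_time,item_id,choice Record fields,
#'   recycled to a common length by `data.frame()` rules only if scalar.
#' @param bank Optional [item_bank]; if given, every `item_id` must resolve
#'   against it.
#' @return A data frame of class `ctf_responses` with columns
#'   `participant_id`, `phase` (factor), `attempt_time` (numeric),
#'   `item_id`, `choice` (factor).
#' @export
response_records <- function(participant_id, phase, attempt_time, item_id,
                             choice, bank = NULL) {
  rec <- data.frame(
    participant_id = as.character(participant_id),
    phase = normalize_phase(phase),
    attempt_time = parse_attempt_time(attempt_time),
    item_id = as.character(item_id),
    choice = normalize_choice(choice),
    stringsAsFactors = FALSE
  )
  if (!is.null(bank)) {
    unknown <- !rec$item_id %in% bank$item_id
    if (any(unknown))
      stop("response row(s) ", paste(which(unknown), collapse = ", "),
           ": unknown item_id ",
           paste(unique(rec$item_id[unknown]), collapse = ", "), call. = FALSE)
  }
  key <- with(rec, paste(participant_id, phase, attempt_time, item_id, sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate response record(s) for (participant, phase, attempt, item): ",
         paste(utils::head(gsub("\r", "/", key[duplicated(key)]), 5),
               collapse = "; "), call. = FALSE)
  class(rec) <- c("ctf_responses", "data.frame")
  rec
}

#' Read CTF responses from CSV
#'
#' Expects a UTF-8 CSV with header
#' `participant_id,phase,attempt_time,item_id,choice`.
#'
#' @param path Path to the CSV file.
#' @param bank An [item_bank]; all item ids must resolve against it.
#' @return A `ctf_responses` data frame (see [response_records()]).
#' @seealso [write_responses()]
#' @export
load_responses <- function(path, bank) {
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  needed <- c("participant_id", "phase", "attempt_time", "item_id", "choice")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("response CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  response_records(raw$participant_id, raw$phase, raw$attempt_time,
                   raw$item_id, raw$choice, bank = bank)
}

#' Write CTF responses to CSV
#'
#' @param records A `ctf_responses` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  out <- data.frame(
    participant_id = records$participant_id,
    phase = as.character(records$phase),
    attempt_time = records$attempt_time,
    item_id = records$item_id,
    choice = as.character(records$choice),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep only the chronologically first posttest attempt
#'
#' When an assessment allows retakes, later posttest attempts are biased
#' upward (participants retake until they pass); scores that come
#' chronologically first are therefore used as the posttest score. For each
#' participant, the posttest attempt with the earliest attempt time is
#' retained and all later attempts dropped; pretest records pass through
#' unchanged. Two distinct posttest attempts with identical attempt times
#' cannot be ordered chronologically and raise an error rather than being
#' silently broken.
#'
#' @param records A `ctf_responses` data frame (multiple posttest attempts
#'   per participant allowed).
#' @return A `ctf_responses` data frame with at most one posttest attempt
#'   per participant. Idempotent.
#' @export
select_first_posttest <- function(records) {
  post <- records$phase == "post"
  if (!any(post)) return(records)
  pid <- records$participant_id[post]
  tm <- records$attempt_time[post]
  keep_post <- tm == stats::ave(tm, pid, FUN = min)
  # tie: the earliest time shared by >1 distinct attempt of one participant
  # surfaces as a duplicated (participant, item) among the retained records
  dup <- duplicated(paste(pid, records$item_id[post], sep = "\r")[keep_post])
  if (any(dup)) {
    offender <- pid[keep_post][dup][1]
    stop("participant ", offender, ": two posttest attempts share the ",
         "earliest attempt_time; chronological first-attempt rule cannot ",
         "break the tie", call. = FALSE)
  }
  keep <- !post
  keep[which(post)[keep_post]] <- TRUE
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the paired complete-case cohort
#'
#' Restricts to participants with exactly one response to every bank item in
#' both phases; anyone lacking a phase or with partial item coverage is
#' excluded (complete-case analysis, no imputation). Run
#' [select_first_posttest()] first if retakes are possible.
#'
#' @param records A `ctf_responses` data frame, already deduplicated to one
#'   posttest attempt per participant.
#' @param bank The [item_bank] the responses answer.
#' @return A list of class `paired_cohort` with elements
#'   \describe{
#'     \item{participants}{character vector of retained participant ids (sorted)}
#'     \item{responses}{data frame `participant_id`, `phase`, `item_id`, `choice`}
#'     \item{n}{number of retained participants}
#'     \item{exclusions}{data frame `participant_id`, `reason` for every
#'       participant dropped}
#'   }
#' @export
build_paired_cohort <- function(records, bank) {
  validate_item_bank(bank)
  n_items <- nrow(bank)
  by_pid <- split(seq_len(nrow(records)), records$participant_id)
  ids <- names(by_pid)
  ok <- logical(length(ids))
  reason <- character(length(ids))
  for (i in seq_along(ids)) {
    sub <- records[by_pid[[i]], , drop = FALSE]
    res <- complete_phase_reason(sub, bank, n_items)
    ok[i] <- is.null(res)
    if (!ok[i]) reason[i] <- res
  }
  if (!any(ok))
    stop("no participant has complete responses in both phases", call. = FALSE)
  keep <- records$participant_id %in% ids[ok]
  resp <- records[keep, c("participant_id", "phase", "item_id", "choice")]
  resp <- resp[order(resp$participant_id, resp$phase, match(resp$item_id, bank$item_id)), ]
  rownames(resp) <- NULL
  structure(
    list(
      participants = ids[ok],
      responses = resp,
      n = sum(ok),
      exclusions = data.frame(participant_id = ids[!ok],
                              reason = reason[!ok],
                              stringsAsFactors = FALSE)
    ),
    class = "paired_cohort"
  )
}

complete_phase_reason <- function(sub, bank, n_items) {
  for (ph in phase_levels) {
    items <- sub$item_id[sub$phase == ph]
    if (length(items) == 0L) return(paste0("missing ", ph, "test"))
    if (anyDuplicated(items)) return(paste0("duplicate items in ", ph, "test"))
    if (!setequal(items, bank$item_id))
      return(paste0("incomplete item coverage in ", ph, "test"))
  }
  NULL
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> n = %d participants, %d items, %d excluded\n",
              x$n, length(unique(x$responses$item_id)), nrow(x$exclusions)))
  invisible(x)
}

# Choice matrix for one phase: participants x items, factor codes 1..4
# (sure_true, unsure_true, unsure_false, sure_false). Row/column order fixed
# by cohort$participants and bank$item_id.
choice_matrix <- function(cohort, bank, phase) {
  resp <- cohort$responses[cohort$responses$phase == phase, , drop = FALSE]
  m <- matrix(NA_integer_, nrow = cohort$n, ncol = nrow(bank),
              dimnames = list(cohort$participants, bank$item_id))
  m[cbind(match(resp$participant_id, cohort$participants),
          match(resp$item_id, bank$item_id))] <- as.integer(resp$choice)
  stopifnot(!anyNA(m))
  m
}
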