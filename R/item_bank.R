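#' Construct an item bank
#'
#' An item bank is the ordered set of true/false statements that make up a
#' confidence-weighted true-false (CTF) assessment, together with the answer
#' key and an optional concept-group tag per item (e.g. the group of items
#' probing one clinical risk tool).
#'
#' @param item_id Character vector of unique, non-empty item identifiers.
#' @param statement Character vector of item statements.
#' @param answer_key Logical vector; `TRUE` means the statement is true.
#' @param concept_group Optional character vector of concept-group tags;
#'   `NA` for untagged items.
#'
#' @return A data frame of class `item_bank` with columns `item_id`,
#'   `statement`, `answer_key`, `concept_group`, preserving input order.
#' @examples
#' bank <- item_bank(c("q1", "q2"), c("Stmt one.", "Stmt two."), c(TRUE, FALSE))
#' bank
#' @export
item_bank <- function(item_id, statement, answer_key, concept_group = NULL) {
  item_id <- as.character(item_id)
  statement <- as.character(statement)
  if (is.null(concept_group)) concept_group <- rep(NA_character_, length(item_id))
  bank <- data.frame(
    item_id = item_id,
    statement = statement,
    answer_key = as.logical(answer_key),
    concept_group = as.character(concept_group),
    stringsAsFactors = FALSE
  )
  class(bank) <- c("item_bank", "data.frame")
  validate_item_bank(bank)
}

validate_item_bank <- function(bank) {
  if (nrow(bank) == 0L)
    stop("item bank is empty: at least one item is required", call. = FALSE)
  if (anyNA(bank$item_id) || any(!nzchar(bank$item_id)))
    stop("item bank: item_id must be non-empty", call. = FALSE)
  dup <- unique(bank$item_id[duplicated(bank$item_id)])
  if (length(dup))
    stop("item bank: duplicate item_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (anyNA(bank$answer_key))
    stop("item bank: answer_key missing for item(s): ",
         paste(bank$item_id[is.na(bank$answer_key)], collapse = ", "),
         call. = FALSE)
  bank
}

#' Read an item bank from JSON
#'
#' Expected layout:
#' \preformatted{{"items":[{"id":"q1","statement":"...","answer":"F","group":"riosord"}, ...]}}
#' with `answer` one of `"T"`/`"F"` (also accepted: `true`/`false` booleans).
#' The `group` field is optional.
#'
#' @param path Path to a JSON file.
#' @return An [item_bank] preserving the file's item order.
#' @seealso [write_item_bank()]
#' @export
load_item_bank <- function(path) {
  if (!file.exists(path)) stop("item bank file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw$items) || NROW(raw$items) == 0L)
    stop("item bank is empty: no 'items' entries in ", path, call. = FALSE)
  items <- raw$items
  if (is.null(items$id) || is.null(items$statement) || is.null(items$answer))
    stop("item bank: each item needs 'id', 'statement' and 'answer'", call. = FALSE)
  key <- parse_answer_key(items$answer)
  group <- if (is.null(items$group)) NULL else as.character(items$group)
  item_bank(items$id, items$statement, key, group)
}

parse_answer_key <- function(x) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- ifelse(x %in% c("T", "TRUE"), TRUE,
                ifelse(x %in% c("F", "FALSE"), FALSE, NA))
  if (anyNA(out))
    stop("item bank: answer must be \"T\"/\"F\", got: ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Write an item bank to JSON
#'
#' Inverse of [load_item_bank()]; answers are serialized as `"T"`/`"F"`.
#'
#' @param bank An [item_bank].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  items <- data.frame(
    id = bank$item_id,
    statement = bank$statement,
    answer = ifelse(bank$answer_key, "T", "F"),
    stringsAsFactors = FALSE
  )
  if (!all(is.na(bank$concept_group))) items$group <- bank$concept_group
  jsonlite::write_json(list(items = items), path, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.item_bank <- function(x, ...) {
  nf <- sum(!x$answer_key)
  cat(sprintf("<item_bank> %d items (%d keyed false, %d keyed true)\n",
              nrow(x), nf, nrow(x) - nf))
  groups <- unique(stats::na.omit(x$concept_group))
  if (length(groups))
    cat("  concept groups: ", paste(groups, collapse = ", "), "\n", sep = "")
  invisible(x)
}
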