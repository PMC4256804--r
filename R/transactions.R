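#' Encode a raw categorical survey table as class-labelled transactions
#'
#' Each option of each question is a distinct item, so a participant's row
#' becomes a set of disjoint coded items: each answered question contributes
#' exactly the one item for the chosen option, and unanswered (`NA`)
#' questions contribute nothing. Rows whose adherence outcome is missing are
#' excluded before construction and counted in the `n_dropped` attribute.
#'
#' @param survey A data frame with one row per participant. Question columns
#'   are named `Q<question_id>` (e.g. `Q130`) and hold option labels from the
#'   codebook; a `participant_id` column is used if present, otherwise row
#'   numbers are assigned. The outcome column holds the class labels
#'   `"adherent"` / `"non_adherent"` (or a factor with those levels); derive
#'   it with [classify_adherence()] when only raw screening history exists.
#' @param codebook A [build_codebook()] codebook covering every answered
#'   (question, label) pair; a response label absent from the codebook is an
#'   error that names the offending row and column.
#' @param outcome Name of the outcome column. Default `"adherence"`.
#' @return A tibble of class `crcs_transactions` with columns
#'   `participant_id`, `class` (factor, levels `adherent`/`non_adherent`) and
#'   `items` (list-column of sorted integer item codes), plus attributes
#'   `n1` (adherent count), `n2` (non-adherent count) and `n_dropped`.
#' @export
encode_responses <- function(survey, codebook, outcome = "adherence") {
  stopifnot(is.data.frame(survey))
  if (!outcome %in% names(survey)) {
    abort(paste0("outcome column `", outcome, "` not found in `survey`"))
  }
  cls <- as.character(survey[[outcome]])
  bad <- !is.na(cls) & !cls %in% CLASS_LEVELS
  if (any(bad)) {
    abort(paste0(
      "outcome values outside {", paste(CLASS_LEVELS, collapse = ", "), "}: ",
      paste(unique(cls[bad]), collapse = ", ")
    ))
  }
  keep <- !is.na(cls)
  n_dropped <- sum(!keep)

  ids <- if ("participant_id" %in% names(survey)) {
    survey$participant_id
  } else {
    seq_len(nrow(survey))
  }

  qcols <- grep("^Q[0-9]+$", names(survey), value = TRUE)
  if (length(qcols) == 0) {
    abort("no question columns (named Q<question_id>) found in `survey`")
  }
  qids <- as.integer(sub("^Q", "", qcols))
  unknown_q <- setdiff(qids, unique(codebook$question_id))
  if (length(unknown_q) > 0) {
    abort(paste0("question column(s) not in codebook: Q",
                 paste(unknown_q, collapse = ", Q")))
  }

  survey <- survey[keep, , drop = FALSE]
  ids <- ids[keep]
  cls <- cls[keep]
  n <- nrow(survey)

  # per-question lookup label -> code, then column-wise vectorised encode
  item_lists <- vector("list", n)
  code_mat <- matrix(NA_integer_, nrow = n, ncol = length(qcols))
  for (j in seq_along(qcols)) {
    qid <- qids[j]
    cb_q <- codebook[codebook$question_id == qid, ]
    resp <- as.character(survey[[qcols[j]]])
    idx <- match(resp, cb_q$option_label)
    bad_resp <- !is.na(resp) & is.na(idx)
    if (any(bad_resp)) {
      r <- which(bad_resp)[1]
      abort(paste0(
        "response not in codebook: row ", r, ", column ", qcols[j],
        ', label "', resp[r], '"'
      ))
    }
    code_mat[, j] <- cb_q$item_code[idx]
  }
  for (i in seq_len(n)) {
    codes <- code_mat[i, ]
    item_lists[[i]] <- sort(codes[!is.na(codes)])
  }

  out <- tibble::tibble(
    participant_id = ids,
    class = factor(cls, levels = CLASS_LEVELS),
    items = item_lists
  )
  new_transactions(out, n_dropped = n_dropped)
}

new_transactions <- function(tbl, n_dropped = 0L) {
  attr(tbl, "n1") <- sum(tbl$class == "adherent")
  attr(tbl, "n2") <- sum(tbl$class == "non_adherent")
  attr(tbl, "n_dropped") <- n_dropped
  class(tbl) <- c("crcs_transactions", setdiff(class(tbl), "crcs_transactions"))
  tbl
}

#' Build a transaction set directly from item-code lists
#'
#' Mainly for tests and small worked examples; [encode_responses()] is the
#' route for real survey tables. Records must be question-disjoint (no two
#' items decoding to the same question).
#'
#' @param items A list of integer item-code vectors, one per record.
#' @param class Character or factor vector of class labels, recycled if
#'   length 1.
#' @param participant_id Optional ids; defaults to `1:n`.
#' @return A `crcs_transactions` tibble.
#' @export
as_transactions <- function(items, class, participant_id = NULL) {
  stopifnot(is.list(items))
  n <- length(items)
  if (length(class) == 1) class <- rep(class, n)
  stopifnot(length(class) == n)
  items <- lapply(items, function(x) sort(as.integer(x)))
  for (i in seq_len(n)) {
    if (anyDuplicated(item_question(items[[i]]))) {
      abort(paste0("record ", i, " has two items from the same question"))
    }
  }
  out <- tibble::tibble(
    participant_id = participant_id %||% seq_len(n),
    class = factor(as.character(class), levels = CLASS_LEVELS),
    items = items
  )
  if (anyNA(out$class)) abort("unknown class label")
  new_transactions(out)
}

#' Transaction class sizes
#'
#' @param transactions A `crcs_transactions` object.
#' @return A named integer vector with the number of adherent (`n1`) and
#'   non-adherent (`n2`) records.
#' @export
class_sizes <- function(transactions) {
  c(n1 = sum(transactions$class == "adherent"),
    n2 = sum(transactions$class == "non_adherent"))
}

class_records <- function(transactions, class_label) {
  check_class_label(class_label)
  recs <- transactions$items[transactions$class == class_label]
  if (length(recs) == 0) {
    abort(paste0("class `", class_label, "` has no records; support is undefined"))
  }
  recs
}

#' Write transactions as JSON lines
#'
#' One JSON object per record: `participant_id`, `class`, and the sorted
#' item codes.
#'
#' @param transactions A `crcs_transactions` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(transactions, path) {
  lines <- vapply(seq_len(nrow(transactions)), function(i) {
    jsonlite::toJSON(
      list(
        participant_id = transactions$participant_id[[i]],
        class = as.character(transactions$class[[i]]),
        items = transactions$items[[i]]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
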