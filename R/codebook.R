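#' Build a survey codebook mapping question options to item codes
#'
#' Every (question, option) pair in a categorical survey becomes a distinct
#' transaction item with an integer code `question_id * 1000 + option_index`
#' (option indices start at 1), so e.g. option 1 of question 130 is item
#' `130001` and option 2 of question 68 is `68002`. Codes are globally unique
#' and decode uniquely back to their question and option.
#'
#' @param questions A data frame with one row per question and columns
#'   `question_id` (positive integer, unique), `question_text` (character),
#'   and `options` (a list-column of character vectors of option labels, in
#'   option-index order). "Refused" / "Don't know" responses are ordinary
#'   options with their own codes; only blank (`NA`) responses carry no item.
#' @return A tibble of class `crcs_codebook` with one row per item:
#'   `question_id`, `question_text`, `option_index`, `option_label`,
#'   `item_code`.
#' @export
#' @examples
#' qs <- tibble::tibble(
#'   question_id = c(130L, 68L),
#'   question_text = c("Usual place of care?", "Family history of CRC?"),
#'   options = list(c("Yes", "No"), c("Yes", "No", "Don't know"))
#' )
#' build_codebook(qs)
build_codebook <- function(questions) {
  stopifnot(is.data.frame(questions))
  required <- c("question_id", "question_text", "options")
  missing_cols <- setdiff(required, names(questions))
  if (length(missing_cols) > 0) {
    abort(paste0("`questions` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  qid <- questions$question_id
  if (any(is.na(qid)) || any(qid != as.integer(qid)) || any(qid < 1)) {
    abort("`question_id` must be positive integers")
  }
  if (anyDuplicated(qid)) {
    abort(paste0(
      "duplicate question_id(s): ",
      paste(unique(qid[duplicated(qid)]), collapse = ", ")
    ))
  }
  n_opts <- lengths(questions$options)
  if (any(n_opts < 1)) {
    abort("every question needs at least one option")
  }
  if (any(n_opts > 999)) {
    abort(paste0(
      "question(s) ", paste(qid[n_opts > 999], collapse = ", "),
      " exceed the 999-option code space"
    ))
  }
  cb <- tibble::tibble(
    question_id = rep(as.integer(qid), n_opts),
    question_text = rep(as.character(questions$question_text), n_opts),
    option_index = unlist(lapply(n_opts, seq_len)),
    option_label = as.character(unlist(questions$options))
  )
  cb$item_code <- item_code(cb$question_id, cb$option_index)
  class(cb) <- c("crcs_codebook", class(cb))
  cb
}

#' Item-code arithmetic
#'
#' `item_code()` maps a (question, option) pair to its integer item code;
#' `item_question()` and `item_option()` invert it.
#'
#' @param question_id Positive integer question id(s).
#' @param option_index Option index(es), starting at 1.
#' @param code Integer item code(s).
#' @return Integer vector.
#' @export
#' @examples
#' item_code(130, 1)      # 130001
#' item_question(68002)   # 68
#' item_option(68002)     # 2
item_code <- function(question_id, option_index) {
  as.integer(question_id) * 1000L + as.integer(option_index)
}

#' @rdname item_code
#' @export
item_question <- function(code) as.integer(code) %/% 1000L

#' @rdname item_code
#' @export
item_option <- function(code) as.integer(code) %% 1000L

#' Decode item codes against a codebook
#'
#' @param codes Integer vector of item codes.
#' @param codebook A `crcs_codebook`.
#' @return A tibble with one row per code: `item_code`, `question_id`,
#'   `option_index`, `question_text`, `option_label`.
#' @export
decode_items <- function(codes, codebook) {
  idx <- match(as.integer(codes), codebook$item_code)
  if (anyNA(idx)) {
    abort(paste0(
      "item code(s) not in codebook: ",
      paste(codes[is.na(idx)], collapse = ", ")
    ))
  }
  codebook[idx, c("item_code", "question_id", "option_index",
                  "question_text", "option_label")]
}

#' Label an itemset using the codebook
#'
#' Formats a set of item codes the way mining reports print them:
#' `"130001: Usual place of care? [Yes]"`.
#'
#' @inheritParams decode_items
#' @param sep Separator between items.
#' @return A single string.
#' @export
format_itemset <- function(codes, codebook, sep = "; ") {
  d <- decode_items(codes, codebook)
  paste0(d$item_code, ": ", d$question_text, " [", d$option_label, "]",
         collapse = sep)
}

#' Read or write a codebook as CSV
#'
#' The on-disk form has one row per item: `question_id`, `question_text`,
#' `option_index`, `option_label`.
#'
#' @param path File path.
#' @param codebook A `crcs_codebook`.
#' @return `read_codebook()` returns a `crcs_codebook`;
#'   `write_codebook()` returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  qs <- raw |>
    dplyr::group_by(.data$question_id) |>
    dplyr::arrange(.data$option_index, .by_group = TRUE) |>
    dplyr::summarise(
      question_text = dplyr::first(.data$question_text),
      options = list(as.character(.data$option_label)),
      .groups = "drop"
    )
  build_codebook(qs)
}

#' @rdname read_codebook
#' @export
write_codebook <- function(codebook, path) {
  readr::write_csv(
    codebook[, c("question_id", "question_text", "option_index", "option_label")],
    path
  )
  invisible(path)
}
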