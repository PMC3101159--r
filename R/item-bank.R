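#' Item bank
#'
#' A calibrated item bank: a table of items (id, label, difficulty in logits,
#' standard error, infit/outfit mean-squares, calibration status) together
#' with one shared [rating_scale()]. Items flagged `misfit` are retained in
#' the table for record-keeping but excluded from every operation that needs
#' a calibrated difficulty (adaptive selection, simulation, estimation).
#'
#' @param items data.frame with columns `item_id`, `label`, `difficulty`,
#'   `se`, `infit`, `outfit`, `status` (`"calibrated"` or `"misfit"`).
#'   Numeric columns may be `NA` on misfit rows.
#' @param scale a [rating_scale()] shared by all items.
#' @return object of class `item_bank`.
#' @seealso [jcq37_bank()] for the packaged example bank.
#' @export
item_bank <- function(items, scale) {
  scale <- as_rating_scale(scale)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  needed <- c("item_id", "label", "difficulty", "se", "infit", "outfit", "status")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols))
    stop("item table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  items <- items[needed]
  items$item_id <- as.integer(items$item_id)
  for (col in c("difficulty", "se", "infit", "outfit"))
    items[[col]] <- as.numeric(items[[col]])
  if (anyDuplicated(items$item_id))
    stop("duplicate item_id in bank", call. = FALSE)
  if (any(items$item_id <= 0L)) stop("item_id must be positive", call. = FALSE)
  if (!all(items$status %in% c("calibrated", "misfit")))
    stop("status must be 'calibrated' or 'misfit'", call. = FALSE)
  cal <- items$status == "calibrated"
  if (!any(cal)) stop("bank needs at least one calibrated item", call. = FALSE)
  if (any(!is.finite(items$difficulty[cal])))
    stop("calibrated items must have finite difficulty", call. = FALSE)
  structure(list(items = items, scale = scale), class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cal <- calibrated_items(x)
  cat(sprintf("Item bank: %d items (%d calibrated, %d misfit), %d categories\n",
              nrow(x$items), nrow(cal), sum(x$items$status == "misfit"),
              x$scale$n_categories))
  cat(sprintf("Calibrated difficulty range: %.2f to %.2f logits\n",
              min(cal$difficulty), max(cal$difficulty)))
  print(x$scale)
  invisible(x)
}

#' Calibrated subset of an item bank
#'
#' @param bank an [item_bank()].
#' @return data.frame of the calibrated rows only.
#' @export
calibrated_items <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  bank$items[bank$items$status == "calibrated", , drop = FALSE]
}

#' Number of response categories of a bank's rating scale
#'
#' @param bank an [item_bank()] (or a [rating_scale()]).
#' @return integer M + 1.
#' @export
n_categories <- function(bank) {
  if (inherits(bank, "rating_scale")) return(bank$n_categories)
  stopifnot(inherits(bank, "item_bank"))
  bank$scale$n_categories
}

#' The packaged job-satisfaction item bank
#'
#' A 37-item hospital job-satisfaction questionnaire (four-point agreement
#' scale) calibrated under the rating-scale Rasch model: 24 items retained
#' with difficulties from -1.03 to 2.73 logits, 13 flagged misfit, and step
#' calibrations (-4.16, -1.50, 2.66). Used throughout the package as the
#' worked example and as the generating bank for simulations.
#'
#' @return an [item_bank()].
#' @examples
#' bank <- jcq37_bank()
#' nrow(calibrated_items(bank))
#' @export
jcq37_bank <- function() {
  path <- system.file("extdata", "table2_bank.csv", package = "raschcat",
                      mustWork = TRUE)
  read_item_bank(path)
}
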