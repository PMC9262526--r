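#' Generate a synthetic graded-response item bank
#'
#' Builds a bank of polytomous items for the multidimensional graded response
#' model. Each item loads on exactly one syndrome element (between-item
#' multidimensionality); items are allocated to elements round-robin so the
#' default 215-item bank has 35 or 36 items per element. Discriminations are
#' log-normal and category thresholds are sorted normal draws centred on a
#' small element-specific offset so elements differ slightly in difficulty.
#'
#' @param n_items total number of items (default 215).
#' @param elements character vector of element names (default
#'   [syndrome_elements()]).
#' @param n_categories number of ordered response categories K (default 5,
#'   giving K - 1 thresholds per item).
#' @param a_meanlog,a_sdlog log-normal parameters of the discriminations.
#' @param b_sd standard deviation of the threshold draws.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `grm_item_bank`: a list with `items` (a
#'   data.frame with columns `item_id`, `element`, `a`, `b1`..`b{K-1}`) and
#'   `elements`.
#' @export
generate_item_bank <- function(n_items = 215, elements = syndrome_elements(),
                               n_categories = 5, a_meanlog = 0.2,
                               a_sdlog = 0.3, b_sd = 1, seed = NULL) {
  n_el <- length(elements)
  if (n_items < n_el) stop_("n_items must be at least the number of elements")
  if (n_categories < 2) stop_("need at least 2 response categories")
  if (!is.null(seed)) set.seed(seed)
  el_idx <- rep_len(seq_len(n_el), n_items)
  a <- stats::rlnorm(n_items, a_meanlog, a_sdlog)
  offs <- seq(-0.5, 0.5, length.out = n_el)[el_idx]
  b <- t(vapply(seq_len(n_items),
                function(i) sort(stats::rnorm(n_categories - 1, offs[i], b_sd)),
                numeric(n_categories - 1)))
  colnames(b) <- paste0("b", seq_len(n_categories - 1))
  items <- data.frame(item_id = seq_len(n_items),
                      element = elements[el_idx],
                      a = a, b, stringsAsFactors = FALSE)
  new_item_bank(items, elements)
}

new_item_bank <- function(items, elements) {
  bank <- structure(list(items = items, elements = elements),
                    class = "grm_item_bank")
  validate_item_bank(bank)
  bank
}

validate_item_bank <- function(bank) {
  items <- bank$items
  bcols <- grep("^b[0-9]+$", names(items), value = TRUE)
  if (length(bcols) < 1) stop_("item bank needs at least one threshold column")
  if (anyDuplicated(items$item_id)) stop_("item_ids must be unique")
  if (any(items$a <= 0)) stop_("discriminations must be positive")
  if (!all(items$element %in% bank$elements))
    stop_("unknown element name in item bank")
  b <- as.matrix(items[bcols])
  for (i in seq_len(nrow(b))) {
    bi <- b[i, !is.na(b[i, ])]
    if (length(bi) < 1 || any(diff(bi) <= 0))
      stop_("thresholds must be strictly increasing (item ",
            items$item_id[i], ")")
  }
  invisible(bank)
}

# Internal numeric view of a bank: discriminations, threshold matrix with
# trailing NA thresholds replaced by +Inf (collapsing unused categories to
# probability zero), and integer element indices.
bank_matrices <- function(bank, rows = NULL) {
  items <- bank$items
  if (!is.null(rows)) items <- items[rows, , drop = FALSE]
  bcols <- grep("^b[0-9]+$", names(items), value = TRUE)
  b <- as.matrix(items[bcols])
  b[is.na(b)] <- Inf
  list(a = items$a, b = b,
       el = match(items$element, bank$elements),
       item_id = items$item_id)
}

#' @export
print.grm_item_bank <- function(x, ...) {
  tab <- table(factor(x$items$element, levels = x$elements))
  cat("Graded-response item bank:", nrow(x$items), "items,",
      length(x$elements), "elements\n")
  cat("Items per element:\n")
  print(tab)
  invisible(x)
}

#' Read / write an item bank as CSV
#'
#' The CSV has columns `item_id, element, a, b1..b{K-1}`; the number of
#' categories is inferred from the non-empty threshold columns.
#'
#' @param bank a `grm_item_bank`.
#' @param path file path.
#' @param elements element universe used to validate the file (default
#'   [syndrome_elements()]).
#' @return `read_item_bank` returns a `grm_item_bank`; `write_item_bank`
#'   returns `path` invisibly.
#' @export
write_item_bank <- function(bank, path) {
  items <- bank$items
  num <- vapply(items, is.numeric, logical(1))
  items[num] <- lapply(items[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.csv(items, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path, elements = syndrome_elements()) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "element", "a")
  if (!all(need %in% names(items)))
    stop_("item bank CSV must have columns item_id, element, a, b1..")
  new_item_bank(items, elements)
}
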