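#' Externalizing subscale definitions
#'
#' The four disruptive-behavior subscales scored by the package: conduct (8
#' items), inattention (9), hyperactivity (9) and oppositional (8), each item
#' rated 1-4.
#'
#' @param names subset of subscales to return (default all four).
#' @return named list of `subscale_def` objects with fields `name`,
#'   `item_columns`, `n_items`, `item_range`.
#' @export
subscale_defs <- function(names = c("conduct", "inattention", "hyperactivity",
                                    "oppositional")) {
  n_items <- c(conduct = 8L, inattention = 9L, hyperactivity = 9L,
               oppositional = 8L)
  names <- match.arg(names, several.ok = TRUE)
  out <- lapply(names, function(nm) {
    structure(list(name = nm,
                   item_columns = sprintf("%s_item%d", nm, seq_len(n_items[[nm]])),
                   n_items = n_items[[nm]], item_range = c(1L, 4L)),
              class = "subscale_def")
  })
  names(out) <- names
  out
}

#' Score subscales from item-level ratings
#'
#' Sums the items of each subscale with the 50%-missing rule: an individual
#' with 50% or more of a subscale's items missing gets a missing score for
#' that subscale; otherwise each missing item is imputed by that item's mean
#' over individuals with an observed value (the respondent-sample mean), and
#' the items are summed. Complete responders' scores are plain row sums.
#'
#' @param items data.frame holding the item columns (values in 1..4 or `NA`)
#'   and any id/covariate columns, which are carried through.
#' @param defs list of subscale definitions from [subscale_defs()].
#' @return a `data.frame` with the carried-through non-item columns, one score
#'   column per subscale, and per-subscale completeness flags
#'   `<name>_complete`; per-subscale missing-score proportions are attached as
#'   attribute `"missing_prop"`.
#' @export
score_subscales <- function(items, defs = subscale_defs()) {
  out <- items[, setdiff(names(items), unlist(lapply(defs, `[[`, "item_columns"))),
               drop = FALSE]
  missing_prop <- numeric(0)
  for (def in defs) {
    missing_cols <- setdiff(def$item_columns, names(items))
    if (length(missing_cols) > 0)
      tv_stop(sprintf("missing item columns: %s", paste(missing_cols, collapse = ", ")),
              "triovc_input_error")
    x <- as.matrix(items[, def$item_columns, drop = FALSE])
    bad <- which(!is.na(x) & (x < def$item_range[1] | x > def$item_range[2] |
                              x != round(x)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      tv_stop(sprintf("item value out of range at row %d, column %s",
                      bad[1, 1], def$item_columns[bad[1, 2]]),
              "triovc_input_error")
    n_miss <- rowSums(is.na(x))
    scored <- n_miss < def$n_items / 2      # strictly less than 50% missing
    item_means <- colMeans(x, na.rm = TRUE)
    xi <- x
    for (j in seq_len(ncol(xi))) xi[is.na(xi[, j]), j] <- item_means[j]
    score <- rowSums(xi)
    score[!scored] <- NA_real_
    out[[def$name]] <- score
    out[[paste0(def$name, "_complete")]] <- n_miss == 0
    missing_prop[def$name] <- mean(!scored)
  }
  attr(out, "missing_prop") <- missing_prop
  out
}
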