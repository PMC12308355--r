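#' First-order probability indices
#'
#' The first-order index of a symptom label is the historical fraction of
#' comprehensive-scale respondents diagnosed positive for it:
#' `P(i) = N(i) / NC`. Labels never diagnosed positive get index 0.
#'
#' @param history a `historical_dataset`.
#' @param labels symptom-label set; defaults to the labels appearing in the
#'   diagnosis annotations (first-appearance order).
#' @return object of class `first_order_indices`: list with `index`
#'   (named numeric in `[0,1]`) and provenance `counts` (`N_label`, `NC`).
#' @export
first_order_indices <- function(history, labels = NULL) {
  counts <- count_positives(history)
  if (counts$NC == 0L)
    stop("no comprehensive-scale history (NC = 0)", call. = FALSE)
  if (is.null(labels)) labels <- unique(history$comp_diagnoses$label)
  labels <- as.character(labels)
  N <- stats::setNames(integer(length(labels)), labels)
  hit <- intersect(labels, names(counts$N_label))
  N[hit] <- counts$N_label[hit]
  structure(list(index = N / counts$NC,
                 counts = list(N_label = N, NC = counts$NC)),
            class = "first_order_indices")
}

#' Second-order probability indices
#'
#' The second-order index of a single-assessment item is the fraction of
#' that scale's historical respondents who answered it positively:
#' `P(i,j) = N(i,j) / NS`, with `NS` counted per single-assessment scale
#' (its own respondent pool).
#'
#' @param history a `historical_dataset` whose `single_responses` carry a
#'   `label` column.
#' @param label one symptom label, or `NULL` for every single scale present.
#' @param strict error (`TRUE`, default) or zero indices (`FALSE`) when a
#'   requested scale has no historical respondents.
#' @param items optional item-id universe per label (named list); items
#'   never answered get index 0.
#' @return object of class `second_order_indices`: per label a list with
#'   `index` (named numeric, in the scale's item order) and `counts`
#'   (`N_item`, `NS`).
#' @export
second_order_indices <- function(history, label = NULL, strict = TRUE,
                                 items = NULL) {
  s <- history$single_responses
  labs <- if (is.null(label)) {
    union(unique(s$label), names(items))
  } else as.character(label)
  out <- lapply(labs, function(l) {
    rows <- s[s$label == l, , drop = FALSE]
    NS <- length(unique(rows$respondent_id))
    ids <- if (!is.null(items) && l %in% names(items)) items[[l]] else unique(rows$item_id)
    if (NS == 0L) {
      if (strict)
        stop("no historical respondents for single-assessment scale '", l, "'",
             call. = FALSE)
      return(list(index = stats::setNames(rep(0, length(ids)), ids),
                  counts = list(N_item = stats::setNames(rep(0L, length(ids)), ids),
                                NS = 0L)))
    }
    pos <- rows[rows$response >= 2L, ]
    pos <- pos[!duplicated(paste(pos$respondent_id, pos$item_id, sep = "\r")), ]
    tab <- table(factor(pos$item_id, levels = ids))
    N_item <- stats::setNames(as.integer(tab), ids)
    list(index = N_item / NS, counts = list(N_item = N_item, NS = NS))
  })
  names(out) <- labs
  structure(out, class = "second_order_indices")
}

stable_desc_order <- function(x) order(-x, seq_along(x))

#' Order symptom labels by first-order index
#'
#' Labels are arranged in non-increasing index order; ties are broken by
#' original position (stable), so output is deterministic.
#'
#' @param P a `first_order_indices` object, or a named numeric vector.
#' @return character vector: the label permutation.
#' @export
order_labels <- function(P) {
  idx <- if (inherits(P, "first_order_indices")) P$index else P
  if (is.null(names(idx))) stop("indices must be named by label", call. = FALSE)
  names(idx)[stable_desc_order(idx)]
}

#' Order single-assessment items by second-order index
#'
#' @param Pi one scale's entry of a `second_order_indices` object, or a
#'   named numeric vector of per-item indices.
#' @return character vector: the item permutation (non-increasing index,
#'   stable ties).
#' @export
order_items <- function(Pi) {
  idx <- if (is.list(Pi)) Pi$index else Pi
  if (is.null(names(idx))) stop("indices must be named by item", call. = FALSE)
  names(idx)[stable_desc_order(idx)]
}

#' Optimize a scale system from historical data
#'
#' Computes first- and second-order probability indices from history and
#' reorders the system: comprehensive symptom blocks in descending
#' first-order index order, items within each single-assessment scale in
#' descending second-order index order. Items *within* a comprehensive
#' block are deliberately left in input order (blocks are small; sorting
#' them is unnecessary). No item is added, dropped or relabelled.
#'
#' @param system a `scale_system`.
#' @param history a `historical_dataset`.
#' @return object of class `optimized_scale_system`: the original system
#'   plus `label_order`, `input_label_order`, `comp_blocks` (in optimized
#'   label order), `single_orders` / `single_input_orders`, and the two
#'   index sets.
#' @export
optimize_scales <- function(system, history) {
  stopifnot(inherits(system, "scale_system"))
  blocks <- comp_blocks(system)
  input_label_order <- names(blocks)
  P1 <- first_order_indices(history, labels = input_label_order)
  label_order <- order_labels(P1)
  sing_universe <- lapply(input_label_order, function(l) single_items(system, l))
  names(sing_universe) <- input_label_order
  sing_universe <- sing_universe[vapply(sing_universe, length, 1L) > 0L]
  P2 <- second_order_indices(history, label = names(sing_universe),
                             strict = FALSE, items = sing_universe)
  single_orders <- lapply(P2, order_items)
  structure(list(system = system,
                 label_order = label_order,
                 input_label_order = input_label_order,
                 comp_blocks = blocks[label_order],
                 single_orders = single_orders,
                 single_input_orders = sing_universe,
                 first_order = P1,
                 second_order = P2),
            class = "optimized_scale_system")
}

#' @export
print.optimized_scale_system <- function(x, ...) {
  cat("<optimized_scale_system>", length(x$label_order), "symptom blocks\n")
  p <- x$first_order$index[x$label_order]
  cat(paste0("  ", format(x$label_order), "  P(i) = ", sprintf("%.3f", p)),
      sep = "\n")
  invisible(x)
}
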