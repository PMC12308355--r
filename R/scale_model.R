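#' Option values and item positivity
#'
#' Responses are recorded on the five-point ordinal scale 0--4
#' (none, mild, moderate, severe, extreme). An item response counts as
#' *positive* when the selected option is at least `min_value`; the
#' conventional criterion is "moderate or worse", i.e. `min_value = 2`.
#' Severity-restricted screening conditions are expressed by moving
#' `min_value` over 1 (mild), 2 (moderate), 3 (severe) and 4 (extreme).
#'
#' @param value integer vector of option values.
#' @param min_value minimum option value counted as positive (default 2).
#' @return `is_positive()` returns a logical vector.
#' @examples
#' is_positive(0:4)            # FALSE FALSE TRUE TRUE TRUE
#' is_positive(0:4, min_value = 3)
#' @export
is_positive <- function(value, min_value = 2L) {
  check_option_values(value)
  if (!min_value %in% 1:4) stop("`min_value` must be in 1..4", call. = FALSE)
  value >= min_value
}

#' @rdname is_positive
#' @export
option_values <- function() 0:4

#' @rdname is_positive
#' @export
option_labels <- function() c("none", "mild", "moderate", "severe", "extreme")

check_option_values <- function(value) {
  if (length(value) && (anyNA(value) || !all(value %in% 0:4)))
    stop("option values must lie in {0,1,2,3,4}", call. = FALSE)
  invisible(value)
}

#' Construct a scale system
#'
#' A scale system holds the comprehensive scale -- items partitioned into
#' symptom-label blocks -- together with the per-symptom single-assessment
#' scales used for second-tier confirmation.
#'
#' @param items data.frame with columns `item_id` (unique), `label`
#'   (symptom label), `text` (item wording), `home`
#'   (`"comprehensive"` or `"single"`), and `scale_id` (the owning scale).
#' @param labels character vector giving the symptom-label set and its
#'   pre-optimization order; defaults to first appearance order in `items`.
#' @return an object of class `scale_system`.
#' @export
scale_system <- function(items, labels = NULL) {
  if (nrow(items) == 0L) {
    items <- data.frame(item_id = character(), label = character(),
                        text = character(), home = character(),
                        scale_id = character(), stringsAsFactors = FALSE)
  }
  need <- c("item_id", "label", "text", "home", "scale_id")
  miss <- setdiff(need, names(items))
  if (length(miss))
    stop("items is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  items <- items[, need]
  items[] <- lapply(items, as.character)
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup))
    stop("duplicate item_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!all(items$home %in% c("comprehensive", "single")))
    stop("`home` must be 'comprehensive' or 'single'", call. = FALSE)
  if (is.null(labels)) labels <- unique(items$label)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate symptom labels", call. = FALSE)
  bad <- setdiff(unique(items$label), labels)
  if (length(bad))
    stop("items reference unknown labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  # a single-assessment scale measures exactly one symptom
  sing <- items[items$home == "single", ]
  if (nrow(sing)) {
    per <- tapply(sing$label, sing$scale_id, function(x) length(unique(x)))
    if (any(per > 1L))
      stop("single-assessment scale with items under more than one label: ",
           paste(names(per)[per > 1L], collapse = ", "), call. = FALSE)
    lab_scales <- tapply(sing$scale_id, sing$label, function(x) length(unique(x)))
    if (any(lab_scales > 1L))
      stop("label served by more than one single-assessment scale: ",
           paste(names(lab_scales)[lab_scales > 1L], collapse = ", "),
           call. = FALSE)
  }
  structure(list(labels = labels, items = items), class = "scale_system")
}

#' @export
print.scale_system <- function(x, ...) {
  nc <- sum(x$items$home == "comprehensive")
  ns <- sum(x$items$home == "single")
  cat("<scale_system> ", length(x$labels), " symptom labels, ",
      nc, " comprehensive items, ", ns, " single-assessment items\n", sep = "")
  invisible(x)
}

#' Comprehensive blocks and single scales of a system
#'
#' `comp_blocks()` returns the comprehensive items partitioned by symptom
#' label (input order within block -- blocks are never item-sorted);
#' `single_items()` returns the single-assessment item ids for one label,
#' or `character(0)` when the label has no confirmation scale.
#'
#' @param system a `scale_system`.
#' @param label a symptom label.
#' @return `comp_blocks()`: named list label -> character vector of item ids.
#' @export
comp_blocks <- function(system) {
  comp <- system$items[system$items$home == "comprehensive", ]
  out <- lapply(system$labels, function(l) comp$item_id[comp$label == l])
  names(out) <- system$labels
  out[vapply(out, length, 1L) > 0L]
}

#' @rdname comp_blocks
#' @export
single_items <- function(system, label) {
  sing <- system$items[system$items$home == "single", ]
  sing$item_id[sing$label == label]
}

#' Partition an unlabeled item collection into a scale system
#'
#' Applies a supplied classification map `f: item -> symptom label` to an
#' item collection, producing the labelled comprehensive blocks and single
#' scales. The classification is given, not learned.
#'
#' @param items data.frame with columns `item_id`, `text`, `home`,
#'   `scale_id` (no `label` needed; one present is ignored).
#' @param labeling named character vector, `item_id -> label`.
#' @param labels optional symptom-label set (order = pre-optimization order).
#' @return a `scale_system`.
#' @export
assign_labels <- function(items, labeling, labels = NULL) {
  if (nrow(items) == 0L) return(scale_system(items = data.frame(), labels = labels))
  unlabeled <- setdiff(items$item_id, names(labeling))
  if (length(unlabeled))
    stop("no label assigned for item(s): ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  items$label <- unname(labeling[items$item_id])
  if (!is.null(labels)) {
    bad <- setdiff(unique(items$label), labels)
    if (length(bad))
      stop("item(s) labeled with unknown label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  scale_system(items, labels = labels)
}

#' Construct a historical response dataset
#'
#' Historical data carry, for the comprehensive scale and for the
#' single-assessment scales separately, per-respondent item responses plus
#' per-symptom positive/negative diagnosis annotations. Diagnoses are an
#' explicit annotation column, never re-derived from scores.
#'
#' @param comp_responses data.frame `respondent_id, item_id, response`.
#' @param comp_diagnoses data.frame `respondent_id, label, diagnosis`
#'   with diagnosis in `"positive"`/`"negative"`.
#' @param single_responses data.frame `respondent_id, item_id, response`
#'   and, if `system` is not given, a `label` column naming the owning
#'   single scale's symptom.
#' @param single_diagnoses as `comp_diagnoses`, for single-scale users.
#' @param system optional `scale_system` used to attach the `label`
#'   column of `single_responses` from item membership.
#' @return object of class `historical_dataset`.
#' @export
historical_dataset <- function(comp_responses = NULL, comp_diagnoses = NULL,
                               single_responses = NULL, single_diagnoses = NULL,
                               system = NULL) {
  empty_resp <- data.frame(respondent_id = character(), item_id = character(),
                           response = integer(), stringsAsFactors = FALSE)
  empty_diag <- data.frame(respondent_id = character(), label = character(),
                           diagnosis = character(), stringsAsFactors = FALSE)
  if (is.null(comp_responses)) comp_responses <- empty_resp
  if (is.null(comp_diagnoses)) comp_diagnoses <- empty_diag
  if (is.null(single_responses)) single_responses <- cbind(empty_resp, label = character())
  if (is.null(single_diagnoses)) single_diagnoses <- empty_diag
  check_option_values(comp_responses$response)
  check_option_values(single_responses$response)
  if (!all(comp_diagnoses$diagnosis %in% c("positive", "negative")) ||
      !all(single_diagnoses$diagnosis %in% c("positive", "negative")))
    stop("diagnosis must be 'positive' or 'negative'", call. = FALSE)
  if (!"label" %in% names(single_responses)) {
    if (is.null(system))
      stop("single_responses needs a `label` column or a `system` to derive it",
           call. = FALSE)
    map <- stats::setNames(system$items$label, system$items$item_id)
    unknown <- setdiff(single_responses$item_id, names(map))
    if (length(unknown))
      stop("single responses to items not in the system: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    single_responses$label <- unname(map[single_responses$item_id])
  }
  structure(list(comp_responses = comp_responses,
                 comp_diagnoses = comp_diagnoses,
                 single_responses = single_responses,
                 single_diagnoses = single_diagnoses),
            class = "historical_dataset")
}

#' @export
print.historical_dataset <- function(x, ...) {
  cat("<historical_dataset> NC =", length(unique(x$comp_responses$respondent_id)),
      "comprehensive respondents;",
      length(unique(x$single_responses$respondent_id)),
      "single-scale respondents\n")
  invisible(x)
}

#' Tally positive-diagnosis and positive-response counts
#'
#' Computes the counts feeding the probability indices: `NC` (comprehensive
#' respondents), per-label `N_i` (positive diagnoses on the comprehensive
#' scale), per-single-scale `NS_i` (respondents who used that scale) and
#' per-item `N_ij` (respondents answering the item positively).
#'
#' @param history a `historical_dataset`.
#' @param positivity_min minimum option value counted positive for `N_ij`.
#' @return list with elements `NC`, `N_label` (named integer), `NS`
#'   (named integer, per single-scale label), `N_item` (named integer).
#' @export
count_positives <- function(history, positivity_min = 2L) {
  stopifnot(inherits(history, "historical_dataset"))
  NC <- length(unique(history$comp_responses$respondent_id))
  d <- history$comp_diagnoses
  pos <- d[d$diagnosis == "positive", ]
  N_label <- if (nrow(pos)) {
    tab <- table(pos$label)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  s <- history$single_responses
  if (nrow(s)) {
    NS_tab <- tapply(s$respondent_id, s$label, function(x) length(unique(x)))
    NS <- stats::setNames(as.integer(NS_tab), names(NS_tab))
    sp <- s[s$response >= positivity_min, ]
    # one respondent counts once per item
    sp <- sp[!duplicated(paste(sp$respondent_id, sp$item_id, sep = "\r")), ]
    it_tab <- table(sp$item_id)
    N_item <- stats::setNames(as.integer(it_tab), names(it_tab))
    all_items <- unique(s$item_id)
    N_item <- stats::setNames(
      ifelse(all_items %in% names(N_item), N_item[all_items], 0L), all_items)
    storage.mode(N_item) <- "integer"
  } else {
    NS <- stats::setNames(integer(0), character(0))
    N_item <- stats::setNames(integer(0), character(0))
  }
  list(NC = NC, N_label = N_label, NS = NS, N_item = N_item)
}
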