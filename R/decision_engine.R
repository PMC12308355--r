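#' Preset positivity thresholds
#'
#' A preset threshold is the minimum positive score over the total score,
#' e.g. 1 of 2 items gives the worked 50% preset. `screen_thresholds()`
#' bundles the first-tier preset (triggers descent into the
#' single-assessment scale) and the second-tier preset (declares the
#' symptom positive); both default to 0.5.
#'
#' @param s_min minimum score for a positive call, `0 < s_min <= s_total`.
#' @param s_total total score.
#' @param p1,p2 first-/second-tier presets in `(0, 1]`.
#' @return `preset_threshold()`: the ratio `s_min / s_total`.
#' @examples
#' preset_threshold(1, 2)  # 0.5
#' @export
preset_threshold <- function(s_min, s_total) {
  if (length(s_total) != 1L || s_total == 0)
    stop("s_total must be a nonzero scalar", call. = FALSE)
  if (s_min <= 0 || s_min > s_total)
    stop("need 0 < s_min <= s_total", call. = FALSE)
  s_min / s_total
}

#' @rdname preset_threshold
#' @export
screen_thresholds <- function(p1 = 0.5, p2 = 0.5) {
  if (p1 <= 0 || p1 > 1 || p2 <= 0 || p2 > 1)
    stop("presets must lie in (0, 1]", call. = FALSE)
  structure(list(p1 = p1, p2 = p2), class = "screen_thresholds")
}

#' First-order positivity rate
#'
#' Fraction of a symptom block's items answered positively; the block size
#' is the fixed denominator.
#'
#' @param positives count of positively answered items.
#' @param denominator total items of the block (must be >= 1).
#' @return the exact ratio.
#' @export
first_order_rate <- function(positives, denominator) {
  if (denominator < 1L)
    stop("symptom label has no comprehensive items (zero denominator)",
         call. = FALSE)
  if (positives < 0L || positives > denominator)
    stop("positives must lie in 0..denominator", call. = FALSE)
  positives / denominator
}

#' First-tier classification rule
#'
#' Positive when the first-order rate meets or exceeds the preset; the
#' boundary is inclusive.
#'
#' @param rate first-order positivity rate in `[0, 1]`.
#' @param thresholds a `screen_thresholds` (or a scalar preset).
#' @return `"positive"` or `"non-positive"`.
#' @export
classify_first_order <- function(rate, thresholds = screen_thresholds()) {
  p1 <- if (inherits(thresholds, "screen_thresholds")) thresholds$p1 else thresholds
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  if (rate >= p1) "positive" else "non-positive"
}

#' Second-tier sequential confirmation with early stopping
#'
#' One step of the single-assessment confirmation test. The denominator is
#' the *total* item count of the single scale, fixed in advance, so the
#' running second-order rate is non-decreasing in answered positives: the
#' test stops positive the moment the rate reaches the preset (even
#' mid-scale), and concludes negative only after every item has been
#' answered below it.
#'
#' @param state a second-order state from `new_second_order_state()`.
#' @param response the respondent's option value for the next item.
#' @return the updated state; `state$status` is `"continue"`,
#'   `"positive-stop"` or `"negative-done"`, and `state$rate` the running
#'   second-order positivity rate.
#' @export
second_order_step <- function(state, response) {
  if (state$status != "continue")
    stop("second-tier test for this label already finished", call. = FALSE)
  check_option_values(response)
  state$n_answered <- state$n_answered + 1L
  state$n_pos <- state$n_pos + as.integer(response >= state$positivity_min)
  state$score <- state$score + as.integer(response)   # 'count' running score
  state$rate <- state$n_pos / state$n_total
  state$status <-
    if (state$rate >= state$p2) "positive-stop"
    else if (state$n_answered >= state$n_total) "negative-done"
    else "continue"
  state
}

#' @rdname second_order_step
#' @param n_total total item count of the single-assessment scale.
#' @param p2 second-tier preset threshold.
#' @param positivity_min minimum option value counted positive.
#' @export
new_second_order_state <- function(n_total, p2 = 0.5, positivity_min = 2L) {
  if (n_total < 1L) stop("single scale has no items", call. = FALSE)
  list(n_total = as.integer(n_total), p2 = p2,
       positivity_min = as.integer(positivity_min),
       n_answered = 0L, n_pos = 0L, score = 0L, rate = 0,
       status = "continue")
}

#' Ablation variants of the decision engine
#'
#' Configurations used in the ablation study: `full` keeps every
#' innovation; `no_sorting` keeps the tree, conditional descent and early
#' stopping but administers labels and items in input order;
#' `comprehensive_only` administers the sorted comprehensive scale alone
#' and classifies by the first-tier rule; `no_indices` administers the
#' unsorted comprehensive scale and always descends into the full single
#' scale (no early stop), classifying by the second-tier rule.
#'
#' @param name one of `"full"`, `"no_sorting"`, `"comprehensive_only"`,
#'   `"no_indices"`, or an already-built configuration list.
#' @return engine configuration list.
#' @export
ablation_variant <- function(name = c("full", "no_sorting",
                                      "comprehensive_only", "no_indices")) {
  if (is.list(name)) return(name)
  name <- match.arg(name)
  switch(name,
    full = list(name = name, sort_order = TRUE, descend = "conditional",
                early_stop = TRUE, classify = "second"),
    no_sorting = list(name = name, sort_order = FALSE, descend = "conditional",
                      early_stop = TRUE, classify = "second"),
    comprehensive_only = list(name = name, sort_order = TRUE,
                              descend = "never", early_stop = TRUE,
                              classify = "first"),
    no_indices = list(name = name, sort_order = FALSE, descend = "always",
                      early_stop = FALSE, classify = "second"))
}

resolve_respondent <- function(respondent) {
  if (is.function(respondent)) return(respondent)
  if (is.numeric(respondent) && !is.null(names(respondent))) {
    vec <- respondent
    return(function(item_id) {
      v <- vec[[item_id]]
      if (is.null(v) || is.na(v)) stop("no response for item ", item_id)
      v
    })
  }
  stop("respondent must be a function(item_id) or a named numeric vector",
       call. = FALSE)
}

#' Administer the scale tree adaptively to one respondent
#'
#' Walks the symptom blocks in traversal order. For each label, every
#' comprehensive item of the block is asked and the first-order rate
#' computed; if it meets the first-tier preset, the single-assessment
#' scale is administered in optimized item order with early stopping
#' (second tier). The final classification of a label is the second-tier
#' verdict; labels that never descend are negative, and labels without a
#' confirmation scale keep their first-tier verdict.
#'
#' @param tree a `scale_tree`.
#' @param respondent a `function(item_id)` returning an option value, or a
#'   named numeric vector of responses covering the tree's items.
#' @param thresholds a `screen_thresholds`.
#' @param positivity_min minimum option value counted positive (screening
#'   severity level: 1 mild ... 4 extreme; default 2, moderate-or-worse).
#' @param variant ablation variant name or configuration
#'   (see [ablation_variant()]).
#' @param keep_log record the ordered administered-item log (`TRUE`) or
#'   only counts (`FALSE`, faster for batch evaluation).
#' @return object of class `session_result`: `classification` (named
#'   character, `"positive"`/`"negative"` per label), `question_count`,
#'   `detail` (per label: first-order rate, stage reached, items asked,
#'   block score `num`, single-scale score `count`), and `log` (data.frame
#'   `item_id`, `response` in administration order, or `NULL`).
#' @export
administer <- function(tree, respondent, thresholds = screen_thresholds(),
                       positivity_min = 2L, variant = "full",
                       keep_log = TRUE) {
  stopifnot(inherits(tree, "scale_tree"))
  cfg <- ablation_variant(variant)
  if (is.numeric(respondent) && !is.null(names(respondent)))
    return(administer_vec(tree, respondent, thresholds, positivity_min,
                          cfg, keep_log))
  ask <- resolve_respondent(respondent)
  labs <- if (cfg$sort_order) tree$label_order else tree$input_label_order
  singles <- if (cfg$sort_order) tree$singles else tree$singles_input
  classification <- stats::setNames(character(length(labs)), labs)
  detail <- stats::setNames(vector("list", length(labs)), labs)
  log_items <- character(0); log_resp <- integer(0)
  qcount <- 0L

  abort_session <- function(e) {
    log <- if (length(log_items))
      data.frame(item_id = log_items, response = log_resp,
                 stringsAsFactors = FALSE) else NULL
    cond <- structure(class = c("screentree_session_error", "error", "condition"),
                      list(message = paste0("session aborted: ",
                                            conditionMessage(e)),
                           call = sys.call(-1), log = log))
    stop(cond)
  }

  for (lab in labs) {
    block <- tree$blocks[[lab]]
    resp <- tryCatch(vapply(block, function(id) as.integer(ask(id)), 1L),
                     error = abort_session)
    check_option_values(resp)
    if (keep_log) { log_items <- c(log_items, block); log_resp <- c(log_resp, resp) }
    qcount <- qcount + length(block)
    n_pos <- sum(resp >= positivity_min)
    rate <- first_order_rate(n_pos, length(block))
    first <- classify_first_order(rate, thresholds)
    sitems <- singles[[lab]]
    descend <- switch(cfg$descend,
                      conditional = identical(first, "positive"),
                      always = TRUE, never = FALSE) && length(sitems) > 0L
    info <- list(first_order_rate = rate, first_order = first,
                 num = sum(resp), count = NA_integer_,
                 second_order_rate = NA_real_, stage = "first-order",
                 items_asked = length(block))
    if (cfg$classify == "first" || (!descend && cfg$descend == "never")) {
      classification[[lab]] <- if (identical(first, "positive")) "positive" else "negative"
    } else if (!descend) {
      # either first-tier negative, or no confirmation scale for this label
      classification[[lab]] <- if (length(sitems) == 0L && identical(first, "positive"))
        "positive" else "negative"
    } else {
      st <- new_second_order_state(length(sitems), p2 = thresholds$p2,
                                   positivity_min = positivity_min)
      for (id in sitems) {
        r <- tryCatch(as.integer(ask(id)), error = abort_session)
        check_option_values(r)
        if (keep_log) { log_items <- c(log_items, id); log_resp <- c(log_resp, r) }
        qcount <- qcount + 1L
        st <- second_order_step(st, r)
        if (cfg$early_stop && st$status != "continue") break
        if (!cfg$early_stop && st$n_answered >= st$n_total) break
      }
      verdict <- if (cfg$early_stop) st$status == "positive-stop"
                 else st$rate >= thresholds$p2
      classification[[lab]] <- if (verdict) "positive" else "negative"
      info$stage <- "second-order"
      info$count <- st$score
      info$second_order_rate <- st$rate
      info$items_asked <- info$items_asked + st$n_answered
    }
    detail[[lab]] <- info
  }
  structure(list(classification = classification,
                 question_count = qcount,
                 detail = detail,
                 log = if (keep_log)
                   data.frame(item_id = log_items, response = log_resp,
                              stringsAsFactors = FALSE) else NULL,
                 variant = cfg$name %||% "custom",
                 positivity_min = positivity_min),
            class = "session_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized path for complete response vectors; semantics identical to the
# per-item callback loop (the test suite checks both against an independent
# full-administration oracle)
administer_vec <- function(tree, responses, thresholds, positivity_min,
                           cfg, keep_log) {
  labs <- if (cfg$sort_order) tree$label_order else tree$input_label_order
  singles <- if (cfg$sort_order) tree$singles else tree$singles_input
  missing_ids <- setdiff(c(unlist(tree$blocks, use.names = FALSE),
                           unlist(singles, use.names = FALSE)),
                         names(responses))
  if (length(missing_ids))
    stop("no response for item ", missing_ids[[1L]], call. = FALSE)
  classification <- stats::setNames(character(length(labs)), labs)
  detail <- stats::setNames(vector("list", length(labs)), labs)
  log_items <- vector("list", 2L * length(labs)); li <- 0L
  qcount <- 0L
  for (lab in labs) {
    block <- tree$blocks[[lab]]
    resp <- as.integer(responses[block])
    check_option_values(resp)
    if (keep_log) { li <- li + 1L; log_items[[li]] <- block }
    qcount <- qcount + length(block)
    rate <- sum(resp >= positivity_min) / length(block)
    first <- if (rate >= thresholds$p1) "positive" else "non-positive"
    sitems <- singles[[lab]]
    descend <- switch(cfg$descend,
                      conditional = identical(first, "positive"),
                      always = TRUE, never = FALSE) && length(sitems) > 0L
    info <- list(first_order_rate = rate, first_order = first,
                 num = sum(resp), count = NA_integer_,
                 second_order_rate = NA_real_, stage = "first-order",
                 items_asked = length(block))
    if (cfg$classify == "first" || (!descend && cfg$descend == "never")) {
      classification[[lab]] <- if (identical(first, "positive")) "positive" else "negative"
    } else if (!descend) {
      classification[[lab]] <- if (length(sitems) == 0L && identical(first, "positive"))
        "positive" else "negative"
    } else {
      sresp <- as.integer(responses[sitems])
      check_option_values(sresp)
      ns <- length(sresp)
      rates <- cumsum(sresp >= positivity_min) / ns
      hit <- if (cfg$early_stop) which(rates >= thresholds$p2)[1L] else NA_integer_
      asked <- if (!is.na(hit)) hit else ns
      verdict <- if (cfg$early_stop) !is.na(hit) else rates[[ns]] >= thresholds$p2
      if (keep_log) { li <- li + 1L; log_items[[li]] <- sitems[seq_len(asked)] }
      qcount <- qcount + asked
      classification[[lab]] <- if (verdict) "positive" else "negative"
      info$stage <- "second-order"
      info$count <- sum(sresp[seq_len(asked)])
      info$second_order_rate <- sum(sresp[seq_len(asked)] >= positivity_min) / ns
      info$items_asked <- info$items_asked + asked
    }
    detail[[lab]] <- info
  }
  log <- NULL
  if (keep_log) {
    ids <- unlist(log_items[seq_len(li)], use.names = FALSE)
    log <- data.frame(item_id = ids,
                      response = as.integer(responses[ids]),
                      stringsAsFactors = FALSE)
  }
  structure(list(classification = classification, question_count = qcount,
                 detail = detail, log = log,
                 variant = cfg$name %||% "custom",
                 positivity_min = positivity_min),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result>", sum(x$classification == "positive"),
      "positive of", length(x$classification), "labels;",
      x$question_count, "questions asked\n")
  invisible(x)
}
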