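#' Double-stratified k-fold plan
#'
#' Respondents are stratified first by age group, then by dominant
#' (maximum) latent severity within the age group, and dealt cyclically
#' into `k` folds after a seeded shuffle -- each fold's stratum
#' composition matches the cohort within one respondent per stratum.
#'
#' @param cohort a `synthetic_cohort`.
#' @param k number of folds (>= 2, <= cohort size).
#' @param seed integer seed for the shuffle.
#' @return object of class `fold_plan`: `folds` (list of respondent-id
#'   vectors), `strata` (named stratum per respondent), `k`, `seed`.
#' @export
stratified_kfold <- function(cohort, k = 5L, seed = 1L) {
  rids <- cohort$profiles$respondent_id
  n <- length(rids)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the cohort size", call. = FALSE)
  dom <- tapply(cohort$severity$severity, cohort$severity$respondent_id, max)
  dom_all <- stats::setNames(rep(0L, n), rids)
  dom_all[names(dom)] <- as.integer(dom)
  strata <- paste(cohort$profiles$age_group, dom_all[rids], sep = "/")
  names(strata) <- rids
  set.seed(seed)
  ordered_ids <- character(0)
  for (s in sort(unique(strata))) {
    members <- rids[strata == s]
    ordered_ids <- c(ordered_ids, resample(members, length(members)))
  }
  fold_of <- rep_len(seq_len(k), n)
  folds <- split(ordered_ids, fold_of)
  names(folds) <- NULL
  structure(list(folds = folds, strata = strata, k = k, seed = seed),
            class = "fold_plan")
}

#' Confusion-matrix metrics
#'
#' @param pred,truth logical vectors (positive = `TRUE`) of equal length.
#' @return named list: `accuracy`, `sensitivity` (recall), `specificity`,
#'   `precision`, `f1`, plus raw counts. Rates with empty denominators are
#'   `NA` with a warning, never silently 0.
#' @export
confusion_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, ": empty denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(accuracy = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
       sensitivity = sens,
       specificity = safe(tn, tn + fp, "specificity"),
       precision = prec, f1 = f1,
       tp = tp, fn = fn, tn = tn, fp = fp)
}

# level-matched ground truth: positive <=> latent severity >= screening level,
# with the cohort's annotation flips applied on top
level_truth <- function(cohort, positivity_min) {
  truth <- cohort$truth
  key <- paste(truth$respondent_id, truth$label, sep = "\r")
  sev <- stats::setNames(cohort$severity$severity,
                         paste(cohort$severity$respondent_id,
                               cohort$severity$label, sep = "\r"))[key]
  sev[is.na(sev)] <- 0L
  pos <- sev >= positivity_min
  if (!is.null(cohort$noise_flips) && nrow(cohort$noise_flips)) {
    fkey <- paste(cohort$noise_flips$respondent_id, cohort$noise_flips$label,
                  sep = "\r")
    at <- key %in% fkey
    pos[at] <- !pos[at]
  }
  data.frame(respondent_id = truth$respondent_id, label = truth$label,
             positive = pos, severity = as.integer(sev),
             stringsAsFactors = FALSE)
}

split_response_vectors <- function(responses) {
  idx <- split(seq_len(nrow(responses)), responses$respondent_id)
  lapply(idx, function(i)
    stats::setNames(responses$response[i], responses$item_id[i]))
}

#' Evaluate an engine variant under the fivefold protocol
#'
#' For each fold, the probability indices (the algorithm's only trained
#' component) are fitted on the training folds' responses and annotations,
#' the optimized tree is built, and every validation respondent is
#' administered adaptively with full state reset between respondents.
#' Per-(respondent, label) predictions are compared with level-matched
#' ground truth and macro-averaged over folds; the whole procedure is
#' repeated `n_trials` times with freshly drawn respondent jitter and
#' averaged.
#'
#' @param cohort a `synthetic_cohort`.
#' @param variant ablation variant (see [ablation_variant()]).
#' @param thresholds a `screen_thresholds`.
#' @param positivity_min screening severity level (1 mild .. 4 extreme).
#' @param n_trials repeated trials (default 100; the reference protocol
#'   uses 1000 -- scale up via this flag).
#' @param k folds.
#' @param seed master seed (folds and trial jitter derive from it).
#' @param folds optional pre-computed `fold_plan`.
#' @return object of class `metrics_report`: `metrics` (trial-averaged
#'   macro metrics: accuracy, sensitivity, specificity,
#'   sensitivity_moderate, precision, recall, f1, mean_questions),
#'   `ci_halfwidth` (95% over trials), `per_fold` (last trial's per-fold
#'   values), and the run configuration.
#' @export
evaluate_variant <- function(cohort, variant = "full",
                             thresholds = screen_thresholds(),
                             positivity_min = 2L, n_trials = 100L,
                             k = 5L, seed = 1L, folds = NULL) {
  if (nrow(cohort$profiles) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(folds)) folds <- stratified_kfold(cohort, k = k, seed = seed)
  truth <- level_truth(cohort, positivity_min)
  tkey <- paste(truth$respondent_id, truth$label, sep = "\r")
  truth_map <- stats::setNames(truth$positive, tkey)
  sev_map <- stats::setNames(truth$severity, tkey)
  prof <- cohort$profiles
  age_of <- stats::setNames(prof$age_group, prof$respondent_id)
  items_home <- do.call(rbind, lapply(cohort$systems, function(s)
    s$items[, c("item_id", "home")]))
  comp_ids <- items_home$item_id[items_home$home == "comprehensive"]
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  fold_names <- paste0("fold", seq_along(folds$folds))
  metric_names <- c("accuracy", "sensitivity", "specificity",
                    "sensitivity_moderate", "precision", "recall", "f1",
                    "mean_questions")
  trial_macro <- matrix(NA_real_, n_trials, length(metric_names),
                        dimnames = list(NULL, metric_names))
  per_fold_last <- NULL
  for (t in seq_len(n_trials)) {
    responses <- draw_responses(cohort, seed = trial_seeds[[t]])
    resp_vec <- split_response_vectors(responses)
    is_comp <- responses$item_id %in% comp_ids
    fold_rows <- matrix(NA_real_, length(folds$folds), length(metric_names),
                        dimnames = list(fold_names, metric_names))
    for (f in seq_along(folds$folds)) {
      valid_ids <- folds$folds[[f]]
      train_ids <- setdiff(prof$respondent_id, valid_ids)
      ages_present <- intersect(names(cohort$systems),
                                unique(prof$age_group))
      trees <- lapply(ages_present, function(a) {
        sys <- cohort$systems[[a]]
        ids <- intersect(train_ids, prof$respondent_id[prof$age_group == a])
        sel <- responses$respondent_id %in% ids
        hist <- historical_dataset(
          comp_responses = responses[sel & is_comp, ],
          comp_diagnoses = data.frame(
            respondent_id = truth$respondent_id,
            label = truth$label,
            diagnosis = ifelse(cohort$truth$positive, "positive", "negative"),
            stringsAsFactors = FALSE)[truth$respondent_id %in% ids, ],
          single_responses = responses[sel & !is_comp, ],
          single_diagnoses = NULL, system = sys)
        build_scale_tree(optimize_scales(sys, hist))
      })
      names(trees) <- ages_present
      pred_key <- character(0); pred_val <- logical(0)
      qcounts <- numeric(length(valid_ids))
      for (i in seq_along(valid_ids)) {
        rid <- valid_ids[[i]]
        res <- administer(trees[[age_of[[rid]]]], resp_vec[[rid]],
                          thresholds = thresholds,
                          positivity_min = positivity_min,
                          variant = variant, keep_log = FALSE)
        pred_key <- c(pred_key, paste(rid, names(res$classification), sep = "\r"))
        pred_val <- c(pred_val, unname(res$classification == "positive"))
        qcounts[[i]] <- res$question_count
      }
      tv <- truth_map[pred_key]
      sv <- sev_map[pred_key]
      cm <- suppressWarnings(confusion_metrics(pred_val, tv))
      mod <- sv == 2L & tv
      sens_mod <- if (any(mod)) mean(pred_val[mod]) else NA_real_
      fold_rows[f, ] <- c(cm$accuracy, cm$sensitivity, cm$specificity,
                          sens_mod, cm$precision, cm$sensitivity, cm$f1,
                          mean(qcounts))
    }
    trial_macro[t, ] <- colMeans(fold_rows, na.rm = TRUE)
    per_fold_last <- fold_rows
  }
  means <- colMeans(trial_macro, na.rm = TRUE)
  halfw <- apply(trial_macro, 2, function(x)
    if (n_trials > 1L) 1.96 * stats::sd(x, na.rm = TRUE) / sqrt(n_trials)
    else NA_real_)
  structure(list(metrics = as.list(means),
                 ci_halfwidth = as.list(halfw),
                 per_fold = as.data.frame(per_fold_last),
                 per_trial = as.data.frame(trial_macro),
                 variant = if (is.list(variant)) variant$name else variant,
                 positivity_min = positivity_min, n_trials = n_trials,
                 k = length(folds$folds), seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> variant =", x$variant,
      "| level =", x$positivity_min, "| trials =", x$n_trials, "\n")
  m <- unlist(x$metrics)
  cat(paste0("  ", format(names(m)), " ", sprintf("%.4f", m)), sep = "\n")
  invisible(x)
}

#' Severity sweep
#'
#' Re-runs the fivefold evaluation with the positivity criterion set to
#' each screening level (mild 1 .. extreme 4), with level-matched ground
#' truth, reporting accuracy and mean question count per level.
#'
#' @param cohort a `synthetic_cohort`.
#' @param levels named integer screening levels.
#' @param variant,thresholds,n_trials,k,seed as [evaluate_variant()].
#' @return data.frame, one row per level.
#' @export
severity_sweep <- function(cohort,
                           levels = c(mild = 1L, moderate = 2L,
                                      severe = 3L, extreme = 4L),
                           variant = "full",
                           thresholds = screen_thresholds(),
                           n_trials = 10L, k = 5L, seed = 1L) {
  folds <- stratified_kfold(cohort, k = k, seed = seed)
  rows <- lapply(seq_along(levels), function(i) {
    rep <- evaluate_variant(cohort, variant = variant, thresholds = thresholds,
                            positivity_min = levels[[i]], n_trials = n_trials,
                            seed = seed, folds = folds)
    data.frame(level = names(levels)[[i]], positivity_min = levels[[i]],
               accuracy = rep$metrics$accuracy,
               sensitivity = rep$metrics$sensitivity,
               specificity = rep$metrics$specificity,
               mean_questions = rep$metrics$mean_questions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Positive-count sweep
#'
#' Generates cohorts with a forced number of affected symptom labels and
#' evaluates the engine on each, reporting how accuracy and question count
#' scale with the number of positives.
#'
#' @param template scale template name (single-template cohorts).
#' @param n_positive integer vector of forced affected-label counts.
#' @param n_per_cell cohort size per count.
#' @param variant,thresholds,n_trials,k,seed as [evaluate_variant()].
#' @return data.frame, one row per count.
#' @export
positives_sweep <- function(template = "MSSMHS", n_positive = 0:4,
                            n_per_cell = 200L, variant = "full",
                            thresholds = screen_thresholds(),
                            n_trials = 5L, k = 5L, seed = 1L) {
  age <- attr(scale_template(template), "age_group")
  age_mix <- stats::setNames(rep(0, 3), c("adult", "adolescent", "child"))
  age_mix[age] <- 1
  rows <- lapply(n_positive, function(np) {
    cfg <- generation_config(n_samples = n_per_cell, age_mix = age_mix,
                             forced_affected = np,
                             seed = seed + 1000L * np)
    cohort <- generate_cohort(cfg)
    rep <- evaluate_variant(cohort, variant = variant,
                            thresholds = thresholds, n_trials = n_trials,
                            k = k, seed = seed)
    data.frame(n_positive = np,
               accuracy = rep$metrics$accuracy,
               mean_questions = rep$metrics$mean_questions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ablation study
#'
#' Evaluates the four engine variants on an adolescent-scale cohort (the
#' 60-item template serves as the representative comprehensive scale),
#' reporting accuracy and mean question count per variant.
#'
#' @param cohort optional pre-built cohort; default is a single-template
#'   adolescent cohort of `n_samples`.
#' @param thresholds,n_trials,k,seed as [evaluate_variant()].
#' @param n_samples cohort size when `cohort` is NULL.
#' @return data.frame, one row per variant.
#' @export
ablation_study <- function(cohort = NULL,
                           thresholds = screen_thresholds(),
                           n_trials = 10L, k = 5L, seed = 1L,
                           n_samples = 400L) {
  if (is.null(cohort)) {
    cfg <- generation_config(n_samples = n_samples,
                             age_mix = c(adult = 0, adolescent = 1, child = 0),
                             seed = seed)
    cohort <- generate_cohort(cfg)
  }
  folds <- stratified_kfold(cohort, k = k, seed = seed)
  variants <- c("full", "no_sorting", "comprehensive_only", "no_indices")
  rows <- lapply(variants, function(v) {
    rep <- evaluate_variant(cohort, variant = v, thresholds = thresholds,
                            n_trials = n_trials, seed = seed, folds = folds)
    data.frame(variant = v, accuracy = rep$metrics$accuracy,
               mean_questions = rep$metrics$mean_questions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
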