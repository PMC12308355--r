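#' Synthetic scale templates
#'
#' Three scale families are emulated with generated placeholder item text
#' (no copyrighted wording is shipped): an adult 90-item / 11-label
#' checklist (`"SCL90"`-like), an adolescent 60-item / 10-label scale
#' (`"MSSMHS"`-like) and a child 40-item / 8-label scale (`"MHRSP"`-like),
#' all on 5-point options. Every label also gets a 10-item
#' single-assessment confirmation scale. The returned system carries
#' attributes `age_group` and `coupling` (label pairs boosted for
#' co-occurrence).
#'
#' @param name `"SCL90"`, `"MSSMHS"` or `"MHRSP"`.
#' @return a `scale_system`.
#' @export
scale_template <- function(name = c("SCL90", "MSSMHS", "MHRSP")) {
  name <- match.arg(name)
  spec <- switch(name,
    SCL90 = list(
      age_group = "adult",
      blocks = c(somatization = 12L, obsessive = 10L,
                 interpersonal_sensitivity = 9L, depression = 13L,
                 heart_racing = 4L, anxiety = 10L, hostility = 6L,
                 terror = 7L, paranoia = 6L, psychoticism = 10L, others = 3L),
      coupling = list(c("anxiety", "depression"),
                      c("somatization", "anxiety"))),
    MSSMHS = list(
      age_group = "adolescent",
      blocks = stats::setNames(rep(6L, 10L),
                 c("academic_stress", "maladjustment", "emotion_dysregulation",
                   "psychological_imbalance", "interpersonal_sensitivity",
                   "depression", "anxiety", "hostility", "paranoia",
                   "obsessive")),
      coupling = list(c("anxiety", "depression"))),
    MHRSP = list(
      age_group = "child",
      blocks = stats::setNames(rep(5L, 8L),
                 c("learning_anxiety", "social_anxiety", "loneliness",
                   "self_blame", "sensitivity", "physical_symptoms",
                   "terror", "impulsiveness")),
      coupling = list(c("learning_anxiety", "social_anxiety"))))
  labs <- names(spec$blocks)
  comp <- do.call(rbind, lapply(labs, function(l) {
    k <- spec$blocks[[l]]
    data.frame(item_id = sprintf("%s_%s_c%02d", tolower(name), l, seq_len(k)),
               label = l,
               text = sprintf("Synthetic %s item %d (%s)", l, seq_len(k), name),
               home = "comprehensive", scale_id = tolower(name),
               stringsAsFactors = FALSE)
  }))
  sing <- do.call(rbind, lapply(labs, function(l) {
    data.frame(item_id = sprintf("%s_%s_s%02d", tolower(name), l, 1:10),
               label = l,
               text = sprintf("Synthetic %s confirmation item %d", l, 1:10),
               home = "single", scale_id = paste0("single_", tolower(name), "_", l),
               stringsAsFactors = FALSE)
  }))
  sys <- scale_system(rbind(comp, sing), labels = labs)
  attr(sys, "template") <- name
  attr(sys, "age_group") <- spec$age_group
  attr(sys, "coupling") <- spec$coupling
  sys
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults state the simulated world: 2134 respondents; latent severity of
#' an affected symptom drawn mild/moderate/severe = 60/30/10%; 30% of cases
#' single-symptom and 70% comorbid (two or more affected labels, coupled
#' pairs boosted); 5% of respondents receive one contradictory diagnosis
#' annotation; respondents are assigned the age-matched template (adults
#' 50%, adolescents 30%, children 20%; sexes 50/50). The response style
#' models clinical answering: affected items sit at the top score of the
#' severity band with ±1 jitter (0.15 per direction), are under-reported to
#' a low option with probability 0.30, and unaffected items are endorsed at
#' option 1 with probability 0.60.
#'
#' @param n_samples cohort size.
#' @param severity_mix named numeric `(mild, moderate, severe)`, sums to 1.
#' @param comorbid_rate fraction of cases with >= 2 affected labels.
#' @param noise_rate fraction of respondents with one flipped annotation.
#' @param age_mix named numeric over `adult`, `adolescent`, `child`.
#' @param sex_ratio named numeric over `female`, `male`.
#' @param coupling_boost sampling-weight multiplier for labels coupled to
#'   an already-affected label.
#' @param comorbid_extra_size,comorbid_extra_prob comorbid cases affect
#'   `2 + Binomial(size, prob)` labels (capped at the label count).
#' @param response_style list with `jitter`, `minimize`, `endorse_absent`;
#'   see [respond()].
#' @param forced_affected force every profile to exactly this many affected
#'   labels (`NULL` = use the case mixture; used by the positives sweep).
#' @param seed integer seed making the cohort bit-reproducible.
#' @return list of class `generation_config`.
#' @export
generation_config <- function(n_samples = 2134L,
                              severity_mix = c(mild = 0.60, moderate = 0.30,
                                               severe = 0.10),
                              comorbid_rate = 0.70,
                              noise_rate = 0.05,
                              age_mix = c(adult = 0.50, adolescent = 0.30,
                                          child = 0.20),
                              sex_ratio = c(female = 0.5, male = 0.5),
                              coupling_boost = 2.0,
                              comorbid_extra_size = 5L,
                              comorbid_extra_prob = 0.5,
                              response_style = list(jitter = 0.15,
                                                    minimize = 0.30,
                                                    endorse_absent = 0.60),
                              forced_affected = NULL,
                              seed = 20250101L) {
  if (n_samples < 0L) stop("n_samples must be >= 0", call. = FALSE)
  for (mx in list(severity_mix, age_mix, sex_ratio))
    if (abs(sum(mx) - 1) > 1e-8)
      stop("mixture weights must sum to 1", call. = FALSE)
  if (noise_rate < 0 || noise_rate > 1)
    stop("noise_rate must lie in [0, 1]", call. = FALSE)
  if (comorbid_rate < 0 || comorbid_rate > 1)
    stop("comorbid_rate must lie in [0, 1]", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 severity_mix = severity_mix, comorbid_rate = comorbid_rate,
                 noise_rate = noise_rate, age_mix = age_mix,
                 sex_ratio = sex_ratio, coupling_boost = coupling_boost,
                 comorbid_extra_size = as.integer(comorbid_extra_size),
                 comorbid_extra_prob = comorbid_extra_prob,
                 response_style = response_style,
                 forced_affected = forced_affected,
                 seed = as.integer(seed)),
            class = "generation_config")
}

#' Draw one respondent profile
#'
#' Draws case composition (single-symptom vs comorbid), the affected
#' symptom labels (coupled pairs boosted) and each affected label's latent
#' severity from the configured mixtures, using the current RNG state.
#' Latent severity is coded 0 absent, 1 mild, 2 moderate, 3 severe;
#' ground-truth positivity is severity >= moderate.
#'
#' @param config a `generation_config`.
#' @param system the respondent's assigned `scale_system` (template).
#' @return list with `labels` (affected labels), `severity` (named integer
#'   over affected labels), `comorbid` flag.
#' @export
sample_profile <- function(config, system) {
  labs <- system$labels
  m <- length(labs)
  n_aff <- if (!is.null(config$forced_affected)) {
    min(config$forced_affected, m)
  } else if (stats::runif(1) < config$comorbid_rate) {
    min(m, 2L + stats::rbinom(1L, config$comorbid_extra_size,
                              config$comorbid_extra_prob))
  } else 1L
  affected <- character(0)
  coupling <- attr(system, "coupling") %||% list()
  while (length(affected) < n_aff) {
    rem <- setdiff(labs, affected)
    w <- rep(1, length(rem))
    for (pair in coupling) {
      if (any(pair %in% affected))
        w[rem %in% pair] <- config$coupling_boost
    }
    affected <- c(affected, sample(rem, 1L, prob = w))
  }
  sev <- sample(1:3, length(affected), replace = TRUE,
                prob = config$severity_mix)
  list(labels = affected,
       severity = stats::setNames(as.integer(sev), affected),
       comorbid = length(affected) >= 2L)
}

# vectorized response draw for one severity stratum
draw_option_values <- function(severity, style) {
  n <- length(severity)
  out <- integer(n)
  absent <- severity == 0L
  out[absent] <- stats::rbinom(sum(absent), 1L, style$endorse_absent)
  aff <- which(!absent)
  if (length(aff)) {
    base <- severity[aff] + 1L            # mild->2, moderate->3, severe->4
    minimized <- stats::runif(length(aff)) < style$minimize
    jit <- sample(c(-1L, 0L, 1L), length(aff), replace = TRUE,
                  prob = c(style$jitter, 1 - 2 * style$jitter, style$jitter))
    v <- pmin(4L, pmax(0L, base + jit))
    low <- sample(0:1, length(aff), replace = TRUE)
    out[aff] <- ifelse(minimized, low, v)
  }
  out
}

#' Simulate one item response
#'
#' Items under an affected label are answered at the top score of the
#' latent severity band (mild 2, moderate 3, severe 4; the condition-matching
#' higher-score option is prioritized), shifted ±1 by response-style jitter,
#' or under-reported to option 0/1 with probability `minimize`. Items under
#' unaffected labels are answered 1 with probability `endorse_absent`, else
#' 0. Uses the current RNG state.
#'
#' @param profile a profile from [sample_profile()].
#' @param item an item row (list/data.frame row with `label`), or a label.
#' @param style response-style list (`jitter`, `minimize`, `endorse_absent`);
#'   set all to 0 for deterministic severity-matched answers.
#' @return an option value in 0..4.
#' @export
respond <- function(profile, item,
                    style = list(jitter = 0.15, minimize = 0.30,
                                 endorse_absent = 0.60)) {
  lab <- if (is.character(item) && length(item) == 1L) item else item$label
  sev <- unname(profile$severity[lab])
  if (length(sev) != 1L || is.na(sev)) sev <- 0L
  draw_option_values(as.integer(sev), style)
}

#' Inject contradictory annotation noise
#'
#' Flips the diagnosis annotation of exactly one label for a
#' nearest-rounded `rate` fraction of respondents, leaving responses
#' untouched -- emulating records annotated "no condition" while the
#' responses clearly endorse it. A positively annotated label is flipped
#' negative when one exists; otherwise one label is flipped positive.
#'
#' @param cohort a `synthetic_cohort`.
#' @param rate fraction of respondents to corrupt, in `[0, 1]`.
#' @return the cohort with updated `truth` and a `noise_flips` record.
#' @export
inject_noise <- function(cohort, rate) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  rids <- cohort$profiles$respondent_id
  n_flip <- round(rate * length(rids))
  if (n_flip == 0L) {
    cohort$noise_flips <- data.frame(respondent_id = character(),
                                     label = character(),
                                     stringsAsFactors = FALSE)
    return(cohort)
  }
  chosen <- sample(rids, n_flip)
  truth <- cohort$truth
  key <- split(seq_len(nrow(truth)), truth$respondent_id)
  flips <- lapply(chosen, function(rid) {
    rows <- key[[rid]]
    pos <- rows[truth$positive[rows]]
    at <- if (length(pos)) resample(pos, 1L) else resample(rows, 1L)
    at
  })
  at <- unlist(flips)
  truth$positive[at] <- !truth$positive[at]
  cohort$truth <- truth
  cohort$noise_flips <- data.frame(respondent_id = truth$respondent_id[at],
                                   label = truth$label[at],
                                   stringsAsFactors = FALSE)
  cohort
}

# sample() that never expands a length-1 x into 1:x
resample <- function(x, size) x[sample.int(length(x), size)]

#' Generate a synthetic respondent cohort
#'
#' Produces the full simulated world: age-assigned scale templates,
#' respondent profiles with latent severities and comorbidity, ground-truth
#' per-label positivity (severity >= moderate), annotation noise, and one
#' drawn response vector per respondent over their template's
#' comprehensive and single-assessment items. Bit-reproducible from
#' `config` (which embeds the seed).
#'
#' @param config a `generation_config`.
#' @return object of class `synthetic_cohort` with `systems` (named list
#'   of templates used), `profiles`, `severity` (long: respondent_id,
#'   label, severity), `truth` (long: respondent_id, label, positive),
#'   `noise_flips`, `responses` (long: respondent_id, item_id, response)
#'   and `config`.
#' @export
generate_cohort <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  set.seed(config$seed)
  systems <- list(adult = scale_template("SCL90"),
                  adolescent = scale_template("MSSMHS"),
                  child = scale_template("MHRSP"))
  n <- config$n_samples
  if (n == 0L) {
    empty <- data.frame(stringsAsFactors = FALSE)
    cohort <- structure(list(systems = systems,
                             profiles = data.frame(respondent_id = character(),
                                                   age_group = character(),
                                                   sex = character(),
                                                   template = character(),
                                                   comorbid = logical(),
                                                   stringsAsFactors = FALSE),
                             severity = data.frame(respondent_id = character(),
                                                   label = character(),
                                                   severity = integer(),
                                                   stringsAsFactors = FALSE),
                             truth = data.frame(respondent_id = character(),
                                                label = character(),
                                                positive = logical(),
                                                stringsAsFactors = FALSE),
                             noise_flips = empty,
                             responses = data.frame(respondent_id = character(),
                                                    item_id = character(),
                                                    response = integer(),
                                                    stringsAsFactors = FALSE),
                             config = config),
                        class = "synthetic_cohort")
    return(cohort)
  }
  age <- sample(names(config$age_mix), n, replace = TRUE, prob = config$age_mix)
  sex <- sample(names(config$sex_ratio), n, replace = TRUE,
                prob = config$sex_ratio)
  rid <- sprintf("r%05d", seq_len(n))
  template <- vapply(age, function(a) attr(systems[[a]], "template"), "")
  prof_list <- lapply(seq_len(n), function(i)
    sample_profile(config, systems[[age[[i]]]]))
  profiles <- data.frame(respondent_id = rid, age_group = age, sex = sex,
                         template = template,
                         comorbid = vapply(prof_list, `[[`, TRUE, "comorbid"),
                         stringsAsFactors = FALSE)
  severity <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- prof_list[[i]]
    if (!length(p$labels)) return(NULL)
    data.frame(respondent_id = rid[[i]], label = p$labels,
               severity = unname(p$severity), stringsAsFactors = FALSE)
  }))
  if (is.null(severity))
    severity <- data.frame(respondent_id = character(), label = character(),
                           severity = integer(), stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(names(systems), function(a) {
    ids <- rid[age == a]
    labs <- systems[[a]]$labels
    if (!length(ids)) return(NULL)
    data.frame(respondent_id = rep(ids, each = length(labs)),
               label = rep(labs, times = length(ids)),
               positive = FALSE, stringsAsFactors = FALSE)
  }))
  sev_key <- paste(severity$respondent_id, severity$label, sep = "\r")
  sev_map <- stats::setNames(severity$severity, sev_key)
  tkey <- paste(truth$respondent_id, truth$label, sep = "\r")
  tsev <- sev_map[tkey]
  tsev[is.na(tsev)] <- 0L
  truth$positive <- tsev >= 2L
  cohort <- structure(list(systems = systems, profiles = profiles,
                           severity = severity, truth = truth,
                           noise_flips = NULL, responses = NULL,
                           config = config),
                      class = "synthetic_cohort")
  cohort <- inject_noise(cohort, config$noise_rate)
  resp_seed <- sample.int(.Machine$integer.max, 1L)
  cohort$responses <- draw_responses(cohort, seed = resp_seed)
  cohort
}

#' Redraw response vectors for a cohort
#'
#' Regenerates every respondent's item responses from their fixed latent
#' profile under a new seed -- "fresh respondent jitter" for repeated
#' evaluation trials. Profiles, ground truth and annotations are untouched.
#'
#' @param cohort a `synthetic_cohort`.
#' @param seed integer seed.
#' @return long data.frame `respondent_id, item_id, response`.
#' @export
draw_responses <- function(cohort, seed) {
  set.seed(seed)
  style <- cohort$config$response_style
  sev_map <- stats::setNames(cohort$severity$severity,
                             paste(cohort$severity$respondent_id,
                                   cohort$severity$label, sep = "\r"))
  out <- lapply(names(cohort$systems), function(a) {
    sys <- cohort$systems[[a]]
    ids <- cohort$profiles$respondent_id[cohort$profiles$age_group == a]
    if (!length(ids)) return(NULL)
    items <- sys$items
    ni <- nrow(items)
    rid <- rep(ids, each = ni)
    item <- rep(items$item_id, times = length(ids))
    lab <- rep(items$label, times = length(ids))
    sev <- sev_map[paste(rid, lab, sep = "\r")]
    sev[is.na(sev)] <- 0L
    data.frame(respondent_id = rid, item_id = item,
               response = draw_option_values(as.integer(sev), style),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$profiles), "respondents (",
      paste(names(table(x$profiles$age_group)),
            as.integer(table(x$profiles$age_group)), collapse = ", "),
      ");", nrow(x$responses %||% data.frame()), "responses\n")
  invisible(x)
}
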