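# Fixtures and independent oracles used across the suite.

# toy system: 2 labels x 3 comprehensive items x 4 single items
toy_system <- function() {
  items <- rbind(
    data.frame(item_id = paste0("a_c", 1:3), label = "alpha",
               text = "a", home = "comprehensive", scale_id = "comp",
               stringsAsFactors = FALSE),
    data.frame(item_id = paste0("b_c", 1:3), label = "beta",
               text = "b", home = "comprehensive", scale_id = "comp",
               stringsAsFactors = FALSE),
    data.frame(item_id = paste0("a_s", 1:4), label = "alpha",
               text = "as", home = "single", scale_id = "sa",
               stringsAsFactors = FALSE),
    data.frame(item_id = paste0("b_s", 1:4), label = "beta",
               text = "bs", home = "single", scale_id = "sb",
               stringsAsFactors = FALSE))
  scale_system(items, labels = c("alpha", "beta"))
}

# random historical dataset over a system, with known RNG state
random_history <- function(system, n_comp = 40, n_single = 40, seed = 1) {
  set.seed(seed)
  comp_items <- system$items$item_id[system$items$home == "comprehensive"]
  sing <- system$items[system$items$home == "single", ]
  rid_c <- sprintf("c%03d", seq_len(n_comp))
  rid_s <- sprintf("s%03d", seq_len(n_single))
  comp_responses <- data.frame(
    respondent_id = rep(rid_c, each = length(comp_items)),
    item_id = rep(comp_items, times = n_comp),
    response = sample(0:4, n_comp * length(comp_items), replace = TRUE),
    stringsAsFactors = FALSE)
  comp_diagnoses <- data.frame(
    respondent_id = rep(rid_c, each = length(system$labels)),
    label = rep(system$labels, times = n_comp),
    diagnosis = sample(c("positive", "negative"),
                       n_comp * length(system$labels), replace = TRUE),
    stringsAsFactors = FALSE)
  single_responses <- data.frame(
    respondent_id = rep(rid_s, each = nrow(sing)),
    item_id = rep(sing$item_id, times = n_single),
    response = sample(0:4, n_single * nrow(sing), replace = TRUE),
    stringsAsFactors = FALSE)
  historical_dataset(comp_responses, comp_diagnoses, single_responses,
                     system = system)
}

# one-pass enumeration oracle for count_positives
tally_oracle <- function(history) {
  NC <- length(unique(history$comp_responses$respondent_id))
  N_label <- sapply(split(history$comp_diagnoses$diagnosis,
                          history$comp_diagnoses$label),
                    function(d) sum(d == "positive"))
  s <- history$single_responses
  N_item <- sapply(split(s, s$item_id), function(rows)
    length(unique(rows$respondent_id[rows$response >= 2])))
  NS <- sapply(split(s, s$label),
               function(rows) length(unique(rows$respondent_id)))
  list(NC = NC, N_label = N_label, NS = NS, N_item = N_item)
}

# independent reference engine: administers EVERY item (no early stopping,
# no tree shortcuts) and applies the two threshold rules on complete data
full_administration_oracle <- function(tree, responses, p1 = 0.5, p2 = 0.5,
                                       positivity_min = 2) {
  out <- character(0)
  qcount <- 0
  for (lab in tree$label_order) {
    block <- responses[tree$blocks[[lab]]]
    qcount <- qcount + length(block)
    rate1 <- sum(block >= positivity_min) / length(block)
    sitems <- tree$singles[[lab]]
    if (rate1 >= p1 && length(sitems)) {
      sresp <- responses[sitems]
      qcount <- qcount + length(sresp)
      rate2 <- sum(sresp >= positivity_min) / length(sresp)
      out[lab] <- if (rate2 >= p2) "positive" else "negative"
    } else if (rate1 >= p1) {
      out[lab] <- "positive"      # no confirmation scale: first-tier verdict
    } else {
      out[lab] <- "negative"
    }
  }
  list(classification = out, question_count = qcount)
}

# optimized toy tree from a fixed random history
toy_tree <- function(seed = 1) {
  sys <- toy_system()
  build_scale_tree(optimize_scales(sys, random_history(sys, seed = seed)))
}

# the printed first-order index ranking used as an ordering fixture
printed_label_ranking <- function() {
  c(somatization = 63.5, obsessive = 59.7, interpersonal_sensitivity = 55.7,
    depression = 55.3, heart_racing = 48.2, anxiety = 44.9, hostility = 42.1,
    terror = 40.5, paranoia = 37.2, psychoticism = 32.6, others = 30.0) / 100
}

printed_sas_ranking <- function() {
  c(sas01 = 82.2, sas02 = 74.5, sas03 = 72.5, sas04 = 63.8, sas05 = 58.2,
    sas06 = 56.7, sas07 = 53.1, sas08 = 32.1, sas09 = 27.2, sas10 = 26.1,
    sas11 = 22.7) / 100
}
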