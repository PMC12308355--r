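#' Read and write scale definition files
#'
#' The interchange format is JSON with top-level keys `labels`,
#' `comprehensive` (objects `item_id`, `label`, `text`) and `singles`
#' (objects `scale_id`, `label`, `items` of `item_id`/`text`). Files are
#' structurally validated on read; errors name the offending location.
#' `write_scale_file()` followed by `read_scale_file()` is lossless.
#'
#' @param path file path.
#' @param system a `scale_system`.
#' @return `read_scale_file()` returns a `scale_system`.
#' @export
read_scale_file <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  req <- c("labels", "comprehensive", "singles")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("scale file /", paste(miss, collapse = ", /"),
         ": required key missing", call. = FALSE)
  labels <- vapply(x$labels, as.character, "")
  need_str <- function(obj, key, where) {
    v <- obj[[key]]
    if (is.null(v) || !is.character(as.character(v)) || !nzchar(as.character(v)))
      stop("scale file ", where, "/", key, ": missing or empty", call. = FALSE)
    as.character(v)
  }
  comp <- do.call(rbind, lapply(seq_along(x$comprehensive), function(i) {
    o <- x$comprehensive[[i]]
    where <- sprintf("/comprehensive/%d", i - 1L)
    data.frame(item_id = need_str(o, "item_id", where),
               label = need_str(o, "label", where),
               text = as.character(o$text %||% ""),
               home = "comprehensive",
               scale_id = as.character(o$scale_id %||% "comprehensive"),
               stringsAsFactors = FALSE)
  }))
  sing <- do.call(rbind, lapply(seq_along(x$singles), function(i) {
    s <- x$singles[[i]]
    where <- sprintf("/singles/%d", i - 1L)
    sid <- need_str(s, "scale_id", where)
    lab <- need_str(s, "label", where)
    do.call(rbind, lapply(seq_along(s$items), function(j) {
      o <- s$items[[j]]
      data.frame(item_id = need_str(o, "item_id",
                                    sprintf("%s/items/%d", where, j - 1L)),
                 label = lab,
                 text = as.character(o$text %||% ""),
                 home = "single", scale_id = sid,
                 stringsAsFactors = FALSE)
    }))
  }))
  items <- rbind(comp, sing)
  if (is.null(items)) items <- data.frame()
  if (nrow(items)) {
    dup <- items$item_id[duplicated(items$item_id)]
    if (length(dup))
      stop("scale file: duplicate item_id ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    bad <- setdiff(unique(items$label), labels)
    if (length(bad))
      stop("scale file: item references undeclared label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  scale_system(items, labels = labels)
}

#' @rdname read_scale_file
#' @export
write_scale_file <- function(system, path) {
  stopifnot(inherits(system, "scale_system"))
  comp <- system$items[system$items$home == "comprehensive", ]
  sing <- system$items[system$items$home == "single", ]
  singles <- lapply(unique(sing$scale_id), function(sid) {
    rows <- sing[sing$scale_id == sid, ]
    list(scale_id = sid, label = rows$label[[1L]],
         items = Map(function(id, tx) list(item_id = id, text = tx),
                     rows$item_id, rows$text, USE.NAMES = FALSE))
  })
  out <- list(labels = as.list(system$labels),
              comprehensive = Map(function(id, l, tx, sid)
                list(item_id = id, label = l, text = tx, scale_id = sid),
                comp$item_id, comp$label, comp$text, comp$scale_id,
                USE.NAMES = FALSE),
              singles = singles)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write tabular response and diagnosis data
#'
#' CSV dialect: UTF-8, comma-separated, header row, RFC-4180 quoting.
#' Responses are long form (`respondent_id,item_id,response`); diagnoses
#' are `respondent_id,label,diagnosis` with `positive`/`negative` values.
#'
#' @param path file path.
#' @param df data.frame to write.
#' @return data.frames.
#' @export
read_responses_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(respondent_id = "character",
                                       item_id = "character"))
  check_option_values(df$response)
  df
}

#' @rdname read_responses_csv
#' @export
read_diagnoses_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(respondent_id = "character",
                                       label = "character"))
  if (!all(df$diagnosis %in% c("positive", "negative")))
    stop("diagnosis column must be 'positive'/'negative'", call. = FALSE)
  df
}

#' @rdname read_responses_csv
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write probability indices as auditable JSON
#'
#' Serializes first- and second-order indices together with their
#' provenance counts (numerators and denominators).
#'
#' @param first a `first_order_indices`.
#' @param second a `second_order_indices`.
#' @param path output file.
#' @export
write_indices_json <- function(first, second, path) {
  out <- list(
    first_order = list(index = as.list(first$index),
                       counts = list(N_label = as.list(first$counts$N_label),
                                     NC = first$counts$NC)),
    second_order = lapply(unclass(second), function(sc)
      list(index = as.list(sc$index),
           counts = list(N_item = as.list(sc$counts$N_item),
                         NS = sc$counts$NS))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest
#'
#' Every non-interactive CLI run emits one manifest recording the
#' subcommand, seed, a hash of the effective configuration, digests of the
#' input files, the package version and a timestamp, so identical inputs
#' can be re-run to identical outputs.
#'
#' @param subcommand subcommand name.
#' @param config effective configuration (list).
#' @param seed integer seed.
#' @param inputs character vector of input file paths.
#' @param path output file.
#' @export
write_manifest <- function(subcommand, config, seed, inputs, path) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  on.exit(unlink(tmp))
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(subcommand = subcommand,
                   config_hash = unname(tools::md5sum(tmp)),
                   seed = seed,
                   input_digests = as.list(tools::md5sum(inputs)),
                   package_version = as.character(utils::packageVersion("screentree")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
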