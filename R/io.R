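#' Write a ratings table to CSV
#'
#' Writes the package's ratings dialect: a comment header line embedding
#' the seed and a configuration fingerprint (so every artifact records how
#' it was produced), then columns `subject_id`, `condition`, `domain`,
#' `query_id`, `target`, `evidence`, `rating`. Evidence is serialized as
#' `"X=1,YB=0"`.
#'
#' @param ratings ratings data frame.
#' @param path output file.
#' @param seed seed recorded in the header (default `NA`).
#' @param config object whose fingerprint is recorded (default the ratings
#'   themselves).
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path, seed = NA, config = NULL) {
  cols <- c("subject_id", "condition", "domain", "query_id", "target",
            "evidence", "rating")
  if (!"domain" %in% names(ratings)) ratings$domain <- "unspecified"
  if (!"target" %in% names(ratings)) ratings$target <- NA
  if (!"evidence" %in% names(ratings)) ratings$evidence <- NA
  fp <- config_fingerprint(if (is.null(config)) ratings[cols] else config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mutationsampler ratings seed=%s config_hash=%s",
                     as.character(seed), fp), con)
  utils::write.csv(ratings[cols], con, row.names = FALSE)
  invisible(path)
}

# small stable fingerprint of an R object (hex of a polynomial rolling sum
# over its deparsed form); identifies configs in artifact headers
config_fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  v <- utf8ToInt(s)
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    m <- 2^31 - 1
    for (ci in chunk) h <- (h * 131 + ci) %% m
  }
  sprintf("%08x", h)
}

#' Read and validate a ratings table
#'
#' Reads a CSV of per-subject conditional-probability ratings, optionally
#' renaming external columns and transforming the response scale first, so
#' that differently laid-out deposits can be adapted without code changes.
#' Rows failing validation (ratings outside \[0, 100\], duplicate
#' (subject, query) pairs) are reported with their line numbers.
#'
#' @param path CSV file; lines starting with `#` are ignored.
#' @param mapping optional list with elements `columns` (named character
#'   vector mapping external names to `subject_id`, `condition`,
#'   `query_id`, `rating`, optionally `domain`, `target`, `evidence`),
#'   `rating_transform` (function applied to the rating column, e.g. a
#'   0-1 to 0-100 rescale), and `aggregate` (`TRUE` to average multiple
#'   rows per (subject, query), for per-trial deposits).
#' @param battery optional `query_battery`; if given, every `query_id`
#'   must resolve in it.
#' @return validated ratings data frame.
#' @export
read_ratings <- function(path, mapping = NULL, battery = NULL) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!is.null(mapping$columns)) {
    cm <- mapping$columns
    miss <- setdiff(names(cm), names(df))
    if (length(miss))
      stop("mapped columns absent from file: ", paste(miss, collapse = ", "))
    names(df)[match(names(cm), names(df))] <- unname(cm)
  }
  need <- c("subject_id", "condition", "query_id", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!is.null(mapping$rating_transform))
    df$rating <- mapping$rating_transform(df$rating)
  df$rating <- as.numeric(df$rating)
  bad <- which(is.na(df$rating) | df$rating < 0 | df$rating > 100)
  if (length(bad))
    stop("ratings outside [0,100] (or non-numeric) at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (isTRUE(mapping$aggregate)) {
    agg <- stats::aggregate(rating ~ subject_id + condition + query_id,
                            data = df, FUN = mean)
    keepc <- intersect(c("domain", "target", "evidence"), names(df))
    if (length(keepc)) {
      first <- df[!duplicated(df[, c("subject_id", "query_id")]),
                  c("subject_id", "query_id", keepc)]
      agg <- merge(agg, first, by = c("subject_id", "query_id"),
                   sort = FALSE)
    }
    df <- agg
  }
  dup <- which(duplicated(df[, c("subject_id", "query_id")]))
  if (length(dup))
    stop("duplicate (subject, query) pairs at data row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  if (!is.null(battery)) {
    unknown <- setdiff(unique(df$query_id), battery$id)
    if (length(unknown))
      stop("query ids not in battery: ",
           paste(utils::head(unknown, 10), collapse = ", "))
  }
  df
}

#' Read a network (and optional parameter block) from a YAML config
#'
#' Config layout:
#' ```yaml
#' variables: [X, YA, YB, Z]
#' links:
#'   - [X, YA, generative]
#'   - [X, YB, generative]
#'   - [YA, Z, generative]
#'   - [YB, Z, generative]
#' params:
#'   root_prior: {X: 0.65}
#'   link_weight: {generative: 0.476}   # tied; or a per-link list
#'   exo_weight: 0.454                  # tied; or per-variable map
#' ```
#'
#' @param path YAML file.
#' @return list with `network` ([causal_network()]) and `params`
#'   ([parameterization()] or `NULL` when the config has no `params`
#'   block).
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  links <- do.call(rbind, lapply(cfg$links, function(l)
    data.frame(from = l[[1]], to = l[[2]], polarity = l[[3]])))
  network <- causal_network(unlist(cfg$variables), links)
  params <- NULL
  if (!is.null(cfg$params)) {
    p <- cfg$params
    lw <- p$link_weight
    if (is.list(lw) && is.null(names(lw))) lw <- unlist(lw)
    if (is.list(lw)) lw <- unlist(lw)
    ew <- p$exo_weight
    if (is.list(ew)) ew <- unlist(ew)
    params <- parameterization(network,
                               root_prior = unlist(p$root_prior),
                               link_weight = lw, exo_weight = ew)
  }
  list(network = network, params = params)
}

#' Write a summary report as JSON
#'
#' @param report a list (e.g. from [markov_stats_report()] together with
#'   fit summaries).
#' @param path output file.
#' @param seed seed recorded in the report.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(report, path, seed = NA) {
  report$meta <- list(package = "mutationsampler",
                      version = as.character(utils::packageVersion("mutationsampler")),
                      seed = seed,
                      config_hash = config_fingerprint(report))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
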