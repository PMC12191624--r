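#' Specification for one synthetic subject
#'
#' @param subject_id unique subject identifier.
#' @param condition one of `"Generative"`, `"YA-Inhibitory"`,
#'   `"YB-Inhibitory"` (fixes the network's polarity pattern).
#' @param variant generating model: `"normative"`, `"ms_prototypes"` or
#'   `"ms_noprototypes"`.
#' @param par named true parameters (`wX`, `wgen`, `winh` for inhibitory
#'   conditions, `wexo`, and `lambda` for sampler variants).
#' @param noise_sd response noise standard deviation on the 0-100 scale
#'   (>= 0); noise is Gaussian, clipped to the scale ends.
#' @param domain content-domain label (carried through, no effect on
#'   generation).
#' @param seed integer seed for the subject's noise draws.
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, condition, variant, par, noise_sd,
                         domain = "economics", seed = 1) {
  stopifnot(noise_sd >= 0)
  condition <- match.arg(condition,
                         c("Generative", "YA-Inhibitory", "YB-Inhibitory"))
  variant <- match.arg(variant,
                       c("normative", "ms_prototypes", "ms_noprototypes"))
  structure(list(subject_id = subject_id, condition = condition,
                 variant = variant, par = par, noise_sd = noise_sd,
                 domain = domain, seed = seed),
            class = "subject_spec")
}

#' Generate one synthetic subject's ratings
#'
#' Computes the generating model's predicted probability for every battery
#' query, scales to 0-100, adds Gaussian response noise and clips to
#' \[0, 100\] — the simplest response model consistent with a bounded
#' rating slider. With `noise_sd = 0` the ratings equal the model
#' predictions exactly.
#'
#' @param spec a [subject_spec()].
#' @param network the subject's [causal_network()] (defaults to the
#'   condition's diamond).
#' @param battery the `query_battery` to rate.
#' @return data frame rows: `subject_id`, `condition`, `domain`,
#'   `query_id`, `target`, `evidence`, `rating`, `true_prob`.
#' @export
generate_subject <- function(spec, network = NULL, battery) {
  if (is.null(network)) network <- diamond_network(spec$condition)
  if (spec$variant == "ms_prototypes" &&
      length(derive_prototypes(network)) == 0 &&
      !isTRUE(attr(spec, "force_prototypes")))
    stop("prototype generator requested for a network with no prototypes")
  ms <- model_spec(spec$variant, network)
  miss <- setdiff(ms$par_names, names(spec$par))
  if (length(miss))
    stop("missing true parameters: ", paste(miss, collapse = ", "))
  pred <- make_predictor(ms, battery)(spec$par[ms$par_names])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  rating <- pmin(pmax(100 * pred + stats::rnorm(length(pred),
                                                sd = spec$noise_sd), 0), 100)
  data.frame(subject_id = spec$subject_id, condition = spec$condition,
             domain = spec$domain, query_id = battery$id,
             target = battery$target,
             evidence = vapply(battery$evidence, serialize_evidence, ""),
             rating = as.numeric(rating), true_prob = as.numeric(pred))
}

serialize_evidence <- function(ev) {
  if (!length(ev)) return("")
  paste0(names(ev), "=", as.integer(ev), collapse = ",")
}

parse_evidence <- function(s) {
  if (is.na(s) || s == "") return(NULL)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  vapply(kv, `[`, "", 1))
}

#' Experiment configuration for a synthetic cohort
#'
#' Defaults reproduce the study's between-subject layout: 56 subjects in
#' the all-generative condition and 28 in each one-inhibitory condition,
#' three content-domain labels cycled within condition, 32 queries per
#' subject. Per-subject true parameters are drawn uniformly from ranges
#' bracketing typical fitted values: wX ~ U(0.4, 0.8), wgen ~ U(0.2, 1.0),
#' winh ~ U(-1.0, -0.2), wexo ~ U(0, 1), lambda log-uniform on \[8, 40\].
#' By default the all-generative condition is generated by the
#' prototype-start sampler and the inhibitory conditions by the
#' uniform-start sampler.
#'
#' @param n_per_condition named integer vector of subjects per condition.
#' @param generating_model named character vector mapping condition to
#'   generating variant.
#' @param noise_sd response noise sd (0-100 scale).
#' @param param_ranges named list of length-2 ranges for `wX`, `wgen`,
#'   `winh`, `wexo`, `lambda`.
#' @param seed master seed; expands deterministically to per-subject seeds.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(
    n_per_condition = c("Generative" = 56, "YA-Inhibitory" = 28,
                        "YB-Inhibitory" = 28),
    generating_model = c("Generative" = "ms_prototypes",
                         "YA-Inhibitory" = "ms_noprototypes",
                         "YB-Inhibitory" = "ms_noprototypes"),
    noise_sd = 10,
    param_ranges = list(wX = c(0.4, 0.8), wgen = c(0.2, 1.0),
                        winh = c(-1.0, -0.2), wexo = c(0, 1),
                        lambda = c(8, 40)),
    seed = 1) {
  stopifnot(all(names(n_per_condition) %in%
                  c("Generative", "YA-Inhibitory", "YB-Inhibitory")),
            all(names(n_per_condition) %in% names(generating_model)),
            noise_sd >= 0)
  for (rn in c("wX", "wgen", "winh", "wexo", "lambda")) {
    r <- param_ranges[[rn]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2])
      stop("invalid range for ", rn)
  }
  if (param_ranges$lambda[1] < 1) stop("lambda range must be >= 1")
  structure(list(n_per_condition = n_per_condition,
                 generating_model = generating_model,
                 noise_sd = noise_sd, param_ranges = param_ranges,
                 seed = seed),
            class = "experiment_config")
}

#' Generate a full synthetic cohort
#'
#' Expands an [experiment_config()] into one ratings table covering every
#' (subject, query) pair exactly once. Fully deterministic under the master
#' seed. The per-subject true parameters and generating variants are
#' attached as attribute `truth`.
#'
#' @param config an [experiment_config()].
#' @param battery the `query_battery` (default [default_battery_32()] on
#'   the condition's diamond; the battery is shared across conditions).
#' @return a ratings data frame with attribute `truth`.
#' @export
generate_experiment <- function(config, battery = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(battery))
    battery <- default_battery_32(diamond_network("generative"))
  domains <- c("economics", "meteorology", "sociology")
  rows <- list()
  truth <- list()
  sidx <- 0
  for (cond in names(config$n_per_condition)) {
    network <- diamond_network(cond)
    variant <- config$generating_model[[cond]]
    nms <- model_spec(variant, network)$par_names
    for (i in seq_len(config$n_per_condition[[cond]])) {
      sidx <- sidx + 1
      sseed <- (config$seed * 10007L + sidx * 389L) %% 2147483647L
      old <- .Random.seed_save()
      set.seed(sseed)
      rg <- config$param_ranges
      par <- c(wX = stats::runif(1, rg$wX[1], rg$wX[2]),
               wgen = stats::runif(1, rg$wgen[1], rg$wgen[2]),
               winh = stats::runif(1, rg$winh[1], rg$winh[2]),
               wexo = stats::runif(1, rg$wexo[1], rg$wexo[2]),
               lambda = exp(stats::runif(1, log(rg$lambda[1]),
                                         log(rg$lambda[2]))))
      .Random.seed_restore(old)
      spec <- subject_spec(
        subject_id = sprintf("S%03d", sidx), condition = cond,
        variant = variant, par = par[nms], noise_sd = config$noise_sd,
        domain = domains[(i - 1) %% 3 + 1],
        seed = (sseed + 1L) %% 2147483647L)
      rows[[sidx]] <- generate_subject(spec, network, battery)
      truth[[sidx]] <- data.frame(subject_id = spec$subject_id,
                                  condition = cond, variant = variant,
                                  domain = spec$domain, t(par),
                                  noise_sd = config$noise_sd)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Model- and parameter-recovery experiment
#'
#' Generates a synthetic cohort, fits every model variant to every subject,
#' and reports (a) the model-recovery rate per condition — the fraction of
#' subjects whose generating variant attains the lowest AIC — and (b)
#' parameter-recovery error (bias and RMSE of the generating variant's
#' fitted parameters against truth, including the chain-length bias for
#' prototype-sampler subjects, with lambda summarized on the log scale).
#'
#' @param config an [experiment_config()].
#' @param variants variants to fit (default all three).
#' @param battery the `query_battery`.
#' @param n_starts,seed fitting settings, passed to [fit_cohort()].
#' @return list with `fits`, `truth`, `recovery` (per condition),
#'   `param_recovery` (per condition x parameter), and `summary`
#'   ([compare_models()] output).
#' @export
recovery_experiment <- function(config,
                                variants = c("normative", "ms_prototypes",
                                             "ms_noprototypes"),
                                battery = NULL, n_starts = 20, seed = 1) {
  if (is.null(battery))
    battery <- default_battery_32(diamond_network("generative"))
  ratings <- generate_experiment(config, battery)
  truth <- attr(ratings, "truth")
  fits <- fit_cohort(ratings, variants, battery, n_starts = n_starts,
                     seed = seed)
  # model recovery: generating variant has strictly lowest AIC
  rec <- NULL
  for (cond in unique(truth$condition)) {
    tsub <- truth[truth$condition == cond, ]
    hit <- vapply(tsub$subject_id, function(s) {
      fs <- fits[fits$subject_id == s, ]
      gen <- tsub$variant[tsub$subject_id == s]
      fs$variant[which.min(fs$aic)] == gen
    }, TRUE)
    rec <- rbind(rec, data.frame(condition = cond,
                                 generating = tsub$variant[1],
                                 n = nrow(tsub),
                                 recovery_rate = mean(hit)))
  }
  # parameter recovery under the generating variant's own fit
  pr <- NULL
  for (cond in unique(truth$condition)) {
    tsub <- truth[truth$condition == cond, ]
    gen <- tsub$variant[1]
    fsub <- fits[fits$condition == cond & fits$variant == gen, ]
    fsub <- fsub[match(tsub$subject_id, fsub$subject_id), ]
    for (pn in intersect(c("wX", "wgen", "winh", "wexo", "lambda"),
                         names(fsub))) {
      if (all(is.na(fsub[[pn]]))) next
      if (pn == "lambda") {
        err <- log(fsub[[pn]]) - log(tsub[[pn]])
        scale <- "log"
      } else {
        err <- fsub[[pn]] - tsub[[pn]]
        scale <- "natural"
      }
      pr <- rbind(pr, data.frame(condition = cond, parameter = pn,
                                 scale = scale, bias = mean(err),
                                 rmse = sqrt(mean(err^2)),
                                 median_abs_err = stats::median(abs(err))))
    }
  }
  list(fits = fits, truth = truth, recovery = rec, param_recovery = pr,
       summary = compare_models(fits))
}
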