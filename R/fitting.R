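#' Model specification for per-subject fitting
#'
#' Three model variants are fitted to each subject's ratings:
#' * `"normative"` — the exact causal-graphical-model predictions;
#' * `"ms_prototypes"` — the mutation sampler started at the fixed
#'   all-absent / all-present state pair (the prototype set of an
#'   all-generative structure), with chain length `lambda` as a free
#'   parameter;
#' * `"ms_noprototypes"` — the mutation sampler started at a uniformly
#'   random state, again with free `lambda`.
#'
#' Free parameters are `wX` (root base rate), a single `wgen` tied across
#' all generative links, `winh` (only when the network has an inhibitory
#' link), a single exogenous weight `wexo` tied across non-root variables,
#' and `lambda` (sampler variants only, fitted on the log scale). So the
#' parameter count is 3 or 4 for the normative model (all-generative vs.
#' one-inhibitory network) and 4 or 5 for the sampler variants.
#'
#' @param variant one of `"normative"`, `"ms_prototypes"`,
#'   `"ms_noprototypes"`.
#' @param network the [causal_network()] the subject reasoned about.
#' @return an object of class `model_spec` with fields `variant`,
#'   `par_names`, `lower`, `upper` and `p` (parameter count).
#' @export
model_spec <- function(variant = c("normative", "ms_prototypes",
                                   "ms_noprototypes"),
                       network) {
  variant <- match.arg(variant)
  has_inh <- any(network$links$polarity == "inhibitory")
  nm <- c("wX", "wgen", if (has_inh) "winh", "wexo",
          if (variant != "normative") "lambda")
  bounds <- list(wX = c(0.01, 0.99), wgen = c(0, 5), winh = c(-5, 0),
                 wexo = c(-5, 5), lambda = c(1, 100))
  structure(list(variant = variant, network = network, par_names = nm,
                 lower = vapply(bounds[nm], `[`, 0, 1),
                 upper = vapply(bounds[nm], `[`, 0, 2),
                 p = length(nm)),
            class = "model_spec")
}

# parameterization from a named fitting vector (tied weights)
.par_to_params <- function(network, par) {
  lw <- ifelse(network$links$polarity == "generative",
               par[["wgen"]],
               if ("winh" %in% names(par)) par[["winh"]] else NA_real_)
  parameterization(network, root_prior = par[["wX"]], link_weight = lw,
                   exo_weight = par[["wexo"]])
}

#' Build a fast battery predictor for a model variant
#'
#' Returns `function(par)` mapping a named parameter vector to the
#' variant's predicted probabilities for every battery query. Used by the
#' fitting routines; precomputes state and battery structure once.
#'
#' @param spec a [model_spec()].
#' @param battery a `query_battery`.
#' @param zero_mass_fallback probability for zero-mass evidence.
#' @return a prediction function.
#' @export
make_predictor <- function(spec, battery, zero_mass_fallback = 0.5) {
  network <- spec$network
  vars <- network$variables
  n <- length(vars)
  N <- 2^n
  S <- state_matrix(n)
  Ssign <- 2 * S - 1
  mm <- battery_matrices(network, battery)
  roots <- network$roots
  nonroots <- setdiff(vars, roots)
  # per-non-root parent columns and polarities
  pinfo <- lapply(nonroots, function(v) {
    idx <- which(network$links$to == v)
    list(cols = match(network$links$from[idx], vars),
         gen = network$links$polarity[idx] == "generative",
         self = match(v, vars))
  })
  rootcols <- match(roots, vars)
  # neighbor index matrix for the MH transition matrix
  NB <- sapply(0:(n - 1), function(b) bitwXor(0:(N - 1), 2^b) + 1L)
  offdiag_idx <- cbind(as.vector(NB), rep(seq_len(N), n))
  diag_idx <- cbind(seq_len(N), seq_len(N))

  fast_joint <- function(par) {
    p <- rep(1, N)
    for (rc in rootcols) {
      sc <- S[, rc]
      p <- p * ((1 - sc) + (2 * sc - 1) * par[["wX"]])
    }
    for (pi in pinfo) {
      w <- ifelse(pi$gen, par[["wgen"]], par[["winh"]])
      eta <- as.numeric(Ssign[, pi$cols, drop = FALSE] %*% w) + par[["wexo"]]
      p1 <- stats::plogis(eta)
      sc <- S[, pi$self]
      p <- p * ((1 - sc) + (2 * sc - 1) * p1)
    }
    p
  }

  start <- switch(spec$variant,
    normative = NULL,
    ms_prototypes = {
      d <- numeric(N); d[c(1, N)] <- 0.5; d
    },
    ms_noprototypes = rep(1 / N, N))

  function(par) {
    joint <- fast_joint(par)
    if (spec$variant == "normative") {
      occ <- joint
    } else {
      A <- matrix(joint[NB], N, n) / joint  # proposal density ratios
      A[A > 1] <- 1
      Tm <- matrix(0, N, N)
      Tm[offdiag_idx] <- as.vector(A) / n  # Tm[NB[s,b], s] <- A[s,b]/n
      Tm[diag_idx] <- 1 - rowSums(A) / n
      lam <- par[["lambda"]]
      lo <- floor(lam); w <- lam - lo
      v <- start; acc <- v
      if (lo > 1) for (t in seq_len(lo - 1)) {
        v <- as.numeric(Tm %*% v); acc <- acc + v
      }
      occ <- acc / lo
      if (w > 0) {
        v <- as.numeric(Tm %*% v)
        occ <- (1 - w) * occ + w * ((acc + v) / (lo + 1))
      }
    }
    num <- as.numeric(mm$num %*% occ)
    den <- as.numeric(mm$den %*% occ)
    stats::setNames(ifelse(den == 0, zero_mass_fallback, num / den),
                    battery$id)
  }
}

# box <-> unconstrained transforms (lambda handled on the log scale)
.to_box <- function(z, spec) {
  lo <- spec$lower; hi <- spec$upper
  if ("lambda" %in% spec$par_names) {
    k <- match("lambda", spec$par_names)
    lo[k] <- log(lo[k]); hi[k] <- log(hi[k])
  }
  par <- lo + (hi - lo) * stats::plogis(z)
  if ("lambda" %in% spec$par_names)
    par[match("lambda", spec$par_names)] <-
      exp(par[match("lambda", spec$par_names)])
  stats::setNames(par, spec$par_names)
}
.from_box <- function(par, spec) {
  lo <- spec$lower; hi <- spec$upper
  if ("lambda" %in% spec$par_names) {
    k <- match("lambda", spec$par_names)
    par[k] <- log(par[k]); lo[k] <- log(lo[k]); hi[k] <- log(hi[k])
  }
  u <- pmin(pmax((par - lo) / (hi - lo), 1e-6), 1 - 1e-6)
  stats::qlogis(u)
}

#' Fit one model variant to one subject's ratings
#'
#' Minimizes the sum of squared error between the model's predictions
#' (scaled to 0-100) and the subject's ratings, by seeded multi-start
#' derivative-free search (Nelder-Mead on a logit-transformed box, so every
#' iterate respects the parameter bounds: wX in \[0.01, 0.99\], wgen in
#' \[0, 5\], winh in \[-5, 0\], wexo in \[-5, 5\], lambda in \[1, 100\] on
#' the log scale). Refitting with the same seed reproduces the result
#' exactly.
#'
#' @param ratings named numeric vector of 0-100 ratings (names = query ids)
#'   or a data frame with columns `query_id` and `rating`.
#' @param spec a [model_spec()].
#' @param battery the `query_battery` the ratings answer.
#' @param n_starts number of optimizer starts (>= 1; default 20).
#' @param seed integer seed for the start set.
#' @return an object of class `fit_result`: fitted `par`, `sse`, `n`, `r`
#'   (Pearson correlation of predicted vs. observed), `aic`, `predicted`,
#'   and the spec's `variant`.
#' @export
fit_subject <- function(ratings, spec, battery, n_starts = 20, seed = 1) {
  if (is.data.frame(ratings))
    ratings <- stats::setNames(ratings$rating, ratings$query_id)
  ratings <- ratings[!is.na(ratings)]
  keep <- intersect(battery$id, names(ratings))
  if (length(keep) < spec$p + 2)
    stop("need at least p + 2 = ", spec$p + 2, " rated queries, got ",
         length(keep))
  bsub <- battery[match(keep, battery$id), ]
  class(bsub) <- c("query_battery", "data.frame")
  attr(bsub, "markov_cells") <- attr(battery, "markov_cells")
  y <- as.numeric(ratings[keep])
  predict_fn <- make_predictor(spec, bsub)
  obj <- function(z) {
    pred <- predict_fn(.to_box(z, spec))
    sum((100 * pred - y)^2)
  }
  # seeded start set: one canonical start plus uniform draws in the box
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  canon <- c(wX = 0.65, wgen = 0.5, winh = -0.4, wexo = 0.45, lambda = 17)
  starts <- list(.from_box(canon[spec$par_names], spec))
  if (n_starts > 1) for (i in seq_len(n_starts - 1)) {
    u <- stats::runif(spec$p)
    lo <- spec$lower; hi <- spec$upper
    par0 <- lo + (hi - lo) * u
    if ("lambda" %in% spec$par_names) {
      k <- match("lambda", spec$par_names)
      par0[k] <- exp(log(lo[k]) + (log(hi[k]) - log(lo[k])) * u[k])
    }
    starts[[i + 1]] <- .from_box(stats::setNames(par0, spec$par_names), spec)
  }
  # two-phase multistart: short runs screen every start, the leaders are
  # then polished to convergence
  phase1 <- lapply(starts, function(z0)
    stats::optim(z0, obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8)))
  vals <- vapply(phase1, `[[`, 0, "value")
  keep_k <- utils::head(order(vals), max(3, ceiling(length(starts) / 5)))
  best <- NULL
  for (k in keep_k) {
    fit <- stats::optim(phase1[[k]]$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- .to_box(best$par, spec)
  pred <- predict_fn(par)
  sse <- sum((100 * pred - y)^2)
  r <- if (stats::sd(pred) > 0 && stats::sd(y) > 0)
    stats::cor(100 * pred, y) else NA_real_
  structure(list(variant = spec$variant, par = par, sse = sse,
                 n = length(y), p = spec$p, r = r,
                 aic = aic(sse, length(y), spec$p),
                 predicted = pred, observed = stats::setNames(y, keep)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result [", x$variant, "]\n", sep = "")
  print(round(x$par, 4))
  cat(sprintf("SSE = %.3f  n = %d  R = %.3f  AIC = %.2f\n",
              x$sse, x$n, x$r, x$aic))
  invisible(x)
}

#' AIC for least-squares fits
#'
#' `n * log(SSE/n) + 2 * (p + 1)` with the natural logarithm — the form
#' appropriate for models fitted by least squares, the error variance
#' counting as the extra (+1) parameter. Lower is better.
#'
#' @param sse sum of squared errors (> 0; a perfect fit returns `-Inf` with
#'   a warning).
#' @param n number of fitted data points.
#' @param p number of model parameters.
#' @return the AIC value.
#' @export
aic <- function(sse, n, p) {
  stopifnot(n > 0, sse >= 0)
  if (sse == 0) {
    warning("perfect fit (SSE = 0): AIC is -Inf")
    return(-Inf)
  }
  n * log(sse / n) + 2 * (p + 1)
}

#' Geometric mean of chain-length estimates
#'
#' Chain-length estimates are strongly right-skewed across subjects, so the
#' group summary exponentiates the mean of the logarithms.
#'
#' @param lambdas positive chain lengths.
#' @return the geometric mean.
#' @export
geometric_mean_lambda <- function(lambdas) {
  if (any(lambdas <= 0)) stop("all lambdas must be positive")
  exp(mean(log(lambdas)))
}

#' Summarize per-subject fits across model variants
#'
#' For each condition x variant cell: mean fitted parameters with standard
#' errors, mean correlation, mean AIC, geometric-mean lambda, and the
#' percentage of subjects whose AIC is lowest under that variant (exact
#' ties split equally among the tied variants).
#'
#' @param fits a data frame with one row per subject x variant, as returned
#'   by [fit_cohort()]: columns `subject_id`, `condition`, `variant`,
#'   fitted parameters (`wX`, `wgen`, `winh`, `wexo`, `lambda` as
#'   applicable), `sse`, `r`, `aic`.
#' @return a data frame with one row per condition x variant.
#' @export
compare_models <- function(fits) {
  need <- c("subject_id", "condition", "variant", "aic")
  stopifnot(all(need %in% names(fits)))
  subj_sets <- tapply(fits$subject_id, fits$variant, function(s) sort(unique(s)))
  if (length(unique(lapply(subj_sets, paste, collapse = "|"))) != 1)
    stop("every subject must be fitted under every variant")
  # per-subject best-fit weight, ties split equally
  fits$best_wt <- 0
  for (s in unique(fits$subject_id)) {
    rows <- which(fits$subject_id == s)
    a <- fits$aic[rows]
    winners <- rows[abs(a - min(a)) < 1e-9]
    fits$best_wt[winners] <- 1 / length(winners)
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  cells <- unique(fits[, c("condition", "variant")])
  out <- NULL
  for (i in seq_len(nrow(cells))) {
    sub <- fits[fits$condition == cells$condition[i] &
                fits$variant == cells$variant[i], ]
    row <- data.frame(condition = cells$condition[i],
                      variant = cells$variant[i],
                      n_subjects = nrow(sub))
    for (pn in c("wX", "wgen", "winh", "wexo")) {
      if (pn %in% names(sub) && !all(is.na(sub[[pn]]))) {
        row[[paste0("mean_", pn)]] <- mean(sub[[pn]], na.rm = TRUE)
        row[[paste0("se_", pn)]] <- se(sub[[pn]][!is.na(sub[[pn]])])
      }
    }
    if ("lambda" %in% names(sub) && !all(is.na(sub$lambda)))
      row$geomean_lambda <- geometric_mean_lambda(sub$lambda[!is.na(sub$lambda)])
    row$mean_r <- mean(sub$r, na.rm = TRUE)
    row$mean_aic <- mean(sub$aic)
    row$pct_best <- 100 * sum(sub$best_wt) / nrow(sub)
    out <- if (is.null(out)) row else merge(out, row, all = TRUE, sort = FALSE)
  }
  out[order(out$condition, out$variant), ]
}

#' Fit several model variants to every subject in a ratings table
#'
#' Loops [fit_subject()] over subjects and variants. The network for each
#' subject is chosen from its condition label via [diamond_network()]
#' unless an explicit `network` is supplied.
#'
#' @param ratings a ratings table (data frame with `subject_id`,
#'   `condition`, `query_id`, `rating`).
#' @param variants character vector of [model_spec()] variants.
#' @param battery the `query_battery`.
#' @param network optional fixed network overriding per-condition lookup.
#' @param n_starts,seed passed to [fit_subject()]; each subject x variant
#'   gets a distinct seed derived from `seed`.
#' @return a data frame with one row per subject x variant.
#' @export
fit_cohort <- function(ratings, variants = c("normative", "ms_prototypes",
                                             "ms_noprototypes"),
                       battery, network = NULL, n_starts = 20, seed = 1) {
  subjects <- unique(ratings$subject_id)
  out <- vector("list", length(subjects) * length(variants))
  k <- 0
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    sub <- ratings[ratings$subject_id == s, ]
    cond <- sub$condition[1]
    net <- if (is.null(network)) diamond_network(cond) else network
    for (vi in seq_along(variants)) {
      v <- variants[vi]
      spec <- model_spec(v, net)
      fit <- fit_subject(stats::setNames(sub$rating, sub$query_id),
                         spec, battery, n_starts = n_starts,
                         seed = (seed * 7919L + si * 131L + vi) %% 2147483647L)
      k <- k + 1
      row <- data.frame(subject_id = s, condition = cond, variant = v,
                        sse = fit$sse, n = fit$n, p = fit$p, r = fit$r,
                        aic = fit$aic)
      for (pn in names(fit$par)) row[[pn]] <- fit$par[[pn]]
      out[[k]] <- row
    }
  }
  merge_rows(out)
}

# rbind data frames with non-identical columns (missing filled with NA)
merge_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  }))
}
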