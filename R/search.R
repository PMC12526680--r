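#' Hyperparameter search-space domains
#'
#' `param_set` is a finite set of values (the only domain grid search
#' accepts), `param_int` an inclusive integer range, and `param_loguniform` a
#' continuous range sampled uniformly on the log scale (for scale parameters
#' such as learning rates or regularisation strengths).
#'
#' @param values vector of allowed values.
#' @param lower,upper range bounds (`lower > 0` for log-uniform).
#' @return a domain object used inside a named search-space list.
#' @name search_space
NULL

#' @rdname search_space
#' @export
param_set <- function(values) {
  stopifnot(length(values) >= 1)
  structure(list(values = values), class = c("param_set", "param_domain"))
}

#' @rdname search_space
#' @export
param_int <- function(lower, upper) {
  stopifnot(lower <= upper)
  structure(list(lower = as.integer(lower), upper = as.integer(upper)),
            class = c("param_int", "param_domain"))
}

#' @rdname search_space
#' @export
param_loguniform <- function(lower, upper) {
  stopifnot(lower > 0, lower < upper)
  structure(list(lower = lower, upper = upper),
            class = c("param_loguniform", "param_domain"))
}

sample_domain <- function(dom) {
  if (inherits(dom, "param_set")) {
    dom$values[[sample.int(length(dom$values), 1)]]
  } else if (inherits(dom, "param_int")) {
    sample(seq.int(dom$lower, dom$upper), 1)
  } else {
    exp(stats::runif(1, log(dom$lower), log(dom$upper)))
  }
}

domain_values <- function(dom) {
  if (inherits(dom, "param_set")) dom$values
  else if (inherits(dom, "param_int")) seq.int(dom$lower, dom$upper)
  else stop("continuous domain passed to grid search; grids require finite ",
            "sets", call. = FALSE)
}

in_domain <- function(dom, x) {
  if (inherits(dom, "param_set")) x %in% dom$values
  else x >= dom$lower && x <= dom$upper
}

## Adaptive strategy: a compact tree-structured-Parzen-style sampler. After a
## random startup phase, trials are split at the gamma quantile into "good"
## and "bad"; candidates are drawn from a kernel model of the good set and
## ranked by the good/bad density ratio.
tpe_propose <- function(space, history, values_list, gamma = 0.25,
                        n_candidates = 24) {
  n_done <- length(values_list[[1]]$trial_values)
  ord <- order(values_list[[1]]$trial_values, decreasing = TRUE)
  n_good <- max(1L, ceiling(gamma * n_done))
  good <- ord[seq_len(n_good)]
  bad <- if (n_done > n_good) ord[(n_good + 1):n_done] else ord

  score_one <- function(dom, obs_good, obs_bad, x) {
    if (inherits(dom, "param_set")) {
      K <- length(dom$values)
      lg <- (sum(obs_good == x) + 1) / (length(obs_good) + K)
      lb <- (sum(obs_bad == x) + 1) / (length(obs_bad) + K)
      log(lg) - log(lb)
    } else {
      trans <- if (inherits(dom, "param_loguniform")) log else identity
      span <- trans(dom$upper) - trans(dom$lower)
      kde <- function(obs, xx) {
        bw <- stats::sd(trans(obs))
        if (!is.finite(bw) || bw <= 0) bw <- span / 8
        mean(stats::dnorm(trans(xx), trans(obs), bw)) + 1e-12
      }
      log(kde(obs_good, x)) - log(kde(obs_bad, x))
    }
  }

  draw_one <- function(dom, obs_good) {
    if (inherits(dom, "param_set")) {
      K <- length(dom$values)
      wts <- vapply(dom$values,
                    function(v) sum(obs_good == v) + 1, numeric(1))
      dom$values[[sample.int(K, 1, prob = wts)]]
    } else {
      trans <- if (inherits(dom, "param_loguniform")) log else identity
      inv <- if (inherits(dom, "param_loguniform")) exp else identity
      span <- trans(dom$upper) - trans(dom$lower)
      bw <- stats::sd(trans(obs_good))
      if (!is.finite(bw) || bw <= 0) bw <- span / 8
      centre <- trans(obs_good[sample.int(length(obs_good), 1)])
      x <- inv(min(max(stats::rnorm(1, centre, bw), trans(dom$lower)),
                   trans(dom$upper)))
      if (inherits(dom, "param_int")) as.integer(round(x)) else x
    }
  }

  best_cand <- NULL
  best_score <- -Inf
  for (k in seq_len(n_candidates)) {
    cand <- list()
    score <- 0
    for (nm in names(space)) {
      dom <- space[[nm]]
      obs <- history[[nm]]
      cand[[nm]] <- draw_one(dom, obs[good])
      score <- score + score_one(dom, obs[good], obs[bad], cand[[nm]])
    }
    if (score > best_score) {
      best_score <- score
      best_cand <- cand
    }
  }
  best_cand
}

#' Hyperparameter search: grid, random, or adaptive
#'
#' Grid search enumerates the full Cartesian product of finite domains (the
#' `budget` is ignored; continuous domains are an error). Random search draws
#' `budget` i.i.d. configurations. Adaptive search performs sequential
#' model-based sampling (a tree-structured-Parzen-style good/bad density
#' ratio) after a random startup phase. All strategies are deterministic for
#' a fixed seed; the best trial is the argmax of the objective, ties broken
#' by the earliest trial.
#'
#' @param strategy `"grid"`, `"random"` or `"adaptive"`.
#' @param space named list of domains ([param_set], [param_int],
#'   [param_loguniform]).
#' @param objective `function(params)` (named list) returning a scalar to
#'   maximise, e.g. a CV mean accuracy.
#' @param budget number of trials (random/adaptive).
#' @param seed integer RNG seed.
#' @return list with `best` (params, value, trial) and `history` (data.frame
#'   of sampled parameters, value, trial, strategy).
#' @export
run_search <- function(strategy = c("grid", "random", "adaptive"), space,
                       objective, budget = 20, seed = 42) {
  strategy <- match.arg(strategy)
  stopifnot(length(space) >= 1, !is.null(names(space)),
            all(nzchar(names(space))))
  if (strategy != "grid" && budget < 1) {
    stop("budget must be at least 1", call. = FALSE)
  }
  set.seed(seed)

  trials <- if (strategy == "grid") {
    grid <- expand.grid(lapply(space, domain_values),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  } else {
    NULL
  }

  n_trials <- if (strategy == "grid") length(trials) else budget
  n_startup <- if (strategy == "adaptive") max(1L, min(5L, budget)) else 0L
  history <- lapply(space, function(d) vector(mode = "list", n_trials))
  values <- numeric(n_trials)

  get_params <- function(t) {
    if (strategy == "grid") return(trials[[t]])
    if (strategy == "random" || t <= n_startup) {
      return(lapply(space, sample_domain))
    }
    obs <- lapply(names(space), function(nm) {
      vapply(history[[nm]][seq_len(t - 1)],
             function(v) if (is.numeric(v)) v else NA_real_, numeric(1))
    })
    names(obs) <- names(space)
    # keep raw (possibly non-numeric) observations for param_set domains
    for (nm in names(space)) {
      if (inherits(space[[nm]], "param_set")) {
        obs[[nm]] <- unlist(history[[nm]][seq_len(t - 1)])
      }
    }
    tpe_propose(space, obs,
                list(list(trial_values = values[seq_len(t - 1)])))
  }

  for (t in seq_len(n_trials)) {
    params <- get_params(t)
    for (nm in names(space)) {
      if (!in_domain(space[[nm]], params[[nm]])) {
        stop("sampled value out of domain for '", nm, "'", call. = FALSE)
      }
      history[[nm]][[t]] <- params[[nm]]
    }
    values[t] <- objective(params)
  }

  hist_df <- as.data.frame(lapply(history, function(col) {
    simplify2array(lapply(col, identity))
  }), stringsAsFactors = FALSE)
  hist_df$value <- values
  hist_df$trial <- seq_len(n_trials)
  hist_df$strategy <- strategy
  best_t <- which.max(values)           # which.max takes the earliest tie
  best_params <- lapply(history, function(col) col[[best_t]])
  list(best = list(params = best_params, value = values[best_t],
                   trial = best_t, strategy = strategy, seed = seed),
       history = hist_df)
}
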