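#' Bundle of all model parameters
#'
#' @param rates a [tn_rates()] (gain/loss rates and root prior).
#' @param seq_params a [tn_seq_params()] (`q` and the calling threshold).
#' @param expr_params a [tn_expr_params()] (per-species theta0/theta1).
#' @param weight nonnegative exponent on the expression likelihood; larger
#'   values weight expression more relative to sequence. `weight = 0`
#'   removes expression from the model entirely.
#' @return An object of class `tn_params`.
#' @export
tn_params <- function(rates, seq_params, expr_params, weight = 1) {
  stopifnot(inherits(rates, "tn_rates"), inherits(seq_params, "tn_seq_params"),
            inherits(expr_params, "tn_expr_params"))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0)
    stop_tn("'weight' must be a single nonnegative number")
  structure(list(rates = rates, seq = seq_params, expr = expr_params,
                 weight = weight), class = "tn_params")
}

#' @export
print.tn_params <- function(x, ...) {
  cat("tn_params:\n  ")
  print(x$rates)
  cat(sprintf("  q = %.6g, weight = %.3g\n", x$seq$q, x$weight))
  for (sp in names(x$expr$theta0))
    cat(sprintf("  %s: K = %d, max theta1 = %.3f (cluster %d)\n", sp,
                x$expr$K[[sp]], max(x$expr$theta1[[sp]]),
                which.max(x$expr$theta1[[sp]])))
  invisible(x)
}

# per-species per-state emission log-likelihood matrices (M x N)
emission_loglik <- function(data, params, mode = "both") {
  M <- n_groups(data)
  N <- length(data$species)
  S0 <- S1 <- matrix(0, M, N, dimnames = list(data$groups, data$species))
  if (mode != "expr") {
    q <- params$seq$q
    S0 <- S0 + data$log_bgp
    S1 <- S1 + data$log_bgp + data$n_background * log(1 - q) +
      data$n_motifs * log(q) + data$log_r
  }
  if (mode != "seq" && params$weight > 0) {
    for (j in seq_len(N)) {
      sp <- data$species[j]
      lab <- data$labels[, j]
      S0[, j] <- S0[, j] + params$weight * log(params$expr$theta0[[sp]][lab])
      S1[, j] <- S1[, j] + params$weight * log(params$expr$theta1[[sp]][lab])
    }
  }
  list(S0 = S0, S1 = S1)
}

# E-step core: log-posterior over leaf configs for every group
posterior_core <- function(data, tree, params, mode = "both",
                           prior_tab = NULL) {
  tree <- tn_tree(tree)
  if (!identical(tree$species, data$species))
    stop_tn("tree leaf species must match the data's species")
  if (is.null(prior_tab)) prior_tab <- config_prior_table(tree, params$rates)
  C <- prior_tab$configs
  lp_prior <- log(prior_tab$prior)
  em <- emission_loglik(data, params, mode)
  lp <- em$S0 %*% t(1 - C) + em$S1 %*% t(C)
  lp <- sweep(lp, 2L, lp_prior, `+`)
  ll <- row_logsumexp(lp)
  list(logpost = lp - ll, loglik = ll, configs = C, prior = prior_tab$prior)
}

#' Joint log-likelihood of ortholog groups under the model
#'
#' For each group: `log sum_configs P(config | tree, rates) *
#' prod_species P(S | z)^1 * P(E | z)^weight`, computed in log space with
#' log-sum-exp. The dataset log-likelihood is the sum over groups.
#'
#' @param data a [tn_data_from_windows()] / [prepare_tn_data()] object (one
#'   or many groups).
#' @param tree a [tn_tree()].
#' @param params a [tn_params()].
#' @param mode `"both"` (default), `"seq"` (ignore expression) or `"expr"`
#'   (ignore sequence).
#' @return Numeric vector of per-group log-likelihoods (named by group).
#' @export
group_loglik <- function(data, tree, params, mode = c("both", "seq", "expr")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "tn_data"), inherits(params, "tn_params"))
  pc <- posterior_core(data, tree, params, mode)
  stats::setNames(pc$loglik, data$groups)
}

#' Posterior over leaf regulatory-state configurations for each group
#'
#' Bayes' rule over all `2^N` configurations: prior from the phylogenetic
#' chain, emissions from sequence scans and expression labels. The MAP
#' configuration breaks ties toward the lexicographically smallest
#' configuration.
#'
#' @inheritParams group_loglik
#' @return A list with `posterior` (M x 2^N matrix), `configs`,
#'   `marginal` (M x N matrix of per-species P(Z = 1)), `map` (M x N 0/1
#'   matrix), `loglik`.
#' @export
group_posterior <- function(data, tree, params, mode = c("both", "seq", "expr")) {
  mode <- match.arg(mode)
  pc <- posterior_core(data, tree, params, mode)
  post <- exp(pc$logpost)
  map_idx <- apply(pc$logpost, 1L, which.max)  # first max = lex smallest
  list(posterior = post,
       configs = pc$configs,
       marginal = post %*% pc$configs,
       map = pc$configs[map_idx, , drop = FALSE],
       loglik = stats::setNames(pc$loglik, data$groups))
}

# expected log prior of configs, negated, as a function of rate parameters
make_rates_objective <- function(tree, W, tied_root) {
  lo <- log(1e-6); hi <- log(1e3)
  function(par) {
    if (any(par[1:2] < lo) || any(par[1:2] > hi)) return(1e12)
    pi_root <- if (tied_root) "stationary" else stats::plogis(par[3L])
    r <- tn_rates(exp(par[1L]), exp(par[2L]), pi_root)
    pr <- config_prior_table(tree, r)$prior
    if (any(pr <= 0)) return(1e12)
    -sum(W * log(pr))
  }
}

# data-driven initialization of the parameters
init_params <- function(data, tree, weight, smoothing, tie_root) {
  tree <- tn_tree(tree)
  depth <- mean(ape::node.depth.edgelength(tree$phylo)[seq_len(tree$n_tips)])
  if (!is.finite(depth) || depth <= 0) depth <- 1
  rates <- tn_rates(0.7 / depth, 0.7 / depth,
                    if (tie_root) "stationary" else 0.5)
  qraw <- sum(data$n_motifs) /
    max(sum(data$n_motifs + data$n_background), 1)
  q0 <- min(max(2 * qraw, 1e-4), 0.2)
  sp0 <- data$seq_params
  sp0$q <- q0
  # seed theta by soft responsibilities from the sequence evidence alone
  delta <- data$n_background * log(1 - q0) + data$n_motifs * log(q0) + data$log_r
  r <- stats::plogis(delta - stats::median(delta))
  theta0 <- theta1 <- list()
  for (j in seq_along(data$species)) {
    sp <- data$species[j]
    theta1[[sp]] <- estimate_multinomial(data$labels[, j], r[, j],
                                         K = data$K[[sp]], smoothing = smoothing)
    theta0[[sp]] <- estimate_multinomial(data$labels[, j], 1 - r[, j],
                                         K = data$K[[sp]], smoothing = smoothing)
  }
  tn_params(rates, sp0, tn_expr_params(theta0, theta1), weight)
}

jitter_params <- function(params, data, seed, smoothing) {
  set.seed(seed)
  r <- params$rates
  rates <- tn_rates(r$lam * exp(stats::runif(1, -1, 1)),
                    r$mu * exp(stats::runif(1, -1, 1)),
                    if (r$tied_root) "stationary" else stats::runif(1, 0.2, 0.8))
  sp <- params$seq
  sp$q <- min(max(sp$q * exp(stats::runif(1, -1, 1)), 1e-6), 0.3)
  theta0 <- theta1 <- list()
  for (s in names(params$expr$theta0)) {
    K <- params$expr$K[[s]]
    d1 <- stats::rgamma(K, 1) ; d0 <- stats::rgamma(K, 1)
    theta1[[s]] <- (params$expr$theta1[[s]] + d1 / sum(d1)) / 2
    theta0[[s]] <- (params$expr$theta0[[s]] + d0 / sum(d0)) / 2
  }
  tn_params(rates, sp, tn_expr_params(theta0, theta1), params$weight)
}

#' Fit the transcription-network evolution model by EM
#'
#' Maximizes the weighted joint likelihood of sequence scans and
#' expression labels over all ortholog groups. The E-step computes each
#' group's posterior over leaf regulatory-state configurations; the M-step
#' updates `q` and the expression multinomials in closed form from the
#' expected sufficient statistics, and improves the rate parameters
#' (lambda, mu, root prior) by bounded Nelder-Mead maximization of the
#' expected log configuration-prior, started at the current values and
#' accepted only on improvement, which preserves the EM monotonicity
#' guarantee. The expression `weight` is a fixed tuning input, never
#' estimated.
#'
#' @param data a `tn_data`.
#' @param tree a [tn_tree()] whose leaves match `data$species`.
#' @param weight fixed expression weight (>= 0); default 1.
#' @param mode `"both"`, `"seq"` (sequence-only model) or `"expr"`
#'   (expression-only model).
#' @param init optional [tn_params()] starting point; default is a
#'   data-driven moment-style initialization.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` (default 1e-6) or after `max_iter` iterations.
#' @param fixed character subset of `c("rates", "q", "theta")` held at
#'   their initial values.
#' @param tie_root tie the root prior to the stationary distribution
#'   lambda/(lambda+mu) instead of estimating it freely.
#' @param smoothing pseudocount per cluster in the theta updates.
#' @param n_restarts number of EM runs (first from `init`, the rest from
#'   seeded jitters of it); the best final likelihood is kept.
#' @param seed seed for the restart jitters.
#' @param drop_singletons drop groups whose gene sits in a singleton
#'   cluster in some species (requires cluster sizes; labels equal to a
#'   cluster observed only once in the data column are treated as
#'   singletons). Default FALSE: the caller curates the data.
#' @return An object of class `tn_fit` with elements `params`, `trace`
#'   (the EM objective per iteration: log-likelihood plus the theta
#'   smoothing regularizer, which is the quantity EM monotonically
#'   improves), `loglik` (raw data log-likelihood), `posterior` (training-data
#'   [group_posterior()]), `converged`, `n_iter`, `mode`, `data`, `tree`.
#' @seealso [predict.tn_fit()], [infer_states()], [rewiring_rate()]
#' @export
tn_fit <- function(data, tree, weight = 1, mode = c("both", "seq", "expr"),
                   init = NULL, max_iter = 100L, tol = 1e-6,
                   fixed = character(), tie_root = FALSE, smoothing = 0.5,
                   n_restarts = 1L, seed = 1L, drop_singletons = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "tn_data"))
  tree <- tn_tree(tree)
  if (!identical(tree$species, data$species))
    stop_tn("tree leaf species must match the data's species")
  if (n_groups(data) < 2L) stop_tn("need at least 2 ortholog groups to fit")
  if (!all(fixed %in% c("rates", "q", "theta")))
    stop_tn("'fixed' must be a subset of c(\"rates\", \"q\", \"theta\")")
  if (mode == "seq") weight <- 0
  if (drop_singletons) {
    single <- rowSums(sapply(seq_along(data$species), function(j) {
      tab <- table(data$labels[, j])
      data$labels[, j] %in% as.integer(names(tab)[tab == 1L])
    })) > 0
    if (any(single)) data <- data[!single]
  }

  if (is.null(init)) init <- init_params(data, tree, weight, smoothing, tie_root)
  init$weight <- weight

  # Dirichlet-style regularizer on the thetas; the EM objective is
  # loglik + theta_penalty, which the trace tracks and which is monotone.
  theta_penalty <- function(params) {
    if (mode == "seq" || weight == 0 || smoothing == 0) return(0)
    smoothing * sum(vapply(names(params$expr$theta0), function(sp)
      sum(log(params$expr$theta0[[sp]])) + sum(log(params$expr$theta1[[sp]])),
      0))
  }

  run_one <- function(start) {
    params <- start
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      prior_tab <- config_prior_table(tree, params$rates)
      pc <- posterior_core(data, tree, params, mode, prior_tab)
      ll <- sum(pc$loglik) + theta_penalty(params)
      trace <- c(trace, ll)
      if (it > 1L && ll - trace[it - 1L] < tol) {
        converged <- TRUE
        break
      }
      post <- exp(pc$logpost)
      Ez <- post %*% pc$configs                     # M x N marginal P(Z=1)
      Ez[] <- pmin(pmax(Ez, 0), 1)                  # guard rounding overshoot

      if (mode != "expr" && !"q" %in% fixed) {
        num <- sum(Ez * data$n_motifs)
        den <- sum(Ez * (data$n_motifs + data$n_background))
        if (den > 0) params$seq$q <- min(max(num / den, 1e-8), 0.999)
      }
      if (mode != "seq" && weight > 0 && !"theta" %in% fixed) {
        # pseudocount scaled by the weight so that the update maximizes the
        # penalized objective block w * E[log theta] + smoothing * log theta
        for (j in seq_along(data$species)) {
          sp <- data$species[j]
          params$expr$theta1[[sp]] <- estimate_multinomial(
            data$labels[, j], Ez[, j], K = data$K[[sp]],
            smoothing = smoothing / weight)
          params$expr$theta0[[sp]] <- estimate_multinomial(
            data$labels[, j], 1 - Ez[, j], K = data$K[[sp]],
            smoothing = smoothing / weight)
        }
      }
      if (!"rates" %in% fixed) {
        W <- colSums(post)
        obj <- make_rates_objective(tree, W, params$rates$tied_root)
        par0 <- c(log(params$rates$lam), log(params$rates$mu))
        if (!params$rates$tied_root)
          par0 <- c(par0, stats::qlogis(min(max(params$rates$pi_root, 1e-6), 1 - 1e-6)))
        opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                            control = list(maxit = 300L))
        if (opt$value < obj(par0) - 1e-12) {
          params$rates <- tn_rates(
            exp(opt$par[1L]), exp(opt$par[2L]),
            if (params$rates$tied_root) "stationary"
            else stats::plogis(opt$par[3L]))
        }
      }
      if (!is.finite(ll))
        stop_tn("non-finite log-likelihood during EM; check the input data")
    }
    list(params = params, trace = trace, loglik = trace[length(trace)],
         converged = converged, n_iter = length(trace))
  }

  best <- run_one(init)
  if (n_restarts > 1L) {
    for (r in 2:n_restarts) {
      alt <- run_one(jitter_params(init, data, derive_seed(seed, paste0("restart", r)),
                                   smoothing))
      if (alt$loglik > best$loglik) best <- alt
    }
  }

  out <- best
  out$mode <- mode
  out$weight <- weight
  out$data <- data
  out$tree <- tree
  out$posterior <- group_posterior(data, tree, out$params, mode)
  out$loglik <- sum(out$posterior$loglik)  # raw data log-likelihood
  class(out) <- "tn_fit"
  out
}

#' @export
print.tn_fit <- function(x, ...) {
  cat(sprintf("tn_fit (%s): %d groups x %d species, logLik = %.4f\n",
              x$mode, n_groups(x$data), length(x$data$species), x$loglik))
  cat(sprintf("  %d EM iterations (%s)\n", x$n_iter,
              if (x$converged) "converged" else "iteration limit"))
  print(x$params)
  invisible(x)
}

#' @export
coef.tn_fit <- function(object, ...) {
  c(lam = object$params$rates$lam, mu = object$params$rates$mu,
    pi_root = object$params$rates$pi_root, q = object$params$seq$q,
    weight = object$weight)
}

#' @export
logLik.tn_fit <- function(object, ...) {
  npar <- 3L + 1L +
    sum(2L * (object$params$expr$K - 1L))
  structure(object$loglik, df = npar, nobs = n_groups(object$data),
            class = "logLik")
}

#' @export
summary.tn_fit <- function(object, ...) {
  st <- infer_states(object$data, object$tree, object$params, mode = object$mode)
  structure(list(fit = object, states = st,
                 rewiring = rewiring_rate(st)), class = "summary.tn_fit")
}

#' @export
print.summary.tn_fit <- function(x, ...) {
  print(x$fit)
  cat("\nConservation of inferred TF-target links:\n")
  print(x$rewiring)
  invisible(x)
}

#' @export
plot.tn_fit <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
                 xlab = "EM iteration", ylab = "log-likelihood", ...)
  invisible(x)
}

#' @export
fitted.tn_fit <- function(object, ...) {
  object$posterior$marginal
}

#' Predict regulatory states for (new) ortholog groups
#'
#' @param object a [tn_fit()].
#' @param newdata a `tn_data`; default the training data.
#' @param ... unused.
#' @return A [tn_states] object (MAP configuration, per-species marginals,
#'   conservation category per group).
#' @export
predict.tn_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  infer_states(newdata, object$tree, object$params, mode = object$mode)
}

#' Simulate datasets from a fitted model
#'
#' Draws regulatory states from the fitted phylogenetic chain, promoter
#' windows from the fitted scan model (motifs planted at rate `q` from the
#' data's PSSM), and cluster labels from the fitted multinomials.
#'
#' @param object a [tn_fit()].
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param M groups per dataset; default the training size.
#' @param window_length window length in bp; default the training window
#'   length.
#' @param ... unused.
#' @return A list of `tn_sim` datasets (length `nsim`).
#' @export
simulate.tn_fit <- function(object, nsim = 1, seed = 1L, M = NULL,
                            window_length = NULL, ...) {
  if (is.null(M)) M <- n_groups(object$data)
  if (is.null(window_length))
    window_length <- nchar(object$data$windows[1L, 1L])
  lapply(seq_len(nsim), function(i) {
    simulate_from_params(
      tree = object$tree, params = object$params, M = M,
      pssm = object$data$pssm, window_length = window_length,
      seed = derive_seed(seed, paste0("simfit", i)))
  })
}

#' Infer MAP regulatory states and marginals under given parameters
#'
#' Deterministic decoding: posterior over all leaf configurations, MAP by
#' argmax (ties to the lexicographically smallest configuration), and
#' per-species marginal target probabilities.
#'
#' @inheritParams group_loglik
#' @return A `tn_states` object.
#' @export
infer_states <- function(data, tree, params, mode = c("both", "seq", "expr")) {
  mode <- match.arg(mode)
  gp <- group_posterior(data, tree, params, mode)
  new_tn_states(gp, data)
}
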