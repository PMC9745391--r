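#' MCMC settings
#'
#' Desk-scale defaults (3 chains of 20,000 iterations, 5,000 burn-in,
#' thin 5) suit the slice-within-Gibbs sampler, whose draws are much less
#' autocorrelated than a generic one-node-at-a-time sampler; the long-run
#' settings used for multi-landscape field datasets (3 chains of
#' 1,000,000, 200,000 burn-in, thin 80, i.e. 30,000 retained draws) are
#' available by argument.
#'
#' @param chains number of chains (>= 2 so Rhat is defined).
#' @param iterations total iterations per chain.
#' @param burn_in discarded initial iterations (< iterations).
#' @param thin keep every thin-th post-burn-in draw (>= 1).
#' @param seed integer seed controlling initial values and all MCMC
#'   randomness; identical settings and seed give identical draws.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, iterations = 20000, burn_in = 5000,
                          thin = 5, seed = 1) {
  stopifnot(chains >= 1, burn_in >= 0, burn_in < iterations, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Retained draw count implied by MCMC settings
#'
#' `chains * (iterations - burn_in) / thin`, the number of posterior
#' draws kept across all chains.
#'
#' @param settings an `mcmc_settings`.
#' @return integer draw count.
#' @export
retained_draws <- function(settings) {
  as.integer(settings$chains *
               ((settings$iterations - settings$burn_in) %/% settings$thin))
}

#' Fit the two-species co-abundance model by MCMC
#'
#' Runs the package's slice-within-Gibbs sampler: latent abundances are
#' updated by exact categorical draws over `0..K`, continuous parameters
#' (including the interaction delta and, when enabled, every ODRE value)
#' by slice sampling. Because the dominant species' latent abundance is a
#' sampled state feeding the subordinate's expected count, the posterior
#' of delta propagates the dominant species' estimation uncertainty.
#'
#' @param data a [coabund_data()] bundle.
#' @param spec a [model_spec()].
#' @param settings an [mcmc_settings()].
#' @param monitor_latent also store draws of latent `N` and (when the
#'   ODRE is on) `eps`; required by [posterior_predictive_check()].
#'   Default TRUE.
#' @return object of class `coabund_fit` with `draws` array
#'   `[draw, chain, parameter]` (dimnames name the parameters), the
#'   resolved truncation bound `K`, and the inputs.
#' @export
fit_coabundance <- function(data, spec = model_spec(),
                            settings = mcmc_settings(),
                            monitor_latent = TRUE) {
  stopifnot(inherits(data, "coabund_data"), inherits(spec, "model_spec"),
            inherits(settings, "mcmc_settings"))
  hist <- data$history
  J <- length(hist$units); O <- dim(hist$counts)[3L]
  C <- ncol(data$covariates$values)
  L <- length(data$covariates$landscape_names)
  K <- resolve_K(spec, hist)
  obs <- hist$counts
  obs_max <- if (any(hist$mask)) max(obs[hist$mask]) else 0L
  if (obs_max > K) stop("K smaller than the largest observed count")

  n_arr <- array(-1L, c(2L, J, O))
  n_arr[hist$mask] <- obs[hist$mask]
  # the C++ state is laid out occasion-fastest: [i][j][k] with flat index
  # k + O*j + O*J*i, so permute before flattening
  n_flat <- as.integer(aperm(n_arr, c(3L, 2L, 1L)))
  Z <- data$informant$Z
  storage.mode(Z) <- "integer"

  cspec <- list(K = K, izip = (spec$abundance == "izip"),
                binom = (spec$detection == "binomial"), odre = spec$odre,
                eps_p = spec$eps_p, coef_sd = spec$prior_coef_sd,
                sd_upper = spec$prior_sd_upper)

  set.seed(settings$seed)
  chains <- vector("list", settings$chains)
  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(settings$chains)) {
    init <- draw_inits(data, spec, J, C, L, K)
    check_init(data, spec, init, ch)
    res <- .run_chain(n_flat, dim(n_arr), Z,
                      data$covariates$values,
                      as.integer(data$covariates$landscape_index),
                      data$covariates$effort_std, cspec, init,
                      settings$iterations, settings$burn_in, settings$thin,
                      monitor_latent)
    chains[[ch]] <- res$draws
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  nm <- par_names(data, spec, monitor_latent)
  n_save <- nrow(chains[[1L]])
  draws <- array(NA_real_, c(n_save, settings$chains, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  for (ch in seq_len(settings$chains)) draws[, ch, ] <- chains[[ch]]
  if (any(!is.finite(draws))) stop("non-finite values in posterior draws")

  structure(list(draws = draws, par_names = nm,
                 n_top = n_top_params(data, spec),
                 settings = settings, spec = spec, data = data, K = K,
                 monitor_latent = monitor_latent, elapsed = elapsed),
            class = "coabund_fit")
}

sp_labels <- c("dom", "sub")

n_top_params <- function(data, spec) {
  C <- ncol(data$covariates$values)
  L <- length(data$covariates$landscape_names)
  2L + 2L * C + 2L * L + 2L + 1L + 2L + 2L + if (spec$odre) 2L else 0L
}

par_names <- function(data, spec, monitor_latent) {
  covn <- data$covariates$names
  landn <- data$covariates$landscape_names
  units <- data$history$units
  O <- dim(data$history$counts)[3L]
  nm <- c(sprintf("alpha0[%s]", sp_labels),
          as.vector(t(outer(sp_labels, covn,
                            function(a, b) sprintf("alpha_%s[%s]", b, a)))),
          as.vector(t(outer(sp_labels, landn,
                            function(a, b) sprintf("land[%s,%s]", a, b)))),
          sprintf("sigma_land[%s]", sp_labels),
          "delta",
          sprintf("beta0[%s]", sp_labels),
          sprintf("beta1[%s]", sp_labels))
  if (spec$odre) nm <- c(nm, sprintf("tau[%s]", sp_labels))
  if (monitor_latent) {
    nm <- c(nm, as.vector(t(outer(sp_labels, units,
                                  function(a, b) sprintf("N[%s,%s]", a, b)))))
    if (spec$odre) {
      grid <- expand.grid(k = seq_len(O), u = units, s = sp_labels,
                          stringsAsFactors = FALSE)  # k fastest, s slowest
      nm <- c(nm, sprintf("eps[%s,%s,%d]", grid$s, grid$u, grid$k))
    }
  }
  nm
}

draw_inits <- function(data, spec, J, C, L, K) {
  hist <- data$history
  obs <- hist$counts; obs[!hist$mask] <- 0L
  Nmax <- apply(obs, c(1L, 2L), max)
  Ninit <- Nmax + 1L
  if (spec$abundance == "izip") Ninit[data$informant$Z == 0L] <- 0L
  Ninit <- pmin(Ninit, K)
  storage.mode(Ninit) <- "integer"
  list(alpha0 = stats::runif(2, -0.1, 0.1),
       alpha = matrix(stats::runif(2 * C, -0.1, 0.1), 2L, C),
       land = matrix(0, 2L, L),
       sigma_land = c(0.5, 0.5),
       delta = stats::runif(1, -0.1, 0.1),
       beta0 = stats::runif(2, -0.1, 0.1),
       beta1 = stats::runif(2, -0.1, 0.1),
       tau = c(0.5, 0.5),
       N = Ninit)
}

check_init <- function(data, spec, init, chain) {
  O <- dim(data$history$counts)[3L]
  J <- length(data$history$units)
  params <- coabund_params(alpha0 = init$alpha0, alpha = init$alpha,
                           land = init$land, sigma_land = init$sigma_land,
                           delta = init$delta, beta0 = init$beta0,
                           beta1 = init$beta1, tau = init$tau,
                           eps = array(0, c(2L, J, O)))
  ll <- joint_log_density(data, params, spec, N_dom = init$N[1L, ])
  if (!is.finite(ll)) {
    stop("non-finite log-density at initialization (chain ", chain, "); ",
         "initial values: ",
         paste(utils::capture.output(utils::str(init)), collapse = " "))
  }
  invisible(ll)
}

#' Extract draws of one parameter
#'
#' @param fit a `coabund_fit`.
#' @param par parameter name (see `fit$par_names`).
#' @return numeric matrix `[draw, chain]`.
#' @export
get_draws <- function(fit, par) {
  stopifnot(inherits(fit, "coabund_fit"))
  i <- match(par, fit$par_names)
  if (is.na(i)) stop("unknown parameter: ", par)
  fit$draws[, , i, drop = TRUE]
}

#' @export
print.coabund_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("coabund_fit:", x$spec$abundance,
      if (x$spec$odre) "+ ODRE" else "", "/", x$spec$detection,
      "detection\n")
  cat("  ", d[2L], "chains x", d[1L], "draws (", d[2L] * d[1L],
      "total ) over", d[3L], "monitored quantities; K =", x$K, "\n")
  cat("   sampling took", round(x$elapsed, 1), "s\n")
  s <- summarize(x)
  print(utils::head(s[order(s$parameter != "delta"), ], 8L), digits = 3)
  invisible(x)
}
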