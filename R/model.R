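#' Model specification for the two-species co-abundance model
#'
#' Selects among the four model structures compared in the package: plain
#' Poisson abundance vs informed zero-inflated Poisson (iZIP), with or
#' without the detection overdispersion random effect (ODRE), and a
#' binomial or Poisson detection process.
#'
#' @param abundance `"izip"` (default) or `"poisson"`. Under `"poisson"`
#'   the zero informant is ignored (all Z treated as 1).
#' @param detection `"binomial"` (default) or `"poisson"`. The Poisson
#'   detection process models `n ~ Poisson(N * r)` with a log-link
#'   per-individual detection rate `r`, relaxing the no-double-counting
#'   assumption of the binomial observation model.
#' @param odre include the per-unit-per-occasion overdispersion random
#'   effect on detection (default TRUE).
#' @param K truncation bound for the latent abundance sum; `NULL` (the
#'   default) resolves per dataset to `5 * max(count) + 20`, validated by
#'   the K-doubling invariance of the marginal likelihood.
#' @param prior_coef_sd SD of the Normal(0, .) prior on all regression
#'   coefficients and the interaction delta (default 10).
#' @param prior_sd_upper upper bound of the Uniform(0, .) prior on the
#'   ODRE SD tau and the landscape-intercept SD (default 5).
#' @param eps_p stabilization floor: detection probabilities are clamped
#'   to `[eps_p, 1 - eps_p]` so the logit transform cannot collapse to 0
#'   or 1 (default 1e-6; must lie in (0, 0.5)).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(abundance = c("izip", "poisson"),
                       detection = c("binomial", "poisson"),
                       odre = TRUE, K = NULL,
                       prior_coef_sd = 10, prior_sd_upper = 5,
                       eps_p = 1e-6) {
  abundance <- match.arg(abundance)
  detection <- match.arg(detection)
  stopifnot(eps_p > 0, eps_p < 0.5, prior_coef_sd > 0, prior_sd_upper > 0)
  if (!is.null(K)) stopifnot(K >= 1)
  structure(list(abundance = abundance, detection = detection,
                 odre = isTRUE(odre), K = K,
                 prior_coef_sd = prior_coef_sd,
                 prior_sd_upper = prior_sd_upper, eps_p = eps_p),
            class = "model_spec")
}

#' Named model variants
#'
#' Convenience constructor for the four structures of the comparison
#' harness: `"poisson"`, `"izip"`, `"poisson_odre"`, `"izip_odre"` (the
#' full model), all with binomial detection.
#'
#' @param name variant name.
#' @param ... passed on to [model_spec()].
#' @export
variant_spec <- function(name = c("izip_odre", "poisson", "izip",
                                  "poisson_odre"), ...) {
  name <- match.arg(name)
  switch(name,
         poisson = model_spec("poisson", odre = FALSE, ...),
         izip = model_spec("izip", odre = FALSE, ...),
         poisson_odre = model_spec("poisson", odre = TRUE, ...),
         izip_odre = model_spec("izip", odre = TRUE, ...))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec: abundance =", x$abundance, "| detection =", x$detection,
      "| ODRE", if (x$odre) "on" else "off", "\n")
  cat("  K =", if (is.null(x$K)) "auto (5*max(count)+20)" else x$K,
      "| coef prior sd =", x$prior_coef_sd,
      "| sd prior U(0,", x$prior_sd_upper, ") | eps_p =", x$eps_p, "\n")
  invisible(x)
}

resolve_K <- function(spec, history) {
  if (!is.null(spec$K)) return(as.integer(spec$K))
  obs <- history$counts; obs[!history$mask] <- 0L
  as.integer(5L * max(obs) + 20L)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Expected-count linear predictor
#'
#' Evaluates `lambda_j = exp(alpha0 + X_j alpha + land[landscape(j)] +
#' delta * N_dom_j)` for one species. The interaction term is present
#' only for the subordinate species, and multiplies the raw latent
#' abundance of the dominant species.
#'
#' @param covs a `site_covariates` object (standardized covariates).
#' @param alpha0 intercept.
#' @param alpha covariate coefficients, one per column of `covs$values`.
#' @param land landscape random-intercept values, one per landscape.
#' @param delta interaction coefficient (subordinate only) or NULL.
#' @param N_dom dominant latent abundance per unit; required iff `delta`
#'   is non-NULL.
#' @return positive vector `lambda` per unit; a non-finite linear
#'   predictor is an error.
#' @export
abundance_linpred <- function(covs, alpha0, alpha, land = NULL,
                              delta = NULL, N_dom = NULL) {
  X <- covs$values
  stopifnot(length(alpha) == ncol(X))
  eta <- alpha0 + as.numeric(X %*% alpha)
  if (!is.null(land)) eta <- eta + land[covs$landscape_index]
  if (!is.null(delta)) {
    if (is.null(N_dom)) stop("delta given without N_dom")
    stopifnot(length(N_dom) == nrow(X))
    eta <- eta + delta * N_dom
  } else if (!is.null(N_dom)) {
    stop("N_dom given without delta")
  }
  if (any(!is.finite(eta))) stop("non-finite abundance linear predictor")
  exp(eta)
}

#' Detection probability on the logit scale
#'
#' `p = clamp(plogis(beta0 + beta1 * effort_std + eps), eps_p, 1 - eps_p)`.
#' The clamp is the stabilizing device keeping the logit transform away
#' from exact 0/1.
#'
#' @param effort_std standardized effort (scalar or vector).
#' @param beta0,beta1 detection intercept and effort effect.
#' @param eps ODRE draw(s); 0 when the ODRE is off.
#' @param eps_p stabilization floor in (0, 0.5).
#' @return probabilities in `[eps_p, 1 - eps_p]`.
#' @export
detection_prob <- function(effort_std, beta0, beta1, eps = 0,
                           eps_p = 1e-6) {
  stopifnot(eps_p > 0, eps_p < 0.5)
  p <- stats::plogis(beta0 + beta1 * effort_std + eps)
  pmin(pmax(p, eps_p), 1 - eps_p)
}

# log density of one occasion's count given latent N (vectorized over N)
ldetect_vec <- function(n, Nvec, p = NULL, rate = NULL,
                        detection = "binomial") {
  if (detection == "binomial") {
    stats::dbinom(n, Nvec, p, log = TRUE)   # -Inf where n > N
  } else {
    stats::dpois(n, Nvec * rate, log = TRUE)  # N=0: 0 iff n=0 else -Inf
  }
}

#' Site-level marginal log-likelihood
#'
#' Log-probability of one species' count vector at one sampling unit with
#' the latent abundance summed out:
#' `log sum_{N=0}^{K} Poisson(N; lambda * Z) prod_k Detect(n_k | N, .)`.
#' With Z = 0 only the N = 0 term survives: probability 1 for an all-zero
#' history, and -Inf (with a warning) if any count is positive.
#'
#' @param counts integer counts per occasion.
#' @param lambda expected abundance (> 0).
#' @param p detection probability per occasion (binomial detection).
#' @param Z 0/1 zero-informant value for this unit.
#' @param K truncation bound for the latent sum; must be >= max(counts)
#'   under binomial detection.
#' @param mask logical per occasion, `TRUE` = observed (default all).
#' @param detection `"binomial"` or `"poisson"`.
#' @param rate per-occasion per-individual detection rate (Poisson
#'   detection only).
#' @param unit label used in the impossible-event warning.
#' @return scalar log-probability.
#' @export
site_marginal_loglik <- function(counts, lambda, p = NULL, Z = 1, K,
                                 mask = NULL, detection = "binomial",
                                 rate = NULL, unit = "?") {
  if (is.null(mask)) mask <- rep(TRUE, length(counts))
  n <- counts[mask]
  if (length(n) == 0L) return(0)
  if (Z == 0) {
    if (any(n > 0)) {
      warning("unit ", unit, ": positive count where Z = 0 (impossible event)")
      return(-Inf)
    }
    return(0)
  }
  if (detection == "binomial") {
    if (is.null(p)) stop("binomial detection needs p")
    p <- p[mask]
    if (any(n > K)) stop("count exceeds truncation bound K at unit ", unit)
  } else {
    if (is.null(rate)) stop("poisson detection needs rate")
    rate <- rate[mask]
  }
  Nvec <- 0:K
  lw <- stats::dpois(Nvec, lambda, log = TRUE)
  for (k in seq_along(n)) {
    lw <- lw + ldetect_vec(n[k], Nvec,
                           p = if (detection == "binomial") p[k],
                           rate = if (detection == "poisson") rate[k],
                           detection = detection)
  }
  logsumexp(lw)
}

#' Parameter bundle for the co-abundance model
#'
#' A plain validated list; species index 1 is the dominant, 2 the
#' subordinate.
#'
#' @param alpha0 length-2 abundance intercepts.
#' @param alpha 2 x C matrix of covariate effects.
#' @param land 2 x L matrix of landscape random intercepts.
#' @param sigma_land length-2 landscape-intercept SDs (> 0).
#' @param delta interaction coefficient (effect of dominant latent
#'   abundance on subordinate log-abundance).
#' @param beta0,beta1 length-2 detection intercept and effort effect.
#' @param tau length-2 ODRE SDs (> 0; ignored when the ODRE is off).
#' @param eps optional ODRE values, array `[2, J, O]`.
#' @return object of class `coabund_params`.
#' @export
coabund_params <- function(alpha0, alpha, land, sigma_land, delta,
                           beta0, beta1, tau = c(0.5, 0.5), eps = NULL) {
  alpha <- rbind(alpha)
  if (nrow(alpha) == 1L) alpha <- rbind(alpha, alpha)
  land <- rbind(land)
  if (nrow(land) == 1L) land <- rbind(land, land)
  stopifnot(length(alpha0) == 2L, nrow(alpha) == 2L, nrow(land) == 2L,
            length(sigma_land) == 2L, all(sigma_land > 0),
            length(delta) == 1L, length(beta0) == 2L, length(beta1) == 2L,
            length(tau) == 2L)
  structure(list(alpha0 = alpha0, alpha = alpha, land = land,
                 sigma_land = sigma_land, delta = delta, beta0 = beta0,
                 beta1 = beta1, tau = tau, eps = eps),
            class = "coabund_params")
}

params_lambda <- function(data, params, species, N_dom = NULL) {
  abundance_linpred(data$covariates,
                    alpha0 = params$alpha0[species],
                    alpha = params$alpha[species, ],
                    land = params$land[species, ],
                    delta = if (species == 2L) params$delta,
                    N_dom = if (species == 2L) N_dom)
}

params_detect <- function(data, params, spec) {
  J <- length(data$history$units); O <- dim(data$history$counts)[3L]
  eps <- params$eps
  if (!spec$odre || is.null(eps)) eps <- array(0, c(2L, J, O))
  out <- list()
  for (i in 1:2) {
    lp <- params$beta0[i] + params$beta1[i] * data$covariates$effort_std
    lp <- matrix(lp, J, O) + matrix(eps[i, , ], J, O)
    if (spec$detection == "binomial") {
      out[[i]] <- pmin(pmax(stats::plogis(lp), spec$eps_p), 1 - spec$eps_p)
    } else {
      out[[i]] <- exp(lp)
    }
  }
  out
}

#' Joint log-density of the full hierarchy
#'
#' Sums the two species' observation-model contributions, the ODRE
#' log-densities, and the landscape-intercept log-densities. Masked cells
#' contribute nothing. Two conditioning modes are available for the
#' dominant latent abundance that links the two species:
#'
#' * `N_dom` supplied (a latent draw): the dominant contributes
#'   `Poisson(N_dom; lambda_dom Z) * prod_k Detect(n | N_dom, p)` and the
#'   subordinate's expected count uses `delta * N_dom`; this is the
#'   density the MCMC sampler targets.
#' * `N_dom = NULL`: both latent abundances are marginalized by nested
#'   enumeration up to K (the subordinate sum is evaluated inside each
#'   dominant term), giving the exact marginal likelihood.
#'
#' @param data a `coabund_data`.
#' @param params a `coabund_params`.
#' @param spec a `model_spec`.
#' @param N_dom optional integer vector of dominant latent abundance per
#'   unit.
#' @return scalar log-density.
#' @export
joint_log_density <- function(data, params, spec = model_spec(),
                              N_dom = NULL) {
  hist <- data$history
  J <- length(hist$units); O <- dim(hist$counts)[3L]
  K <- resolve_K(spec, hist)
  Z <- data$informant$Z
  if (spec$abundance == "poisson") Z <- matrix(1L, 2L, J)
  det <- params_detect(data, params, spec)
  lam1 <- params_lambda(data, params, 1L)
  if (!is.null(N_dom)) {
    stopifnot(length(N_dom) == J)
    lam2 <- params_lambda(data, params, 2L, N_dom = N_dom)
  }
  ll <- 0
  for (j in seq_len(J)) {
    m <- hist$mask[1L, j, ]
    n1 <- hist$counts[1L, j, ]; n2 <- hist$counts[2L, j, ]
    m2 <- hist$mask[2L, j, ]
    p1 <- det[[1L]][j, ]; p2 <- det[[2L]][j, ]
    if (!is.null(N_dom)) {
      # conditional on the current dominant draw
      if (Z[1L, j] == 0) {
        ld <- if (N_dom[j] == 0) 0 else -Inf
      } else {
        ld <- stats::dpois(N_dom[j], lam1[j], log = TRUE)
      }
      if (any(m)) {
        ld <- ld + sum(ldetect_vec(n1[m], rep(N_dom[j], sum(m)),
                                   p = if (spec$detection == "binomial") p1[m],
                                   rate = if (spec$detection == "poisson") p1[m],
                                   detection = spec$detection))
      }
      ll <- ll + ld +
        site_marginal_loglik(n2, lam2[j],
                             p = if (spec$detection == "binomial") p2,
                             Z = Z[2L, j], K = K, mask = m2,
                             detection = spec$detection,
                             rate = if (spec$detection == "poisson") p2,
                             unit = hist$units[j])
    } else {
      # full marginalization: enumerate the dominant abundance
      Nvals <- if (Z[1L, j] == 0) 0L else 0:K
      lw <- numeric(length(Nvals))
      for (q in seq_along(Nvals)) {
        N1 <- Nvals[q]
        ld <- if (Z[1L, j] == 0) 0 else stats::dpois(N1, lam1[j], log = TRUE)
        if (any(m)) {
          ld <- ld + sum(ldetect_vec(n1[m], rep(N1, sum(m)),
                                     p = if (spec$detection == "binomial") p1[m],
                                     rate = if (spec$detection == "poisson") p1[m],
                                     detection = spec$detection))
        }
        lam2j <- params_lambda(data, params, 2L,
                               N_dom = rep(N1, J))[j]
        lw[q] <- ld +
          site_marginal_loglik(n2, lam2j,
                               p = if (spec$detection == "binomial") p2,
                               Z = Z[2L, j], K = K, mask = m2,
                               detection = spec$detection,
                               rate = if (spec$detection == "poisson") p2,
                               unit = hist$units[j])
      }
      ll <- ll + logsumexp(lw)
    }
  }
  # random-effect densities
  for (i in 1:2) {
    ll <- ll + sum(stats::dnorm(params$land[i, ], 0, params$sigma_land[i],
                                log = TRUE))
    if (spec$odre && !is.null(params$eps)) {
      mi <- hist$mask[i, , ]
      ll <- ll + sum(stats::dnorm(params$eps[i, , ][mi], 0, params$tau[i],
                                  log = TRUE))
    }
  }
  ll
}

#' Prior log-density
#'
#' Vague priors: Normal(0, sd = `prior_coef_sd`) on all regression
#' coefficients (abundance and detection) and on the interaction delta;
#' Uniform(0, `prior_sd_upper`) on the ODRE SDs and landscape-intercept
#' SDs (-Inf outside support). The landscape intercepts themselves are
#' hierarchical and belong to [joint_log_density()].
#'
#' @param params a `coabund_params`.
#' @param spec a `model_spec`.
#' @return scalar log-density.
#' @export
prior_log_density <- function(params, spec = model_spec()) {
  s <- spec$prior_coef_sd; u <- spec$prior_sd_upper
  coefs <- c(params$alpha0, as.numeric(params$alpha), params$delta,
             params$beta0, params$beta1)
  lp <- sum(stats::dnorm(coefs, 0, s, log = TRUE))
  sds <- c(params$sigma_land, if (spec$odre) params$tau)
  if (any(sds <= 0 | sds >= u)) return(-Inf)
  lp + sum(stats::dunif(sds, 0, u, log = TRUE))
}
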