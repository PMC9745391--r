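#' Chi-square discrepancy
#'
#' `sum over observed cells of (obs - exp)^2 / (exp + pad)`. The pad
#' stabilizes cells whose expected count is near zero.
#'
#' @param observed numeric array/matrix of counts.
#' @param expected positive reals, same shape.
#' @param mask logical, same shape; `TRUE` = include (default all).
#' @param pad small constant added to the denominator (default 0.5).
#' @return non-negative scalar.
#' @export
chi2_discrepancy <- function(observed, expected, mask = NULL, pad = 0.5) {
  if (!all(dim(as.array(observed)) == dim(as.array(expected)))) {
    stop("chi2_discrepancy: shape mismatch")
  }
  if (is.null(mask)) mask <- rep(TRUE, length(observed))
  o <- as.numeric(observed)[as.logical(mask)]
  e <- as.numeric(expected)[as.logical(mask)]
  if (any(e + pad <= 0)) stop("expected + pad must be positive")
  sum((o - e)^2 / (e + pad))
}

# reconstruct per-draw lambda (2 x J) and detection p or rate (2 x J x O)
# from one row of the pooled draw matrix
draw_state <- function(fit, row) {
  data <- fit$data; spec <- fit$spec
  covs <- data$covariates
  J <- length(data$history$units); O <- dim(data$history$counts)[3L]
  C <- ncol(covs$values); L <- length(covs$landscape_names)
  g <- function(nm) unname(row[nm])
  lam <- matrix(NA_real_, 2L, J)
  N1 <- as.integer(row[sprintf("N[dom,%s]", data$history$units)])
  for (i in 1:2) {
    alpha <- row[sprintf("alpha_%s[%s]", covs$names, sp_labels[i])]
    land <- row[sprintf("land[%s,%s]", sp_labels[i], covs$landscape_names)]
    eta <- g(sprintf("alpha0[%s]", sp_labels[i])) +
      as.numeric(covs$values %*% alpha) + unname(land)[covs$landscape_index]
    if (i == 2L) eta <- eta + g("delta") * N1
    lam[i, ] <- exp(eta)
  }
  det <- array(NA_real_, c(2L, J, O))
  for (i in 1:2) {
    lp <- matrix(g(sprintf("beta0[%s]", sp_labels[i])) +
                   g(sprintf("beta1[%s]", sp_labels[i])) * covs$effort_std,
                 J, O)
    if (spec$odre) {
      epsn <- sprintf("eps[%s,%s,%d]", sp_labels[i],
                      rep(data$history$units, each = O), rep(seq_len(O),
                                                             times = J))
      lp <- lp + matrix(row[epsn], J, O, byrow = TRUE)
    }
    det[i, , ] <- if (spec$detection == "binomial") {
      pmin(pmax(stats::plogis(lp), spec$eps_p), 1 - spec$eps_p)
    } else {
      exp(lp)
    }
  }
  list(lambda = lam, det = det, N1 = N1)
}

pool_draws <- function(fit) {
  d <- dim(fit$draws)
  pool <- do.call(rbind, lapply(seq_len(d[2L]), function(ch) fit$draws[, ch, ]))
  colnames(pool) <- fit$par_names
  pool
}

#' Posterior predictive goodness-of-fit check
#'
#' For each of `n_replicates` posterior draws (subsampled evenly across
#' chains), a replicate count history is simulated from the draw's
#' generative model -- latent abundance redrawn from
#' `Poisson(lambda * Z)`, counts from the detection process at the draw's
#' detection probabilities (which carry that draw's ODRE values) -- and
#' both the observed and replicate histories are scored against the
#' N-marginal expected count `E = p * lambda * Z` per cell with the
#' chi-square discrepancy. Per species:
#' `bayes_p = Pr(T_rep > T_obs)` (ties count one half) and
#' `c_hat = mean(T_obs / T_rep)` (draws with `T_rep = 0` are excluded and
#' counted). Bayesian p-values between .25 and .75 indicate acceptable
#' fit (.5 is perfect); c-hat above 1.1 flags remaining overdispersion.
#'
#' @param fit a `coabund_fit` with `monitor_latent = TRUE`.
#' @param n_replicates posterior draws to use (default 1000, capped at
#'   the retained draw count).
#' @param seed seed for the replicate simulations.
#' @param pad chi-square stabilization constant (default 0.5).
#' @param c_hat_method `"mean_ratio"` (default; mean of per-draw
#'   `T_obs/T_rep`) or `"ratio_of_means"`.
#' @return object of class `ppc_result`: per-species `bayes_p` and
#'   `c_hat`, the per-draw discrepancy table, and bookkeeping.
#' @export
posterior_predictive_check <- function(fit, n_replicates = 1000, seed = 1,
                                       pad = 0.5,
                                       c_hat_method = c("mean_ratio",
                                                        "ratio_of_means")) {
  stopifnot(inherits(fit, "coabund_fit"))
  if (!fit$monitor_latent) stop("fit lacks latent draws; refit with monitor_latent = TRUE")
  c_hat_method <- match.arg(c_hat_method)
  data <- fit$data; spec <- fit$spec
  hist <- data$history
  J <- length(hist$units); O <- dim(hist$counts)[3L]
  Z <- data$informant$Z
  if (spec$abundance == "poisson") Z <- matrix(1L, 2L, J)
  pool <- pool_draws(fit)
  n_replicates <- min(n_replicates, nrow(pool))
  idx <- unique(round(seq(1L, nrow(pool), length.out = n_replicates)))
  set.seed(seed)
  Tobs <- Trep <- matrix(NA_real_, length(idx), 2L,
                         dimnames = list(NULL, sp_labels))
  for (q in seq_along(idx)) {
    st <- draw_state(fit, pool[idx[q], ])
    for (i in 1:2) {
      m <- hist$mask[i, , ]
      pmat <- matrix(st$det[i, , ], J, O)
      Emat <- Z[i, ] * st$lambda[i, ] * pmat
      Tobs[q, i] <- chi2_discrepancy(matrix(hist$counts[i, , ], J, O),
                                     Emat, mask = m, pad = pad)
      Nrep <- stats::rpois(J, st$lambda[i, ] * Z[i, ])
      Nrep[!is.finite(Nrep)] <- fit$K
      rep_counts <- if (spec$detection == "binomial") {
        matrix(stats::rbinom(J * O, rep(Nrep, O), as.numeric(pmat)), J, O)
      } else {
        matrix(stats::rpois(J * O, rep(Nrep, O) * as.numeric(pmat)), J, O)
      }
      Trep[q, i] <- chi2_discrepancy(rep_counts, Emat, mask = m, pad = pad)
    }
  }
  bayes_p <- c_hat <- stats::setNames(numeric(2L), sp_labels)
  n_degenerate <- stats::setNames(integer(2L), sp_labels)
  for (i in 1:2) {
    bayes_p[i] <- mean(Trep[, i] > Tobs[, i]) + 0.5 * mean(Trep[, i] == Tobs[, i])
    ok <- Trep[, i] > 0
    n_degenerate[i] <- sum(!ok)
    c_hat[i] <- if (c_hat_method == "mean_ratio") {
      mean(Tobs[ok, i] / Trep[ok, i])
    } else {
      mean(Tobs[ok, i]) / mean(Trep[ok, i])
    }
  }
  structure(list(bayes_p = bayes_p, c_hat = c_hat,
                 n_replicates = length(idx), seed = seed, pad = pad,
                 c_hat_method = c_hat_method, n_degenerate = n_degenerate,
                 discrepancies = data.frame(T_obs_dom = Tobs[, 1L],
                                            T_rep_dom = Trep[, 1L],
                                            T_obs_sub = Tobs[, 2L],
                                            T_rep_sub = Trep[, 2L])),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("posterior predictive check (", x$n_replicates, "draws )\n")
  for (i in 1:2) {
    cat(sprintf("  %s: Bayesian p = %.3f %s | c-hat = %.3f %s\n",
                names(x$bayes_p)[i], x$bayes_p[i],
                if (x$bayes_p[i] > 0.25 && x$bayes_p[i] < 0.75) "(good fit)"
                else "(LACK OF FIT)",
                x$c_hat[i],
                if (x$c_hat[i] > 1.1) "(overdispersed)" else ""))
  }
  if (any(x$n_degenerate > 0)) {
    cat("  degenerate T_rep = 0 draws excluded from c-hat:",
        paste(names(x$n_degenerate), x$n_degenerate, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}
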