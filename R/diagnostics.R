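#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) form: with m chains of n draws, within-chain
#' variance W (mean of chain variances), between-chain variance B
#' (n times the variance of chain means), pooled estimate
#' `vhat = (n-1)/n W + B/n`, and `Rhat = sqrt(vhat / W)`.
#'
#' Degenerate cases follow the conventions: chains with no between-chain
#' variance (identical chains, or a completely constant parameter) return
#' exactly 1; zero within-chain variance with unequal chain means returns
#' `+Inf` (reported, not raised). Values in `[1, 1.2]` are taken as
#' converged.
#'
#' @param x numeric matrix `[draw, chain]` (or list of equal-length
#'   chains) of one parameter's samples; >= 2 chains with >= 2 draws.
#' @return scalar Rhat.
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (m < 2L || n < 2L) stop("rhat needs >= 2 chains of >= 2 draws")
  means <- colMeans(x)
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(means)
  if (B == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Probability of direction
#'
#' The posterior probability that a parameter is strictly positive or
#' strictly negative, whichever is larger; draws exactly at zero are
#' split evenly between the two signs. Always in `[0.5, 1]`.
#'
#' @param draws numeric vector of posterior draws (>= 1).
#' @return scalar pd.
#' @export
probability_of_direction <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) == 0L) stop("probability_of_direction: empty draws")
  pos <- mean(draws > 0); neg <- mean(draws < 0); zer <- mean(draws == 0)
  max(pos, neg) + zer / 2
}

#' Posterior summary table
#'
#' Per parameter: posterior mean, SD, equal-tailed 95% credible interval
#' (empirical 2.5% and 97.5% quantiles with linear interpolation), the
#' Gelman-Rubin Rhat across chains, the probability of direction, and a
#' `clear_effect` flag (TRUE when 0 lies outside the 95% CrI). The
#' attribute `"converged"` records whether every reported Rhat is finite
#' and at most 1.2.
#'
#' @param fit a `coabund_fit` (or a 3-d draws array
#'   `[draw, chain, parameter]` with parameter dimnames).
#' @param pars parameters to summarize; defaults to the model parameters
#'   (latent N and eps excluded).
#' @return data.frame, one row per parameter.
#' @export
summarize <- function(fit, pars = NULL) {
  if (inherits(fit, "coabund_fit")) {
    draws <- fit$draws
    if (is.null(pars)) pars <- fit$par_names[seq_len(fit$n_top)]
  } else {
    draws <- fit
    if (is.null(pars)) pars <- dimnames(draws)[[3L]]
  }
  nm <- dimnames(draws)[[3L]]
  out <- lapply(pars, function(p) {
    i <- match(p, nm)
    if (is.na(i)) stop("unknown parameter: ", p)
    x <- draws[, , i, drop = FALSE]
    dim(x) <- dim(draws)[1:2]
    pooled <- as.numeric(x)
    q <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE, type = 7)
    r <- if (ncol(x) >= 2L && nrow(x) >= 2L) rhat(x) else NA_real_
    data.frame(parameter = p, mean = mean(pooled), sd = stats::sd(pooled),
               q2.5 = q[1L], q97.5 = q[2L], rhat = r,
               pd = probability_of_direction(pooled),
               clear_effect = (q[1L] > 0 || q[2L] < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  rh <- out$rhat[!is.na(out$rhat)]
  attr(out, "converged") <- length(rh) > 0 && all(is.finite(rh) & rh <= 1.2)
  out
}

#' Write a posterior summary to CSV
#'
#' @param summary data.frame from [summarize()].
#' @param path output file.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
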