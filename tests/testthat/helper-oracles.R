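# Independent oracles and fixture builders. The oracles work in plain
# probability space with naive summation, deliberately sharing no code
# path with the package's log-space implementations.

# brute-force site marginal: sum_N Poisson(N; lambda*Z) prod_k Detect(n_k|N)
oracle_site_marginal <- function(counts, lambda, p = NULL, Z = 1, K,
                                 mask = NULL, detection = "binomial",
                                 rate = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(counts))
  tot <- 0
  for (N in 0:K) {
    term <- stats::dpois(N, lambda * Z)
    for (k in which(mask)) {
      term <- term * if (detection == "binomial") {
        stats::dbinom(counts[k], N, p[k])
      } else {
        stats::dpois(counts[k], N * rate[k])
      }
    }
    tot <- tot + term
  }
  log(tot)
}

# exhaustive joint enumeration over (N_dom, N_sub) for a 2-species toy;
# returns the observation-model part only (no land / eps densities)
oracle_joint_obs <- function(data, params, spec, Kmax) {
  hist <- data$history
  J <- length(hist$units)
  Z <- data$informant$Z
  if (spec$abundance == "poisson") Z <- matrix(1L, 2L, J)
  X <- data$covariates$values
  li <- data$covariates$landscape_index
  eff <- data$covariates$effort_std
  O <- dim(hist$counts)[3L]
  eps <- params$eps
  if (is.null(eps) || !spec$odre) eps <- array(0, c(2, J, O))
  total <- 0
  for (j in seq_len(J)) {
    pj <- matrix(NA_real_, 2, O)
    for (i in 1:2) {
      lp <- params$beta0[i] + params$beta1[i] * eff[j] + eps[i, j, ]
      pj[i, ] <- if (spec$detection == "binomial") {
        pmin(pmax(plogis(lp), spec$eps_p), 1 - spec$eps_p)
      } else {
        exp(lp)
      }
    }
    eta1 <- params$alpha0[1] + sum(X[j, ] * params$alpha[1, ]) +
      params$land[1, li[j]]
    eta2b <- params$alpha0[2] + sum(X[j, ] * params$alpha[2, ]) +
      params$land[2, li[j]]
    pr <- 0
    N1r <- if (Z[1, j] == 0) 0 else 0:Kmax
    N2r <- if (Z[2, j] == 0) 0 else 0:Kmax
    for (N1 in N1r) {
      t1 <- if (Z[1, j] == 0) 1 else stats::dpois(N1, exp(eta1))
      for (k in which(hist$mask[1, j, ])) {
        t1 <- t1 * if (spec$detection == "binomial") {
          stats::dbinom(hist$counts[1, j, k], N1, pj[1, k])
        } else {
          stats::dpois(hist$counts[1, j, k], N1 * pj[1, k])
        }
      }
      lam2 <- exp(eta2b + params$delta * N1)
      for (N2 in N2r) {
        t2 <- if (Z[2, j] == 0) 1 else stats::dpois(N2, lam2)
        for (k in which(hist$mask[2, j, ])) {
          t2 <- t2 * if (spec$detection == "binomial") {
            stats::dbinom(hist$counts[2, j, k], N2, pj[2, k])
          } else {
            stats::dpois(hist$counts[2, j, k], N2 * pj[2, k])
          }
        }
        pr <- pr + t1 * t2
      }
    }
    total <- total + log(pr)
  }
  total
}

# type-7 quantile by explicit order statistics
oracle_quantile <- function(x, prob) {
  xs <- sort(x)
  h <- (length(xs) - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# hand records builder: minutes are offsets from a fixed origin
make_records <- function(minutes, species = "tiger", unit = "u1",
                         landscape = "A", count = 1) {
  n <- length(minutes)
  data.frame(species = rep(species, length.out = n),
             unit = rep(unit, length.out = n),
             landscape = rep(landscape, length.out = n),
             timestamp = as.POSIXct("2020-01-01 00:00:00", tz = "UTC") +
               minutes * 60,
             count = rep(count, length.out = n),
             stringsAsFactors = FALSE)
}

# small hand-built two-species dataset with fixed, collinearity-safe
# covariates
make_tiny_data <- function(J = 4, O = 3, counts = NULL, mask = NULL,
                           Z = NULL, landscape = NULL, seed = 42) {
  set.seed(seed)
  if (is.null(counts)) counts <- array(rpois(2 * J * O, 1), c(2, J, O))
  if (is.null(landscape)) landscape <- rep(c("A", "B"), length.out = J)
  hist <- count_history(counts, mask, occasion_days = 5,
                        effort = seq(10, 10 + J - 1),
                        species = c("dominant", "subordinate"),
                        units = paste0("u", seq_len(J)),
                        landscape = landscape)
  X <- if (J >= 4) {
    cbind(FLII = seq(-1, 1, length.out = J),
          HFP = rep(c(-1, 1), length.out = J) * seq(0.5, 1, length.out = J))
  } else {
    cbind(FLII = seq(-1, 1, length.out = J))  # any 2-point pair is collinear
  }
  covs <- standardize_covariates(X, landscape = landscape,
                                 effort = hist$effort)
  informant <- NULL
  if (!is.null(Z)) {
    informant <- structure(list(Z = Z, species = hist$species,
                                units = hist$units),
                           class = "zero_informant")
  }
  coabund_data(hist, covs, informant)
}

default_params <- function(data, delta = -0.2, eps = NULL) {
  C <- ncol(data$covariates$values)
  L <- length(data$covariates$landscape_names)
  coabund_params(alpha0 = c(-0.5, 0.5),
                 alpha = matrix(c(0.3, -0.2, 0.4, -0.1)[seq_len(2 * C)],
                                2, C),
                 land = matrix(0.1, 2, L), sigma_land = c(0.5, 0.5),
                 delta = delta, beta0 = c(0.2, -0.3), beta1 = c(0.3, 0.2),
                 tau = c(0.5, 0.5), eps = eps)
}

# fast MCMC settings for structural tests
tiny_settings <- function(seed = 1, chains = 2, iterations = 300,
                          burn_in = 100, thin = 2) {
  mcmc_settings(chains = chains, iterations = iterations, burn_in = burn_in,
                thin = thin, seed = seed)
}
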