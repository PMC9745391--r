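test_that("abundance linear predictor matches closed forms", {
  data <- make_tiny_data(J = 4, O = 2)
  covs <- data$covariates
  lam <- abundance_linpred(covs, alpha0 = 0, alpha = c(0, 0),
                           land = rep(0, 2))
  expect_equal(lam, rep(1, 4))

  lam <- abundance_linpred(covs, alpha0 = 0, alpha = c(0, 0),
                           land = rep(0, 2), delta = -0.2,
                           N_dom = rep(5, 4))
  expect_equal(lam, rep(exp(-1), 4), tolerance = 1e-12)

  # a unit with FLII exactly 1 SD above the mean and a FLII effect of
  # 0.69 multiplies expected abundance by exp(0.69) ~ 1.994
  covs1 <- covs
  covs1$values[, "FLII"] <- c(1, -1, 1, -1) # mean 0, sd ~1.15; use directly
  lam <- abundance_linpred(covs1, alpha0 = 0, alpha = c(0.69, 0),
                           land = rep(0, 2))
  expect_equal(lam[1], exp(0.69), tolerance = 1e-12)
  expect_equal(exp(0.69), 1.994, tolerance = 1e-3)

  expect_error(abundance_linpred(covs, alpha0 = Inf, alpha = c(0, 0)),
               "non-finite")
  expect_error(abundance_linpred(covs, alpha0 = 0, alpha = c(0, 0),
                                 N_dom = rep(1, 4)), "without delta")
})

test_that("detection probability uses the logit link with clamping", {
  expect_equal(detection_prob(0, 0, 0), 0.5)
  expect_equal(detection_prob(0, -50, 0, eps_p = 1e-6), 1e-6)
  expect_equal(detection_prob(0, 50, 0, eps_p = 1e-6), 1 - 1e-6)
  expect_equal(detection_prob(1, 0, 1), plogis(1), tolerance = 1e-12)
  expect_equal(plogis(1), 0.731, tolerance = 1e-3)
})

test_that("site marginal handles the informed-zero point mass", {
  expect_equal(site_marginal_loglik(c(0, 0), lambda = 2, p = c(0.5, 0.5),
                                    Z = 0, K = 30), 0)
  expect_warning(
    ll <- site_marginal_loglik(c(1, 0), lambda = 2, p = c(0.5, 0.5),
                               Z = 0, K = 30),
    "impossible event")
  expect_identical(ll, -Inf)
  expect_error(site_marginal_loglik(c(40), lambda = 1, p = 0.5, Z = 1,
                                    K = 20), "exceeds truncation")
})

test_that("site marginal matches the worked brute-force example", {
  # lambda = 1, p = 0.5 on two occasions, counts [1, 0]:
  # high-precision enumeration gives P = 0.118091638185254
  ll <- site_marginal_loglik(c(1, 0), lambda = 1, p = c(0.5, 0.5), Z = 1,
                             K = 50)
  expect_equal(exp(ll), 0.118091638185254, tolerance = 1e-12)
  expect_equal(ll, -2.13629436111989, tolerance = 1e-12)
})

test_that("site marginal agrees with exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:120) {
    O <- sample(1:5, 1)
    K <- sample(8:20, 1)
    lambda <- runif(1, 0.1, 4)
    detection <- sample(c("binomial", "poisson"), 1)
    p <- runif(O, 0.05, 0.95)
    rate <- runif(O, 0.05, 1.5)
    counts <- rpois(O, 1.2)
    counts <- pmin(counts, K)
    mask <- runif(O) > 0.2
    if (!any(mask)) mask[1] <- TRUE
    got <- site_marginal_loglik(counts, lambda, p = p, Z = 1, K = K,
                                mask = mask, detection = detection,
                                rate = rate)
    want <- oracle_site_marginal(counts, lambda, p = p, Z = 1, K = K,
                                 mask = mask, detection = detection,
                                 rate = rate)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("marginal likelihood is invariant to K beyond convergence", {
  set.seed(5)
  for (rep in 1:10) {
    O <- 3
    lambda <- runif(1, 0.2, 5)
    p <- runif(O, 0.1, 0.9)
    counts <- rpois(O, 1)
    K <- 60
    a <- site_marginal_loglik(counts, lambda, p = p, Z = 1, K = K)
    b <- site_marginal_loglik(counts, lambda, p = p, Z = 1, K = 2 * K)
    expect_lt(abs(a - b), 1e-8)
  }
})

test_that("iZIP reduces to Poisson when Z is identically 1", {
  data <- make_tiny_data(J = 4, O = 3)
  params <- default_params(data)
  for (det in c("binomial", "poisson")) {
    a <- joint_log_density(data, params,
                           model_spec("izip", det, odre = FALSE, K = 25))
    b <- joint_log_density(data, params,
                           model_spec("poisson", det, odre = FALSE, K = 25))
    expect_identical(a, b)
  }
})

test_that("ODRE-on with all eps = 0 reduces to ODRE-off", {
  data <- make_tiny_data(J = 4, O = 3)
  # eps = 0 everywhere: identical detection probabilities, and the
  # eps-density terms are excluded alongside the eps values themselves
  p_on <- joint_log_density(data, default_params(data),
                            model_spec(odre = TRUE, K = 25))
  p_off <- joint_log_density(data, default_params(data),
                             model_spec(odre = FALSE, K = 25))
  expect_identical(p_on, p_off)
  # and detection_prob with eps = 0 is the no-ODRE probability
  expect_equal(detection_prob(0.3, 0.1, 0.2, eps = 0),
               detection_prob(0.3, 0.1, 0.2))
})

test_that("joint density decomposes and matches the enumeration oracle", {
  # delta = 0: the joint observation model is the sum of two independent
  # site marginals
  data <- make_tiny_data(J = 2, O = 1,
                         counts = array(c(1L, 2L, 0L, 1L), c(2, 2, 1)))
  params <- default_params(data, delta = 0)
  spec <- model_spec(odre = FALSE, K = 20)
  lam1 <- abundance_linpred(data$covariates, params$alpha0[1],
                            params$alpha[1, ], params$land[1, ])
  lam2 <- abundance_linpred(data$covariates, params$alpha0[2],
                            params$alpha[2, ], params$land[2, ],
                            delta = 0, N_dom = rep(0, 2))
  expected <- sum(dnorm(params$land, 0, 0.5, log = TRUE))
  for (j in 1:2) {
    for (i in 1:2) {
      lam <- if (i == 1) lam1[j] else lam2[j]
      p <- detection_prob(data$covariates$effort_std[j],
                          params$beta0[i], params$beta1[i])
      expected <- expected +
        site_marginal_loglik(data$history$counts[i, j, ], lam, p = p,
                             Z = 1, K = 20)
    }
  }
  expect_equal(joint_log_density(data, params, spec), expected,
               tolerance = 1e-10)

  # masked cells contribute nothing
  data2 <- make_tiny_data(J = 2, O = 2)
  mask <- array(TRUE, c(2, 2, 2)); mask[1, 1, 2] <- FALSE
  counts <- data2$history$counts
  d_masked <- make_tiny_data(J = 2, O = 2, counts = counts, mask = mask)
  ll1 <- joint_log_density(d_masked, default_params(d_masked), spec)
  counts2 <- counts; counts2[1, 1, 2] <- counts2[1, 1, 2] + 7L
  d_masked2 <- make_tiny_data(J = 2, O = 2, counts = counts2, mask = mask)
  ll2 <- joint_log_density(d_masked2, default_params(d_masked2), spec)
  expect_identical(ll1, ll2)

  # full marginalization matches nested exhaustive enumeration with a
  # nonzero interaction, including an extirpated unit
  set.seed(31)
  counts <- array(rpois(2 * 2 * 2, 1), c(2, 2, 2))
  counts[1, 2, ] <- 0L
  Z <- matrix(1L, 2, 2); Z[1, 2] <- 0L
  data3 <- make_tiny_data(J = 2, O = 2, counts = counts, Z = Z,
                          landscape = c("A", "B"))
  for (det in c("binomial", "poisson")) {
    spec3 <- model_spec("izip", det, odre = TRUE, K = 10)
    eps <- array(rnorm(2 * 2 * 2, 0, 0.3), c(2, 2, 2))
    params3 <- default_params(data3, delta = -0.4, eps = eps)
    got <- joint_log_density(data3, params3, spec3)
    want <- oracle_joint_obs(data3, params3, spec3, Kmax = 10) +
      sum(dnorm(params3$land, 0, 0.5, log = TRUE)) +
      sum(dnorm(eps, 0, 0.5, log = TRUE))
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("prior density has the stated support and symmetry", {
  data <- make_tiny_data(J = 4, O = 2)
  p1 <- default_params(data)
  spec <- model_spec()

  p_bad <- p1; p_bad$tau <- c(6, 0.5)
  expect_identical(prior_log_density(p_bad, spec), -Inf)

  p0 <- coabund_params(alpha0 = c(0, 0), alpha = matrix(0, 2, 2),
                       land = matrix(0, 2, 2), sigma_land = c(1, 1),
                       delta = 0, beta0 = c(0, 0), beta1 = c(0, 0),
                       tau = c(1, 1))
  want <- 11 * dnorm(0, 0, 10, log = TRUE) + 4 * dunif(1, 0, 5, log = TRUE)
  expect_equal(prior_log_density(p0, spec), want, tolerance = 1e-12)

  pa <- p1; pa$delta <- 0.7
  pb <- p1; pb$delta <- -0.7
  expect_equal(prior_log_density(pa, spec), prior_log_density(pb, spec))
})

test_that("simulated counts match the binomial-detection expectation", {
  # E[n] = p * lambda; law of large numbers at 1e5 draws
  set.seed(101)
  lambda <- 2; p <- 0.5
  N <- rpois(1e5, lambda)
  n <- rbinom(1e5, N, p)
  expect_equal(mean(n), p * lambda, tolerance = 0.01)
})
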