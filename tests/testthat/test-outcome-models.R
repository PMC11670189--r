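test_that("GP covariance matches the elementwise kernel and is PD", {
  K <- gp_covariance(5, amplitude = 1, lengthscale = 2, jitter = 1e-6)
  for (i in 1:5) for (j in 1:5)
    expect_equal(K[i, j], exp(-(i - j)^2 / 8) + (i == j) * 1e-6,
                 tolerance = 1e-12)
  expect_equal(diag(gp_covariance(4, 2, 1, jitter = 0.01)),
               rep(4.01, 4), tolerance = 1e-12)
  # lengthscale -> 0: off-diagonals vanish
  K0 <- gp_covariance(4, 1, 1e-4)
  expect_lt(max(abs(K0[upper.tri(K0)])), 1e-12)
  # PD across a hyperparameter grid (Cholesky succeeds)
  for (a in c(0.1, 1, 5)) for (l in c(0.3, 1, 3, 10, 40))
    expect_no_error(chol(gp_covariance(19, a, l)))
  expect_error(gp_covariance(3, -1, 1), "positive")
})

test_that("GP prior draws get smoother as the lengthscale grows", {
  set.seed(9)
  lag1 <- sapply(c(0.5, 2, 8), function(l) {
    L <- t(chol(gp_covariance(40, 1, l)))
    draws <- L %*% matrix(rnorm(40 * 400), 40)
    mean(apply(draws, 2, function(v) cor(v[-1], v[-40])))
  })
  expect_true(all(diff(lag1) > 0))
})

test_that("linear predictor assembles every term of the hierarchical model", {
  res <- make_test_panel(n_children = 40, seed = 11)
  panel <- res$panel
  years <- seq(min(panel$year), max(panel$year))
  mids <- unique(panel$mother_id[panel$mother_id != "EXTERNAL"])
  fids <- unique(panel$father_id[panel$father_id != "EXTERNAL"])
  set.seed(12)
  p <- make_parameter_set("mother", years = years, mother_ids = mids,
                          father_ids = fids, alpha = 0.3)
  p$beta[] <- rnorm(length(p$beta), 0, 0.5)
  p$gamma <- rnorm(10); p$eps_year[] <- rnorm(length(years))
  p$kappa[] <- rnorm(length(mids)); p$eta[] <- rnorm(length(fids))

  theta <- linear_predictor(panel, p)
  X <- model_matrix(panel, "mother")
  for (i in sample(nrow(panel), 25)) {   # term-by-term manual summation
    want <- p$alpha + p$gamma[min(panel$bo_cat[i], 10)] +
      p$eps_year[as.character(panel$year[i])] +
      (if (panel$mother_id[i] %in% mids) p$kappa[panel$mother_id[i]] else 0) +
      (if (panel$father_id[i] %in% fids) p$eta[panel$father_id[i]] else 0) +
      sum(p$beta[, panel$age[i] + 1] * X[i, ])
    expect_equal(theta[i], unname(want), tolerance = 1e-12)
  }
  # base case: all covariates zero, all random effects zero
  p0 <- make_parameter_set("mother", years = years, alpha = 0.3)
  base_row <- panel[panel$mother_state == "BIO_MONO" &
                      panel$father_state == "BIO_MONO" &
                      panel$male == 0 & panel$twin == 0, ][1, ]
  expect_equal(linear_predictor(base_row, p0), 0.3)
  # male adds beta[1,a] + beta[2,a] relative to alpha when only those are set
  p0$beta["intercept", ] <- 0.7
  p0$beta["male", ] <- -0.2
  male_row <- base_row; male_row$male <- 1L
  expect_equal(linear_predictor(male_row, p0), 0.3 + 0.7 - 0.2)
})

test_that("survival log-likelihood matches a per-row loop and factorizes", {
  res <- make_test_panel(n_children = 50, seed = 13)
  panel <- res$panel
  p <- res$truth$survival
  got <- survival_loglik(panel, p)
  theta <- linear_predictor(panel, p)
  want <- sum(dbinom(panel$survived, 1, plogis(theta), log = TRUE))
  expect_equal(got, want, tolerance = 1e-10)
  # one row at theta = 0 contributes log(0.5) regardless of outcome
  one <- panel[1, ]; p0 <- make_parameter_set("mother", years = 1990:2014)
  expect_equal(survival_loglik(one, p0), log(0.5))
  one$survived <- 0L
  expect_equal(survival_loglik(one, p0), log(0.5))
  # disjoint child sets add
  kids <- unique(panel$child_id)
  a <- panel[panel$child_id %in% kids[1:20], ]
  b <- panel[!panel$child_id %in% kids[1:20], ]
  class(a) <- class(b) <- class(panel)
  expect_equal(survival_loglik(a, p) + survival_loglik(b, p), got,
               tolerance = 1e-10)
  bad <- panel; bad$survived[1] <- 2L
  expect_error(survival_loglik(bad, p), "0 or 1")
})

test_that("height and weight log-likelihoods match closed-form evaluation", {
  res <- make_test_panel(n_children = 60, seed = 17)
  panel <- res$panel
  hp <- res$truth$height
  rows <- panel[!is.na(panel$height_cm), ]
  theta <- linear_predictor(rows, hp)
  expect_equal(height_loglik(panel, hp),
               sum(dnorm(log(rows$height_cm), theta, hp$lambda, log = TRUE)),
               tolerance = 1e-10)
  # zero-residual row sits at the Normal mode
  one <- rows[1, ]
  hp2 <- hp; one$height_cm <- exp(linear_predictor(one, hp))
  expect_equal(height_loglik(one, hp2),
               dnorm(0, 0, hp$lambda, log = TRUE), tolerance = 1e-10)
  # doubling lambda lowers the density of small residuals (closed form)
  hp3 <- hp; hp3$lambda <- 2 * hp$lambda
  expect_lt(height_loglik(one, hp3), height_loglik(one, hp2))

  wp <- res$truth$weight
  wrows <- panel[!is.na(panel$weight_kg), ]
  mu <- linear_predictor(wrows, wp) +
    wp$beta_height[wrows$age + 1] *
      (log(wrows$height_cm) - wp$height_center[wrows$age + 1])
  expect_equal(weight_loglik(panel, wp),
               sum(dnorm(log(wrows$weight_kg), mu, wp$lambda, log = TRUE)),
               tolerance = 1e-10)
  # with beta_height = 0 the weight model nests the height-model form
  wp0 <- wp; wp0$beta_height[] <- 0
  expect_equal(weight_loglik(panel, wp0),
               sum(dnorm(log(wrows$weight_kg), linear_predictor(wrows, wp),
                         wp$lambda, log = TRUE)), tolerance = 1e-10)
  # weight rows require height
  broken <- panel; broken$height_cm[!is.na(broken$weight_kg)][1] <- NA
  expect_error(weight_loglik(broken, wp), "requires height")
})

test_that("ZIP log-pmf matches the mixture formula and normalizes", {
  expect_equal(zip_logpmf(0, 1, 5), 0)
  expect_equal(zip_logpmf(0, 0.3, 2), log(0.3 + 0.7 * exp(-2)),
               tolerance = 1e-12)
  expect_equal(zip_logpmf(3, 0.3, 2), log(0.7) + dpois(3, 2, log = TRUE),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    p <- runif(1); r <- runif(1, 0.1, 20)
    total <- sum(exp(zip_logpmf(0:400, p, r)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
  expect_error(zip_logpmf(-1, 0.5, 1), "non-negative")
  expect_error(zip_logpmf(1, 1.2, 1), "\\[0, 1\\]")
})

test_that("education log-likelihood composes the two ZIP predictors", {
  res <- make_test_panel(n_children = 60, seed = 19)
  panel <- res$panel
  ep <- res$truth$education
  rows <- panel[!is.na(panel$edu_years), ]
  p_never <- plogis(linear_predictor(rows, ep$theta))
  rate <- exp(linear_predictor(rows, ep$rate))
  expect_equal(education_loglik(panel, ep),
               sum(zip_logpmf(rows$edu_years, p_never, rate)),
               tolerance = 1e-10)
  # single observed row equals the pmf directly
  single <- panel[!is.na(panel$edu_years), ][3, ]
  expect_equal(education_loglik(single, ep),
               zip_logpmf(single$edu_years,
                          plogis(linear_predictor(single, ep$theta)),
                          exp(linear_predictor(single, ep$rate))),
               tolerance = 1e-12)
  # saturated zeros with p_never -> 1 have log-likelihood -> 0
  sat <- rows; sat$edu_years <- 0L
  class(sat) <- class(panel)
  ep1 <- ep; ep1$theta$alpha <- 40
  expect_equal(education_loglik(sat, ep1), 0, tolerance = 1e-10)
})

test_that("log-density oracles hold on a thousand random inputs", {
  set.seed(23)
  n <- 1000
  # Bernoulli-logit
  theta <- rnorm(n, 0, 2); s <- rbinom(n, 1, 0.5)
  ours <- ifelse(s == 1, plogis(theta, log.p = TRUE),
                 plogis(-theta, log.p = TRUE))
  brute <- log(ifelse(s == 1, 1 / (1 + exp(-theta)),
                      1 - 1 / (1 + exp(-theta))))
  expect_lt(max(abs(ours - brute) / pmax(abs(brute), 1)), 1e-10)
  # Normal
  y <- rnorm(n); mu <- rnorm(n); sd <- runif(n, 0.2, 3)
  expect_lt(max(abs(dnorm(y, mu, sd, log = TRUE) -
                      (-log(sd) - 0.5 * log(2 * pi) -
                         0.5 * ((y - mu) / sd)^2))), 1e-10)
  # ZIP against direct mixture arithmetic
  yz <- rpois(n, 2); pz <- runif(n); rz <- runif(n, 0.1, 10)
  brute_zip <- log(pz * (yz == 0) + (1 - pz) * dpois(yz, rz))
  expect_lt(max(abs(zip_logpmf(yz, pz, rz) - brute_zip) /
                  pmax(abs(brute_zip), 1)), 1e-10)
})
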