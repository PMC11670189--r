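test_that("assembled joint density = prior + outcome likelihood (all outcomes)", {
  res <- make_test_panel(n_children = 40, seed = 7, sex_unknown = 0)
  panel <- res$panel
  for (oc in c("survival", "height", "weight", "education")) {
    fc <- fit_config(oc, chains = 2, seed = 1)
    m <- assemble_model(panel, fc)
    set.seed(101)
    q <- rnorm(m$n_par, 0, 0.4)
    p1 <- r_unpack_params(q, m, 1L)
    loglik <- switch(oc,
                     survival = survival_loglik(panel, p1),
                     height = height_loglik(panel, p1),
                     weight = weight_loglik(panel, p1),
                     education = education_loglik(
                       panel, list(theta = p1, rate = r_unpack_params(q, m, 2L))))
    expect_equal(m$lp(q)$value, r_log_prior(q, m) + loglik,
                 tolerance = 1e-8, info = oc)
  }
  # empty likelihood: a panel with no observed outcome leaves the prior alone
  blank <- panel; blank$edu_years[] <- NA_integer_
  class(blank) <- class(panel)
  fc <- fit_config("education", chains = 2, seed = 1)
  m0 <- assemble_model(blank, fc)
  q0 <- rnorm(m0$n_par, 0, 0.3)
  expect_equal(m0$lp(q0)$value, r_log_prior(q0, m0), tolerance = 1e-8)
})

test_that("compiled gradient matches numerical differentiation", {
  res <- make_test_panel(n_children = 30, seed = 3,
                         sex_unknown = 0.15)  # exercises the sex mixture
  panel <- res$panel
  for (oc in c("survival", "height", "education")) {
    fc <- fit_config(oc, chains = 2, seed = 1)
    m <- assemble_model(panel, fc)
    set.seed(77)
    q <- rnorm(m$n_par, 0, 0.3)
    g <- m$lp(q)$grad
    idx <- sample(m$n_par, 40)
    for (j in idx) {
      e <- 1e-6
      qp <- q; qp[j] <- q[j] + e
      qm <- q; qm[j] <- q[j] - e
      num <- (m$lp(qp)$value - m$lp(qm)$value) / (2 * e)
      expect_equal(g[j], num, tolerance = 1e-4,
                   info = sprintf("%s par %s", oc, m$par_names[j]))
    }
  }
})

test_that("unknown-sex mixture equals explicit two-branch enumeration", {
  res <- make_test_panel(n_children = 30, seed = 3, sex_unknown = 0.2)
  panel <- res$panel
  fc <- fit_config("survival", chains = 2, seed = 1)
  m <- assemble_model(panel, fc)
  set.seed(5)
  q <- rnorm(m$n_par, 0, 0.3)
  p1 <- r_unpack_params(q, m, 1L)
  pm <- m$data$pm
  kids <- unique(panel$child_id)
  loglik <- 0
  for (k in kids) {
    rows <- panel[panel$child_id == k, ]
    class(rows) <- class(panel)
    if (is.na(rows$male[1])) {
      r0 <- rows; r0$male <- 0L
      r1 <- rows; r1$male <- 1L
      loglik <- loglik + log(pm * exp(survival_loglik(r1, p1)) +
                               (1 - pm) * exp(survival_loglik(r0, p1)))
    } else {
      loglik <- loglik + survival_loglik(rows, p1)
    }
  }
  expect_equal(m$lp(q)$value, r_log_prior(q, m) + loglik, tolerance = 1e-8)
})

test_that("likelihood depends on natural parameters only (reparameterization)", {
  res <- make_test_panel(n_children = 30, seed = 9)
  fc <- fit_config("survival", chains = 2, seed = 1)
  m <- assemble_model(res$panel, fc)
  set.seed(31)
  q1 <- rnorm(m$n_par, 0, 0.3)
  # rescale one effect's amplitude by c and its innovations by 1/c: the
  # natural beta row is unchanged, so the likelihood part must be identical
  A <- m$data$A; K <- ncol(m$data$X)
  q2 <- q1
  k <- 3L
  q2[1 + ((k - 1) * A + 1):(k * A)] <- q1[1 + ((k - 1) * A + 1):(k * A)] / 2
  q2[1 + K * A + k] <- q1[1 + K * A + k] + log(2)
  lik1 <- m$lp(q1)$value - r_log_prior(q1, m)
  lik2 <- m$lp(q2)$value - r_log_prior(q2, m)
  expect_equal(lik1, lik2, tolerance = 1e-8)
})

test_that("sampler recovers a conjugate Normal posterior and is reproducible", {
  set.seed(1)
  toy <- conjugate_toy(rnorm(25, 1.3, 1))
  fc <- fit_config("survival", chains = 2, warmup = 300, samples = 600,
                   seed = 42, max_treedepth = 4)
  d1 <- quiet_mcmc(toy, fc)
  mu <- draw_matrix(d1)[, 1]
  mcse <- sd(mu) / sqrt(ess_mean(sapply(d1$chains, function(ch) ch[, 1])))
  expect_lt(abs(mean(mu) - toy$post_mean), 4 * mcse + 0.01)
  expect_equal(sd(mu), toy$post_sd, tolerance = 0.15)
  # same seed twice: identical draws
  d2 <- quiet_mcmc(toy, fc)
  expect_identical(d1$chains, d2$chains)
  # different seed: different draws
  fc3 <- fit_config("survival", chains = 2, warmup = 300, samples = 600,
                    seed = 43, max_treedepth = 4)
  expect_false(identical(quiet_mcmc(toy, fc3)$chains[[1]], d1$chains[[1]]))
})

test_that("Monte Carlo error shrinks about sqrt(2) when draws double", {
  set.seed(2)
  toy <- conjugate_toy(rnorm(20, 0.5, 1))
  est <- function(samples, seed) {
    fc <- fit_config("survival", chains = 2, warmup = 150, samples = samples,
                     seed = seed, max_treedepth = 4)
    mean(draw_matrix(quiet_mcmc(toy, fc)))
  }
  e1 <- sapply(1:24, function(s) est(120L, 100L + s))
  e2 <- sapply(1:24, function(s) est(480L, 200L + s))
  ratio <- sd(e1) / sd(e2)
  expect_gt(ratio, 1.3)   # expect about 2, allow wide Monte Carlo slack
  expect_lt(ratio, 3.2)
})

test_that("initialization failure reports clearly", {
  bad <- list(lp = function(par) list(value = NaN, grad = par),
              n_par = 3L, par_names = c("a", "b", "c"))
  fc <- fit_config("survival", chains = 2, warmup = 50, samples = 50, seed = 1)
  expect_error(quiet_mcmc(bad, fc), "initialization error")
})

test_that("recovery report is exact in the degenerate truth-equals-draws case", {
  res <- make_test_panel(n_children = 25, seed = 15)
  fc <- fit_config("survival", chains = 2, warmup = 60, samples = 40,
                   seed = 4, max_treedepth = 3)
  m <- assemble_model(res$panel, fc)
  # draws concentrated at one fixed point: zero bias against its own implied
  # truth and full coverage (tiny jitter keeps the intervals non-degenerate)
  q <- rep(0.2, m$n_par)
  set.seed(8)
  mk <- function() matrix(rep(q, 30), 30, byrow = TRUE,
                          dimnames = list(NULL, m$par_names)) +
    rnorm(30 * m$n_par, 0, 1e-6)
  fake <- structure(list(chains = list(mk(), mk()),
                         par_names = m$par_names, seed = 4L,
                         config = fc), class = "fam_draws")
  truth <- r_unpack_params(q, m, 1L)
  rep_tab <- parameter_recovery_report(truth, fake, m)
  expect_true(all(abs(rep_tab$bias) < 1e-4))
  expect_true(all(rep_tab$rmse < 1e-4))
  expect_true(all(rep_tab$covered))
  # dimension mismatch is refused
  short <- truth; short$beta <- truth$beta[, 1:10]
  expect_error(parameter_recovery_report(short, fake, m), "age columns")
})

test_that("draws round-trip through the columnar file with metadata", {
  set.seed(3)
  toy <- conjugate_toy(rnorm(10))
  fc <- fit_config("survival", chains = 2, warmup = 100, samples = 80,
                   seed = 11, max_treedepth = 3)
  d <- quiet_mcmc(toy, fc)
  path <- file.path(withr::local_tempdir(), "draws.csv")
  write_draws(d, path)
  expect_true(file.exists(paste0(path, ".meta.json")))
  d2 <- read_draws(path)
  expect_equal(d2$chains[[1]], d$chains[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(d2$seed, 11L)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  expect_identical(meta$config$samples, 80L)
})

test_that("90% HPDIs are calibrated when truth is drawn from the prior", {
  # reduced-scale simulation-based calibration: draw the generating
  # parameters from the model's own prior, simulate survival data, refit,
  # and check the global intercept's 90% HPDI coverage across replicates
  sc <- sim_config(n_children = 25L, year_range = c(2000L, 2014L), seed = 55,
                   p_sex_unknown = 0)
  h <- simulate_histories(sc)
  tl <- build_marriage_timeline(h$spells, h$vitals, year_range = sc$year_range)
  panel0 <- build_child_year_panel(h$children, tl,
                                   survey_years = sc$survey_years)
  fc0 <- fit_config("survival", chains = 2L, warmup = 150L, samples = 120L,
                    seed = 1L, max_treedepth = 4L)
  m <- assemble_model(panel0, fc0)
  pr <- fc0$prior
  draw_prior_q <- function() {
    q <- rnorm(m$n_par)            # alpha and all z innovations
    amp <- grepl("log_amp|log_sigma", m$par_names)
    q[amp] <- log(abs(rnorm(sum(amp), 0, pr$amp_sd)))
    ls <- grepl("log_ls", m$par_names)
    q[ls] <- rnorm(sum(ls), pr$ls_meanlog, pr$ls_sdlog)
    q
  }
  n_rep <- 50L
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    q_true <- draw_prior_q()
    truth <- r_unpack_params(q_true, m, 1L)
    sim <- simulate_outcomes(panel0, list(survival = truth),
                             seed = 7500 + r, records = h$children)
    fc <- fit_config("survival", chains = 2L, warmup = 150L, samples = 120L,
                     seed = 7000 + r, max_treedepth = 4L)
    fit <- quiet_mcmc(assemble_model(sim$panel, fc), fc)
    hp <- hpdi(draw_matrix(fit)[, 1], 0.90)   # unconstrained alpha
    covered[r] <- hp[1] <= q_true[1] && q_true[1] <= hp[2]
  }
  # nominal 0.9 within ~3 binomial standard errors over 50 replicates
  expect_gte(mean(covered), 0.76)
})
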