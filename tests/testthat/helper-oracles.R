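# Independent oracles and shared fixtures for the test suite.

# brute-force per-year spouse scan over raw spells, capped at both partners'
# death years (membership through the death year inclusive)
brute_spouses <- function(spells, vitals, parent, year, max_year = 2014L) {
  death <- setNames(vitals$death_year, vitals$parent_id)
  out <- character(0)
  both <- rbind(
    data.frame(p = spells$parent_id, s = spells$spouse_id,
               a = spells$start_year, b = spells$end_year),
    {
      known <- !(is.na(spells$spouse_id) | spells$spouse_id == "EXTERNAL")
      data.frame(p = spells$spouse_id[known], s = spells$parent_id[known],
                 a = spells$start_year[known], b = spells$end_year[known])
    })
  for (i in seq_len(nrow(both))) {
    if (both$p[i] != parent) next
    b <- if (is.na(both$b[i])) max_year else both$b[i]
    dp <- death[both$p[i]]; ds <- death[both$s[i]]
    if (!is.na(dp)) b <- min(b, dp)
    if (!is.na(ds) && !is.na(both$s[i])) b <- min(b, ds)
    if (year >= both$a[i] && year <= b) out <- c(out, both$s[i])
  }
  sort(unique(out))
}

# exhaustive O(n^2) window scan for the narrowest mass-covering interval
brute_hpdi <- function(x, mass = 0.9) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(x[1], x[n]); bw <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < bw - 1e-15) { bw <- w; best <- c(x[i], x[i + m - 1]) }
  }
  best
}

# small simulated panel with outcomes for likelihood / inference tests
make_test_panel <- function(n_children = 50, seed = 7, sex_unknown = 0,
                            year_range = c(1990L, 2014L),
                            inject = NULL) {
  sc <- sim_config(n_children = n_children, year_range = year_range,
                   seed = seed, p_sex_unknown = sex_unknown)
  h <- simulate_histories(sc)
  tl <- build_marriage_timeline(h$spells, h$vitals, year_range = year_range)
  panel <- build_child_year_panel(h$children, tl,
                                  survey_years = sc$survey_years)
  tp <- make_true_params(years = seq(year_range[1], year_range[2]))
  if (!is.null(inject)) tp <- inject(tp)
  sim <- simulate_outcomes(panel, tp, seed = seed + 1L, records = h$children)
  list(panel = sim$panel, records = sim$records, truth = tp, config = sc,
       histories = h, timeline = tl)
}

# R mirror of the sampler's unconstrained parameterization: unpack one stack
# of a parameter vector into a fam_params object (independent reimplementation
# of the transform used in src/loglik.cpp, via R's chol())
r_unpack_params <- function(q, model, stack = 1L) {
  d <- model$data
  K <- ncol(d$X); A <- d$A; G <- d$G; Yn <- d$Yn; M <- d$M; Fn <- d$Fn
  i <- (stack - 1L) * model$meta$stack_size
  take <- function(n) { v <- q[(i + 1):(i + n)]; i <<- i + n; v }
  sqexp_L <- function(n, ls) {
    dd <- outer(seq_len(n), seq_len(n), `-`)
    t(chol(exp(-dd^2 / (2 * ls^2)) + 1e-6 * diag(n)))
  }
  alpha <- take(1)
  zb <- matrix(take(K * A), A, K)
  la <- take(K); ll <- take(K)
  beta <- matrix(0, K, A, dimnames = list(colnames(d$X), NULL))
  for (k in seq_len(K))
    beta[k, ] <- exp(la[k]) * as.numeric(sqexp_L(A, exp(ll[k])) %*% zb[, k])
  zg <- take(G); lag <- take(1); llg <- take(1)
  gam <- exp(lag) * as.numeric(sqexp_L(G, exp(llg)) %*% zg)
  ze <- take(Yn); lae <- take(1); lle <- take(1)
  eps <- exp(lae) * as.numeric(sqexp_L(Yn, exp(lle)) %*% ze)
  zk <- if (M > 0) take(M) else numeric(0)
  lsk <- take(1)
  zf <- if (Fn > 0) take(Fn) else numeric(0)
  lsf <- take(1)

  eff <- setdiff(colnames(d$X), "logH_c")
  p <- make_parameter_set(model$meta$config$perspective, n_age = A,
                          bo_levels = G, years = model$meta$years,
                          mother_ids = model$meta$mother_ids,
                          father_ids = model$meta$father_ids)
  p$alpha <- alpha
  p$beta <- beta[eff, , drop = FALSE]
  if ("logH_c" %in% colnames(d$X)) {
    p$beta_height <- beta["logH_c", ]
    p$height_center <- model$meta$height_center
  }
  p$gamma <- gam
  p$eps_year <- setNames(eps, model$meta$years)
  p$kappa <- setNames(exp(lsk) * zk, model$meta$mother_ids)
  p$eta <- setNames(exp(lsf) * zf, model$meta$father_ids)
  if (model$data$type == 2L) p$lambda <- exp(q[model$n_par])
  attr(p, "hyper") <- list(la = la, ll = ll, lag = lag, llg = llg,
                           lae = lae, lle = lle, lsk = lsk, lsf = lsf,
                           z2 = sum(zb^2) + sum(zg^2) + sum(ze^2) +
                             sum(zk^2) + sum(zf^2))
  p
}

# R mirror of the prior log-density (same closed forms as the compiled code)
r_log_prior <- function(q, model) {
  pr <- model$data$prior
  half_normal <- function(u, sd) -0.5 * exp(u)^2 / sd^2 + u
  lognormal_ls <- function(u) -0.5 * ((u - pr$ls_meanlog) / pr$ls_sdlog)^2
  stacks <- if (model$data$type == 3L) 1:2 else 1L
  lp <- 0
  for (s in stacks) {
    p <- r_unpack_params(q, model, s)
    h <- attr(p, "hyper")
    lp <- lp - 0.5 * p$alpha^2 / pr$alpha_sd^2 - 0.5 * h$z2 +
      sum(half_normal(h$la, pr$amp_sd)) + sum(lognormal_ls(h$ll)) +
      half_normal(h$lag, pr$amp_sd) + lognormal_ls(h$llg) +
      half_normal(h$lae, pr$amp_sd) + lognormal_ls(h$lle) +
      half_normal(h$lsk, pr$sigma_sd) + half_normal(h$lsf, pr$sigma_sd)
  }
  if (model$data$type == 2L)
    lp <- lp + half_normal(q[model$n_par], pr$lambda_sd)
  lp
}

# toy differentiable model for the sampler: Normal(mu, sd) likelihood with
# Normal(m0, s0) prior on mu -> conjugate Normal posterior
conjugate_toy <- function(y, sd = 1, m0 = 0, s0 = 2) {
  lp <- function(par) {
    mu <- par[1]
    list(value = sum(dnorm(y, mu, sd, log = TRUE)) +
           dnorm(mu, m0, s0, log = TRUE),
         grad = sum(y - mu) / sd^2 - (mu - m0) / s0^2)
  }
  post_var <- 1 / (length(y) / sd^2 + 1 / s0^2)
  post_mean <- post_var * (sum(y) / sd^2 + m0 / s0^2)
  list(lp = lp, n_par = 1L, par_names = "mu",
       post_mean = post_mean, post_sd = sqrt(post_var))
}

quiet_mcmc <- function(model, config) {
  suppressWarnings(run_mcmc(model, config))
}
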