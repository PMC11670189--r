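## The four outcome likelihoods and the Gaussian-process prior kernel, as
## pure log-density computations over a child-year panel. These are the
## reference implementations; the sampler uses a compiled equivalent that is
## cross-checked against them.

#' Effect names of the age-specific coefficient matrix
#'
#' Row order of the `beta` matrix for each model perspective. The mother
#' perspective carries an age-specific intercept, male and twin effects, and
#' the indicators father-deceased (F), mother-deceased (X), mother-unmarried
#' (W), step-father (Z), mother-in-polygyny (P) and external parent (U). The
#' `"split"` coding replaces the single P with separate with-biological-father
#' (PB) and with-step-father (PN) polygyny indicators. The father perspective
#' uses mother-deceased, father-deceased, father-unmarried (WF), step-mother
#' (ZF), polygyny with (PBF) / without (PNF) the biological mother, and U.
#'
#' @param perspective `"mother"` or `"father"`.
#' @param mother_poly_coding `"single"` (one polygyny indicator) or `"split"`.
#' @return character vector of effect names.
#' @export
model_effects <- function(perspective = c("mother", "father"),
                          mother_poly_coding = c("single", "split")) {
  perspective <- match.arg(perspective)
  mother_poly_coding <- match.arg(mother_poly_coding)
  if (perspective == "father") {
    c("intercept", "male", "twin", "X", "F", "WF", "ZF", "PBF", "PNF", "U")
  } else if (mother_poly_coding == "single") {
    c("intercept", "male", "twin", "F", "X", "W", "Z", "P", "U")
  } else {
    c("intercept", "male", "twin", "F", "X", "W", "Z", "PB", "PN", "U")
  }
}

#' Covariate matrix for a panel under one perspective
#'
#' @param panel a `fam_panel`.
#' @inheritParams model_effects
#' @param male_na_zero unknown-sex rows get 0 in the male column (their sex
#'   contribution is handled by a mixture in the fitted likelihood).
#' @return numeric matrix, one column per [model_effects()] entry.
#' @export
model_matrix <- function(panel, perspective = c("mother", "father"),
                         mother_poly_coding = c("single", "split"),
                         male_na_zero = FALSE) {
  perspective <- match.arg(perspective)
  mother_poly_coding <- match.arg(mother_poly_coding)
  male <- panel$male
  if (male_na_zero) male[is.na(male)] <- 0L
  base <- cbind(intercept = rep(1, nrow(panel)), male = male,
                twin = panel$twin)
  ext <- if (perspective == "father") {
    cbind(X = panel$X, F = panel$F, WF = panel$WF, ZF = panel$ZF,
          PBF = panel$PBF, PNF = panel$PNF, U = panel$U)
  } else if (mother_poly_coding == "single") {
    cbind(F = panel$F, X = panel$X, W = panel$W, Z = panel$Z, P = panel$P,
          U = panel$U)
  } else {
    cbind(F = panel$F, X = panel$X, W = panel$W, Z = panel$Z,
          PB = as.integer(panel$mother_state == "BIO_POLY"),
          PN = as.integer(panel$mother_state == "STEP_POLY"),
          U = panel$U)
  }
  m <- cbind(base, ext)
  storage.mode(m) <- "double"
  m
}

#' Zero-initialised parameter set for one outcome model
#'
#' Container for every parameter of the hierarchical linear predictor: global
#' intercept `alpha`; `beta`, an effect-by-age matrix of age-specific
#' coefficients; `gamma` over birth-order categories; `eps_year` over calendar
#' years; `kappa` and `eta`, mother- and father-identity random effects;
#' residual scale `lambda` for the log-normal models; and for the weight model
#' an age-specific coefficient `beta_height` on centred log height with its
#' centring constants `height_center`.
#'
#' @inheritParams model_effects
#' @param n_age number of age categories (ages `0..n_age-1`).
#' @param bo_levels number of birth-order categories.
#' @param years calendar years the year effect covers.
#' @param mother_ids,father_ids identity levels for the parent random effects.
#' @param alpha,lambda scalar initial values.
#' @return list with class `fam_params`.
#' @export
make_parameter_set <- function(perspective = "mother", n_age = 19L,
                               bo_levels = 10L, years = integer(0),
                               mother_ids = character(0),
                               father_ids = character(0),
                               alpha = 0, lambda = 1,
                               mother_poly_coding = "single") {
  eff <- model_effects(perspective, mother_poly_coding)
  structure(list(
    perspective = perspective,
    alpha = alpha,
    beta = matrix(0, length(eff), n_age,
                  dimnames = list(eff, paste0("age", seq_len(n_age) - 1L))),
    gamma = numeric(bo_levels),
    eps_year = setNames(numeric(length(years)), as.character(years)),
    kappa = setNames(numeric(length(mother_ids)), mother_ids),
    eta = setNames(numeric(length(father_ids)), father_ids),
    lambda = lambda,
    beta_height = numeric(n_age),
    height_center = numeric(n_age)
  ), class = "fam_params")
}

#' Squared-exponential Gaussian-process covariance over ordered levels
#'
#' `k(i, j) = amplitude^2 * exp(-(i - j)^2 / (2 * lengthscale^2))`, plus
#' `jitter` on the diagonal. This is the prior over age-, birth-order- and
#' year-indexed effect vectors: it pools neighbouring categories without
#' imposing a functional form.
#'
#' @param n_levels number of ordered levels (>= 1).
#' @param amplitude,lengthscale positive kernel hyperparameters; the
#'   lengthscale is in units of level index.
#' @param jitter small positive diagonal stabiliser.
#' @return symmetric positive-definite matrix `n_levels x n_levels`.
#' @export
gp_covariance <- function(n_levels, amplitude, lengthscale, jitter = 1e-6) {
  if (n_levels < 1L) stop_validation("n_levels must be >= 1")
  if (amplitude <= 0 || lengthscale <= 0 || jitter < 0)
    stop_validation("GP hyperparameters must be positive")
  d <- outer(seq_len(n_levels), seq_len(n_levels), `-`)
  amplitude^2 * exp(-d^2 / (2 * lengthscale^2)) + jitter * diag(n_levels)
}

## random-effect value looked up by name; absent/external levels contribute 0
.re_lookup <- function(vec, ids) {
  out <- rep(0, length(ids))
  if (!length(vec)) return(out)
  hit <- match(as.character(ids), names(vec))
  ok <- !is.na(hit)
  out[ok] <- vec[hit[ok]]
  out
}

#' Linear predictor of the hierarchical models
#'
#' theta = alpha + gamma[birth order] + eps[year] + kappa[mother] +
#' eta[father] + sum_k beta[k, age] * x_k, with external parents contributing
#' zero to the identity random effects.
#'
#' @param panel a `fam_panel` (any subset of rows).
#' @param params a `fam_params` parameter set.
#' @inheritParams model_effects
#' @return numeric vector theta, one value per panel row.
#' @export
linear_predictor <- function(panel, params,
                             perspective = params$perspective,
                             mother_poly_coding = "single") {
  X <- model_matrix(panel, perspective, mother_poly_coding)
  if (anyNA(X))
    stop_validation("linear_predictor needs complete covariates; unknown sex is handled by the fitted likelihood, not here")
  if (ncol(X) != nrow(params$beta))
    stop_validation("beta has %d rows but the %s design has %d effects",
                    nrow(params$beta), perspective, ncol(X))
  a <- panel$age + 1L
  if (any(a < 1L | a > ncol(params$beta)))
    stop_validation("age outside the parameter age range")
  bo <- pmin(panel$bo_cat, length(params$gamma))
  theta <- params$alpha +
    params$gamma[bo] +
    .re_lookup(params$eps_year, panel$year) +
    .re_lookup(params$kappa, panel$mother_id) +
    .re_lookup(params$eta, panel$father_id) +
    rowSums(X * t(params$beta)[a, , drop = FALSE])
  unname(theta)
}

#' Discrete-time survival log-likelihood
#'
#' Each child-year at risk contributes a Bernoulli term for surviving the
#' year with probability `logistic(theta)`; rows exist only while at risk, so
#' nothing follows a death.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
survival_loglik <- function(panel, params,
                            perspective = params$perspective) {
  s <- panel$survived
  if (any(!s %in% c(0L, 1L)))
    stop_validation("survived must be 0 or 1")
  theta <- linear_predictor(panel, params, perspective)
  sum(ifelse(s == 1L, stats::plogis(theta, log.p = TRUE),
             stats::plogis(-theta, log.p = TRUE)))
}

#' Log-normal height log-likelihood
#'
#' `log(height_cm) ~ Normal(theta, lambda)` over rows with an observed
#' height.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
height_loglik <- function(panel, params,
                          perspective = params$perspective) {
  rows <- panel[!is.na(panel$height_cm), , drop = FALSE]
  if (!nrow(rows)) return(0)
  if (any(rows$height_cm <= 0))
    stop_validation("heights must be positive")
  theta <- linear_predictor(rows, params, perspective)
  sum(dnorm(log(rows$height_cm), theta, params$lambda, log = TRUE))
}

#' Log-normal weight-for-height log-likelihood
#'
#' `log(weight_kg) ~ Normal(theta + beta_height[age] * (log(height) -
#' center[age]), lambda)`: weight controlled for height through an
#' age-specific coefficient on centred log height.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
weight_loglik <- function(panel, params,
                          perspective = params$perspective) {
  rows <- panel[!is.na(panel$weight_kg), , drop = FALSE]
  if (!nrow(rows)) return(0)
  if (any(is.na(rows$height_cm)))
    stop_validation("weight-for-height requires height on every weight row")
  if (any(rows$weight_kg <= 0))
    stop_validation("weights must be positive")
  a <- rows$age + 1L
  theta <- linear_predictor(rows, params, perspective) +
    params$beta_height[a] * (log(rows$height_cm) - params$height_center[a])
  sum(dnorm(log(rows$weight_kg), theta, params$lambda, log = TRUE))
}

#' Zero-inflated Poisson log-probability mass
#'
#' `log[p_never * 1(y = 0) + (1 - p_never) * Poisson(y; rate)]`: a point mass
#' at zero (children who never attend school) mixed with a Poisson count for
#' attendees.
#'
#' @param y non-negative integer count(s).
#' @param p_never zero-inflation probability in `[0, 1]`.
#' @param rate positive Poisson rate.
#' @return log-pmf, vectorised over the longest argument.
#' @export
zip_logpmf <- function(y, p_never, rate) {
  n <- max(length(y), length(p_never), length(rate))
  y <- rep_len(y, n); p_never <- rep_len(p_never, n); rate <- rep_len(rate, n)
  if (any(y < 0) || any(y != floor(y)))
    stop_validation("y must be non-negative integers")
  if (any(p_never < 0 | p_never > 1))
    stop_validation("p_never must lie in [0, 1]")
  if (any(rate <= 0)) stop_validation("rate must be positive")
  out <- numeric(n)
  z <- y == 0
  ## log(p + (1-p) e^-rate) via logsumexp for stability
  if (any(z)) {
    l1 <- log(p_never[z])
    l2 <- log1p(-p_never[z]) - rate[z]
    m <- pmax(l1, l2)
    out[z] <- ifelse(p_never[z] == 1, 0,
                     ifelse(p_never[z] == 0, l2,
                            m + log(exp(l1 - m) + exp(l2 - m))))
  }
  if (any(!z)) {
    out[!z] <- log1p(-p_never[!z]) + dpois(y[!z], rate[!z], log = TRUE)
  }
  out
}

#' Zero-inflated Poisson education log-likelihood
#'
#' Years of schooling observed in survey years follow a ZIP whose
#' never-attend probability is `logistic(theta)` and whose rate is
#' `exp(eta_pred)`; both linear predictors use the same covariates with
#' independent parameter sets.
#'
#' @param panel a `fam_panel`.
#' @param params list with elements `theta` and `rate`, each a `fam_params`.
#' @param perspective `"mother"` or `"father"`.
#' @return scalar log-likelihood.
#' @export
education_loglik <- function(panel, params,
                             perspective = params$theta$perspective) {
  rows <- panel[!is.na(panel$edu_years), , drop = FALSE]
  if (!nrow(rows)) return(0)
  p_never <- stats::plogis(linear_predictor(rows, params$theta, perspective))
  rate <- exp(linear_predictor(rows, params$rate, perspective))
  sum(zip_logpmf(rows$edu_years, p_never, rate))
}
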