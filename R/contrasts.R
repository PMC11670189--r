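## Posterior predicted outcome curves per parental state, contrasts against
## the monogamous-two-biological-parent base case, and HPDI summaries.
##
## Predictions are for a population-typical child: first birth-order
## category, the draw's mean year effect, the draw's mean parent effects
## (an all-zero option is available; contrasts agree under both).
## Log-normal outcomes report the distribution mean exp(theta + lambda^2/2)
## (natural units, cm / kg); education reports the zero-inflated Poisson
## mean (1 - p_never) * rate.

#' Highest posterior density interval
#'
#' The narrowest interval containing `mass` of the draws: over all sorted
#' windows of `ceiling(mass * n)` samples, the one of smallest width (ties
#' broken by the lowest lower bound).
#'
#' @param samples numeric vector of posterior draws (>= 2 finite values).
#' @param mass probability mass in (0, 1).
#' @return `c(lower, upper)`.
#' @export
hpdi <- function(samples, mass = 0.90) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2L)
    stop_validation("hpdi needs at least 2 finite samples")
  if (!(mass > 0 && mass < 1))
    stop_validation("mass must lie strictly between 0 and 1")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  w <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(w)  # which.min takes the first (lowest lower bound) on ties
  c(x[i], x[i + m - 1L])
}

.curve <- function(mat, outcome, sex, mother_state, father_state, units) {
  structure(mat, outcome = outcome, sex = sex,
            mother_state = mother_state, father_state = father_state,
            units = units, class = c("fam_curve", class(mat)))
}

.validate_profile <- function(state, A, what) {
  state <- rep_len(as.character(state), A)
  bad <- !(state %in% PARENT_STATE_LEAVES)
  if (any(bad))
    stop_validation("invalid %s state: %s", what,
                    paste(unique(state[bad]), collapse = ", "))
  dec <- which(state == "DECEASED")
  if (length(dec) && any(state[seq(min(dec), A)] != "DECEASED"))
    stop_validation("impossible %s profile: DECEASED is absorbing", what)
  if (any(state == "EXTERNAL") && !all(state == "EXTERNAL"))
    stop_validation("impossible %s profile: EXTERNAL is constant", what)
  state
}

#' Posterior predicted outcome curve for one parental-state profile
#'
#' Assembles the linear predictor age by age for a child of the given sex
#' under the given (possibly age-varying) parental states, with the shared
#' hierarchical terms at population-typical values (see `random_effects`),
#' and applies the outcome's inverse link.
#'
#' @param draws a `fam_draws`.
#' @param model the fitted `fam_model`.
#' @param sex `"female"` or `"male"`.
#' @param mother_state,father_state one leaf from [PARENT_STATE_LEAVES], or a
#'   vector with one leaf per age (DECEASED must be absorbing, EXTERNAL
#'   constant).
#' @param twin 0 or 1.
#' @param random_effects `"typical"` (default) evaluates each draw at the
#'   population-typical values of the shared terms — first birth-order
#'   category, the draw's mean year effect, the draw's mean mother and
#'   father effects — so absolute levels are preserved even though the
#'   posterior splits the overall level softly across components;
#'   `"zero"` sets all of them to exactly zero (contrasts are identical
#'   under both, since shared terms cancel drawwise).
#' @param thin keep every `thin`-th draw.
#' @return a `fam_curve`: matrix draws x ages in natural units (annual
#'   survival probability; cm; kg; expected years of schooling). For
#'   education the never-attend probability draws are attached as attribute
#'   `p_never`.
#' @export
predict_curve <- function(draws, model, sex = c("female", "male"),
                          mother_state = "BIO_MONO",
                          father_state = "BIO_MONO", twin = 0L,
                          random_effects = c("typical", "zero"), thin = 1L) {
  sex <- match.arg(sex)
  random_effects <- match.arg(random_effects)
  A <- model$data$A
  mother_state <- .validate_profile(mother_state, A, "mother")
  father_state <- .validate_profile(father_state, A, "father")
  ind <- encode_covariates(mother_state, father_state)
  coding <- model$meta$config$mother_poly_coding %||% "single"
  ind$PB <- as.integer(mother_state == "BIO_POLY")
  ind$PN <- as.integer(mother_state == "STEP_POLY")
  ind$intercept <- 1
  ind$male <- as.integer(sex == "male")
  ind$twin <- as.integer(twin)
  ind$logH_c <- 0
  eff <- model$meta$effects
  miss <- setdiff(eff, names(ind))
  if (length(miss))
    stop_validation("no covariate rule for effect(s): %s",
                    paste(miss, collapse = ", "))
  Xa <- as.matrix(ind[, eff, drop = FALSE])  # A x K

  theta_from <- function(ex) {
    off <- if (random_effects == "typical") {
      ## year effect averaged over the years the outcome was observed in
      ## (elsewhere the GP reverts to its prior mean and would dilute it)
      oy <- as.character(model$meta$obs_years %||% model$meta$years)
      oy <- intersect(oy, colnames(ex$eps))
      ex$gamma[, 1] + rowMeans(ex$eps[, oy, drop = FALSE]) +
        ex$kappa_mean + ex$eta_mean
    } else 0
    th <- matrix(ex$alpha + off, ex$n_draws, A)
    for (k in seq_along(eff)) {
      th <- th + sweep(ex$beta[, k, , drop = TRUE], 2, Xa[, k], `*`)
    }
    th
  }
  outcome <- model$meta$outcome
  ex1 <- extract_params(draws, model, stack = 1L, thin = thin)
  th1 <- theta_from(ex1)
  units <- switch(outcome, survival = "probability", height = "cm",
                  weight = "kg", education = "years")
  if (outcome == "survival") {
    mat <- stats::plogis(th1)
  } else if (outcome %in% c("height", "weight")) {
    mat <- exp(th1 + ex1$lambda^2 / 2)
  } else {
    ex2 <- extract_params(draws, model, stack = 2L, thin = thin)
    p_never <- stats::plogis(th1)
    rate <- exp(theta_from(ex2))
    mat <- (1 - p_never) * rate
    out <- .curve(mat, outcome, sex, mother_state, father_state, units)
    attr(out, "p_never") <- p_never
    return(out)
  }
  .curve(mat, outcome, sex, mother_state, father_state, units)
}

#' Cumulative survival from annual survival probabilities
#'
#' `cum[a] = prod_{k <= a} annual[k]`; survival to age 19 is the final
#' element of a 19-age (0..18) curve.
#'
#' @param annual numeric vector over ages, or a draws x ages matrix
#'   (a `fam_curve` keeps its attributes).
#' @return same shape, cumulative products along age.
#' @export
cumulative_survival <- function(annual) {
  vals <- unclass(annual)
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    stop_validation("annual survival probabilities must lie in [0, 1]")
  if (is.matrix(vals)) {
    out <- t(apply(vals, 1, cumprod))
  } else {
    out <- cumprod(vals)
  }
  if (inherits(annual, "fam_curve")) {
    attributes(out) <- attributes(annual)
    attr(out, "outcome") <- "cumulative_survival"
  }
  out
}

#' Drawwise contrast between a focal and a base curve
#'
#' `focal - base` per draw and age, preserving posterior dependence (both
#' curves must come from the same posterior sample indices).
#'
#' @param base,focal `fam_curve` matrices with identical dimensions.
#' @return a `fam_curve` of differences, labelled by the focal state.
#' @export
contrast <- function(base, focal) {
  if (!identical(dim(base), dim(focal)))
    stop_validation("contrast needs matched draws: dims %s vs %s",
                    paste(dim(base), collapse = "x"),
                    paste(dim(focal), collapse = "x"))
  out <- unclass(focal) - unclass(base)
  attributes(out) <- attributes(focal)
  attr(out, "contrast") <- TRUE
  out
}

#' Per-age posterior mean and HPDI of a curve
#'
#' @param curve a `fam_curve` (predicted curve or contrast).
#' @param mass HPDI probability mass.
#' @return data.frame: age, mean, hpdi_lower, hpdi_upper, with a `units`
#'   attribute.
#' @export
summarize_contrast <- function(curve, mass = 0.90) {
  mat <- unclass(curve)
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1)
  out <- data.frame(
    age = seq_len(ncol(mat)) - 1L,
    mean = colMeans(mat),
    hpdi_lower = apply(mat, 2, function(v) hpdi(v, mass)[1]),
    hpdi_upper = apply(mat, 2, function(v) hpdi(v, mass)[2])
  )
  attr(out, "units") <- attr(curve, "units")
  attr(out, "outcome") <- attr(curve, "outcome")
  rownames(out) <- NULL
  out
}

#' Plot a set of per-age curve summaries
#'
#' Mean lines with shaded HPDI ribbons, one facet per summary; a light
#' wrapper over ggplot2 for the reporting pipeline.
#'
#' @param summaries named list of data.frames from [summarize_contrast()].
#' @param ylab y-axis label (units).
#' @param hline optional horizontal reference line (0 for contrasts).
#' @return a ggplot object.
#' @export
plot_curves <- function(summaries, ylab = "", hline = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_curves requires the 'ggplot2' package", call. = FALSE)
  df <- do.call(rbind, lapply(names(summaries), function(nm) {
    cbind(summaries[[nm]], panel = nm)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hpdi_lower,
                                      ymax = .data$hpdi_upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "age (years)", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(hline))
    p <- p + ggplot2::geom_hline(yintercept = hline, linetype = 2)
  p
}
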