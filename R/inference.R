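## Model assembly and Hamiltonian Monte Carlo.
##
## The joint density is prior x likelihood on an unconstrained vector with
## non-centered hierarchical terms (see src/loglik.cpp for the layout). The
## sampler is dynamic HMC with a no-U-turn termination rule and multinomial
## state selection, dual-averaging step-size adaptation, and expanding
## diagonal mass-matrix adaptation windows during warmup.

#' Fit configuration
#'
#' @param outcome one of `"survival"`, `"height"`, `"weight"`, `"education"`.
#' @param perspective `"mother"` or `"father"`.
#' @param chains number of chains (>= 2 recommended for diagnostics).
#' @param warmup,samples iterations per chain.
#' @param seed integer seed; per-chain seeds are derived from it and it is
#'   recorded in all outputs.
#' @param prior named list of prior scales; defaults: `alpha_sd = 1` (Normal
#'   intercept), `amp_sd = 1` (half-Normal GP amplitudes), `sigma_sd = 1`
#'   (half-Normal random-effect scales), `lambda_sd = 1` (half-Normal residual
#'   scale), `ls_meanlog = log(3)`, `ls_sdlog = 0.75` (log-Normal GP
#'   lengthscales, in category units).
#' @param max_treedepth cap on the doubling depth of each no-U-turn
#'   trajectory (at most `2^max_treedepth` leapfrog steps per iteration).
#' @param adapt_target dual-averaging acceptance target.
#' @param mother_poly_coding `"single"` or `"split"` (see [model_effects()]).
#' @return list with class `fam_config`.
#' @export
fit_config <- function(outcome = c("survival", "height", "weight", "education"),
                       perspective = c("mother", "father"),
                       chains = 2L, warmup = 500L, samples = 500L, seed = 1L,
                       prior = list(), max_treedepth = 5L,
                       adapt_target = 0.8,
                       mother_poly_coding = c("single", "split")) {
  outcome <- match.arg(outcome)
  perspective <- match.arg(perspective)
  mother_poly_coding <- match.arg(mother_poly_coding)
  defaults <- list(alpha_sd = 1, amp_sd = 1, sigma_sd = 1, lambda_sd = 1,
                   ls_meanlog = log(3), ls_sdlog = 0.75)
  prior <- utils::modifyList(defaults, prior)
  if (chains < 2L)
    warning("chains < 2: split-Rhat and between-chain diagnostics are weak")
  structure(list(outcome = outcome, perspective = perspective,
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 samples = as.integer(samples), seed = as.integer(seed),
                 prior = prior, max_treedepth = as.integer(max_treedepth),
                 adapt_target = adapt_target,
                 mother_poly_coding = mother_poly_coding),
            class = "fam_config")
}

## unconstrained-vector layout; mirrors src/loglik.cpp
par_layout <- function(K, A, G, Yn, M, F, effects, years,
                       mother_ids, father_ids, type) {
  stack_names <- function(pre) {
    c(paste0(pre, "alpha"),
      paste0(pre, "zb_", rep(effects, each = A), "_a", rep(seq_len(A) - 1L, K)),
      paste0(pre, "log_amp_", effects),
      paste0(pre, "log_ls_", effects),
      paste0(pre, "zg_", seq_len(G)),
      paste0(pre, c("log_amp_gamma", "log_ls_gamma")),
      paste0(pre, "ze_", years),
      paste0(pre, c("log_amp_eps", "log_ls_eps")),
      if (M > 0) paste0(pre, "zk_", mother_ids),
      paste0(pre, "log_sigma_kappa"),
      if (F > 0) paste0(pre, "zf_", father_ids),
      paste0(pre, "log_sigma_eta"))
  }
  nm <- switch(type,
               `1` = stack_names(""),
               `2` = c(stack_names(""), "log_lambda"),
               `3` = c(stack_names("theta."), stack_names("rate.")))
  list(names = nm, n = length(nm),
       stack_size = 1L + K * A + 2L * K + G + 2L + Yn + 2L + M + 1L + F + 1L)
}

#' Assemble an outcome model into a differentiable joint log-density
#'
#' Subsets the panel to the rows the outcome observes, builds the index
#' structures of the hierarchical linear predictor, and returns the joint
#' log-posterior (weakly regularising priors plus the outcome likelihood) and
#' its analytic gradient on the unconstrained scale. Unknown-sex children
#' contribute a child-level mixture over male in `{0, 1}` weighted by the
#' male fraction among sexed children.
#'
#' @param panel a `fam_panel`.
#' @param config a `fam_config`.
#' @return an object of class `fam_model` with elements `lp` (function
#'   returning `list(value, grad)`), `n_par`, `par_names`, `data`, `meta`.
#' @export
assemble_model <- function(panel, config) {
  stopifnot(inherits(panel, "fam_panel"), inherits(config, "fam_config"))
  outcome <- config$outcome
  rows <- switch(outcome,
                 survival = panel,
                 height = panel[!is.na(panel$height_cm), , drop = FALSE],
                 weight = panel[!is.na(panel$weight_kg), , drop = FALSE],
                 education = panel[!is.na(panel$edu_years), , drop = FALSE])
  if (outcome == "survival" && any(!rows$survived %in% c(0L, 1L)))
    stop_validation("survived must be 0 or 1")
  if (outcome == "weight" && any(is.na(rows$height_cm)))
    stop_validation("weight-for-height requires height on every weight row")

  X <- model_matrix(rows, config$perspective, config$mother_poly_coding,
                    male_na_zero = TRUE)
  effects <- colnames(X)
  A <- (attr(panel, "max_age") %||% 18L) + 1L
  height_center <- numeric(A)
  if (outcome == "weight") {
    lh <- log(rows$height_cm)
    for (a in seq_len(A)) {
      sel <- rows$age == a - 1L
      if (any(sel)) height_center[a] <- mean(lh[sel])
    }
    X <- cbind(X, logH_c = lh - height_center[rows$age + 1L])
    effects <- colnames(X)
  }

  G <- attr(panel, "birth_order_cap") %||% 10L
  if (nrow(rows)) G <- max(G, rows$bo_cat)
  years <- seq(min(panel$year), max(panel$year))
  mother_ids <- sort(unique(rows$mother_id[!is_external_id(rows$mother_id)]))
  father_ids <- sort(unique(rows$father_id[!is_external_id(rows$father_id)]))

  unknown <- as.integer(is.na(rows$male))
  ukids <- unique(rows$child_id[unknown == 1L])
  uchild <- ifelse(unknown == 1L, match(rows$child_id, ukids), 0L)
  uchild[is.na(uchild)] <- 0L
  known_children <- !duplicated(panel$child_id) & !is.na(panel$male)
  pm <- if (any(known_children)) mean(panel$male[known_children] == 1L) else 0.5
  pm <- min(max(pm, 1e-6), 1 - 1e-6)

  y <- switch(outcome,
              survival = as.numeric(rows$survived),
              height = log(rows$height_cm),
              weight = log(rows$weight_kg),
              education = as.numeric(rows$edu_years))
  if (outcome %in% c("height", "weight") && any(!is.finite(y)))
    stop_validation("non-positive %s measurements", outcome)
  type <- switch(outcome, survival = 1L, height = 2L, weight = 2L,
                 education = 3L)

  data <- list(
    type = type, X = X, y = y,
    age = as.integer(rows$age + 1L), A = A,
    bo = as.integer(pmin(rows$bo_cat, G)), G = as.integer(G),
    yr = as.integer(rows$year - years[1] + 1L), Yn = length(years),
    mid = ifelse(is_external_id(rows$mother_id), 0L,
                 match(rows$mother_id, mother_ids)),
    fid = ifelse(is_external_id(rows$father_id), 0L,
                 match(rows$father_id, father_ids)),
    M = length(mother_ids), Fn = length(father_ids),
    unknown = unknown, uchild = as.integer(uchild), nu = length(ukids),
    pm = pm, male_col = match("male", effects),
    prior = config$prior
  )
  data$mid <- as.integer(ifelse(is.na(data$mid), 0L, data$mid))
  data$fid <- as.integer(ifelse(is.na(data$fid), 0L, data$fid))

  layout <- par_layout(ncol(X), A, data$G, data$Yn, data$M, data$Fn,
                       effects, years, mother_ids, father_ids, type)
  ptr <- fam_model_ptr_cpp(data)
  lp <- function(par) fam_lp_grad_ptr_cpp(par, ptr)
  structure(list(lp = lp, n_par = layout$n, par_names = layout$names,
                 data = data,
                 meta = list(outcome = outcome, config = config,
                             effects = effects, years = years,
                             obs_years = sort(unique(rows$year)),
                             mother_ids = mother_ids, father_ids = father_ids,
                             height_center = height_center,
                             stack_size = layout$stack_size,
                             n_rows = nrow(rows))),
            class = "fam_model")
}

#' @export
print.fam_model <- function(x, ...) {
  cat(sprintf("<fam_model> outcome=%s perspective=%s rows=%d parameters=%d\n",
              x$meta$outcome, x$meta$config$perspective, x$meta$n_rows,
              x$n_par))
  cat("prior scales:",
      paste(names(x$meta$config$prior), unlist(x$meta$config$prior),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Joint log-posterior of a model at a parameter point
#'
#' @param model a `fam_model` (or any list with `lp` and `n_par`).
#' @param par unconstrained parameter vector.
#' @param gradient also return the analytic gradient.
#' @return scalar value, or `list(value, grad)` when `gradient = TRUE`.
#' @export
log_posterior <- function(model, par, gradient = FALSE) {
  res <- model$lp(par)
  if (gradient) res else res$value
}

## ---- Hamiltonian Monte Carlo (multinomial NUTS) ------------------------

.lse2 <- function(a, b) {
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

## one dynamic trajectory with multinomial state selection and a no-U-turn
## termination rule; inv_mass is the diagonal inverse mass (posterior
## variance scale)
.nuts_iter <- function(lp, q0, value0, grad0, eps, inv_mass, max_depth) {
  n <- length(q0)
  p0 <- rnorm(n) / sqrt(inv_mass)
  H0 <- -value0 + 0.5 * sum(p0^2 * inv_mass)
  sum_alpha <- 0; n_alpha <- 0L; n_leap <- 0L

  uturn <- function(qm, pm, qp, pp) {
    dq <- qp - qm
    sum(dq * (inv_mass * pm)) < 0 || sum(dq * (inv_mass * pp)) < 0
  }
  leaf <- function(q, p, grad, dir) {
    n_leap <<- n_leap + 1L
    p1 <- p + 0.5 * dir * eps * grad
    q1 <- q + dir * eps * inv_mass * p1
    r <- lp(q1)
    if (!is.finite(r$value) || !all(is.finite(r$grad)))
      return(list(div = TRUE))
    p1 <- p1 + 0.5 * dir * eps * r$grad
    dH <- (-r$value + 0.5 * sum(p1^2 * inv_mass)) - H0
    if (!is.finite(dH) || dH > 1000) return(list(div = TRUE))
    sum_alpha <<- sum_alpha + min(1, exp(-dH))
    n_alpha <<- n_alpha + 1L
    list(div = FALSE, stop = FALSE,
         qm = q1, pm = p1, gm = r$grad, qp = q1, pp = p1, gp = r$grad,
         qprop = q1, vprop = r$value, gprop = r$grad, lw = -dH)
  }
  build <- function(q, p, grad, dir, depth) {
    if (depth == 0L) return(leaf(q, p, grad, dir))
    t1 <- build(q, p, grad, dir, depth - 1L)
    if (t1$div || t1$stop) return(t1)
    t2 <- if (dir == 1L) build(t1$qp, t1$pp, t1$gp, dir, depth - 1L)
          else build(t1$qm, t1$pm, t1$gm, dir, depth - 1L)
    if (t2$div || t2$stop) {
      t1$div <- isTRUE(t2$div)
      t1$stop <- TRUE
      return(t1)
    }
    lw <- .lse2(t1$lw, t2$lw)
    keep <- if (log(runif(1)) < t2$lw - lw) t2 else t1
    out <- list(div = FALSE, lw = lw, qprop = keep$qprop,
                vprop = keep$vprop, gprop = keep$gprop)
    if (dir == 1L) {
      out[c("qm", "pm", "gm")] <- t1[c("qm", "pm", "gm")]
      out[c("qp", "pp", "gp")] <- t2[c("qp", "pp", "gp")]
    } else {
      out[c("qm", "pm", "gm")] <- t2[c("qm", "pm", "gm")]
      out[c("qp", "pp", "gp")] <- t1[c("qp", "pp", "gp")]
    }
    out$stop <- uturn(out$qm, out$pm, out$qp, out$pp)
    out
  }

  tree <- list(qm = q0, pm = p0, gm = grad0, qp = q0, pp = p0, gp = grad0,
               qprop = q0, vprop = value0, gprop = grad0, lw = 0)
  divergent <- FALSE
  depth <- 0L
  while (depth < max_depth) {
    dir <- if (runif(1) < 0.5) -1L else 1L
    sub <- if (dir == 1L) build(tree$qp, tree$pp, tree$gp, 1L, depth)
           else build(tree$qm, tree$pm, tree$gm, -1L, depth)
    if (isTRUE(sub$div)) { divergent <- TRUE; break }
    if (isTRUE(sub$stop)) break
    ## biased progressive sampling toward the new subtree
    if (log(runif(1)) < sub$lw - tree$lw) {
      tree$qprop <- sub$qprop; tree$vprop <- sub$vprop; tree$gprop <- sub$gprop
    }
    tree$lw <- .lse2(tree$lw, sub$lw)
    if (dir == 1L) tree[c("qp", "pp", "gp")] <- sub[c("qp", "pp", "gp")]
    else tree[c("qm", "pm", "gm")] <- sub[c("qm", "pm", "gm")]
    depth <- depth + 1L
    if (uturn(tree$qm, tree$pm, tree$qp, tree$pp)) break
  }
  list(q = tree$qprop, value = tree$vprop, grad = tree$gprop,
       accept_stat = if (n_alpha) sum_alpha / n_alpha else 0,
       divergent = divergent, depth = depth, n_leapfrog = n_leap)
}

.hmc_chain <- function(model, config, chain_seed, init_sd = 0.1) {
  set.seed(chain_seed)
  n <- model$n_par
  lp <- model$lp
  warmup <- config$warmup
  n_samp <- config$samples
  target <- config$adapt_target

  Dmax <- config$max_treedepth
  q <- NULL
  for (try in seq_len(20L)) {
    cand <- rnorm(n, 0, init_sd)
    res <- lp(cand)
    if (is.finite(res$value) && all(is.finite(res$grad))) {
      q <- cand
      break
    }
  }
  if (is.null(q))
    stop("initialization error: log density non-finite at 20 random starts; ",
         "check the panel and parameter dimensions", call. = FALSE)

  inv_mass <- rep(1, n)
  ## dual averaging state (Hoffman & Gelman 2014 defaults)
  eps <- 0.1 / n^0.25
  mu <- log(10 * eps)
  log_eps_bar <- 0; H_bar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa_da <- 0.75
  da_iter <- 0L

  ## expanding variance-accumulation windows for the diagonal mass matrix
  init_buf <- min(75L, floor(0.15 * warmup))
  term_buf <- min(50L, floor(0.1 * warmup))
  w_ends <- integer(0)
  if (warmup - term_buf - init_buf >= 20L) {
    pos <- init_buf; size <- 25L
    while (pos + size < warmup - term_buf) {
      pos <- pos + size
      w_ends <- c(w_ends, pos)
      size <- size * 2L
    }
    w_ends <- c(w_ends[-length(w_ends)], warmup - term_buf)
    if (!length(w_ends)) w_ends <- warmup - term_buf
  }
  count <- 0L; mean_acc <- numeric(n); m2_acc <- numeric(n)

  draws <- matrix(NA_real_, n_samp, n,
                  dimnames = list(NULL, model$par_names))
  lp_trace <- numeric(n_samp)
  divergences <- 0L; accept_sum <- 0; n_acc_samples <- 0L
  res <- lp(q)

  total <- warmup + n_samp
  for (it in seq_len(total)) {
    out <- .nuts_iter(lp, q, res$value, res$grad, eps, inv_mass, Dmax)
    q <- out$q
    res <- list(value = out$value, grad = out$grad)
    a_prob <- out$accept_stat
    if (out$divergent && it > warmup) divergences <- divergences + 1L

    if (it <= warmup) {
      da_iter <- da_iter + 1L
      H_bar <- (1 - 1 / (da_iter + t0)) * H_bar +
        (target - a_prob) / (da_iter + t0)
      log_eps <- mu - sqrt(da_iter) / gamma_da * H_bar
      w <- da_iter^(-kappa_da)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (length(w_ends) && it > init_buf && it <= max(w_ends)) {
        count <- count + 1L
        delta <- q - mean_acc
        mean_acc <- mean_acc + delta / count
        m2_acc <- m2_acc + delta * (q - mean_acc)
        if (it %in% w_ends && count > 10L) {
          v <- m2_acc / (count - 1L)
          inv_mass <- (count / (count + 5)) * v +
            (5 / (count + 5)) * rep(1e-3, n)
          inv_mass[inv_mass < 1e-8] <- 1e-8
          ## restart step-size adaptation under the new metric
          eps <- exp(log_eps_bar)
          mu <- log(10 * eps)
          da_iter <- 0L; H_bar <- 0; log_eps_bar <- 0
          count <- 0L; mean_acc <- numeric(n); m2_acc <- numeric(n)
        }
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      accept_sum <- accept_sum + a_prob
      n_acc_samples <- n_acc_samples + 1L
      draws[it - warmup, ] <- q
      lp_trace[it - warmup] <- res$value
    }
  }
  list(draws = draws, lp = lp_trace, eps = eps,
       accept = accept_sum / max(n_acc_samples, 1L),
       divergences = divergences, seed = chain_seed)
}

#' Run adaptive Hamiltonian Monte Carlo
#'
#' Chains run sequentially with deterministic per-chain seeds derived from
#' `config$seed`; the same configuration reproduces identical draws. Warnings
#' are issued when any split-Rhat exceeds 1.01 or any post-warmup divergence
#' occurs.
#'
#' @param model a `fam_model` from [assemble_model()], or any list with
#'   elements `lp(par) -> list(value, grad)`, `n_par` and `par_names`.
#' @param config a `fam_config` (only `chains`, `warmup`, `samples`, `seed`,
#'   `max_treedepth`, `adapt_target` are used here).
#' @return an object of class `fam_draws`: per-chain draw matrices, sampler
#'   diagnostics, configuration and seed.
#' @export
run_mcmc <- function(model, config) {
  chains <- lapply(seq_len(config$chains), function(ch) {
    .hmc_chain(model, config, chain_seed = config$seed + 7919L * ch)
  })
  out <- structure(list(
    chains = lapply(chains, `[[`, "draws"),
    lp = lapply(chains, `[[`, "lp"),
    par_names = model$par_names,
    accept = vapply(chains, `[[`, numeric(1), "accept"),
    step_size = vapply(chains, `[[`, numeric(1), "eps"),
    divergences = vapply(chains, `[[`, integer(1), "divergences"),
    seed = config$seed,
    config = config,
    meta = model$meta
  ), class = "fam_draws")
  dg <- diagnose(out)
  if (any(out$divergences > 0L))
    warning(sprintf("%d divergent transition(s) after warmup",
                    sum(out$divergences)))
  if (any(dg$rhat > 1.01, na.rm = TRUE))
    warning(sprintf("%d parameter(s) with split-Rhat > 1.01 (max %.3f)",
                    sum(dg$rhat > 1.01, na.rm = TRUE),
                    max(dg$rhat, na.rm = TRUE)))
  out
}

#' @export
print.fam_draws <- function(x, ...) {
  cat(sprintf("<fam_draws> %d chain(s) x %d draws of %d parameters (seed %d)\n",
              length(x$chains), nrow(x$chains[[1]]), length(x$par_names),
              x$seed))
  cat(sprintf("mean accept %.2f, step sizes %s, divergences %s\n",
              mean(x$accept), paste(signif(x$step_size, 3), collapse = "/"),
              paste(x$divergences, collapse = "/")))
  invisible(x)
}

#' Stack all chains into one draw matrix
#'
#' @param draws a `fam_draws`.
#' @return matrix `(chains * samples) x n_par`.
#' @export
draw_matrix <- function(draws) {
  do.call(rbind, draws$chains)
}

## ---- convergence diagnostics ------------------------------------------

#' Split-Rhat of one quantity
#'
#' @param x matrix iterations x chains (a vector is treated as one chain).
#' @return potential scale reduction factor on split chains.
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  cm <- colMeans(sp)
  if (sd(cm) == 0 && all(apply(sp, 2, sd) == 0)) return(1)
  B <- nn * var(cm)
  W <- mean(apply(sp, 2, var))
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of one quantity
#'
#' Multi-chain ESS using chain-combined autocorrelations with Geyer's
#' initial-positive-sequence truncation.
#'
#' @param x matrix iterations x chains (a vector is treated as one chain).
#' @return effective number of draws.
#' @export
ess_mean <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(x, 2, var))
  if (W == 0) return(NA_real_)
  B <- if (m > 1) n * var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 1L, 500L)
  rho <- numeric(max_lag)
  acov <- sapply(seq_len(m), function(j) {
    v <- x[, j] - mean(x[, j])
    stats::acf(v, lag.max = max_lag, plot = FALSE,
               type = "covariance", demean = FALSE)$acf[, 1, 1]
  })
  for (t in seq_len(max_lag))
    rho[t] <- 1 - (W - mean(acov[t + 1L, ])) / var_plus
  ## Geyer: sum while paired autocorrelations stay positive
  tau <- 1
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  min(m * n, m * n / tau)
}

#' Per-parameter posterior summary with convergence diagnostics
#'
#' @param draws a `fam_draws`.
#' @param pars optional regular expression selecting parameter names.
#' @return data.frame: parameter, mean, sd, split-Rhat, effective sample size.
#' @export
diagnose <- function(draws, pars = NULL) {
  idx <- seq_along(draws$par_names)
  if (!is.null(pars)) idx <- grep(pars, draws$par_names)
  res <- lapply(idx, function(j) {
    x <- sapply(draws$chains, function(ch) ch[, j])
    c(mean = mean(x), sd = sd(x), rhat = split_rhat(x), ess = ess_mean(x))
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(parameter = draws$par_names[idx], out)
  rownames(out) <- NULL
  out
}

## ---- natural-scale extraction -----------------------------------------

#' Natural-scale parameter draws from a fit
#'
#' Transforms each unconstrained draw back to the model's natural parameters
#' (intercept, effect-by-age matrix, GP hyperparameters, random-effect
#' scales, residual scale).
#'
#' @param draws a `fam_draws` from a [run_mcmc()] fit of a `fam_model`.
#' @param model the `fam_model` that produced them.
#' @param stack 1 for the main predictor; 2 for the zero-inflated education
#'   rate predictor.
#' @param thin keep every `thin`-th draw.
#' @return list with `alpha` (vector), `beta` (draws x effect x age array),
#'   `lambda` (vector or NULL), `gamma`, `eps` matrices, hyperparameter
#'   summaries, and `effects` names.
#' @export
extract_params <- function(draws, model, stack = 1L, thin = 1L) {
  dm <- draw_matrix(draws)
  keep <- seq(1L, nrow(dm), by = thin)
  dm <- dm[keep, , drop = FALSE]
  K <- length(model$meta$effects)
  A <- model$data$A
  nd <- nrow(dm)
  alpha <- numeric(nd)
  beta <- array(NA_real_, c(nd, K, A),
                dimnames = list(NULL, model$meta$effects, NULL))
  gamma <- matrix(NA_real_, nd, model$data$G)
  eps <- matrix(NA_real_, nd, model$data$Yn,
                dimnames = list(NULL, model$meta$years))
  kappa_mean <- numeric(nd)
  eta_mean <- numeric(nd)
  lambda <- if (model$data$type == 2L) exp(dm[, model$n_par]) else NULL
  for (i in seq_len(nd)) {
    s <- fam_unpack_stack_cpp(dm[i, ], model$data, stack)
    alpha[i] <- s$alpha
    beta[i, , ] <- s$beta
    gamma[i, ] <- s$gamma
    eps[i, ] <- s$eps
    kappa_mean[i] <- if (length(s$kappa)) mean(s$kappa) else 0
    eta_mean[i] <- if (length(s$eta)) mean(s$eta) else 0
  }
  list(alpha = alpha, beta = beta, gamma = gamma, eps = eps,
       kappa_mean = kappa_mean, eta_mean = eta_mean, lambda = lambda,
       effects = model$meta$effects, n_draws = nd)
}

#' Parameter-recovery report against known truth
#'
#' For each age-specific effect: posterior-mean bias, RMSE over draws, and
#' whether the 90% HPDI covers the true value. Used by the simulation-based
#' calibration suite (fit models to data generated with known parameters).
#'
#' @param true_params a `fam_params` holding the generating values.
#' @param draws a `fam_draws`.
#' @param model the fitted `fam_model`.
#' @param effects which beta rows to report (default: all shared with truth).
#' @param mass HPDI probability mass.
#' @return data.frame: effect, age, truth, posterior mean, bias, rmse,
#'   hpdi bounds, covered.
#' @export
parameter_recovery_report <- function(true_params, draws, model,
                                      effects = NULL, mass = 0.90) {
  ex <- extract_params(draws, model)
  eff <- effects %||% intersect(ex$effects, rownames(true_params$beta))
  bad <- setdiff(eff, ex$effects)
  if (length(bad))
    stop_validation("effects absent from the fit: %s",
                    paste(bad, collapse = ", "))
  if (ncol(true_params$beta) != dim(ex$beta)[3])
    stop_validation("true beta has %d age columns, fit has %d",
                    ncol(true_params$beta), dim(ex$beta)[3])
  rows <- list()
  for (e in eff) {
    for (a in seq_len(dim(ex$beta)[3])) {
      dr <- ex$beta[, e, a]
      tr <- true_params$beta[e, a]
      h <- hpdi(dr, mass)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = e, age = a - 1L, truth = tr, post_mean = mean(dr),
        bias = mean(dr) - tr, rmse = sqrt(mean((dr - tr)^2)),
        hpdi_lower = h[1], hpdi_upper = h[2],
        covered = h[1] <= tr && tr <= h[2])
    }
  }
  do.call(rbind, rows)
}

## ---- persistence -------------------------------------------------------

#' Write posterior draws to a self-describing pair of files
#'
#' The draws go to CSV (`chain`, `iteration`, then one column per parameter);
#' configuration, seed, diagnostics and package version go to a JSON sidecar
#' next to it.
#'
#' @param draws a `fam_draws`.
#' @param csv_path output CSV path; the sidecar is `<path>.meta.json`.
#' @return `csv_path`, invisibly.
#' @export
write_draws <- function(draws, csv_path) {
  mats <- lapply(seq_along(draws$chains), function(ch) {
    cbind(chain = ch, iteration = seq_len(nrow(draws$chains[[ch]])),
          draws$chains[[ch]])
  })
  write.csv(do.call(rbind, mats), csv_path, row.names = FALSE)
  dg <- diagnose(draws)
  meta <- list(package = "famstates",
               version = as.character(utils::packageVersion("famstates")),
               seed = draws$seed,
               config = unclass(draws$config),
               accept = draws$accept, step_size = draws$step_size,
               divergences = draws$divergences,
               max_rhat = max(dg$rhat, na.rm = TRUE),
               min_ess = min(dg$ess, na.rm = TRUE),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, paste0(csv_path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(csv_path)
}
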