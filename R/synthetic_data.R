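## Synthetic family histories with the statistical structure the analysis
## assumes: women move annually between unmarried and married states by a
## Markov kernel, men may hold several concurrent marriages (polygyny),
## parents die at a constant annual hazard, a fraction of parents are
## external to the registry, and child outcomes are drawn from the exact
## model likelihoods at survey years only.

#' Simulation configuration
#'
#' Defaults emulate a small high-fertility village registry: unstable
#' marriages (annual marriage probability 0.3, divorce 0.05), roughly 10% of
#' new marriages polygynous, 2% annual adult mortality, external biological
#' fathers for 28% of children and external mothers for 6% (so external
#' parents are ~80% fathers), 7.5% of children with unrecorded sex, a 1.5%
#' twin-birth rate, and the ten survey years 1995-2014.
#'
#' @param n_children approximate number of children to generate.
#' @param year_range `c(first, last)` calendar years of the registry.
#' @param seed integer seed.
#' @param p_marry annual marriage probability of an unmarried woman aged
#'   15-49.
#' @param p_divorce annual dissolution probability per union.
#' @param p_polygyny probability a new marriage joins an already-married man.
#' @param max_wives cap on concurrent wives.
#' @param parent_mortality annual adult death probability.
#' @param p_birth annual birth probability of a married woman aged 15-45.
#' @param p_birth_single annual birth probability of an unmarried woman
#'   (child's father external).
#' @param p_father_external,p_mother_external probability a child's recorded
#'   parent is external to the registry.
#' @param p_sex_unknown probability a child's sex is unrecorded.
#' @param twin_rate probability a birth is a twin pair.
#' @param survey_years calendar years with anthropometric/education
#'   measurement.
#' @return list with class `fam_sim_config`.
#' @export
sim_config <- function(n_children = 500L,
                       year_range = c(1950L, 2014L),
                       seed = 1L,
                       p_marry = 0.30, p_divorce = 0.05,
                       p_polygyny = 0.10, max_wives = 3L,
                       parent_mortality = 0.02,
                       p_birth = 0.25, p_birth_single = 0.08,
                       p_father_external = 0.28,
                       p_mother_external = 0.06,
                       p_sex_unknown = 0.075,
                       twin_rate = 0.015,
                       survey_years = c(1995L, 1996L, 1998L, 2000L, 2002L,
                                        2004L, 2006L, 2010L, 2012L, 2014L)) {
  probs <- c(p_marry = p_marry, p_divorce = p_divorce,
             p_polygyny = p_polygyny, parent_mortality = parent_mortality,
             p_birth = p_birth, p_birth_single = p_birth_single,
             p_father_external = p_father_external,
             p_mother_external = p_mother_external,
             p_sex_unknown = p_sex_unknown, twin_rate = twin_rate)
  if (any(probs < 0 | probs > 1))
    stop_validation("probabilities must lie in [0, 1]: %s",
                    paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (p_birth == 0 && p_birth_single == 0)
    stop_validation("infeasible config: zero fertility generates no children")
  if (n_children < 1L) stop_validation("n_children must be >= 1")
  structure(as.list(environment()), class = "fam_sim_config")
}

#' Simulate family histories
#'
#' Generates a seeded, reproducible population of women, men and children:
#' marital states evolve by the configured Markov kernel, men may hold
#' overlapping spells (polygyny), external parents are recorded as
#' `"EXTERNAL"`, and birth order counts births within each mother. Child
#' deaths are not generated here; they come from the survival model via
#' [simulate_outcomes()].
#'
#' @param config a `fam_sim_config`.
#' @return list `children` (with a simulation-internal `sex_true` column for
#'   generating outcomes of unknown-sex children), `spells`, `vitals`.
#' @export
simulate_histories <- function(config) {
  stopifnot(inherits(config, "fam_sim_config"))
  set.seed(config$seed)
  y0 <- config$year_range[1]; y1 <- config$year_range[2]
  ## size the women pool for the target child count: average overlap of a
  ## 31-year fertile span with the window, marriage-equilibrium occupancy,
  ## and a discount for mortality and market ramp-up
  W <- y1 - y0 + 1L
  avg_fert <- 31 * W / (W + 30)
  mf <- config$p_marry / max(config$p_marry + config$p_divorce, 1e-9)
  per_woman <- avg_fert * (mf * config$p_birth +
                             (1 - mf) * config$p_birth_single) * 0.55
  n_women <- max(8L, ceiling(config$n_children / max(per_woman, 0.2)))

  draw_death <- function(n, from) {
    if (config$parent_mortality == 0) return(rep(y1 + 1000L, n))
    from + rgeom(n, config$parent_mortality)
  }
  w_birth <- sort(sample(seq(y0 - 45L, y1 - 16L), n_women, replace = TRUE))
  w_death <- draw_death(n_women, w_birth + 15L)
  women <- data.frame(id = sprintf("W%04d", seq_len(n_women)),
                      birth = w_birth, death = w_death,
                      husband = NA_character_, births = 0L,
                      stringsAsFactors = FALSE)
  men <- data.frame(id = character(), birth = integer(), death = integer(),
                    wives = integer(), stringsAsFactors = FALSE)
  spells <- list(); spell_open <- list()  # key "wife" -> list(husband,start)
  kids <- list()
  n_men <- 0L

  new_man <- function(year) {
    n_men <<- n_men + 1L
    id <- sprintf("M%04d", n_men)
    men[nrow(men) + 1L, ] <<- list(id, year - sample(20:35, 1L),
                                   draw_death(1L, year), 0L)
    id
  }
  close_spell <- function(wife, year) {
    op <- spell_open[[wife]]
    if (is.null(op)) return(invisible())
    spells[[length(spells) + 1L]] <<- data.frame(
      parent_id = op$husband, spouse_id = wife,
      start_year = op$start, end_year = year, stringsAsFactors = FALSE)
    men$wives[men$id == op$husband] <<- men$wives[men$id == op$husband] - 1L
    spell_open[[wife]] <<- NULL
    women$husband[women$id == wife] <<- NA_character_
    invisible()
  }

  for (year in seq(y0, y1)) {
    w_alive <- women$death >= year
    m_dead_now <- men$id[men$death == year - 1L]
    ## widowhood and dissolution bookkeeping at the start of the year
    for (w in women$id[!is.na(women$husband)]) {
      h <- women$husband[women$id == w]
      if (h %in% m_dead_now) close_spell(w, year - 1L)
    }
    for (w in women$id[women$death == year - 1L & !is.na(women$husband)])
      close_spell(w, year - 1L)

    age <- year - women$birth
    ## divorces
    mar <- which(w_alive & !is.na(women$husband))
    if (length(mar)) {
      div <- mar[runif(length(mar)) < config$p_divorce]
      for (i in div) close_spell(women$id[i], year)
    }
    ## marriages
    unm <- which(w_alive & is.na(women$husband) & age >= 15 & age <= 49)
    if (length(unm)) {
      marry <- unm[runif(length(unm)) < config$p_marry]
      for (i in marry) {
        poly_pool <- men$id[men$wives >= 1L & men$wives < config$max_wives &
                              men$death >= year]
        h <- if (length(poly_pool) && runif(1) < config$p_polygyny) {
          poly_pool[sample.int(length(poly_pool), 1L)]
        } else {
          free <- men$id[men$wives == 0L & men$death >= year]
          if (length(free) && runif(1) < 0.5)
            free[sample.int(length(free), 1L)]
          else new_man(year)
        }
        women$husband[i] <- h
        men$wives[men$id == h] <- men$wives[men$id == h] + 1L
        spell_open[[women$id[i]]] <- list(husband = h, start = year)
      }
    }
    ## births
    fert <- which(w_alive & age >= 15 & age <= 45)
    for (i in fert) {
      married <- !is.na(women$husband[i])
      pb <- if (married) config$p_birth else config$p_birth_single
      if (runif(1) >= pb) next
      n_born <- if (runif(1) < config$twin_rate) 2L else 1L
      for (b in seq_len(n_born)) {
        women$births[i] <- women$births[i] + 1L
        sex_true <- sample(c("female", "male"), 1L)
        father <- if (married) women$husband[i] else EXTERNAL
        if (married && runif(1) < config$p_father_external) father <- EXTERNAL
        mother <- if (runif(1) < config$p_mother_external) EXTERNAL
                  else women$id[i]
        kids[[length(kids) + 1L]] <- data.frame(
          child_id = sprintf("C%05d", length(kids) + 1L),
          sex = if (runif(1) < config$p_sex_unknown) NA_character_
                else sex_true,
          sex_true = sex_true,
          birth_year = year, twin = n_born == 2L,
          birth_order = women$births[i],
          mother_id = mother, father_id = father,
          death_year = NA_integer_,
          last_observed_year = min(year + 18L, y1),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (w in names(spell_open)) {
    op <- spell_open[[w]]
    spells[[length(spells) + 1L]] <- data.frame(
      parent_id = op$husband, spouse_id = w, start_year = op$start,
      end_year = NA_integer_, stringsAsFactors = FALSE)
  }
  children <- do.call(rbind, kids)
  if (is.null(children))
    stop_validation("infeasible config: no children generated")
  if (nrow(children) > config$n_children) {
    keep <- sort(sample.int(nrow(children), config$n_children))
    children <- children[keep, , drop = FALSE]
  }
  spells <- if (length(spells)) do.call(rbind, spells) else
    data.frame(parent_id = character(), spouse_id = character(),
               start_year = integer(), end_year = integer())
  vitals <- data.frame(
    parent_id = c(women$id, men$id),
    death_year = ifelse(c(women$death, men$death) > y1, NA_integer_,
                        c(women$death, men$death)),
    known = TRUE,
    birth_year = c(women$birth, men$birth),   # extra column, kept for checks
    stringsAsFactors = FALSE)
  sex_true <- children$sex_true
  children$sex_true <- NULL
  children <- validate_children(children)
  children$sex_true <- sex_true
  list(children = children, spells = validate_spells(spells),
       vitals = validate_vitals(vitals))
}

#' Draw child outcomes from the model likelihoods
#'
#' Survival is drawn sequentially age by age from
#' `Bernoulli(logistic(theta))`; a child's rows are truncated at the first
#' death, `survived` is set to 0 on the final row, and the records'
#' `death_year` is updated. Height, weight (conditional on the drawn height)
#' and years of schooling are drawn only at survey years from the log-normal
#' and zero-inflated Poisson likelihoods with the true parameters.
#'
#' @param panel a `fam_panel` built from simulated histories.
#' @param true_params list with elements `survival`, `height`, `weight`
#'   (`fam_params`) and `education` (list `theta`, `rate`); any element may
#'   be NULL to skip that outcome. See [make_true_params()].
#' @param seed integer seed.
#' @param records the `children` table the panel was built from (its
#'   `sex_true` column supplies the latent sex of unknown-sex children; if
#'   absent, latent sexes are drawn fairly).
#' @return list `panel` (truncated, outcomes filled) and `records` (deaths
#'   applied).
#' @export
simulate_outcomes <- function(panel, true_params, seed, records = NULL) {
  stopifnot(inherits(panel, "fam_panel"))
  if (is.null(true_params) || length(true_params) == 0L)
    stop_validation("true parameters are required to simulate outcomes")
  set.seed(seed)
  survey_years <- attr(panel, "survey_years")
  atts <- attributes(panel)

  ## latent sex for generation
  male <- panel$male
  if (anyNA(male)) {
    if (!is.null(records) && !is.null(records$sex_true)) {
      lat <- setNames(as.integer(records$sex_true == "male"),
                      records$child_id)
      male[is.na(male)] <- lat[panel$child_id[is.na(male)]]
    }
    if (anyNA(male)) {
      ukid <- unique(panel$child_id[is.na(male)])
      lat <- setNames(rbinom(length(ukid), 1L, 0.5), ukid)
      male[is.na(male)] <- lat[panel$child_id[is.na(male)]]
    }
  }
  orig_male <- panel$male          # recorded sex (NA where unknown)
  gen <- panel
  gen$male <- male

  if (!is.null(true_params$survival)) {
    theta <- linear_predictor(gen, true_params$survival)
    surv <- rbinom(nrow(gen), 1L, plogis(theta))
    ## truncate at the first death within each child (rows are age-ordered)
    dt <- data.table::data.table(child = gen$child_id, age = gen$age,
                                 s = surv)
    dt[, first_death := {
      d <- which(s == 0L)
      if (length(d)) age[min(d)] else NA_integer_
    }, by = child]
    keep <- is.na(dt$first_death) | dt$age <= dt$first_death
    died <- !is.na(dt$first_death) & dt$age == dt$first_death
    panel <- gen[keep, , drop = FALSE]       # latent sex, for generation
    panel$survived <- as.integer(!died[keep])
    unknown_sex <- is.na(orig_male)[keep]
  } else {
    panel <- gen
    unknown_sex <- is.na(orig_male)
  }

  for (nm in c("survey_years", "max_age", "birth_order_cap")) {
    attr(panel, nm) <- atts[[nm]]
  }
  class(panel) <- c("fam_panel", "data.frame")

  sv <- panel$year %in% survey_years
  if (!is.null(true_params$height)) {
    rows <- which(sv)
    th <- linear_predictor(panel[rows, , drop = FALSE], true_params$height)
    panel$height_cm[rows] <-
      exp(rnorm(length(rows), th, true_params$height$lambda))
  }
  if (!is.null(true_params$weight)) {
    rows <- which(sv & !is.na(panel$height_cm))
    tp <- true_params$weight
    a <- panel$age[rows] + 1L
    th <- linear_predictor(panel[rows, , drop = FALSE], tp) +
      tp$beta_height[a] * (log(panel$height_cm[rows]) - tp$height_center[a])
    panel$weight_kg[rows] <- exp(rnorm(length(rows), th, tp$lambda))
  }
  if (!is.null(true_params$education)) {
    rows <- which(sv)
    sub <- panel[rows, , drop = FALSE]
    p_never <- plogis(linear_predictor(sub, true_params$education$theta))
    rate <- exp(linear_predictor(sub, true_params$education$rate))
    attend <- rbinom(length(rows), 1L, 1 - p_never)
    panel$edu_years[rows] <- ifelse(attend == 1L,
                                    rpois(length(rows), rate), 0L)
  }

  ## mask latent sex back to unknown where the registry lost it
  panel$male[unknown_sex] <- NA_integer_

  if (!is.null(records)) {
    last <- !duplicated(panel$child_id, fromLast = TRUE)
    died <- panel$survived == 0L & last
    dy <- setNames(panel$year[died], panel$child_id[died])
    hit <- match(records$child_id, names(dy))
    records$death_year <- as.integer(ifelse(!is.na(hit), dy[hit],
                                            NA_integer_))
    records$last_observed_year <- as.integer(ifelse(
      !is.na(hit), dy[hit], records$last_observed_year))
  }
  list(panel = panel, records = records)
}

#' Realistic default generating parameters
#'
#' True parameter sets for the four outcome models, used by the simulation
#' and calibration suites: an age-specific survival curve rising from 0.92
#' in the first year towards ~0.996 by late childhood, log-normal growth
#' curves for height and weight with an allometric weight-for-height slope,
#' and a zero-inflated education model in which schooling starts around age
#' 7. All covariate effects default to zero; inject effects by editing the
#' returned `beta` matrices.
#'
#' @param years calendar years the year effect covers (values zero).
#' @param perspective `"mother"` or `"father"`.
#' @param n_age number of age classes.
#' @return list `survival`, `height`, `weight`, `education` (list
#'   `theta`/`rate`), each a `fam_params`.
#' @export
make_true_params <- function(years = integer(0), perspective = "mother",
                             n_age = 19L) {
  ages <- seq_len(n_age) - 1L
  p <- function() make_parameter_set(perspective, n_age = n_age,
                                     years = years)
  surv_prob <- pmin(0.92 + 0.012 * ages, 0.996)
  sp <- p(); sp$beta["intercept", ] <- qlogis(surv_prob)
  height_med <- c(68, 79, 87, 94, 101, 107, 113, 118, 124, 129, 134, 140,
                  146, 151, 155, 158, 160, 161, 162)[seq_len(n_age)]
  hp <- p(); hp$beta["intercept", ] <- log(height_med); hp$lambda <- 0.045
  weight_med <- c(7.5, 10, 12, 14, 16, 18, 20, 22.5, 25, 28, 31, 34.5, 38.5,
                  43, 47, 50, 53, 55, 56)[seq_len(n_age)]
  wp <- p(); wp$beta["intercept", ] <- log(weight_med); wp$lambda <- 0.08
  wp$beta_height <- rep(1.6, n_age)
  wp$height_center <- log(height_med)
  et <- p(); et$beta["intercept", ] <-
    c(4, 4, 4, 4, 4, 4, 1.5, 0.5, 0, -0.3, -0.6, -0.8, -1, -1.1, -1.2,
      -1.3, -1.4, -1.5, -1.5)[seq_len(n_age)]
  er <- p(); er$beta["intercept", ] <-
    log(pmax(0.3, pmin((ages - 5) * 0.7, 9)))
  list(survival = sp, height = hp, weight = wp,
       education = list(theta = et, rate = er))
}

#' Tiny deterministic fixture dataset
#'
#' Twelve hand-written children covering every leaf of both parental-state
#' branching trees, censoring by data end, a child death, a twin pair, an
#' unknown-sex child, an external father and an external mother, plus a few
#' survey-year measurements. The expected panel ships as
#' `extdata/fixture_panel_golden.csv`.
#'
#' @return list `children`, `spells`, `vitals`, `measurements`,
#'   `survey_years`.
#' @export
make_fixture <- function() {
  children <- child_records(
    child_id = sprintf("c%02d", 1:12),
    sex = c("female", "male", "female", "male", "female", "male", "female",
            "male", "female", NA, "female", "male"),
    birth_year = c(1991, 1995, 1993, 1994, 1996, 2003, 1992, 2000, 2001,
                   1998, 1998, 2009),
    twin = c(rep(FALSE, 9), TRUE, TRUE, FALSE),
    birth_order = c(1, 1, 1, 1, 1, 2, 1, 1, 1, 2, 3, 1),
    mother_id = c("M1", "M2", "M3", "M4", "M5", "M4", "M6", "M7", EXTERNAL,
                  "M1", "M1", "M8"),
    father_id = c("F1", "F2", "F3", "F4", "F5", "F5", "F5", EXTERNAL, "F7",
                  "F1", "F1", "F7"),
    death_year = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 1999, NA, NA),
    last_observed_year = c(2009, 2013, 2011, 2012, 2014, 2014, 2010, 2014,
                           2014, 1999, 2014, 2014))
  spells <- marriage_spells(
    parent_id = c("F1", "F2", "F3", "F4", "F4", "F5", "F5", "F5", "F6",
                  "F7"),
    spouse_id = c("M1", "M2", "M3", "M3", "M4", "M5", "M4", "M6", "M6",
                  "M8"),
    start_year = c(1990, 1992, 1990, 2001, 1993, 1995, 2002, 1990, 1998,
                   1999),
    end_year = c(NA, NA, NA, NA, 1996, NA, NA, 1994, NA, NA))
  vitals <- parent_vitals(
    parent_id = c(paste0("M", 1:8), paste0("F", 1:7)),
    death_year = c(NA, 2000, NA, NA, NA, NA, NA, NA,
                   NA, NA, 1998, NA, NA, NA, NA),
    known = TRUE)
  measurements <- data.frame(
    child_id = c("c01", "c05", "c08"),
    year = c(2000, 2005, 2005),
    height_cm = c(130, 129, 105),
    weight_kg = c(28, 27, 17),
    edu_years = c(2L, 3L, 0L),
    stringsAsFactors = FALSE)
  list(children = children, spells = spells, vitals = vitals,
       measurements = measurements, survey_years = c(2000L, 2005L))
}

#' Build the fixture's child-year panel
#'
#' @param fixture output of [make_fixture()].
#' @return a `fam_panel`.
#' @export
fixture_panel <- function(fixture = make_fixture()) {
  tl <- build_marriage_timeline(fixture$spells, fixture$vitals,
                                year_range = c(1985L, 2014L))
  build_child_year_panel(fixture$children, tl,
                         survey_years = fixture$survey_years,
                         measurements = fixture$measurements)
}
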