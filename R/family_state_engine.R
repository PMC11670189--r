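## Marriage timelines and the child-year panel.
##
## Annual resolution: a spell covers start_year..end_year inclusive; with
## several same-year transitions the state in force at the end of the year
## wins (latest-starting spell). A spouse remains in the partner's spouse set
## through the year of death (sets are empty from death_year + 1 onward), but
## the deceased parent's own leaf is DECEASED from the death year itself.

#' @import data.table
NULL

#' Build per-parent marriage timelines
#'
#' Expands marriage spells into per-year spouse sets for every known parent,
#' intersected with both partners' lifespans, and records who is alive in
#' which year. The result feeds the parental-state classifier.
#'
#' @param spells a `fam_spells` table (see [marriage_spells()]).
#' @param vitals a `fam_vitals` table covering every parent referenced by a
#'   spell (input-integrity error otherwise).
#' @param year_range optional `c(min, max)` calendar years the timeline must
#'   cover; defaults to the span of the spells and vital events.
#' @return an object of class `fam_timeline`.
#' @export
build_marriage_timeline <- function(spells, vitals, year_range = NULL) {
  spells <- validate_spells(as.data.frame(spells))
  vitals <- validate_vitals(as.data.frame(vitals))
  refd <- unique(c(spells$parent_id,
                   spells$spouse_id[!is_external_id(spells$spouse_id)]))
  unknown <- setdiff(refd, vitals$parent_id)
  if (length(unknown))
    stop_validation("spell references parent_id absent from vitals: %s",
                    paste(unknown, collapse = ", "))
  death <- setNames(vitals$death_year, vitals$parent_id)
  if (is.null(year_range)) {
    yrs <- c(spells$start_year, spells$end_year, vitals$death_year)
    yrs <- yrs[!is.na(yrs)]
    year_range <- if (length(yrs)) range(yrs) else c(NA_integer_, NA_integer_)
  }
  year_range <- as.integer(year_range)

  cy <- data.table::data.table()
  if (nrow(spells) && !anyNA(year_range)) {
    sp <- data.table::as.data.table(spells)
    sp[, spell := .I]
    ## membership ends at the earliest of: spell end (open -> data range end),
    ## either partner's death year (inclusive), the data range end
    sp[, stop_y := pmin(data.table::fifelse(is.na(end_year),
                                            year_range[2L], end_year),
                        year_range[2L])]
    own_d <- death[sp$parent_id]
    sp[!is.na(own_d), stop_y := pmin(stop_y, own_d[!is.na(own_d)])]
    sps_d <- death[sp$spouse_id]
    sp[!is.na(sps_d), stop_y := pmin(stop_y, sps_d[!is.na(sps_d)])]
    sp <- sp[stop_y >= start_year]
    if (nrow(sp)) {
      ## effective end of the union: divorce year or either partner's death
      ## (Inf = still in force at the data-range end)
      ended <- pmin(data.table::fifelse(is.na(sp$end_year), Inf,
                                        as.double(sp$end_year)),
                    data.table::fifelse(is.na(death[sp$parent_id]), Inf,
                                        as.double(death[sp$parent_id])),
                    data.table::fifelse(is.na(death[sp$spouse_id]), Inf,
                                        as.double(death[sp$spouse_id])))
      sp[, ended_eff := ended]
      expand <- sp[rep(seq_len(.N), stop_y - start_year + 1L)]
      expand[, year := start_year + data.table::rowid(spell) - 1L]
      fwd <- expand[, .(parent_id, spouse_id, year, spell, start_year,
                        ended_eff)]
      bwd <- expand[!is_external_id(spouse_id),
                    .(parent_id = spouse_id, spouse_id = parent_id, year,
                      spell, start_year, ended_eff)]
      cy <- unique(rbind(fwd, bwd))
    }
  }
  if (!nrow(cy)) {
    cy <- data.table::data.table(parent_id = character(), spouse_id = character(),
                                 year = integer(), spell = integer(),
                                 start_year = integer(), ended_eff = double())
  }
  ## a union is "in force at end of year" while the year precedes its
  ## effective end; when every union of the year has ended (dissolution or
  ## death not superseded by a remarriage), the latest-starting ended
  ## union(s) still define that year's state -> "effective" rows
  cy[, in_force := year < ended_eff]
  cy[, eff := if (any(in_force)) in_force
     else start_year == max(start_year), by = .(parent_id, year)]
  ## distinct-spouse key: external spouses are distinguished per spell
  cy[, skey := data.table::fifelse(is_external_id(spouse_id),
                                   paste0(".ext", spell), spouse_id)]
  n_sp <- cy[, .(n_all = data.table::uniqueN(skey),
                 n_eff = data.table::uniqueN(skey[eff])),
             by = .(parent_id, year)]
  ## representative spouse: latest-starting effective union
  ## (ties: lexicographic, deterministic)
  ord <- cy[order(parent_id, year, -eff, -start_year, skey)]
  primary <- ord[, .SD[1L], by = .(parent_id, year)][
    , .(parent_id, year, primary_spouse = spouse_id)]
  data.table::setkey(cy, parent_id, year)
  data.table::setkey(n_sp, parent_id, year)
  data.table::setkey(primary, parent_id, year)

  structure(list(couple_years = cy, n_spouses = n_sp, primary = primary,
                 vitals = vitals, death = death, spells = spells,
                 year_range = year_range),
            class = "fam_timeline")
}

#' @export
print.fam_timeline <- function(x, ...) {
  cat(sprintf("<fam_timeline> %d parents, years %s-%s, %d couple-years\n",
              nrow(x$vitals), x$year_range[1], x$year_range[2],
              nrow(x$couple_years)))
  invisible(x)
}

#' Spouse set and vital status of one parent in one year
#'
#' @param timeline a `fam_timeline`.
#' @param parent_id a single parent identifier.
#' @param year a single calendar year.
#' @return list with `spouses` (character vector, possibly containing
#'   `"EXTERNAL"` entries) and `alive` (logical; `FALSE` from the death year
#'   onward, `NA` for parents unknown to the study).
#' @export
timeline_at <- function(timeline, parent_id, year) {
  stopifnot(inherits(timeline, "fam_timeline"),
            length(parent_id) == 1L, length(year) == 1L)
  v <- timeline$vitals[timeline$vitals$parent_id == parent_id, ]
  if (!nrow(v) || !isTRUE(v$known))
    return(list(spouses = character(), alive = NA))
  dy <- v$death_year
  alive <- is.na(dy) || year < dy
  key <- data.table::data.table(parent_id = as.character(parent_id),
                                year = as.integer(year))
  sp <- timeline$couple_years[key, on = c("parent_id", "year"),
                              nomatch = NULL]
  list(spouses = sp$spouse_id, alive = alive)
}

## fast keyed lookups used by the vectorized classifier; the "effective"
## spouse count/set prefers unions in force at the end of the year and falls
## back to unions that ended during it (annual same-year transition rule)
.lookup_n_spouses <- function(timeline, ids, years) {
  dt <- data.table::data.table(parent_id = as.character(ids),
                               year = as.integer(years))
  res <- timeline$n_spouses[dt, on = c("parent_id", "year")]
  data.table::fifelse(is.na(res$n_eff), 0L, res$n_eff)
}

.lookup_primary <- function(timeline, ids, years) {
  dt <- data.table::data.table(parent_id = as.character(ids),
                               year = as.integer(years))
  timeline$primary[dt, on = c("parent_id", "year")]$primary_spouse
}

.lookup_married_to <- function(timeline, ids, years, spouses) {
  dt <- data.table::data.table(parent_id = as.character(ids),
                               year = as.integer(years),
                               spouse_id = as.character(spouses))
  eff_rows <- timeline$couple_years[eff == TRUE]
  !is.na(eff_rows[dt, on = c("parent_id", "year", "spouse_id"),
                  mult = "first", which = TRUE])
}

#' Classify a parent's marriage state for one child-year
#'
#' Follows the branching tree: external? -> deceased? -> married? -> current
#' spouse set includes the child's other biological parent? -> monogamous vs
#' polygynous. A mother is coded polygynous when her current husband has two
#' or more concurrent wives; a father when he himself has two or more wives.
#'
#' @param child one-row `fam_children` data.frame (or a list with fields
#'   `mother_id`, `father_id`).
#' @param perspective `"mother"` or `"father"`.
#' @param year calendar year.
#' @param timeline a `fam_timeline`.
#' @return one leaf from [PARENT_STATE_LEAVES].
#' @export
classify_parent_state <- function(child, perspective = c("mother", "father"),
                                  year, timeline) {
  perspective <- match.arg(perspective)
  pid <- if (perspective == "mother") child$mother_id else child$father_id
  oid <- if (perspective == "mother") child$father_id else child$mother_id
  classify_states_bulk(pid, oid, perspective, year, timeline)
}

## vectorized core: one leaf per (parent, other-parent, year) triple
classify_states_bulk <- function(pid, oid, perspective, year, timeline) {
  n <- max(length(pid), length(year))
  pid <- rep_len(as.character(pid), n)
  oid <- rep_len(as.character(oid), n)
  year <- rep_len(as.integer(year), n)
  leaf <- rep(NA_character_, n)

  known <- setNames(timeline$vitals$known, timeline$vitals$parent_id)
  k <- !is_external_id(pid) & !is.na(known[pid]) & known[pid]
  leaf[!k] <- "EXTERNAL"

  dy <- timeline$death[pid]
  dead <- k & !is.na(dy) & year >= dy
  leaf[dead] <- "DECEASED"

  todo <- which(k & !dead)
  if (length(todo)) {
    nsp <- .lookup_n_spouses(timeline, pid[todo], year[todo])
    unm <- nsp == 0L
    leaf[todo[unm]] <- "UNMARRIED"
    mar <- todo[!unm]
    if (length(mar)) {
      bio_possible <- !is_external_id(oid[mar]) &
        !is.na(known[oid[mar]]) & known[oid[mar]]
      bio <- rep(FALSE, length(mar))
      bio[bio_possible] <- .lookup_married_to(
        timeline, pid[mar][bio_possible], year[mar][bio_possible],
        oid[mar][bio_possible])
      if (perspective == "father") {
        poly <- .lookup_n_spouses(timeline, pid[mar], year[mar]) >= 2L
      } else {
        ## the mother's relevant husband: the biological father when she is
        ## married to him, otherwise the husband in force at end of year
        husb <- ifelse(bio, oid[mar], .lookup_primary(timeline, pid[mar],
                                                      year[mar]))
        poly <- rep(FALSE, length(mar))
        hk <- !is.na(husb) & !is_external_id(husb)
        poly[hk] <- .lookup_n_spouses(timeline, husb[hk], year[mar][hk]) >= 2L
      }
      leaf[mar] <- paste0(ifelse(bio, "BIO", "STEP"),
                          ifelse(poly, "_POLY", "_MONO"))
    }
  }
  leaf
}

#' Encode parental-state indicator covariates
#'
#' Deterministic map from the pair of state leaves to the indicator set used
#' by the outcome models. Mother perspective: `F` father deceased, `X` mother
#' deceased, `W` mother unmarried, `Z` mother married to a step-father, `P`
#' mother in a polygynous union (with the biological father or a step-father),
#' `U` either parent external. Father perspective adds `WF` father unmarried,
#' `ZF` father married to a step-mother, `PBF` father polygynous with the
#' biological mother, `PNF` father polygynous without her. The
#' monogamous-two-biological-parent base case maps to the all-zero vector; an
#' external parent contributes no marital indicator beyond `U`.
#'
#' @param mother_state,father_state vectors of leaves from
#'   [PARENT_STATE_LEAVES].
#' @return a data.frame of 0/1 indicator columns
#'   `F, X, W, Z, P, U, WF, ZF, PBF, PNF`.
#' @export
encode_covariates <- function(mother_state, father_state) {
  stopifnot(length(mother_state) == length(father_state))
  bad <- !(mother_state %in% PARENT_STATE_LEAVES) |
    !(father_state %in% PARENT_STATE_LEAVES)
  if (any(bad))
    stop_validation("invalid parent state leaf: %s",
                    paste(unique(c(mother_state[bad], father_state[bad])),
                          collapse = ", "))
  data.frame(
    F = as.integer(father_state == "DECEASED"),
    X = as.integer(mother_state == "DECEASED"),
    W = as.integer(mother_state == "UNMARRIED"),
    Z = as.integer(mother_state %in% c("STEP_MONO", "STEP_POLY")),
    P = as.integer(mother_state %in% c("BIO_POLY", "STEP_POLY")),
    U = as.integer(mother_state == "EXTERNAL" | father_state == "EXTERNAL"),
    WF = as.integer(father_state == "UNMARRIED"),
    ZF = as.integer(father_state %in% c("STEP_MONO", "STEP_POLY")),
    PBF = as.integer(father_state == "BIO_POLY"),
    PNF = as.integer(father_state == "STEP_POLY")
  )
}

#' Build the censored child-year panel
#'
#' One row per child per completed-year age 0..18 within the observation
#' window: ages `0..min(18, age at death, age at last observation)`. The
#' `survived` flag is 0 only on the final row of a child who died at or
#' before age 18. Parental states are classified for both perspectives and
#' encoded as indicators; anthropometric/education measurements are attached
#' only in survey years.
#'
#' @param records a `fam_children` table.
#' @param timeline a `fam_timeline` covering the records' years.
#' @param survey_years integer vector of measurement years.
#' @param measurements optional data.frame `child_id, year, height_cm,
#'   weight_kg, edu_years` (only survey-year rows are used).
#' @param max_age oldest modelled age in completed years.
#' @param birth_order_cap birth orders at or above this value share one
#'   category.
#' @return a `fam_panel` data.frame.
#' @export
build_child_year_panel <- function(records, timeline,
                                   survey_years = integer(0),
                                   measurements = NULL,
                                   max_age = 18L, birth_order_cap = 10L) {
  records <- validate_children(as.data.frame(records))
  stopifnot(inherits(timeline, "fam_timeline"))
  death_age <- ifelse(is.na(records$death_year), Inf,
                      records$death_year - records$birth_year)
  last_age <- pmin(max_age, records$last_observed_year - records$birth_year,
                   death_age)
  keep <- last_age >= 0
  rec <- records[keep, ]
  last_age <- as.integer(last_age[keep])

  idx <- rep(seq_len(nrow(rec)), last_age + 1L)
  age <- sequence(last_age + 1L) - 1L
  panel <- data.frame(
    child_id = rec$child_id[idx],
    age = age,
    year = rec$birth_year[idx] + age,
    male = ifelse(is.na(rec$sex[idx]), NA_integer_,
                  as.integer(rec$sex[idx] == "male")),
    twin = as.integer(rec$twin[idx]),
    birth_order = rec$birth_order[idx],
    bo_cat = pmin(rec$birth_order[idx], birth_order_cap),
    mother_id = rec$mother_id[idx],
    father_id = rec$father_id[idx],
    stringsAsFactors = FALSE
  )
  died <- !is.na(rec$death_year[idx]) &
    (rec$death_year[idx] - rec$birth_year[idx]) <= max_age
  panel$survived <- as.integer(!(died & age == last_age[idx]))

  panel$mother_state <- classify_states_bulk(panel$mother_id, panel$father_id,
                                             "mother", panel$year, timeline)
  panel$father_state <- classify_states_bulk(panel$father_id, panel$mother_id,
                                             "father", panel$year, timeline)
  panel <- cbind(panel, encode_covariates(panel$mother_state,
                                          panel$father_state))

  panel$height_cm <- NA_real_
  panel$weight_kg <- NA_real_
  panel$edu_years <- NA_integer_
  if (!is.null(measurements) && nrow(measurements)) {
    m <- measurements[measurements$year %in% survey_years, , drop = FALSE]
    key_p <- paste(panel$child_id, panel$year)
    key_m <- paste(m$child_id, m$year)
    hit <- match(key_p, key_m)
    ok <- !is.na(hit)
    if (!is.null(m$height_cm)) panel$height_cm[ok] <- m$height_cm[hit[ok]]
    if (!is.null(m$weight_kg)) panel$weight_kg[ok] <- m$weight_kg[hit[ok]]
    if (!is.null(m$edu_years))
      panel$edu_years[ok] <- as.integer(m$edu_years[hit[ok]])
  }
  structure(panel, survey_years = as.integer(survey_years),
            max_age = as.integer(max_age),
            birth_order_cap = as.integer(birth_order_cap),
            class = c("fam_panel", "data.frame"))
}

#' Summarise a child-year panel
#'
#' @param panel a `fam_panel`.
#' @return list with row/child counts, death and censoring tallies, parental
#'   state frequencies, and measurement coverage; serialisable to JSON.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "fam_panel"))
  last_rows <- !duplicated(panel$child_id, fromLast = TRUE)
  deaths <- sum(panel$survived[last_rows] == 0L)
  max_age <- attr(panel, "max_age") %||% 18L
  censored <- sum(panel$survived[last_rows] == 1L &
                    panel$age[last_rows] < max_age)
  list(
    n_children = length(unique(panel$child_id)),
    n_rows = nrow(panel),
    n_deaths = deaths,
    n_censored_before_max_age = censored,
    year_range = range(panel$year),
    mother_state_freq = as.list(table(panel$mother_state)),
    father_state_freq = as.list(table(panel$father_state)),
    n_obs = list(height = sum(!is.na(panel$height_cm)),
                 weight = sum(!is.na(panel$weight_kg)),
                 education = sum(!is.na(panel$edu_years))),
    survey_years = attr(panel, "survey_years")
  )
}

#' Same-year child mortality and marital dissolution overlap
#'
#' Counts child deaths whose calendar year equals the end year of a marriage
#' spell of either biological parent — a diagnostic for reverse causation at
#' annual resolution (a child's death precipitating a dissolution).
#'
#' @param panel a `fam_panel`.
#' @param timeline the `fam_timeline` the panel was built from.
#' @return list `overlap` (deaths coinciding with a parental dissolution)
#'   and `total_deaths`.
#' @export
count_same_year_death_dissolution <- function(panel, timeline) {
  stopifnot(inherits(panel, "fam_panel"), inherits(timeline, "fam_timeline"))
  d <- panel[panel$survived == 0L, c("child_id", "year", "mother_id",
                                     "father_id")]
  sp <- timeline$spells
  ends <- sp[!is.na(sp$end_year), c("parent_id", "spouse_id", "end_year")]
  if (!nrow(d)) return(list(overlap = 0L, total_deaths = 0L))
  key <- c(paste(ends$parent_id, ends$end_year),
           paste(ends$spouse_id[!is_external_id(ends$spouse_id)],
                 ends$end_year[!is_external_id(ends$spouse_id)]))
  hit <- paste(d$mother_id, d$year) %in% key |
    paste(d$father_id, d$year) %in% key
  list(overlap = sum(hit), total_deaths = nrow(d))
}

#' Write a panel and its summary to disk
#'
#' @param panel a `fam_panel`.
#' @param csv_path output CSV path (one row per child-year).
#' @param summary_path optional JSON path for [panel_summary()].
#' @return `csv_path`, invisibly.
#' @export
write_panel <- function(panel, csv_path, summary_path = NULL) {
  write.csv(as.data.frame(panel), csv_path, row.names = FALSE, na = "")
  if (!is.null(summary_path)) {
    jsonlite::write_json(panel_summary(panel), summary_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(csv_path)
}
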