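#' famstates: parental marital states and child outcomes
#'
#' Builds censored child-year panels from longitudinal family event
#' histories, classifies each child-year into a branching tree of parental
#' marriage states for both the mother and the father perspective, fits
#' Bayesian hierarchical models (discrete-time survival, log-normal height
#' and weight-for-height, zero-inflated Poisson education) with
#' Gaussian-process-smoothed age-specific effects by Hamiltonian Monte
#' Carlo, and summarises posterior contrasts between family structures.
#'
#' @useDynLib famstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm dpois plogis qlogis rbinom rgeom rnorm rpois runif
#'   sd var quantile setNames
#' @importFrom utils read.csv write.csv packageVersion head tail
#' @keywords internal
"_PACKAGE"

## Sentinel used in parent-id columns for parents whose vital/marital status
## is unknown to the study (never lived in, or left, the village).
EXTERNAL <- "EXTERNAL"

#' Leaf labels of the parental marriage-state branching tree
#'
#' Each child-year is assigned exactly one leaf per parent perspective:
#' `EXTERNAL` (parent unknown to the study), `DECEASED`, `UNMARRIED`,
#' `BIO_MONO` / `BIO_POLY` (married to the child's other biological parent,
#' monogamously / polygynously), `STEP_MONO` / `STEP_POLY` (married to a
#' step-parent, monogamously / polygynously).
#'
#' @export
PARENT_STATE_LEAVES <- c("EXTERNAL", "DECEASED", "UNMARRIED",
                         "BIO_MONO", "BIO_POLY", "STEP_MONO", "STEP_POLY")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_external_id <- function(id) {
  is.na(id) | id == EXTERNAL
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Construct and validate a child registry table
#'
#' @param child_id character or integer identifiers, unique.
#' @param sex one of `"female"`, `"male"`, `NA` (unknown).
#' @param birth_year calendar year of birth.
#' @param twin logical, member of a twin (or higher multiple) birth.
#' @param birth_order positive integer, order among the mother's births.
#' @param mother_id,father_id parent identifiers; `NA` or `"EXTERNAL"` marks
#'   a parent external to the study.
#' @param death_year calendar year of death or `NA`.
#' @param last_observed_year final calendar year with information on the
#'   child; equals `death_year` for children who died.
#' @return a `data.frame` with class `fam_children`.
#' @export
child_records <- function(child_id, sex, birth_year, twin, birth_order,
                          mother_id, father_id, death_year,
                          last_observed_year) {
  df <- data.frame(
    child_id = as.character(child_id),
    sex = as.character(sex),
    birth_year = as.integer(birth_year),
    twin = as.logical(twin),
    birth_order = as.integer(birth_order),
    mother_id = as.character(mother_id),
    father_id = as.character(father_id),
    death_year = as.integer(death_year),
    last_observed_year = as.integer(last_observed_year),
    stringsAsFactors = FALSE
  )
  validate_children(df)
}

#' @rdname child_records
#' @param df a data.frame with the `child_records` columns.
#' @export
validate_children <- function(df) {
  req <- c("child_id", "sex", "birth_year", "twin", "birth_order",
           "mother_id", "father_id", "death_year", "last_observed_year")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_validation("children table is missing columns: %s",
                    paste(miss, collapse = ", "))
  if (anyDuplicated(df$child_id))
    stop_validation("duplicate child_id values in children table")
  bad_sex <- !(df$sex %in% c("female", "male") | is.na(df$sex))
  if (any(bad_sex))
    stop_validation("invalid sex values (use 'female', 'male' or NA): %s",
                    paste(unique(df$sex[bad_sex]), collapse = ", "))
  if (any(df$birth_order < 1L, na.rm = TRUE))
    stop_validation("birth_order must be >= 1")
  dy <- df$death_year
  if (any(!is.na(dy) & dy < df$birth_year))
    stop_validation("death_year before birth_year for child(ren): %s",
                    paste(df$child_id[!is.na(dy) & dy < df$birth_year],
                          collapse = ", "))
  if (any(df$last_observed_year < df$birth_year, na.rm = TRUE))
    stop_validation("last_observed_year before birth_year for child(ren): %s",
                    paste(df$child_id[df$last_observed_year < df$birth_year],
                          collapse = ", "))
  mism <- !is.na(dy) & df$last_observed_year != dy
  if (any(mism))
    stop_validation("children with death_year must have last_observed_year equal to it: %s",
                    paste(df$child_id[mism], collapse = ", "))
  class(df) <- c("fam_children", "data.frame")
  df
}

#' Construct and validate a marriage-spell table
#'
#' One row per marriage spell. Years are inclusive: a spell covers
#' `start_year..end_year`; an open spell (`end_year = NA`) runs to the end
#' of the data range. Spells of one man may overlap in years (polygyny).
#'
#' @param parent_id,spouse_id identifiers; `spouse_id` may be `NA`/EXTERNAL.
#' @param start_year,end_year inclusive calendar years; `end_year = NA` open.
#' @return a `data.frame` with class `fam_spells`.
#' @export
marriage_spells <- function(parent_id, spouse_id, start_year, end_year) {
  df <- data.frame(
    parent_id = as.character(parent_id),
    spouse_id = as.character(spouse_id),
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    stringsAsFactors = FALSE
  )
  validate_spells(df)
}

#' @rdname marriage_spells
#' @param df a data.frame with the `marriage_spells` columns.
#' @export
validate_spells <- function(df) {
  req <- c("parent_id", "spouse_id", "start_year", "end_year")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_validation("spells table is missing columns: %s",
                    paste(miss, collapse = ", "))
  bad <- !is.na(df$end_year) & df$end_year < df$start_year
  if (any(bad))
    stop_validation("spell end_year before start_year in %d row(s)", sum(bad))
  class(df) <- c("fam_spells", "data.frame")
  df
}

#' Construct and validate a parent-vitals table
#'
#' @param parent_id identifiers, unique.
#' @param death_year calendar year of death or `NA` (alive/unknown).
#' @param known logical; `FALSE` marks a parent external to the study.
#' @return a `data.frame` with class `fam_vitals`.
#' @export
parent_vitals <- function(parent_id, death_year, known = TRUE) {
  df <- data.frame(
    parent_id = as.character(parent_id),
    death_year = as.integer(death_year),
    known = as.logical(known),
    stringsAsFactors = FALSE
  )
  validate_vitals(df)
}

#' @rdname parent_vitals
#' @param df a data.frame with the `parent_vitals` columns.
#' @export
validate_vitals <- function(df) {
  req <- c("parent_id", "death_year", "known")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_validation("vitals table is missing columns: %s",
                    paste(miss, collapse = ", "))
  if (anyDuplicated(df$parent_id))
    stop_validation("duplicate parent_id values in vitals table")
  class(df) <- c("fam_vitals", "data.frame")
  df
}

#' Read the three input tables from CSV with an optional column mapping
#'
#' Deposited or third-party data rarely use this package's column names; a
#' mapping (a named list or YAML file, `ours = theirs`) adapts any layout
#' without editing the data. Values equal to the string `"EXTERNAL"` or empty
#' in parent-id columns are treated as external parents.
#'
#' @param children_csv,spells_csv,vitals_csv paths to CSV files.
#' @param column_map optional named list with elements `children`, `spells`,
#'   `vitals`, each a named character vector mapping package column names to
#'   file column names; or a path to a YAML file with that structure.
#' @return list with validated elements `children`, `spells`, `vitals`.
#' @export
read_family_tables <- function(children_csv, spells_csv, vitals_csv,
                               column_map = NULL) {
  if (is.character(column_map) && length(column_map) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_validation("reading a YAML column map requires the 'yaml' package")
    column_map <- yaml::read_yaml(column_map)
  }
  remap <- function(df, map) {
    if (is.null(map)) return(df)
    map <- unlist(map)
    missing_src <- setdiff(unname(map), names(df))
    if (length(missing_src))
      stop_validation("column map refers to absent column(s): %s",
                      paste(missing_src, collapse = ", "))
    out <- df[, unname(map), drop = FALSE]
    names(out) <- names(map)
    out
  }
  read1 <- function(path) read.csv(path, stringsAsFactors = FALSE,
                                   na.strings = c("", "NA"))
  ch <- remap(read1(children_csv), column_map$children)
  sp <- remap(read1(spells_csv), column_map$spells)
  vi <- remap(read1(vitals_csv), column_map$vitals)
  if (is.null(vi$known)) vi$known <- TRUE
  list(children = validate_children(ch),
       spells = validate_spells(sp),
       vitals = validate_vitals(vi))
}
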