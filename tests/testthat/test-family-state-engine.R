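test_that("marriage timelines resolve single and overlapping spells", {
  spells <- marriage_spells(parent_id = c("H1", "H2", "H2"),
                            spouse_id = c("W1", "W2", "W3"),
                            start_year = c(2000, 2000, 2004),
                            end_year = c(2005, 2010, 2006))
  vitals <- parent_vitals(parent_id = c("H1", "H2", "W1", "W2", "W3"),
                          death_year = NA)
  tl <- build_marriage_timeline(spells, vitals, year_range = c(1995, 2014))
  expect_identical(timeline_at(tl, "H1", 2003)$spouses, "W1")
  expect_length(timeline_at(tl, "H1", 2006)$spouses, 0L)
  expect_setequal(timeline_at(tl, "H2", 2005)$spouses, c("W2", "W3"))
  expect_identical(timeline_at(tl, "W3", 2005)$spouses, "H2")
})

test_that("timelines agree with a brute-force year-by-year interval scan", {
  set.seed(42)
  n <- 100
  ids <- sprintf("P%02d", 1:40)
  spells <- marriage_spells(
    parent_id = sample(ids[1:20], n, replace = TRUE),
    spouse_id = sample(c(ids[21:40], "EXTERNAL"), n, replace = TRUE),
    start_year = st <- sample(1960:2010, n, replace = TRUE),
    end_year = ifelse(runif(n) < 0.3, NA, st + sample(0:20, n, TRUE)))
  vitals <- parent_vitals(
    parent_id = ids,
    death_year = ifelse(runif(40) < 0.4, sample(1970:2014, 40, TRUE), NA))
  tl <- build_marriage_timeline(spells, vitals, year_range = c(1960, 2014))
  for (i in 1:60) {
    p <- sample(ids, 1); y <- sample(1960:2014, 1)
    got <- sort(unique(timeline_at(tl, p, y)$spouses))
    want <- brute_spouses(spells, vitals, p, y)
    d <- setNames(vitals$death_year, vitals$parent_id)[p]
    if (!is.na(d) && y > d) want <- character(0)  # own death caps membership
    expect_identical(got, want,
                     info = sprintf("parent %s year %d", p, y))
  }
})

test_that("timeline validation rejects broken inputs", {
  vitals <- parent_vitals("A", NA)
  expect_error(
    build_marriage_timeline(
      marriage_spells("A", "B", 2000, 2005), vitals),
    "absent from vitals")
  expect_error(marriage_spells("A", "B", 2005, 2000), "end_year before")
  expect_error(child_records("c1", "male", 2000, FALSE, 1, "A", "B",
                             1999, 1999), "death_year before")
  expect_error(child_records("c1", "boy", 2000, FALSE, 1, "A", "B",
                             NA, 2010), "invalid sex")
})

test_that("classifier reproduces the hand-written branching-tree truth table", {
  # one family per case; bio parents are M0/F0
  spells <- marriage_spells(
    parent_id = c("F_mono", "F_poly", "F_poly", "F_step", "F_steppoly",
                  "F_steppoly", "H_mono", "H_poly", "H_poly"),
    spouse_id = c("M0", "M0", "M_cowife", "M_other", "M_other2", "M_other3",
                  "M1", "M2", "M_cowife2"),
    start_year = 2000, end_year = NA)
  vitals <- parent_vitals(
    parent_id = c("M0", "M1", "M2", "M_cowife", "M_cowife2", "M_other",
                  "M_other2", "M_other3", "F_mono", "F_poly", "F_step",
                  "F_steppoly", "H_mono", "H_poly", "F_dead", "M_dead",
                  "F_single", "M_single"),
    death_year = c(rep(NA, 14), 2001, 2001, NA, NA))
  tl <- build_marriage_timeline(spells, vitals, year_range = c(2000, 2010))
  kid <- function(m, f) list(mother_id = m, father_id = f)
  # father perspective: (known, alive, married, bio spouse, spouse count)
  expect_identical(classify_parent_state(kid("M0", "EXTERNAL"), "father", 2005, tl), "EXTERNAL")
  expect_identical(classify_parent_state(kid("M0", "F_dead"), "father", 2005, tl), "DECEASED")
  expect_identical(classify_parent_state(kid("M0", "F_dead"), "father", 2000, tl), "UNMARRIED")
  expect_identical(classify_parent_state(kid("M0", "F_single"), "father", 2005, tl), "UNMARRIED")
  expect_identical(classify_parent_state(kid("M0", "F_mono"), "father", 2005, tl), "BIO_MONO")
  expect_identical(classify_parent_state(kid("M0", "F_poly"), "father", 2005, tl), "BIO_POLY")
  expect_identical(classify_parent_state(kid("M0", "F_step"), "father", 2005, tl), "STEP_MONO")
  expect_identical(classify_parent_state(kid("M0", "F_steppoly"), "father", 2005, tl), "STEP_POLY")
  # mother perspective: polygyny follows the husband's concurrent wife count
  expect_identical(classify_parent_state(kid("EXTERNAL", "F_mono"), "mother", 2005, tl), "EXTERNAL")
  expect_identical(classify_parent_state(kid("M_dead", "F_mono"), "mother", 2005, tl), "DECEASED")
  expect_identical(classify_parent_state(kid("M_single", "F_mono"), "mother", 2005, tl), "UNMARRIED")
  expect_identical(classify_parent_state(kid("M0", "F_mono"), "mother", 2005, tl), "BIO_MONO")
  expect_identical(classify_parent_state(kid("M0", "F_poly"), "mother", 2005, tl), "BIO_POLY")
  expect_identical(classify_parent_state(kid("M1", "F_other_bio"), "mother", 2005, tl), "STEP_MONO")
  expect_identical(classify_parent_state(kid("M2", "F_other_bio"), "mother", 2005, tl), "STEP_POLY")
  # deceased dominates marital state
  expect_identical(classify_parent_state(kid("M_dead", "F_poly"), "mother", 2005, tl), "DECEASED")
})

test_that("indicator encoding matches its definition and is leaf-invertible", {
  base <- encode_covariates("BIO_MONO", "BIO_MONO")
  expect_true(all(base == 0))
  sp <- encode_covariates("STEP_POLY", "BIO_MONO")
  expect_identical(c(sp$Z, sp$P), c(1L, 1L))   # step-father in polygyny
  ext <- encode_covariates("BIO_MONO", "EXTERNAL")
  expect_identical(ext$U, 1L)
  expect_true(all(ext[c("F", "WF", "ZF", "PBF", "PNF")] == 0))
  dead <- encode_covariates("DECEASED", "DECEASED")
  expect_identical(c(dead$X, dead$F), c(1L, 1L))
  expect_true(all(dead[c("W", "Z", "P")] == 0))
  expect_error(encode_covariates("WIDOWED", "BIO_MONO"), "invalid")

  # no two distinct leaf pairs share an indicator vector (within the leaf
  # partition the encoding is invertible)
  leaves <- PARENT_STATE_LEAVES
  grid <- expand.grid(m = leaves, f = leaves, stringsAsFactors = FALSE)
  enc <- encode_covariates(grid$m, grid$f)
  keys <- apply(enc, 1, paste, collapse = "")
  mother_leaf_of <- tapply(grid$m, keys, unique)
  father_leaf_of <- tapply(grid$f, keys, unique)
  # identical vectors may only arise when the non-external leaves coincide
  for (k in unique(keys)) {
    ms <- unique(grid$m[keys == k & grid$m != "EXTERNAL" & grid$f != "EXTERNAL"])
    fs <- unique(grid$f[keys == k & grid$m != "EXTERNAL" & grid$f != "EXTERNAL"])
    expect_lte(length(ms), 1)
    expect_lte(length(fs), 1)
  }
})

test_that("panel rows follow the censoring rules", {
  fx <- make_fixture()
  tl <- build_marriage_timeline(fx$spells, fx$vitals, c(1985, 2014))
  panel <- build_child_year_panel(fx$children, tl,
                                  survey_years = fx$survey_years,
                                  measurements = fx$measurements)
  rows_of <- function(id) panel[panel$child_id == id, ]
  # born 2009, data end 2014: ages 0-5 only
  expect_identical(rows_of("c12")$age, 0:5)
  # died in the second year of life: ages 0-1, survived = 0 on the last row
  expect_identical(rows_of("c10")$age, 0:1)
  expect_identical(rows_of("c10")$survived, c(1L, 0L))
  # fully observed child: 19 rows, all base state, survived = 1 throughout
  expect_identical(nrow(rows_of("c01")), 19L)
  expect_true(all(rows_of("c01")$mother_state == "BIO_MONO"))
  expect_true(all(rows_of("c01")$survived == 1L))
  # per-child row counts = min(19, death age + 1, last observed age + 1)
  for (i in seq_len(nrow(fx$children))) {
    ch <- fx$children[i, ]
    want <- min(19, ch$last_observed_year - ch$birth_year + 1)
    expect_identical(nrow(rows_of(ch$child_id)), as.integer(want))
  }
  # measurements only in survey years
  expect_true(all(panel$year[!is.na(panel$height_cm)] %in% fx$survey_years))
  # X = 1 implies W = Z = P = 0; U consistency
  expect_true(all(panel[panel$X == 1, c("W", "Z", "P")] == 0))
  expect_identical(panel$U == 1,
                   panel$mother_state == "EXTERNAL" |
                     panel$father_state == "EXTERNAL")
})

test_that("same-year death/dissolution count matches a pairwise scan", {
  res <- make_test_panel(n_children = 120, seed = 31)
  tl <- res$timeline
  got <- count_same_year_death_dissolution(res$panel, tl)
  d <- res$panel[res$panel$survived == 0, ]
  sp <- res$histories$spells
  ends <- sp[!is.na(sp$end_year), ]
  hit <- 0L
  for (i in seq_len(nrow(d))) {
    par_ids <- c(d$mother_id[i], d$father_id[i])
    if (any(ends$end_year == d$year[i] &
              (ends$parent_id %in% par_ids | ends$spouse_id %in% par_ids)))
      hit <- hit + 1L
  }
  expect_identical(got$total_deaths, nrow(d))
  expect_identical(got$overlap, hit)
  # empty case
  empty <- res$panel[res$panel$survived == 1, , drop = FALSE]
  class(empty) <- class(res$panel)
  expect_identical(count_same_year_death_dissolution(empty, tl),
                   list(overlap = 0L, total_deaths = 0L))
})

test_that("CSV readers apply column maps and validate schemas", {
  fx <- make_fixture()
  dir <- withr::local_tempdir()
  ch <- fx$children
  names(ch) <- c("kid", "sex", "yob", "twin", "parity", "mum", "dad",
                 "yod", "last_seen")
  write.csv(ch, file.path(dir, "children.csv"), row.names = FALSE, na = "")
  write.csv(fx$spells, file.path(dir, "spells.csv"), row.names = FALSE, na = "")
  write.csv(fx$vitals, file.path(dir, "vitals.csv"), row.names = FALSE, na = "")
  map <- list(children = c(child_id = "kid", sex = "sex", birth_year = "yob",
                           twin = "twin", birth_order = "parity",
                           mother_id = "mum", father_id = "dad",
                           death_year = "yod", last_observed_year = "last_seen"))
  tabs <- read_family_tables(file.path(dir, "children.csv"),
                             file.path(dir, "spells.csv"),
                             file.path(dir, "vitals.csv"), column_map = map)
  expect_s3_class(tabs$children, "fam_children")
  expect_identical(tabs$children$child_id, fx$children$child_id)
  expect_error(
    read_family_tables(file.path(dir, "children.csv"),
                       file.path(dir, "spells.csv"),
                       file.path(dir, "vitals.csv"),
                       column_map = list(children = c(child_id = "nope"))),
    "absent column")
})
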