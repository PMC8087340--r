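# Cohort file formats: one CSV per section (personal.csv, diet.csv,
# activity.csv, relations.csv; UTF-8, mandatory header, empty field = missing
# answer) and a single JSON bundle. Numeric cells are written with %.17g so a
# write/read cycle reproduces every double bit-identically.

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.17g", v), character(1)))
}

write_table_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

PERSONAL_NUM <- c("weight", "height", "age", "household_size", "sleep_hours",
                  "cigarettes")
PERSONAL_CHR <- c("gender", "education_level", "marital_status",
                  "main_activity", "zip_code")
PERSONAL_LGL <- c("dx_hypertension", "dx_diabetes", "dx_cholesterol",
                  "dx_cardiovascular")
ACTIVITY_NUM <- c("vigorous_days", "vigorous_minutes", "moderate_days",
                  "moderate_minutes", "walk_days", "walk_minutes",
                  "sitting_hours")

#' Write a cohort as per-section CSV files
#'
#' Writes personal.csv, diet.csv (wide: one column per canonical item),
#' activity.csv and relations.csv into \code{dir}. A participant missing a
#' section has no row in that section's file; an unanswered diet item is an
#' empty cell.
#'
#' @param x \code{cohort}.
#' @param dir output directory (created if needed).
#' @param items canonical item ids defining the diet.csv columns.
#' @return \code{dir}, invisibly.
#' @export
write_cohort_csv <- function(x, dir, items = canonical_food_items()$item_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_list <- x$assessments
  ids <- names(as_list)

  has_p <- vapply(as_list, function(a) !is.null(a$personal), logical(1))
  pdf <- do.call(rbind, lapply(as_list[has_p], function(a) {
    p <- a$personal
    data.frame(user_id = a$user_id, language = a$language,
               t(vapply(PERSONAL_NUM, function(f) fmt_num(p[[f]]), character(1))),
               t(vapply(PERSONAL_CHR, function(f) p[[f]], character(1))),
               t(vapply(PERSONAL_LGL, function(f) as.character(p[[f]]), character(1))),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  if (is.null(pdf))
    pdf <- as.data.frame(setNames(rep(list(character(0)),
                                      2 + length(c(PERSONAL_NUM, PERSONAL_CHR, PERSONAL_LGL))),
                                  c("user_id", "language", PERSONAL_NUM,
                                    PERSONAL_CHR, PERSONAL_LGL)))
  write_table_utf8(pdf, file.path(dir, "personal.csv"))

  has_d <- vapply(as_list, function(a) !is.null(a$diet), logical(1))
  ddf <- do.call(rbind, lapply(as_list[has_d], function(a) {
    row <- setNames(rep("", length(items)), items)
    got <- intersect(names(a$diet$answers), items)
    row[got] <- a$diet$answers[got]
    data.frame(user_id = a$user_id, t(row), stringsAsFactors = FALSE,
               check.names = FALSE)
  }))
  if (is.null(ddf))
    ddf <- as.data.frame(setNames(rep(list(character(0)), 1 + length(items)),
                                  c("user_id", items)))
  write_table_utf8(ddf, file.path(dir, "diet.csv"))

  has_a <- vapply(as_list, function(a) !is.null(a$activity), logical(1))
  adf <- do.call(rbind, lapply(as_list[has_a], function(a) {
    data.frame(user_id = a$user_id,
               t(vapply(ACTIVITY_NUM, function(f) fmt_num(a$activity[[f]]),
                        character(1))),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  if (is.null(adf))
    adf <- as.data.frame(setNames(rep(list(character(0)), 1 + length(ACTIVITY_NUM)),
                                  c("user_id", ACTIVITY_NUM)))
  write_table_utf8(adf, file.path(dir, "activity.csv"))

  rdf <- if (length(x$relations)) {
    do.call(rbind, lapply(x$relations, function(r)
      data.frame(user_a = r$user_a, user_b = r$user_b,
                 relation_type = r$relation_type, stringsAsFactors = FALSE)))
  } else {
    data.frame(user_a = character(), user_b = character(),
               relation_type = character(), stringsAsFactors = FALSE)
  }
  write_table_utf8(rdf, file.path(dir, "relations.csv"))
  invisible(dir)
}

read_section_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  encoding = "UTF-8", check.names = FALSE)
}

#' Read a cohort from per-section CSV files
#'
#' @param dir directory holding personal.csv, diet.csv, activity.csv,
#'   relations.csv (as written by \code{\link{write_cohort_csv}}).
#' @param items canonical diet item ids.
#' @return \code{cohort}.
#' @export
read_cohort_csv <- function(dir, items = canonical_food_items()$item_id) {
  pdf <- read_section_csv(file.path(dir, "personal.csv"))
  ddf <- read_section_csv(file.path(dir, "diet.csv"))
  adf <- read_section_csv(file.path(dir, "activity.csv"))
  rdf <- read_section_csv(file.path(dir, "relations.csv"))

  ids <- unique(c(pdf$user_id, ddf$user_id, adf$user_id))
  assessments <- lapply(ids, function(uid) {
    personal <- NULL
    i <- match(uid, pdf$user_id)
    lang <- "es"
    if (!is.na(i)) {
      r <- pdf[i, ]
      lang <- r$language
      personal <- personal_record(
        weight = as.numeric(r$weight), height = as.numeric(r$height),
        gender = r$gender, age = as.numeric(r$age),
        education_level = r$education_level, marital_status = r$marital_status,
        household_size = as.numeric(r$household_size),
        main_activity = r$main_activity, zip_code = r$zip_code,
        sleep_hours = as.numeric(r$sleep_hours),
        cigarettes = as.numeric(r$cigarettes),
        dx_hypertension = as.logical(r$dx_hypertension),
        dx_diabetes = as.logical(r$dx_diabetes),
        dx_cholesterol = as.logical(r$dx_cholesterol),
        dx_cardiovascular = as.logical(r$dx_cardiovascular))
    }
    diet <- NULL
    i <- match(uid, ddf$user_id)
    if (!is.na(i)) {
      row <- unlist(ddf[i, setdiff(names(ddf), "user_id"), drop = FALSE])
      diet <- diet_record(row[nzchar(row)])
    }
    activity <- NULL
    i <- match(uid, adf$user_id)
    if (!is.na(i)) {
      r <- adf[i, ]
      activity <- activity_record(
        vigorous_days = as.numeric(r$vigorous_days),
        vigorous_minutes = as.numeric(r$vigorous_minutes),
        moderate_days = as.numeric(r$moderate_days),
        moderate_minutes = as.numeric(r$moderate_minutes),
        walk_days = as.numeric(r$walk_days),
        walk_minutes = as.numeric(r$walk_minutes),
        sitting_hours = as.numeric(r$sitting_hours))
    }
    assessment(uid, personal = personal, diet = diet, activity = activity,
               language = lang, items = items)
  })
  relations <- lapply(seq_len(nrow(rdf)), function(i)
    relation(rdf$user_a[i], rdf$user_b[i], rdf$relation_type[i]))
  cohort(assessments, relations)
}

#' Write a cohort as a single JSON bundle
#'
#' @param x \code{cohort}.
#' @param path output .json file.
#' @return \code{path}, invisibly.
#' @export
write_cohort_json <- function(x, path) {
  obj <- list(
    assessments = lapply(unname(x$assessments), function(a) {
      o <- list(user_id = a$user_id, language = a$language)
      if (!is.null(a$personal)) o$personal <- unclass(a$personal)
      if (!is.null(a$diet)) o$diet <- as.list(a$diet$answers)
      if (!is.null(a$activity)) o$activity <- unclass(a$activity)
      o
    }),
    relations = lapply(x$relations, function(r)
      list(user_a = r$user_a, user_b = r$user_b,
           relation_type = r$relation_type))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a JSON bundle
#'
#' @param path .json file written by \code{\link{write_cohort_json}}.
#' @param items canonical diet item ids.
#' @return \code{cohort}.
#' @export
read_cohort_json <- function(path, items = canonical_food_items()$item_id) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  assessments <- lapply(obj$assessments, function(o) {
    personal <- if (!is.null(o$personal)) do.call(personal_record, o$personal)
    diet <- if (!is.null(o$diet)) diet_record(unlist(o$diet))
    activity <- if (!is.null(o$activity)) do.call(activity_record, o$activity)
    assessment(o$user_id, personal = personal, diet = diet,
               activity = activity, language = o$language, items = items)
  })
  relations <- lapply(obj$relations, function(r)
    relation(r$user_a, r$user_b, r$relation_type))
  cohort(assessments, relations)
}
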