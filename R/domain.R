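#' Body mass index from weight and height
#'
#' @param weight Body weight in kilograms.
#' @param height Standing height in metres.
#' @return BMI in kg/m^2 (vectorised).
#' @examples
#' compute_bmi(65, 1.75)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight < 20) || any(weight > 400))
    stop("invalid field 'weight': must be finite and in [20, 400] kg", call. = FALSE)
  if (any(!is.finite(height)) || any(height < 0.9) || any(height > 2.5))
    stop("invalid field 'height': must be finite and in [0.9, 2.5] m", call. = FALSE)
  weight / height^2
}

#' BMI category
#'
#' Partitions BMI into the six WHO-style bands used throughout the toolkit.
#' Intervals are half-open \code{[lo, hi)} so the bands are gapless and
#' mutually exclusive over (0, Inf): underweight < 18.5; normal [18.5, 25);
#' overweight [25, 30); obesity class 1 [30, 35); class 2 [35, 40);
#' class 3 >= 40.
#'
#' @param bmi BMI in kg/m^2 (vectorised).
#' @return Factor with levels underweight, normal, overweight, obesity1,
#'   obesity2, obesity3.
#' @export
bmi_category <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("bmi must be positive and finite", call. = FALSE)
  cut(bmi,
      breaks = c(0, 18.5, 25, 30, 35, 40, Inf),
      labels = c("underweight", "normal", "overweight",
                 "obesity1", "obesity2", "obesity3"),
      right = FALSE)
}

# ---- record constructors ---------------------------------------------------

GENDERS <- c("female", "male", "other")
MAIN_ACTIVITIES <- c("study", "work", "other")
RELATION_TYPES <- c("home", "family", "friend", "work")
LANGUAGES <- c("es", "en", "ca")
FREQ_LEVELS <- c("L0", "L1", "L2", "L3", "L4", "L5")

#' Personal-section record
#'
#' One participant's answers to the personal section: anthropometrics,
#' sociodemographics, sleep, smoking and four cardiometabolic diagnosis /
#' medication flags.
#'
#' @param weight kg, in [20, 400].
#' @param height m, in [0.9, 2.5].
#' @param gender one of "female", "male", "other".
#' @param age years, in [14, 110].
#' @param education_level ordinal string (e.g. "primary".."postgraduate").
#' @param marital_status free categorical string.
#' @param household_size people at home, >= 1.
#' @param main_activity one of "study", "work", "other".
#' @param zip_code postal-code string.
#' @param sleep_hours hours/day, in [0, 24].
#' @param cigarettes cigarettes/day, >= 0.
#' @param dx_hypertension,dx_diabetes,dx_cholesterol,dx_cardiovascular logical
#'   diagnosis-or-medication flags.
#' @return Object of class \code{personal_record}.
#' @export
personal_record <- function(weight, height, gender = "other", age = 30,
                            education_level = "secondary",
                            marital_status = "single", household_size = 1,
                            main_activity = "other", zip_code = "00000",
                            sleep_hours = 8, cigarettes = 0,
                            dx_hypertension = FALSE, dx_diabetes = FALSE,
                            dx_cholesterol = FALSE, dx_cardiovascular = FALSE) {
  structure(list(
    weight = as.numeric(weight), height = as.numeric(height),
    gender = as.character(gender), age = as.numeric(age),
    education_level = as.character(education_level),
    marital_status = as.character(marital_status),
    household_size = as.integer(household_size),
    main_activity = as.character(main_activity),
    zip_code = as.character(zip_code),
    sleep_hours = as.numeric(sleep_hours),
    cigarettes = as.numeric(cigarettes),
    dx_hypertension = isTRUE(dx_hypertension),
    dx_diabetes = isTRUE(dx_diabetes),
    dx_cholesterol = isTRUE(dx_cholesterol),
    dx_cardiovascular = isTRUE(dx_cardiovascular)
  ), class = "personal_record")
}

#' Diet-section record
#'
#' @param answers Named character vector or list mapping food item id to a
#'   frequency level "L0".."L5" (never; <1/week; 1-2/week; 3-6/week; 1/day;
#'   >=2/day). A complete record answers all 51 canonical items.
#' @return Object of class \code{diet_record}.
#' @export
diet_record <- function(answers) {
  a <- vapply(answers, as.character, character(1))
  structure(list(answers = a), class = "diet_record")
}

#' Activity-section record (IPAQ short form fields)
#'
#' @param vigorous_days,moderate_days days/week with that activity, 0..7.
#' @param vigorous_minutes,moderate_minutes minutes per session, 0..960.
#' @param walk_days days/week with >= 10 continuous minutes walking, 0..7.
#' @param walk_minutes walking minutes per session, 0..960.
#' @param sitting_hours hours per week sitting, 0..168.
#' @return Object of class \code{activity_record}.
#' @export
activity_record <- function(vigorous_days = 0, vigorous_minutes = 0,
                            moderate_days = 0, moderate_minutes = 0,
                            walk_days = 0, walk_minutes = 0,
                            sitting_hours = 0) {
  structure(list(
    vigorous_days = as.numeric(vigorous_days),
    vigorous_minutes = as.numeric(vigorous_minutes),
    moderate_days = as.numeric(moderate_days),
    moderate_minutes = as.numeric(moderate_minutes),
    walk_days = as.numeric(walk_days),
    walk_minutes = as.numeric(walk_minutes),
    sitting_hours = as.numeric(sitting_hours)
  ), class = "activity_record")
}

#' Typed undirected relation between two participants
#'
#' Endpoints are stored in canonical (sorted) order so the same pair is never
#' duplicated in reversed form.
#'
#' @param user_a,user_b participant ids (must differ).
#' @param relation_type one of "home", "family", "friend", "work".
#' @return Object of class \code{relation}.
#' @export
relation <- function(user_a, user_b, relation_type) {
  user_a <- as.character(user_a); user_b <- as.character(user_b)
  if (user_a == user_b)
    stop("relation endpoints must differ: ", user_a, call. = FALSE)
  if (!relation_type %in% RELATION_TYPES)
    stop("unknown relation_type '", relation_type, "'", call. = FALSE)
  ends <- sort(c(user_a, user_b))
  structure(list(user_a = ends[1], user_b = ends[2],
                 relation_type = relation_type), class = "relation")
}

#' One participant's assessment
#'
#' Bundles the three questionnaire sections. \code{completed} is derived:
#' TRUE iff personal, diet and activity are all present and pass validation.
#'
#' @param user_id participant id.
#' @param personal \code{personal_record} or NULL.
#' @param diet \code{diet_record} or NULL.
#' @param activity \code{activity_record} or NULL.
#' @param language interface language, one of "es", "en", "ca".
#' @param items canonical diet item ids used for the completeness check.
#' @return Object of class \code{assessment}.
#' @export
assessment <- function(user_id, personal = NULL, diet = NULL, activity = NULL,
                       language = "es", items = canonical_food_items()$item_id) {
  a <- structure(list(user_id = as.character(user_id), personal = personal,
                      diet = diet, activity = activity,
                      language = as.character(language)),
                 class = "assessment")
  a$completed <- !is.null(personal) && !is.null(diet) && !is.null(activity) &&
    nrow(validate_assessment(a, items = items)) == 0L
  a
}

#' A cohort of assessments plus their relations
#'
#' @param assessments list of \code{assessment}, unique user ids.
#' @param relations list of \code{relation}; endpoints must exist among the
#'   assessments and (user_a, user_b, relation_type) triples must be unique.
#' @return Object of class \code{cohort}.
#' @export
cohort <- function(assessments = list(), relations = list()) {
  ids <- vapply(assessments, function(a) a$user_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate user ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(assessments) <- ids
  if (length(relations)) {
    key <- vapply(relations, function(r)
      paste(r$user_a, r$user_b, r$relation_type, sep = "\r"), character(1))
    if (anyDuplicated(key))
      stop("duplicate relation triples", call. = FALSE)
    ends <- unique(unlist(lapply(relations, function(r) c(r$user_a, r$user_b))))
    missing <- setdiff(ends, ids)
    if (length(missing))
      stop("relation endpoints not in cohort: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(assessments = assessments, relations = relations),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_comp <- sum(vapply(x$assessments, function(a) isTRUE(a$completed), logical(1)))
  cat("A cohort: ", length(x$assessments), " participants (",
      n_comp, " complete), ", length(x$relations), " relations\n", sep = "")
  invisible(x)
}

# ---- validation ------------------------------------------------------------

violation <- function(user_id, section, field, reason) {
  data.frame(user_id = user_id, section = section, field = field,
             reason = reason, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(user_id = character(), section = character(),
             field = character(), reason = character(),
             stringsAsFactors = FALSE)
}

check_range <- function(uid, section, field, value, lo, hi) {
  if (is.null(value) || length(value) != 1 || !is.finite(value) ||
      value < lo || value > hi)
    violation(uid, section, field,
              sprintf("must be in [%g, %g], got %s", lo, hi,
                      if (length(value) == 1) format(value) else "<missing>"))
  else no_violations()
}

validate_personal <- function(uid, p) {
  v <- rbind(
    check_range(uid, "personal", "weight", p$weight, 20, 400),
    check_range(uid, "personal", "height", p$height, 0.9, 2.5),
    check_range(uid, "personal", "age", p$age, 14, 110),
    check_range(uid, "personal", "sleep_hours", p$sleep_hours, 0, 24),
    check_range(uid, "personal", "household_size", p$household_size, 1, Inf),
    check_range(uid, "personal", "cigarettes", p$cigarettes, 0, Inf)
  )
  if (!p$gender %in% GENDERS)
    v <- rbind(v, violation(uid, "personal", "gender",
                            paste("must be one of", paste(GENDERS, collapse = "/"))))
  if (!p$main_activity %in% MAIN_ACTIVITIES)
    v <- rbind(v, violation(uid, "personal", "main_activity",
                            paste("must be one of", paste(MAIN_ACTIVITIES, collapse = "/"))))
  v
}

validate_diet <- function(uid, d, items) {
  v <- no_violations()
  ans <- d$answers
  bad_level <- ans[!ans %in% FREQ_LEVELS]
  if (length(bad_level))
    v <- rbind(v, violation(uid, "diet", names(bad_level)[1],
                            paste("invalid frequency level", bad_level[1])))
  missing <- setdiff(items, names(ans))
  if (length(missing))
    v <- rbind(v, violation(uid, "diet", "completeness",
                            paste(length(missing), "of", length(items),
                                  "items unanswered (e.g.", missing[1], ")")))
  extra <- setdiff(names(ans), items)
  if (length(extra))
    v <- rbind(v, violation(uid, "diet", extra[1], "unknown food item id"))
  v
}

validate_activity <- function(uid, a) {
  rbind(
    check_range(uid, "activity", "vigorous_days", a$vigorous_days, 0, 7),
    check_range(uid, "activity", "vigorous_minutes", a$vigorous_minutes, 0, 960),
    check_range(uid, "activity", "moderate_days", a$moderate_days, 0, 7),
    check_range(uid, "activity", "moderate_minutes", a$moderate_minutes, 0, 960),
    check_range(uid, "activity", "walk_days", a$walk_days, 0, 7),
    check_range(uid, "activity", "walk_minutes", a$walk_minutes, 0, 960),
    check_range(uid, "activity", "sitting_hours", a$sitting_hours, 0, 168)
  )
}

#' Validate an assessment
#'
#' Runs every present section through its field invariants.
#'
#' @param x \code{assessment}.
#' @param items canonical diet item ids for the completeness check.
#' @return Data frame of violations (columns user_id, section, field,
#'   reason); zero rows means the assessment is clean.
#' @export
validate_assessment <- function(x, items = canonical_food_items()$item_id) {
  v <- no_violations()
  if (!is.null(x$personal)) v <- rbind(v, validate_personal(x$user_id, x$personal))
  if (!is.null(x$diet))     v <- rbind(v, validate_diet(x$user_id, x$diet, items))
  if (!is.null(x$activity)) v <- rbind(v, validate_activity(x$user_id, x$activity))
  v
}

#' Validate a whole cohort
#'
#' @param x \code{cohort}.
#' @param items canonical diet item ids.
#' @return Data frame of violations across all assessments.
#' @export
validate_cohort <- function(x, items = canonical_food_items()$item_id) {
  do.call(rbind, c(list(no_violations()),
                   lapply(x$assessments, validate_assessment, items = items)))
}

#' Ids of participants that completed all three sections
#'
#' Mirrors the pilot's filtering rule: only participants with valid personal,
#' diet and activity sections enter scoring and reporting.
#'
#' @param x \code{cohort}.
#' @return Character vector of user ids.
#' @export
completed_ids <- function(x) {
  ids <- vapply(x$assessments, function(a) a$user_id, character(1))
  ids[vapply(x$assessments, function(a) isTRUE(a$completed), logical(1))]
}
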