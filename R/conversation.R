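# Transport-agnostic dialogue engine. Question wording lives in per-language
# JSON files under extdata/dialogues; question ids, answer types and
# validation bounds live here so they cannot diverge between translations.
# A transport is just a pair of functions (receive text, deliver prompt); the
# engine itself is a pure state machine over Session values.

SECTION_ORDER <- c("personal", "diet", "activity", "wakanet", "wakastatus",
                   "about")

personal_questions <- function() list(
  list(id = "weight", type = "numeric", min = 20, max = 400),
  list(id = "height", type = "numeric", min = 0.9, max = 2.5),
  list(id = "gender", type = "choice", choices = GENDERS),
  list(id = "age", type = "numeric", min = 14, max = 110),
  list(id = "education_level", type = "choice",
       choices = c("primary", "secondary", "university", "postgraduate")),
  list(id = "marital_status", type = "choice",
       choices = c("single", "partner", "married", "other")),
  list(id = "household_size", type = "numeric", min = 1, max = 30),
  list(id = "main_activity", type = "choice", choices = MAIN_ACTIVITIES),
  list(id = "zip_code", type = "text"),
  list(id = "sleep_hours", type = "numeric", min = 0, max = 24),
  list(id = "cigarettes", type = "numeric", min = 0, max = 200),
  list(id = "dx_hypertension", type = "boolean"),
  list(id = "dx_diabetes", type = "boolean"),
  list(id = "dx_cholesterol", type = "boolean"),
  list(id = "dx_cardiovascular", type = "boolean")
)

activity_questions <- function() list(
  list(id = "vigorous_days", type = "numeric", min = 0, max = 7),
  list(id = "vigorous_minutes", type = "numeric", min = 0, max = 960),
  list(id = "moderate_days", type = "numeric", min = 0, max = 7),
  list(id = "moderate_minutes", type = "numeric", min = 0, max = 960),
  list(id = "walk_days", type = "numeric", min = 0, max = 7),
  list(id = "walk_minutes", type = "numeric", min = 0, max = 960),
  list(id = "sitting_hours", type = "numeric", min = 0, max = 168)
)

#' Languages with a shipped dialogue file
#' @return Character vector of language codes.
#' @export
available_languages <- function() {
  sort(sub("\\.json$", "", list.files(wak_extdata("dialogues"),
                                      pattern = "\\.json$")))
}

#' Load a dialogue specification
#'
#' @param language language code with a shipped dialogue file ("es", "en",
#'   "ca"), or a path to a custom dialogue JSON.
#' @return Object of class \code{dialogue_spec}.
#' @export
dialogue_spec <- function(language) {
  path <- if (file.exists(language)) language
          else file.path(wak_extdata("dialogues"), paste0(language, ".json"))
  if (!file.exists(path))
    stop("unknown language '", language, "'; available: ",
         paste(available_languages(), collapse = ", "), call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  class(spec) <- "dialogue_spec"
  spec
}

# {emoji:key} and {var} substitution; errors on a missing translation key.
render_text <- function(spec, template, vars = list()) {
  if (is.null(template)) stop("missing translation key", call. = FALSE)
  out <- template
  for (key in names(spec$emoji))
    out <- gsub(paste0("{emoji:", key, "}"), spec$emoji[[key]], out,
                fixed = TRUE)
  for (v in names(vars))
    out <- gsub(paste0("{", v, "}"), as.character(vars[[v]]), out,
                fixed = TRUE)
  out
}

spec_get <- function(spec, ...) {
  keys <- c(...)
  node <- spec
  for (k in keys) {
    node <- node[[k]]
    if (is.null(node))
      stop("missing translation key '", paste(keys, collapse = "."),
           "' in language '", spec$language, "'", call. = FALSE)
  }
  node
}

#' Start (or restart) a dialogue session
#'
#' Returns the session at the main menu with the menu prompt. Passing an
#' existing session restarts it at the menu while preserving its completed
#' sections and answers.
#'
#' @param user_id participant id.
#' @param language language code available in the dialogue files.
#' @param spec \code{dialogue_spec}; defaults to the shipped file for
#'   \code{language}.
#' @param session optional existing session to restart.
#' @return List with elements \code{session} and \code{prompt}.
#' @export
start_session <- function(user_id, language = "es",
                          spec = dialogue_spec(language), session = NULL) {
  if (is.null(session)) {
    session <- structure(list(
      user_id = as.character(user_id), language = language, spec = spec,
      state = "menu", section = NULL, q_index = 0L,
      answers = list(personal = list(), diet = character(0),
                     activity = list()),
      completed_sections = character(0)
    ), class = "wak_session")
  } else {
    session$state <- "menu"
    session$section <- NULL
    session$q_index <- 0L
  }
  list(session = session, prompt = render_text(spec, spec_get(spec, "menu", "prompt")))
}

section_questions <- function(section) {
  switch(section,
         personal = personal_questions(),
         activity = activity_questions(),
         stop("no question schema for section ", section, call. = FALSE))
}

question_prompt <- function(session, section, q_index) {
  spec <- session$spec
  if (section == "diet") {
    item <- canonical_food_items()[q_index, ]
    render_text(spec, spec_get(spec, "sections", "diet", "item_prompt"),
                list(item = item$label))
  } else {
    q <- section_questions(section)[[q_index]]
    render_text(spec, spec_get(spec, "sections", section, "questions",
                               q$id, "prompt"))
  }
}

parse_numeric <- function(text) {
  suppressWarnings(as.numeric(gsub(",", ".", trimws(text), fixed = TRUE)))
}

YES_WORDS <- c("yes", "y", "si", "sí", "s", "true", "1")
NO_WORDS <- c("no", "n", "false", "0")

# Returns list(ok, value) or list(ok = FALSE, reprompt)
validate_answer <- function(session, q, text) {
  spec <- session$spec
  txt <- trimws(text)
  switch(q$type,
    numeric = {
      v <- parse_numeric(txt)
      if (is.na(v) || v < q$min || v > q$max)
        list(ok = FALSE,
             reprompt = render_text(spec, spec_get(spec, "strings", "invalid_number"),
                                    list(min = q$min, max = q$max)))
      else list(ok = TRUE, value = v)
    },
    choice = {
      low <- tolower(txt)
      hit <- if (low %in% tolower(q$choices)) q$choices[match(low, tolower(q$choices))]
             else if (grepl("^[0-9]+$", low) &&
                      as.integer(low) >= 1 &&
                      as.integer(low) <= length(q$choices)) q$choices[as.integer(low)]
      if (is.null(hit))
        list(ok = FALSE,
             reprompt = render_text(spec, spec_get(spec, "strings", "invalid_choice")))
      else list(ok = TRUE, value = hit)
    },
    boolean = {
      low <- tolower(txt)
      if (low %in% YES_WORDS) list(ok = TRUE, value = TRUE)
      else if (low %in% NO_WORDS) list(ok = TRUE, value = FALSE)
      else list(ok = FALSE,
                reprompt = render_text(spec, spec_get(spec, "strings", "invalid_boolean")))
    },
    text = list(ok = TRUE, value = txt)
  )
}

n_questions <- function(section) {
  if (section == "diet") nrow(canonical_food_items())
  else length(section_questions(section))
}

#' Advance a session with one user answer
#'
#' A pure transition: valid answers advance the question pointer and write
#' into the partial assessment; invalid answers leave the session unchanged
#' and return a re-prompt; finishing a section marks it complete and returns
#' to the menu. Invalid input is a dialogue event, never an error.
#'
#' @param session \code{wak_session}.
#' @param text the user's answer.
#' @return List with elements \code{session} and \code{prompt}.
#' @export
handle_answer <- function(session, text) {
  spec <- session$spec
  if (session$state == "menu") return(handle_menu(session, text))

  section <- session$section
  if (section == "diet") {
    item <- canonical_food_items()[session$q_index, ]
    low <- trimws(text)
    if (!grepl("^[1-6]$", low)) {
      return(list(session = session,
                  prompt = render_text(spec, spec_get(spec, "sections", "diet", "reprompt"))))
    }
    session$answers$diet[item$item_id] <- FREQ_LEVELS[as.integer(low)]
  } else {
    q <- section_questions(section)[[session$q_index]]
    res <- validate_answer(session, q, text)
    if (!res$ok) return(list(session = session, prompt = res$reprompt))
    session$answers[[section]][[q$id]] <- res$value
  }

  if (session$q_index < n_questions(section)) {
    session$q_index <- session$q_index + 1L
    return(list(session = session,
                prompt = question_prompt(session, section, session$q_index)))
  }
  # section finished
  session$completed_sections <- union(session$completed_sections, section)
  session$state <- "menu"
  session$section <- NULL
  session$q_index <- 0L
  msg <- render_text(spec, spec_get(spec, "strings", "section_complete"),
                     list(section = spec_get(spec, "sections", section, "title")))
  if (all(c("personal", "diet", "activity") %in% session$completed_sections))
    msg <- paste0(msg, "\n",
                  render_text(spec, spec_get(spec, "strings", "assessment_complete")))
  list(session = session,
       prompt = paste0(msg, "\n",
                       render_text(spec, spec_get(spec, "menu", "prompt"))))
}

handle_menu <- function(session, text) {
  spec <- session$spec
  menu_again <- function(msg = NULL) {
    p <- render_text(spec, spec_get(spec, "menu", "prompt"))
    list(session = session,
         prompt = if (is.null(msg)) p else paste0(msg, "\n", p))
  }
  sel <- trimws(text)
  if (!grepl("^[1-6]$", sel))
    return(menu_again(render_text(spec, spec_get(spec, "strings", "invalid_choice"))))
  section <- SECTION_ORDER[as.integer(sel)]
  if (section %in% c("personal", "diet", "activity")) {
    if (section %in% session$completed_sections)
      return(menu_again(render_text(spec, spec_get(spec, "strings", "already_complete"))))
    session$state <- "section"
    session$section <- section
    session$q_index <- 1L
    return(list(session = session,
                prompt = question_prompt(session, section, 1L)))
  }
  if (section == "wakanet") {
    inv <- generate_invites(session)
    intro <- render_text(spec, spec_get(spec, "sections", "wakanet", "intro"),
                         list(n_contacts = 0))
    return(menu_again(paste(c(intro, vapply(inv, `[[`, character(1), "message")),
                            collapse = "\n")))
  }
  if (section == "wakastatus") {
    if (!all(c("personal", "diet", "activity") %in% session$completed_sections))
      return(menu_again(render_text(spec, spec_get(spec, "strings", "not_ready"))))
    sc <- session_scorecard(session)
    return(menu_again(render_status(sc, session$language, spec)))
  }
  menu_again(render_text(spec, spec_get(spec, "sections", "about", "text")))
}

#' Assessment held by a session
#'
#' @param session \code{wak_session}.
#' @return \code{assessment} built from the session's answers (sections not
#'   yet completed are absent).
#' @export
session_assessment <- function(session) {
  done <- session$completed_sections
  personal <- if ("personal" %in% done)
    do.call(personal_record, session$answers$personal)
  diet <- if ("diet" %in% done) diet_record(session$answers$diet)
  activity <- if ("activity" %in% done)
    do.call(activity_record, session$answers$activity)
  assessment(session$user_id, personal = personal, diet = diet,
             activity = activity, language = session$language)
}

# Solo scorecard for in-dialogue feedback: the user's own sub-scores with no
# relations yet (social score 0).
session_scorecard <- function(session) {
  a <- session_assessment(session)
  compute_scorecards(cohort(list(a)))[1, ]
}

#' Create the four typed invitations for a user
#'
#' One invite per relation type (home, family, friend, work), each carrying
#' an opaque token encoding inviter id, relation type and issue time, and a
#' message in the session's language.
#'
#' @param session \code{wak_session} (or any list with user_id, language,
#'   spec).
#' @return List of four invites: token, relation_type, message.
#' @export
generate_invites <- function(session) {
  spec <- session$spec
  lapply(RELATION_TYPES, function(tp) {
    token <- encode_invite(session$user_id, tp)
    msg <- render_text(spec,
                       spec_get(spec, "sections", "wakanet", "invite_messages", tp),
                       list(token = token))
    list(token = token, relation_type = tp, message = msg)
  })
}

encode_invite <- function(user_id, relation_type, time = Sys.time()) {
  payload <- jsonlite::toJSON(list(inviter = user_id, type = relation_type,
                                   ts = as.numeric(time)), auto_unbox = TRUE)
  jsonlite::base64_enc(charToRaw(as.character(payload)))
}

#' Decode an invitation token
#' @param token opaque token from \code{\link{generate_invites}}.
#' @return List: inviter, type, ts.
#' @export
decode_invite <- function(token) {
  fields <- tryCatch(
    jsonlite::fromJSON(rawToChar(jsonlite::base64_dec(token))),
    error = function(e) NULL)
  if (is.null(fields) || is.null(fields$inviter) || is.null(fields$type) ||
      !fields$type %in% RELATION_TYPES)
    stop("malformed invitation token", call. = FALSE)
  fields
}

#' Redeem an invitation token
#'
#' Adds the typed relation (inviter, new user) to the cohort. Redeeming the
#' same token (or an equivalent one) twice is idempotent; self-redemption is
#' an error.
#'
#' @param token invitation token.
#' @param new_user_id redeeming participant (must exist in the cohort).
#' @param cohort \code{cohort}.
#' @return List: \code{cohort} (updated) and \code{relation}.
#' @export
redeem_invite <- function(token, new_user_id, cohort) {
  f <- decode_invite(token)
  if (identical(as.character(new_user_id), as.character(f$inviter)))
    stop("self-invitation: token was issued by ", new_user_id, call. = FALSE)
  rel <- relation(f$inviter, new_user_id, f$type)
  exists <- any(vapply(cohort$relations, function(r)
    identical(r$user_a, rel$user_a) && identical(r$user_b, rel$user_b) &&
      identical(r$relation_type, rel$relation_type), logical(1)))
  if (!exists)
    cohort <- wakamola::cohort(cohort$assessments,
                               c(cohort$relations, list(rel)))
  list(cohort = cohort, relation = rel)
}

#' Render the status feedback message
#'
#' Formats the five scores (one decimal), the BMI category and the
#' language's status template. User-facing wording speaks of "status",
#' never "risk".
#'
#' @param scorecard one scorecard row (from
#'   \code{\link{compute_scorecards}}).
#' @param language language code.
#' @param spec \code{dialogue_spec}.
#' @return Message text.
#' @export
render_status <- function(scorecard, language = "es",
                          spec = dialogue_spec(language)) {
  fmt <- function(x) sprintf("%.1f", round_half_up(x, 1))
  render_text(spec, spec_get(spec, "sections", "wakastatus", "status_message"),
              list(wakastatus = fmt(scorecard$wakastatus),
                   diet_score = fmt(scorecard$diet_score),
                   activity_score = fmt(scorecard$activity_score),
                   bmi_score = fmt(scorecard$bmi_score),
                   social_score = fmt(scorecard$social_score),
                   bmi_category = scorecard$bmi_category))
}

#' Check translation completeness across dialogue files
#'
#' Flattens each language's key paths and compares against a reference
#' language. Question ids are engine-defined so they are identical by
#' construction; this check catches missing texts.
#'
#' @param languages language codes to check.
#' @param reference reference language (default "es").
#' @return Named list: for each language, the key paths present in the
#'   reference but missing there (empty = complete).
#' @export
translation_check <- function(languages = available_languages(),
                              reference = "es") {
  paths <- function(node, prefix = character(0)) {
    if (!is.list(node)) return(paste(prefix, collapse = "."))
    unlist(lapply(names(node), function(k) paths(node[[k]], c(prefix, k))))
  }
  ref <- paths(unclass(dialogue_spec(reference)))
  out <- lapply(setdiff(languages, reference), function(lang)
    setdiff(ref, paths(unclass(dialogue_spec(lang)))))
  names(out) <- setdiff(languages, reference)
  out
}

#' Run a session against a transport
#'
#' A transport is a list with \code{receive()} (returns the next user input,
#' or NULL to stop) and \code{deliver(prompt)}. The engine is identical for
#' every transport; a console transport and a scripted transport produce the
#' same state trajectory for the same inputs.
#'
#' @param session started \code{wak_session}.
#' @param transport transport object (see
#'   \code{\link{scripted_transport}}, \code{\link{console_transport}}).
#' @param max_steps safety bound on dialogue length.
#' @return List: final \code{session} and \code{trajectory}, a data frame of
#'   (input, state, section, q_index) after each step.
#' @export
run_chat <- function(session, transport, max_steps = 10000) {
  steps <- list()
  for (i in seq_len(max_steps)) {
    input <- transport$receive()
    if (is.null(input)) break
    res <- handle_answer(session, input)
    session <- res$session
    transport$deliver(res$prompt)
    steps[[length(steps) + 1L]] <- data.frame(
      input = input, state = session$state,
      section = if (is.null(session$section)) NA_character_ else session$section,
      q_index = session$q_index, stringsAsFactors = FALSE)
  }
  list(session = session, trajectory = do.call(rbind, steps))
}

#' Scripted transport for tests and batch runs
#' @param answers character vector of user inputs, fed in order.
#' @return Transport object; delivered prompts accumulate in
#'   \code{$prompts()}.
#' @export
scripted_transport <- function(answers) {
  i <- 0L
  delivered <- character(0)
  list(
    receive = function() {
      i <<- i + 1L
      if (i > length(answers)) NULL else answers[[i]]
    },
    deliver = function(prompt) delivered[length(delivered) + 1L] <<- prompt,
    prompts = function() delivered
  )
}

#' Interactive console transport
#' @param con connection for input (default stdin).
#' @return Transport object reading lines and printing prompts.
#' @export
console_transport <- function(con = stdin()) {
  list(
    receive = function() {
      line <- readLines(con, n = 1)
      if (length(line) == 0 || identical(line, "/quit")) NULL else line
    },
    deliver = function(prompt) cat(prompt, "\n", sep = "")
  )
}
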