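SESSION_SCHEMA <- "vlt-session/1"

session_to_list <- function(session) {
  variants <- lapply(session$variants, function(v) {
    out <- list(rater = v$rater)
    if (!is.null(v$trials)) {
      out$trials <- lapply(unname(v$trials), function(tr) {
        list(trial_label = tr$trial_label,
             events = lapply(seq_len(nrow(tr$events)), function(i) {
               e <- list(token = tr$events$token[i])
               if (!is.na(tr$events$onset_s[i])) {
                 e$onset_s <- tr$events$onset_s[i]
               }
               e
             }))
      })
    }
    if (!is.null(v$recognition)) {
      out$recognition <- list(word = v$recognition$word,
                              is_target = v$recognition$is_target,
                              response = v$recognition$response)
    }
    if (!is.null(v$counts)) out$counts <- as.list(v$counts)
    out
  })
  list(participant_id = session$participant_id, list_id = session$list_id,
       variants = unname(variants))
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop("invalid session file: missing '", field, "' in ", where,
         call. = FALSE)
  }
  x[[field]]
}

session_from_list <- function(s, idx) {
  where <- paste0("session ", idx)
  pid <- need_field(s, "participant_id", where)
  lid <- need_field(s, "list_id", where)
  variants <- lapply(seq_along(s$variants), function(j) {
    v <- s$variants[[j]]
    vwhere <- paste0(where, " variant ", j)
    rater <- need_field(v, "rater", vwhere)
    trials <- NULL
    if (!is.null(v$trials)) {
      trials <- lapply(seq_along(v$trials), function(k) {
        tr <- v$trials[[k]]
        twhere <- paste0(vwhere, " trial ", k)
        lab <- need_field(tr, "trial_label", twhere)
        tokens <- vapply(tr$events, function(e)
          as.character(need_field(e, "token", twhere)), character(1))
        onsets <- vapply(tr$events, function(e)
          if (is.null(e$onset_s)) NA_real_ else as.numeric(e$onset_s),
          numeric(1))
        vlt_trial(lab, tokens, onsets)
      })
    }
    recognition <- NULL
    if (!is.null(v$recognition)) {
      r <- v$recognition
      recognition <- vlt_recognition(unlist(r$word),
                                     unlist(r$is_target),
                                     unlist(r$response))
    }
    counts <- if (is.null(v$counts)) NULL else unlist(v$counts)
    vlt_variant(rater, trials = trials, recognition = recognition,
                counts = counts)
  })
  vlt_session(pid, lid, variants)
}

#' Write sessions to a JSON file
#'
#' The file carries a schema tag (`vlt-session/1`), the word-list
#' reference, and per variant the trials as arrays of `{token, onset_s}`
#' plus the recognition sheet.  UTF-8 throughout.
#'
#' @param sessions List of [vlt_session] objects.
#' @param path Output path.
#' @export
write_sessions <- function(sessions, path) {
  payload <- list(schema = SESSION_SCHEMA,
                  sessions = lapply(sessions, session_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read sessions from a JSON file
#'
#' Validates the schema tag and required fields, with error messages naming
#' the offending session/variant/trial.
#'
#' @param path Path to a file written by [write_sessions()].
#' @return List of [vlt_session] objects.
#' @export
read_sessions <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  schema <- payload$schema
  if (is.null(schema) || schema != SESSION_SCHEMA) {
    stop("unsupported session file schema: ",
         if (is.null(schema)) "<missing>" else schema,
         " (expected ", SESSION_SCHEMA, ")")
  }
  lapply(seq_along(payload$sessions), function(i) {
    session_from_list(payload$sessions[[i]], i)
  })
}
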