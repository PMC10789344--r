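#' Normalize a recall token
#'
#' Lowercases, strips punctuation and whitespace, and folds diacritics
#' (so "café" and "cafe" compare equal).  Matching downstream is exact on
#' the normalized form; no fuzzy or phonetic matching is attempted, so any
#' clinical-vs-ASR divergence is a property of the transcripts, not of the
#' scorer.
#'
#' @param raw Non-empty character scalar.
#' @return Normalized word string.
#' @examples
#' normalize_token("Boot ")   # "boot"
#' normalize_token("ZON.")    # "zon"
#' @export
normalize_token <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) ||
      !nzchar(raw)) {
    stop("token must be a non-empty string")
  }
  x <- iconv(raw, from = "UTF-8", to = "ASCII//TRANSLIT")
  if (is.na(x)) x <- raw
  x <- tolower(x)
  x <- gsub("[^a-z]", "", x)
  if (!nzchar(x)) stop("token '", raw, "' is empty after normalization")
  x
}

normalize_tokens <- function(tokens) {
  vapply(tokens, normalize_token, character(1), USE.NAMES = FALSE)
}

#' Score one recall trial against the target list
#'
#' Classifies every recall event as exactly one of first-correct (first
#' occurrence of a target word), repetition (re-recall of an already-recalled
#' target within the trial), or intrusion (token not on the list).  The three
#' classes partition the events.
#'
#' @param trial A [vlt_trial].
#' @param word_list A [vlt_word_list].
#' @return A `vlt_scored_trial` list with `trial_label`, `correct_set`
#'   (list positions recalled at least once, in order of first recall),
#'   `correct_count`, `first_recall_order` (same positions, output order),
#'   `repetitions`, `intrusions`, `within_10s_count` (first-correct recalls
#'   with onset <= 10 s; `NA` when any first-correct onset is missing),
#'   and `event_class` (per-event labels).
#' @examples
#' wl <- vlt_word_lists()[[1]]
#' tr <- vlt_trial("T1", c(wl$targets[3], wl$targets[3], "xyz", wl$targets[1]))
#' score_trial(tr, wl)
#' @export
score_trial <- function(trial, word_list) {
  stopifnot(inherits(trial, "vlt_trial"), inherits(word_list, "vlt_word_list"))
  ev <- trial$events
  n <- nrow(ev)
  if (n == 0L) {
    return(structure(list(trial_label = trial$trial_label,
                          correct_set = integer(), correct_count = 0L,
                          first_recall_order = integer(),
                          repetitions = 0L, intrusions = 0L,
                          within_10s_count = 0L,
                          event_class = character()),
                     class = "vlt_scored_trial"))
  }
  tokens <- normalize_tokens(ev$token)
  pos <- match(tokens, word_list$targets)
  cls <- character(n)
  seen <- logical(15L)
  first_order <- integer(0)
  for (i in seq_len(n)) {
    p <- pos[i]
    if (is.na(p)) {
      cls[i] <- "intrusion"
    } else if (seen[p]) {
      cls[i] <- "repetition"
    } else {
      cls[i] <- "first_correct"
      seen[p] <- TRUE
      first_order <- c(first_order, p)
    }
  }
  fc <- cls == "first_correct"
  onsets <- ev$onset_s[fc]
  w10 <- if (anyNA(onsets)) NA_integer_ else sum(onsets <= 10)
  structure(list(trial_label = trial$trial_label,
                 correct_set = first_order,
                 correct_count = length(first_order),
                 first_recall_order = first_order,
                 repetitions = sum(cls == "repetition"),
                 intrusions = sum(cls == "intrusion"),
                 within_10s_count = w10,
                 event_class = cls),
            class = "vlt_scored_trial")
}

#' Score the recognition trial
#'
#' @param recognition A [vlt_recognition] sheet (30 probes, 15 targets + 15
#'   foils).
#' @return Named integer vector: `true_positives` ("yes" on targets) and
#'   `false_positives` ("yes" on foils), both in 0--15.
#' @export
score_recognition <- function(recognition) {
  if (!inherits(recognition, "vlt_recognition")) {
    recognition <- vlt_recognition(recognition$word, recognition$is_target,
                                   recognition$response)
  }
  c(true_positives = sum(recognition$response & recognition$is_target,
                         na.rm = TRUE),
    false_positives = sum(recognition$response & !recognition$is_target,
                          na.rm = TRUE))
}

#' Score all trials of one session variant
#'
#' @param session A [vlt_session].
#' @param rater `"clinical"` or `"asr"` -- which variant to score.
#' @param word_list The [vlt_word_list] the session used; defaults to the
#'   built-in list matching `session$list_id`.
#' @return A `vlt_scored_session` list: `participant_id`, `rater`, `trials`
#'   (named list of `vlt_scored_trial` by label, `NULL` for count-only
#'   variants), `counts` (per-trial correct counts, from transcripts or the
#'   count-only record), `recognition` (tp/fp or `NA`s).
#' @export
score_session <- function(session, rater = "asr", word_list = NULL) {
  stopifnot(inherits(session, "vlt_session"))
  variant <- session$variants[[rater]]
  if (is.null(variant)) {
    stop("session ", session$participant_id, " has no '", rater, "' variant")
  }
  if (is.null(word_list)) word_list <- vlt_word_lists()[[session$list_id]]
  if (is.null(word_list)) {
    stop("unknown word list '", session$list_id, "'; pass word_list=")
  }
  scored <- NULL
  counts <- stats::setNames(rep(NA_real_, 6L), TRIAL_LABELS)
  if (!is.null(variant$trials)) {
    scored <- lapply(variant$trials, score_trial, word_list = word_list)
    for (s in scored) counts[s$trial_label] <- s$correct_count
  } else {
    keep <- intersect(names(variant$counts), TRIAL_LABELS)
    counts[keep] <- variant$counts[keep]
  }
  rec <- c(true_positives = NA_integer_, false_positives = NA_integer_)
  if (!is.null(variant$recognition)) {
    rec <- score_recognition(variant$recognition)
  } else if (!is.null(variant$counts)) {
    if ("recognition_tp" %in% names(variant$counts)) {
      rec["true_positives"] <- variant$counts[["recognition_tp"]]
    }
    if ("recognition_fp" %in% names(variant$counts)) {
      rec["false_positives"] <- variant$counts[["recognition_fp"]]
    }
  }
  structure(list(participant_id = session$participant_id, rater = rater,
                 trials = scored, counts = counts, recognition = rec),
            class = "vlt_scored_session")
}
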