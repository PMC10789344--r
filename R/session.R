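TRIAL_LABELS <- c("T1", "T2", "T3", "T4", "T5", "DELAYED")
IMMEDIATE_LABELS <- c("T1", "T2", "T3", "T4", "T5")

#' Construct a trial transcript
#'
#' One recall trial as an ordered sequence of recall events: the token the
#' participant produced and, when available (speech-derived transcripts), its
#' onset in seconds from the start of the recall phase.  Clinician-entered
#' transcripts may omit onsets.
#'
#' @param trial_label One of `"T1"`..`"T5"` (immediate learning trials) or
#'   `"DELAYED"` (the unannounced delayed free recall).
#' @param tokens Character vector of recalled tokens, in output order.
#' @param onset_s Numeric vector of onsets in seconds (non-decreasing), or
#'   `NULL`/`NA` when timing is unavailable.
#' @return A `vlt_trial` object.
#' @export
vlt_trial <- function(trial_label, tokens = character(), onset_s = NULL) {
  trial_label <- match.arg(trial_label, TRIAL_LABELS)
  tokens <- as.character(tokens)
  if (is.null(onset_s)) onset_s <- rep(NA_real_, length(tokens))
  onset_s <- as.numeric(onset_s)
  if (length(onset_s) != length(tokens)) {
    stop("trial ", trial_label, ": onset_s length (", length(onset_s),
         ") must match tokens length (", length(tokens), ")")
  }
  ok <- !is.na(onset_s)
  if (any(onset_s[ok] < 0)) {
    stop("trial ", trial_label, ": onsets must be non-negative")
  }
  if (any(diff(onset_s[ok]) < 0)) {
    stop("trial ", trial_label, ": onsets must be non-decreasing")
  }
  structure(list(trial_label = trial_label,
                 events = data.frame(token = tokens, onset_s = onset_s,
                                     stringsAsFactors = FALSE)),
            class = "vlt_trial")
}

#' Construct a recognition response sheet
#'
#' The recognition trial presents 30 probes -- the 15 targets intermixed with
#' 15 foils -- and records a yes/no response per probe.
#'
#' @param word Character vector of 30 probe words.
#' @param is_target Logical vector: is the probe a list target?  Exactly 15
#'   `TRUE` and 15 `FALSE`.
#' @param response Logical vector: did the participant answer "yes"?
#' @return A `vlt_recognition` data frame.
#' @export
vlt_recognition <- function(word, is_target, response) {
  if (length(word) != 30L || length(is_target) != 30L ||
      length(response) != 30L) {
    stop("recognition sheet must have exactly 30 probes")
  }
  is_target <- as.logical(is_target)
  response <- as.logical(response)
  if (sum(is_target) != 15L) {
    stop("recognition sheet must have exactly 15 targets and 15 foils, got ",
         sum(is_target), " targets")
  }
  structure(data.frame(word = as.character(word), is_target = is_target,
                       response = response, stringsAsFactors = FALSE),
            class = c("vlt_recognition", "data.frame"))
}

#' Construct a session variant (one rater's record of a session)
#'
#' Each administration can carry up to two variants of the same session: the
#' `"clinical"` reference (a clinician's independent record) and the `"asr"`
#' variant (tokens recovered by automatic speech recognition).  Clinical
#' variants may be count-only -- a clinician recorded per-trial correct counts
#' but no transcript -- in which case only count-level features are
#' computable.
#'
#' @param rater `"clinical"` or `"asr"`.
#' @param trials List of [vlt_trial] objects (unique labels), or `NULL` for a
#'   count-only variant.
#' @param recognition A [vlt_recognition] sheet, or `NULL`.
#' @param counts For count-only variants: named numeric vector with elements
#'   among `T1`..`T5`, `DELAYED` (correct counts) and optionally
#'   `recognition_tp`, `recognition_fp`.
#' @return A `vlt_variant` object.
#' @export
vlt_variant <- function(rater, trials = NULL, recognition = NULL,
                        counts = NULL) {
  rater <- match.arg(rater, c("clinical", "asr"))
  if (is.null(trials) && is.null(counts)) {
    stop("variant must carry trials or counts")
  }
  if (!is.null(trials)) {
    labs <- vapply(trials, `[[`, character(1), "trial_label")
    if (anyDuplicated(labs)) {
      stop("duplicate trial label: ", labs[duplicated(labs)][1])
    }
    names(trials) <- labs
  }
  structure(list(rater = rater, trials = trials, recognition = recognition,
                 counts = counts),
            class = "vlt_variant")
}

#' Construct a session
#'
#' One participant's full test administration: five immediate learning
#' trials, the delayed recall, and the recognition trial, in one or two rater
#' variants sharing the same word list.
#'
#' @param participant_id Character identifier.
#' @param list_id Identifier of the [vlt_word_list] used.
#' @param variants List of [vlt_variant] objects (at least one; raters
#'   unique).
#' @return A `vlt_session` object.
#' @export
vlt_session <- function(participant_id, list_id, variants) {
  if (length(variants) < 1L) stop("session needs at least one variant")
  raters <- vapply(variants, `[[`, character(1), "rater")
  if (anyDuplicated(raters)) stop("duplicate rater variant: ",
                                  raters[duplicated(raters)][1])
  names(variants) <- raters
  structure(list(participant_id = as.character(participant_id),
                 list_id = as.character(list_id), variants = variants),
            class = "vlt_session")
}

#' @export
print.vlt_session <- function(x, ...) {
  cat("<vlt_session>", x$participant_id, " list:", x$list_id,
      " raters:", paste(names(x$variants), collapse = "+"), "\n")
  invisible(x)
}
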