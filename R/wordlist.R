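#' Construct a 15-item word list with recognition foils
#'
#' The 15-word Verbal Learning Test presents 15 unrelated monosyllabic nouns
#' over five learning trials; the recognition trial intermixes the 15 targets
#' with 15 foils.  List positions (1--15) follow the presentation order and
#' anchor all serial-position features.
#'
#' @param list_id Character identifier of the list version.
#' @param targets Character vector of exactly 15 target words in presentation
#'   order.  Must be unique after [normalize_token()].
#' @param foils Character vector of exactly 15 recognition foils, disjoint
#'   from the targets after normalization.
#' @return An object of class `vlt_word_list` with elements `list_id`,
#'   `targets`, `foils` (both stored normalized).
#' @examples
#' wl <- vlt_word_lists()[[1]]
#' wl$targets
#' @export
vlt_word_list <- function(list_id, targets, foils) {
  stopifnot(is.character(list_id), length(list_id) == 1L)
  targets <- vapply(targets, normalize_token, character(1), USE.NAMES = FALSE)
  foils <- vapply(foils, normalize_token, character(1), USE.NAMES = FALSE)
  if (length(targets) != 15L) {
    stop("word list '", list_id, "' must have exactly 15 targets, got ",
         length(targets))
  }
  if (anyDuplicated(targets)) {
    stop("word list '", list_id, "' has duplicate targets after normalization")
  }
  if (length(foils) != 15L) {
    stop("word list '", list_id, "' must have exactly 15 foils, got ",
         length(foils))
  }
  if (anyDuplicated(foils) || any(foils %in% targets)) {
    stop("word list '", list_id,
         "' foils must be unique and disjoint from targets")
  }
  structure(list(list_id = list_id, targets = targets, foils = foils),
            class = "vlt_word_list")
}

#' @export
print.vlt_word_list <- function(x, ...) {
  cat("<vlt_word_list>", x$list_id, "\n")
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  cat("  foils:  ", paste(x$foils, collapse = ", "), "\n")
  invisible(x)
}

#' Load word-list configurations from a JSON file
#'
#' Word lists are configuration data, not code.  The file holds an array of
#' objects `{list_id, targets[15], foils[15]}` (UTF-8).  The package ships
#' three synthetic parallel versions mirroring the three parallel list
#' versions of the Dutch 15-VLT; the clinical Dutch lists are proprietary and
#' are not reproduced.
#'
#' @param path Path to a JSON word-list file.  Default: the synthetic lists
#'   shipped with the package.
#' @return Named list of [vlt_word_list] objects, keyed by `list_id`.
#' @export
vlt_load_word_lists <- function(path = system.file("extdata",
                                                   "wordlists_synthetic.json",
                                                   package = "vltkit")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lists <- lapply(seq_len(nrow(raw)), function(i) {
    vlt_word_list(raw$list_id[i], raw$targets[[i]], raw$foils[[i]])
  })
  names(lists) <- vapply(lists, `[[`, character(1), "list_id")
  lists
}

#' Built-in synthetic word lists
#'
#' Three synthetic parallel versions of a 15-item monosyllabic-noun list with
#' matched recognition foils.  These stand in for the proprietary Dutch
#' 15-VLT lists and are intended for simulation and testing.
#'
#' @return Named list of three [vlt_word_list] objects.
#' @export
vlt_word_lists <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- vlt_load_word_lists()
    cache
  }
})
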