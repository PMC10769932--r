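# Domain model: phrase alphabet, singers, contributions, corpus container.

#' The analysis phrase alphabet
#'
#' Indri song contributions are encoded over six phrase types: the single
#' unit `SU` and descending phrases of two to six notes, `DP2` through
#' `DP6`. All statistics in the package operate on this closed alphabet;
#' other annotation labels (e.g. long notes, `LN`) are filtered out before
#' analysis.
#'
#' @return Character vector of the six admissible phrase-type labels.
#' @export
#' @examples
#' phrase_alphabet()
phrase_alphabet <- function() {
  c("SU", "DP2", "DP3", "DP4", "DP5", "DP6")
}

#' Singer categories
#'
#' Each singer belongs to one of three analysis categories: dominant female,
#' dominant male, or non-dominant (sex not considered for non-dominants).
#'
#' @return Character vector of category labels.
#' @export
singer_categories <- function() {
  c("dominant_female", "dominant_male", "non_dominant")
}

#' Parse a delimited phrase string into tokens
#'
#' Contributions are stored as delimited text such as `"SU|DP3|DP2|DP3"`.
#' This parses one such string into an ordered character vector of phrase
#' tokens.
#'
#' @param raw Single character string, non-empty after trimming.
#' @param delimiter Single-character field delimiter (default `"|"`).
#' @param on_unknown Policy for labels outside [phrase_alphabet()]:
#'   `"error"` (default) stops naming the label and its position;
#'   `"drop"` silently removes them.
#' @return Character vector of phrase tokens in original order. With
#'   `on_unknown = "drop"` the result may be empty (length 0).
#' @export
#' @examples
#' parse_contribution_string("SU|DP3|DP2|DP3")
parse_contribution_string <- function(raw, delimiter = "|",
                                      on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single character string")
  }
  raw <- trimws(raw)
  if (!nzchar(raw)) stop("empty contribution string")
  if (nchar(delimiter) != 1L) stop("`delimiter` must be a single character")
  tokens <- trimws(strsplit(raw, delimiter, fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty contribution string")
  bad <- which(!(tokens %in% phrase_alphabet()))
  if (length(bad) > 0L) {
    if (on_unknown == "error") {
      stop(sprintf("unknown phrase label '%s' at position %d",
                   tokens[bad[1L]], bad[1L]))
    }
    tokens <- tokens[-bad]
  }
  tokens
}

#' Restrict a token sequence to the analysis alphabet
#'
#' Removes any token outside the six-symbol alphabet (SU, DP2-DP6). An
#' all-filtered sequence is returned empty with attribute
#' `excluded = TRUE` so callers can flag the contribution for exclusion
#' rather than erroring.
#'
#' @param tokens Character vector of annotation labels.
#' @return Character vector of retained tokens (possibly empty, with
#'   attribute `excluded` set to `TRUE` when empty).
#' @export
filter_to_analysis_alphabet <- function(tokens) {
  kept <- tokens[tokens %in% phrase_alphabet()]
  if (length(kept) == 0L) attr(kept, "excluded") <- TRUE
  kept
}

#' Construct a song corpus
#'
#' A corpus bundles singer metadata with tokenized song contributions and
#' validates the structural invariants the downstream statistics rely on.
#'
#' @param singers Data frame with columns `singer_id`, `sex`
#'   (`"female"`, `"male"`, or `"unrecorded"`), `status` (`"dominant"` or
#'   `"non_dominant"`), `group_id`.
#' @param contributions Data frame with columns `song_id`, `singer_id`,
#'   `tokens` (a list column of character vectors, or a character column of
#'   pipe-delimited strings).
#' @param provenance Free-text provenance record (source path or a
#'   serialized synthetic configuration).
#' @return An object of class `indri_corpus`: a list with elements
#'   `singers`, `contributions` (tokens as a list column), `provenance`.
#' @details Invariants enforced: every `singer_id` in `contributions`
#'   resolves to a singer; `(song_id, singer_id)` pairs are unique; token
#'   sequences are non-empty and drawn from [phrase_alphabet()]; `sex` may
#'   be `"unrecorded"` only for non-dominants.
#' @export
indri_corpus <- function(singers, contributions, provenance = "") {
  stopifnot(is.data.frame(singers), is.data.frame(contributions))
  need_s <- c("singer_id", "sex", "status", "group_id")
  if (!all(need_s %in% names(singers))) {
    stop("`singers` must have columns: ", paste(need_s, collapse = ", "))
  }
  need_c <- c("song_id", "singer_id", "tokens")
  if (!all(need_c %in% names(contributions))) {
    stop("`contributions` must have columns: ", paste(need_c, collapse = ", "))
  }
  singers <- as.data.frame(singers, stringsAsFactors = FALSE)
  contributions <- as.data.frame(contributions, stringsAsFactors = FALSE)
  if (!is.list(contributions$tokens)) {
    contributions$tokens <- lapply(contributions$tokens,
                                   parse_contribution_string)
  }
  corpus <- structure(
    list(singers = singers, contributions = contributions,
         provenance = provenance),
    class = "indri_corpus"
  )
  validate_corpus(corpus)
  corpus
}

#' Validate corpus invariants
#'
#' @param corpus An [indri_corpus()] object.
#' @return The corpus, invisibly; stops on the first violated invariant.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "indri_corpus"))
  s <- corpus$singers
  ct <- corpus$contributions
  if (anyDuplicated(s$singer_id)) stop("duplicate singer_id in singers table")
  if (!all(s$sex %in% c("female", "male", "unrecorded"))) {
    stop("sex must be one of female, male, unrecorded")
  }
  if (!all(s$status %in% c("dominant", "non_dominant"))) {
    stop("status must be dominant or non_dominant")
  }
  if (any(s$sex == "unrecorded" & s$status == "dominant")) {
    stop("sex may be unrecorded only for non-dominant singers")
  }
  orphan <- setdiff(ct$singer_id, s$singer_id)
  if (length(orphan) > 0L) {
    stop("contribution singer_id not in singers table: ",
         paste(head(orphan, 3L), collapse = ", "))
  }
  key <- paste(ct$song_id, ct$singer_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (song_id, singer_id) pair in contributions")
  }
  lens <- lengths(ct$tokens)
  if (any(lens == 0L)) stop("empty token sequence in contributions")
  ok <- vapply(ct$tokens, function(x) all(x %in% phrase_alphabet()), logical(1))
  if (!all(ok)) stop("contribution contains tokens outside the phrase alphabet")
  invisible(corpus)
}

#' @export
print.indri_corpus <- function(x, ...) {
  cat(sprintf(
    "indri_corpus: %d singers, %d groups, %d songs, %d contributions\n",
    nrow(x$singers), length(unique(x$singers$group_id)),
    length(unique(x$contributions$song_id)), nrow(x$contributions)))
  tab <- table(singer_category(x$singers))
  cat("  contributions by singer category:\n")
  cats <- singer_category(x$singers)[match(x$contributions$singer_id,
                                           x$singers$singer_id)]
  print(table(cats))
  invisible(x)
}

#' Singer category from sex and status
#'
#' @param singers Singers data frame (columns `sex`, `status`).
#' @return Character vector over [singer_categories()].
#' @export
singer_category <- function(singers) {
  ifelse(singers$status == "non_dominant", "non_dominant",
         ifelse(singers$sex == "female", "dominant_female", "dominant_male"))
}

#' Read / write a corpus as delimited text
#'
#' The on-disk schema is one row per contribution with columns `song_id`,
#' `singer_id`, `sex`, `status`, `group_id`, `tokens` (pipe-delimited
#' phrase string). The round trip is lossless.
#'
#' @param path File path.
#' @return `read_corpus_csv` returns an [indri_corpus()];
#'   `write_corpus_csv` returns `path` invisibly.
#' @export
read_corpus_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("song_id", "singer_id", "sex", "status", "group_id", "tokens")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("corpus file missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  singers <- unique(df[, c("singer_id", "sex", "status", "group_id")])
  contributions <- data.frame(song_id = df$song_id, singer_id = df$singer_id,
                              stringsAsFactors = FALSE)
  contributions$tokens <- lapply(df$tokens, parse_contribution_string)
  indri_corpus(singers, contributions, provenance = path)
}

#' @param corpus An [indri_corpus()] object.
#' @rdname read_corpus_csv
#' @export
write_corpus_csv <- function(corpus, path) {
  validate_corpus(corpus)
  ct <- corpus$contributions
  meta <- corpus$singers[match(ct$singer_id, corpus$singers$singer_id), ]
  out <- data.frame(
    song_id = ct$song_id,
    singer_id = ct$singer_id,
    sex = meta$sex,
    status = meta$status,
    group_id = meta$group_id,
    tokens = vapply(ct$tokens, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a corpus as JSON
#'
#' Serializes singers, contributions (tokens as arrays) and provenance into
#' one JSON document.
#'
#' @inheritParams write_corpus_csv
#' @return `path`, invisibly.
#' @export
write_corpus_json <- function(corpus, path) {
  validate_corpus(corpus)
  obj <- list(
    provenance = corpus$provenance,
    singers = corpus$singers,
    contributions = data.frame(song_id = corpus$contributions$song_id,
                               singer_id = corpus$contributions$singer_id,
                               stringsAsFactors = FALSE)
  )
  obj$contributions$tokens <- corpus$contributions$tokens
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
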