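# Praat TextGrid ingest. Hand-rolled reader for the two text dialects
# (long/indented and short/bare); annotation tiers carry one singer each,
# interval labels are phrase-type tokens.

read_textgrid_lines <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  enc <- "UTF-8"
  if (length(bytes) >= 2L) {
    if (bytes[1L] == as.raw(0xFE) && bytes[2L] == as.raw(0xFF)) {
      enc <- "UTF-16BE"; bytes <- bytes[-(1:2)]
    } else if (bytes[1L] == as.raw(0xFF) && bytes[2L] == as.raw(0xFE)) {
      enc <- "UTF-16LE"; bytes <- bytes[-(1:2)]
    } else if (length(bytes) >= 3L && bytes[1L] == as.raw(0xEF) &&
               bytes[2L] == as.raw(0xBB) && bytes[3L] == as.raw(0xBF)) {
      bytes <- bytes[-(1:3)]
    }
  }
  txt <- iconv(list(bytes), from = enc, to = "UTF-8")
  if (is.na(txt)) stop("cannot decode TextGrid file: ", path)
  strsplit(txt, "\r\n|\r|\n")[[1L]]
}

tg_unquote <- function(x) gsub("\"\"", "\"", sub("^\"", "", sub("\"$", "", x)))

# Parse one TextGrid file into a list of tiers:
# list(name=, labels=chr (time-ordered, empty labels dropped))
parse_textgrid <- function(path) {
  lines <- read_textgrid_lines(path)
  if (length(lines) < 3L || !grepl("ooTextFile", lines[1L]) ||
      !grepl("TextGrid", lines[2L])) {
    stop("not a Praat TextGrid (bad header) in ", path)
  }
  body <- lines[-(1:2)]
  body <- body[!grepl("^\\s*$", body)]
  long <- any(grepl("item\\s*\\[", body)) || any(grepl("=", body))
  if (long) parse_textgrid_long(body, path) else parse_textgrid_short(body, path)
}

parse_textgrid_long <- function(body, path) {
  get_val <- function(line) trimws(sub("^[^=]*=", "", line))
  tiers <- list()
  i <- 1L
  n <- length(body)
  while (i <= n) {
    ln <- body[i]
    if (grepl("class\\s*=", ln)) {
      klass <- tg_unquote(get_val(ln))
      # next 'name =' line belongs to this tier
      j <- i + 1L
      while (j <= n && !grepl("name\\s*=", body[j])) j <- j + 1L
      if (j > n) stop("malformed TextGrid (tier without name) near line ",
                      i, " in ", path)
      tname <- tg_unquote(get_val(body[j]))
      if (klass == "IntervalTier") {
        k <- j + 1L
        while (k <= n && !grepl("intervals:\\s*size\\s*=", body[k])) k <- k + 1L
        if (k > n) stop("malformed TextGrid (no intervals size) in ", path)
        n_int <- as.integer(get_val(body[k]))
        xmins <- numeric(n_int); texts <- character(n_int)
        pos <- k
        for (ii in seq_len(n_int)) {
          while (pos <= n && !grepl("intervals\\s*\\[", body[pos])) pos <- pos + 1L
          xmin <- NA_real_; txt <- NA_character_
          pos <- pos + 1L
          while (pos <= n && !grepl("intervals\\s*\\[|item\\s*\\[", body[pos])) {
            if (grepl("^\\s*xmin\\s*=", body[pos])) {
              xmin <- as.numeric(get_val(body[pos]))
            } else if (grepl("^\\s*text\\s*=", body[pos])) {
              txt <- tg_unquote(get_val(body[pos]))
              break
            }
            pos <- pos + 1L
          }
          if (is.na(txt)) stop("malformed TextGrid interval (no text) near line ",
                               pos, " in ", path)
          xmins[ii] <- xmin; texts[ii] <- txt
        }
        ord <- order(xmins)
        labs <- trimws(texts[ord])
        tiers[[length(tiers) + 1L]] <- list(name = tname,
                                            labels = labs[nzchar(labs)])
        i <- pos
      } else {
        i <- j  # point tier or other: skip, no intervals
      }
    }
    i <- i + 1L
  }
  tiers
}

parse_textgrid_short <- function(body, path) {
  vals <- trimws(body)
  # file-level: xmin, xmax, <exists>, n_tiers
  if (length(vals) < 4L) stop("malformed short TextGrid: ", path)
  n_tiers <- suppressWarnings(as.integer(vals[4L]))
  if (is.na(n_tiers)) stop("malformed short TextGrid (tier count) in ", path)
  pos <- 5L
  tiers <- list()
  for (t in seq_len(n_tiers)) {
    klass <- tg_unquote(vals[pos]); tname <- tg_unquote(vals[pos + 1L])
    n_item <- suppressWarnings(as.integer(vals[pos + 4L]))
    if (is.na(n_item)) {
      stop("malformed short TextGrid (item count) near line ", pos + 4L,
           " in ", path)
    }
    pos <- pos + 5L
    if (klass == "IntervalTier") {
      labs <- character(n_item)
      for (ii in seq_len(n_item)) {
        labs[ii] <- tg_unquote(vals[pos + 2L])
        pos <- pos + 3L
      }
      labs <- trimws(labs)
      tiers[[length(tiers) + 1L]] <- list(name = tname,
                                          labels = labs[nzchar(labs)])
    } else {
      pos <- pos + 2L * n_item  # point tier: (time, mark) pairs; skipped
    }
  }
  tiers
}

#' Read a corpus from Praat TextGrid annotation files
#'
#' Each TextGrid file is one song; each mapped interval tier is one
#' singer's contribution, with interval labels read in time order as phrase
#' tokens. Empty-label intervals are skipped; labels outside the analysis
#' alphabet (e.g. `LN`) are filtered out, and a contribution left empty by
#' filtering is dropped with a warning.
#'
#' @param paths Character vector of TextGrid file paths (long or short text
#'   dialect; UTF-8 or UTF-16).
#' @param tier_map Named character vector mapping tier name to `singer_id`.
#'   `NULL` (default) uses tier names as singer ids. Tiers absent from a
#'   non-`NULL` map are skipped with a warning.
#' @param singers Optional singers data frame (`singer_id`, `sex`,
#'   `status`, `group_id`). If `NULL`, placeholder metadata is created
#'   (status `non_dominant`, sex `unrecorded`, one group per file set) so
#'   that sequence-level statistics can run before metadata is curated.
#' @param song_ids Optional character vector of song ids, one per path;
#'   defaults to file base names without extension.
#' @return An [indri_corpus()].
#' @export
read_textgrid_corpus <- function(paths, tier_map = NULL, singers = NULL,
                                 song_ids = NULL) {
  if (is.null(song_ids)) {
    song_ids <- sub("\\.[Tt]ext[Gg]rid$", "", basename(paths))
  }
  stopifnot(length(song_ids) == length(paths))
  rows <- list()
  for (i in seq_along(paths)) {
    tiers <- parse_textgrid(paths[i])
    for (tier in tiers) {
      if (!is.null(tier_map)) {
        if (!tier$name %in% names(tier_map)) {
          warning("tier '", tier$name, "' not in tier_map; skipped (",
                  basename(paths[i]), ")")
          next
        }
        sid <- unname(tier_map[[tier$name]])
      } else {
        sid <- tier$name
      }
      toks <- filter_to_analysis_alphabet(tier$labels)
      if (length(toks) == 0L) {
        warning("tier '", tier$name, "' in ", basename(paths[i]),
                " has no tokens in the analysis alphabet; dropped")
        next
      }
      rows[[length(rows) + 1L]] <- list(song_id = song_ids[i],
                                        singer_id = sid, tokens = toks)
    }
  }
  if (length(rows) == 0L) stop("no contributions found in TextGrid input")
  contributions <- data.frame(
    song_id = vapply(rows, `[[`, character(1), "song_id"),
    singer_id = vapply(rows, `[[`, character(1), "singer_id"),
    stringsAsFactors = FALSE
  )
  contributions$tokens <- lapply(rows, `[[`, "tokens")
  if (is.null(singers)) {
    ids <- unique(contributions$singer_id)
    singers <- data.frame(singer_id = ids, sex = "unrecorded",
                          status = "non_dominant", group_id = "unknown",
                          stringsAsFactors = FALSE)
  }
  indri_corpus(singers, contributions,
               provenance = paste("TextGrid:", paste(paths, collapse = ";")))
}
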