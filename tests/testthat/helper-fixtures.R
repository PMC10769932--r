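# Programmatic fixtures: small corpora and Praat TextGrid files written
# on the fly.

# Deterministic 2-group corpus covering all three singer categories, with
# several contributions per singer so within-distances exist.
tiny_corpus <- function() {
  singers <- data.frame(
    singer_id = c("F1", "M1", "N1", "F2", "M2", "N2"),
    sex = c("female", "male", "unrecorded", "female", "male", "unrecorded"),
    status = c("dominant", "dominant", "non_dominant",
               "dominant", "dominant", "non_dominant"),
    group_id = c("GA", "GA", "GA", "GB", "GB", "GB"),
    stringsAsFactors = FALSE
  )
  seqs <- list(
    c("SU", "DP3", "DP2", "DP3"), c("SU", "DP2", "DP2"),
    c("DP4", "DP5", "DP3"), c("SU", "SU", "DP2", "DP4"),
    c("DP2", "DP3", "DP3", "DP5", "DP4"), c("DP6", "DP5", "DP4"),
    c("SU", "DP3"), c("DP2", "DP2", "DP3"),
    c("DP3", "DP4", "DP2"), c("SU", "DP5", "DP6"),
    c("DP2", "SU", "DP2"), c("DP4", "DP4", "DP3", "SU")
  )
  contributions <- data.frame(
    song_id = rep(c("S1", "S2"), each = 6),
    singer_id = rep(c("F1", "M1", "N1", "F2", "M2", "N2"), 2),
    stringsAsFactors = FALSE
  )
  contributions$tokens <- seqs
  indri_corpus(singers, contributions, provenance = "tiny_corpus fixture")
}

# Long-dialect TextGrid with the given tiers (a named list of
# label character vectors); each interval is 1 s long.
write_long_textgrid <- function(path, tiers) {
  n_max <- max(lengths(tiers))
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    sprintf("xmax = %d", n_max),
    "tiers? <exists>",
    sprintf("size = %d", length(tiers)),
    "item []:"
  )
  for (t in seq_along(tiers)) {
    labs <- tiers[[t]]
    lines <- c(lines,
      sprintf("    item [%d]:", t),
      '        class = "IntervalTier"',
      sprintf('        name = "%s"', names(tiers)[t]),
      "        xmin = 0",
      sprintf("        xmax = %d", n_max),
      sprintf("        intervals: size = %d", length(labs)))
    for (i in seq_along(labs)) {
      lines <- c(lines,
        sprintf("        intervals [%d]:", i),
        sprintf("            xmin = %d", i - 1L),
        sprintf("            xmax = %d", i),
        sprintf('            text = "%s"', labs[i]))
    }
  }
  writeLines(lines, path)
  path
}

# Short-dialect TextGrid with the same content model.
write_short_textgrid <- function(path, tiers) {
  n_max <- max(lengths(tiers))
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "0", sprintf("%d", n_max), "<exists>", sprintf("%d", length(tiers))
  )
  for (t in seq_along(tiers)) {
    labs <- tiers[[t]]
    lines <- c(lines, '"IntervalTier"', sprintf('"%s"', names(tiers)[t]),
               "0", sprintf("%d", n_max), sprintf("%d", length(labs)))
    for (i in seq_along(labs)) {
      lines <- c(lines, sprintf("%d", i - 1L), sprintf("%d", i),
                 sprintf('"%s"', labs[i]))
    }
  }
  writeLines(lines, path)
  path
}
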