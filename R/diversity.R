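# Normalized diversity of contributions and duet covariation tests.

#' Normalized diversity of a token sequence
#'
#' The number of distinct phrase types in a contribution divided by its
#' length in tokens. For `DP2|DP3|DP3|DP5|DP4` the diversity is 4
#' distinct types over 5 tokens, i.e. 0.8. The statistic is order-free
#' (unlike the Jaro similarity) and, with only 6 phrase types, is capped
#' at `min(6, length)/length`.
#'
#' @param tokens Non-empty character vector of phrase tokens.
#' @return List with `richness` (distinct type count), `length` (token
#'   count), and `value = richness/length` in (0, 1].
#' @export
#' @examples
#' normalized_diversity(c("DP2", "DP3", "DP3", "DP5", "DP4"))$value  # 0.8
normalized_diversity <- function(tokens) {
  if (length(tokens) == 0L) stop("empty sequence")
  r <- length(unique(tokens))
  list(richness = r, length = length(tokens), value = r / length(tokens))
}

#' Per-contribution diversity table
#'
#' One row per contribution with its richness, length, normalized
#' diversity, and the log-transformed value used as the mixed-model
#' response.
#'
#' @param corpus An [indri_corpus()].
#' @param log_base Base of the logarithm for `log_nd` (default natural
#'   log; the choice only rescales the modeled response).
#' @return Data frame with columns `song_id`, `singer_id`, `category`,
#'   `group_id`, `richness`, `length`, `nd`, `log_nd`.
#' @export
diversity_table <- function(corpus, log_base = exp(1)) {
  validate_corpus(corpus)
  ct <- corpus$contributions
  meta <- corpus$singers[match(ct$singer_id, corpus$singers$singer_id), ]
  rich <- vapply(ct$tokens, function(x) length(unique(x)), integer(1))
  len <- lengths(ct$tokens)
  nd <- rich / len
  data.frame(
    song_id = ct$song_id,
    singer_id = ct$singer_id,
    category = singer_category(meta),
    group_id = meta$group_id,
    richness = rich,
    length = len,
    nd = nd,
    log_nd = log(nd, base = log_base),
    stringsAsFactors = FALSE
  )
}

#' Pair duetting dominants' diversities within a group
#'
#' For one group, pairs the per-song normalized diversity of the dominant
#' female and the dominant male over the songs where both contributed.
#'
#' @param div Diversity table from [diversity_table()].
#' @param corpus The source [indri_corpus()] (for singer metadata).
#' @param group_id Group to pair.
#' @return Data frame with columns `song_id`, `nd_female`, `nd_male`,
#'   ordered by `song_id`; zero rows if the pair shares no songs.
#' @export
pair_duet_diversities <- function(div, corpus, group_id) {
  s <- corpus$singers[corpus$singers$group_id == group_id, ]
  f <- s$singer_id[s$status == "dominant" & s$sex == "female"]
  m <- s$singer_id[s$status == "dominant" & s$sex == "male"]
  if (length(f) != 1L || length(m) != 1L) {
    stop("group '", group_id,
         "' must have exactly one dominant female and one dominant male")
  }
  df <- div[div$singer_id == f, c("song_id", "nd")]
  dm <- div[div$singer_id == m, c("song_id", "nd")]
  shared <- merge(df, dm, by = "song_id", suffixes = c("_female", "_male"))
  shared[order(shared$song_id), , drop = FALSE]
}

#' Duet diversity covariation per group
#'
#' Spearman rank correlation, within each group, between the normalized
#' diversities of the dominant female and dominant male across the songs
#' where both sang. Groups with fewer than `min_pairs` shared songs are
#' reported untested.
#'
#' @inheritParams pair_duet_diversities
#' @param min_pairs Minimum shared songs for running the test (default 3).
#' @return Data frame with one row per group: `group_id`,
#'   `n_paired_songs`, `rho`, `p_value`, `status`
#'   (`"tested"`/`"untested"`).
#' @export
group_covariation <- function(div, corpus, min_pairs = 3) {
  groups <- sort(unique(corpus$singers$group_id))
  out <- lapply(groups, function(g) {
    pairs <- pair_duet_diversities(div, corpus, g)
    n <- nrow(pairs)
    if (n < min_pairs) {
      return(data.frame(group_id = g, n_paired_songs = n, rho = NA_real_,
                        p_value = NA_real_, status = "untested",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      cor.test(pairs$nd_female, pairs$nd_male, method = "spearman",
               exact = FALSE))
    data.frame(group_id = g, n_paired_songs = n,
               rho = unname(ct$estimate), p_value = ct$p.value,
               status = "tested", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
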