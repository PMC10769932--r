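# Jaro similarity over phrase-token sequences, the full pairwise matrix,
# and the dyadic within/between dataset for the mixed model.

encode_tokens <- function(a, b = NULL, level = "token") {
  if (level == "character") {
    a <- strsplit(paste(a, collapse = "|"), "")[[1L]]
    if (!is.null(b)) b <- strsplit(paste(b, collapse = "|"), "")[[1L]]
  }
  lv <- unique(c(a, b))
  list(a = match(a, lv), b = if (is.null(b)) NULL else match(b, lv))
}

#' Jaro similarity between two token sequences
#'
#' Computes the Jaro string similarity treating each phrase type as one
#' symbol. The score is 1 for identical sequences and 0 when no symbols
#' match; following the source convention for these songs, higher values
#' mean more similar (less flexible) concatenation. For matched count `m`
#' and transposition half-count `t` over sequences of lengths `|a|`, `|b|`:
#' `sim = (m/|a| + m/|b| + (m - t)/m) / 3` (0 when `m = 0`), with the
#' matching window `max(floor(max(|a|,|b|)/2) - 1, 0)`.
#'
#' @param a,b Non-empty character vectors of tokens (or any atomic
#'   symbols).
#' @param level `"token"` (default) matches whole phrase labels;
#'   `"character"` reproduces character-level matching on the
#'   pipe-delimited text representation, for compatibility with generic
#'   string-distance tooling.
#' @param winkler_p Winkler common-prefix boost weight; `0` (default) gives
#'   plain Jaro.
#' @return An object of class `jaro_result`: list with `similarity` in
#'   \[0, 1\], `matches` (integer), `transpositions` (half-counts, may be
#'   `x.5`).
#' @export
#' @examples
#' jaro_similarity(c("SU", "DP3", "DP2", "DP3"), c("SU", "DP3", "DP2", "DP3"))
jaro_similarity <- function(a, b, level = c("token", "character"),
                            winkler_p = 0) {
  level <- match.arg(level)
  if (length(a) == 0L || length(b) == 0L) stop("empty sequence")
  enc <- encode_tokens(a, b, level)
  res <- jaro_int_cpp(enc$a, enc$b, winkler_p)
  structure(res, class = "jaro_result")
}

#' @export
print.jaro_result <- function(x, ...) {
  cat(sprintf("Jaro similarity = %.4f (m = %d, t = %.1f)\n",
              x$similarity, x$matches, x$transpositions))
  invisible(x)
}

#' Jaro distance (1 - similarity)
#'
#' @inheritParams jaro_similarity
#' @return Numeric distance in \[0, 1\]; 0 for identical sequences.
#' @export
jaro_distance <- function(a, b, level = c("token", "character"),
                          winkler_p = 0) {
  1 - jaro_similarity(a, b, match.arg(level), winkler_p)$similarity
}

#' Pairwise Jaro similarity matrix over a corpus
#'
#' Builds the square symmetric matrix of Jaro similarities between all
#' contributions (unit diagonal: 1 = complete match).
#'
#' @param x An [indri_corpus()] or a list of token vectors.
#' @inheritParams jaro_similarity
#' @return Numeric `n x n` matrix, `n` = number of contributions, with
#'   row/column names taken from contribution labels
#'   (`song_id.singer_id`) when `x` is a corpus.
#' @export
pairwise_jaro_matrix <- function(x, level = c("token", "character"),
                                 winkler_p = 0) {
  level <- match.arg(level)
  if (inherits(x, "indri_corpus")) {
    seqs <- x$contributions$tokens
    labs <- paste(x$contributions$song_id, x$contributions$singer_id,
                  sep = ".")
  } else {
    seqs <- x
    labs <- names(x)
  }
  if (length(seqs) < 2L) stop("need at least 2 contributions")
  if (any(lengths(seqs) == 0L)) stop("empty sequence in input")
  if (level == "character") {
    seqs <- lapply(seqs, function(s) strsplit(paste(s, collapse = "|"),
                                              "")[[1L]])
  }
  lv <- unique(unlist(seqs, use.names = FALSE))
  seqs_int <- lapply(seqs, match, table = lv)
  m <- jaro_matrix_cpp(seqs_int, winkler_p)
  dimnames(m) <- list(labs, labs)
  m
}

#' The nine dyad-category factor levels
#'
#' Within-individual levels by singer category (`WDF`, `WDM`, `WND`),
#' between-individual same-category levels (`BDF`, `BDM`, `BND`), and
#' between-individual cross-category levels (`B-DF-DM`, `B-DF-ND`,
#' `B-DM-ND`).
#'
#' @return Character vector of the 9 canonical levels.
#' @export
dyad_factor_levels <- function() {
  c("WDF", "WDM", "WND", "BDF", "BDM", "BND",
    "B-DF-DM", "B-DF-ND", "B-DM-ND")
}

category_code <- function(category) {
  c(dominant_female = "DF", dominant_male = "DM",
    non_dominant = "ND")[category]
}

#' Build the dyadic within/between distance dataset
#'
#' Expands the upper triangle of the pairwise similarity matrix into one
#' record per unordered contribution pair: the dyad of singers, the
#' distance type (`within` if both contributions come from the same
#' individual, `between` otherwise), the combined
#' distance-type/sex/status factor (9 levels when all categories are
#' present), the Jaro value and its square root (the mixed-model
#' response).
#'
#' @param matrix Square similarity matrix from [pairwise_jaro_matrix()].
#' @param corpus The [indri_corpus()] the matrix was computed from (same
#'   contribution order).
#' @return Data frame with `n(n-1)/2` rows and columns `dyad_id`,
#'   `singer_a`, `singer_b`, `distance_type`, `category_factor` (factor
#'   over [dyad_factor_levels()]), `jd`, `jd_sqrt`.
#' @export
build_dyad_dataset <- function(matrix, corpus) {
  validate_corpus(corpus)
  ct <- corpus$contributions
  n <- nrow(ct)
  if (nrow(matrix) != n || ncol(matrix) != n) {
    stop("matrix dimension does not match the number of contributions")
  }
  idx <- which(upper.tri(matrix), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  singer <- ct$singer_id
  cat_all <- singer_category(corpus$singers)[match(singer,
                                                   corpus$singers$singer_id)]
  if (anyNA(cat_all)) stop("singer metadata missing for some contributions")
  sa <- singer[i]; sb <- singer[j]
  ca <- category_code(cat_all[i]); cb <- category_code(cat_all[j])
  within <- sa == sb
  lo <- pmin(ca, cb); hi <- pmax(ca, cb)
  fac <- ifelse(within, paste0("W", ca),
                ifelse(lo == hi, paste0("B", lo),
                       paste("B", lo, hi, sep = "-")))
  fac <- factor(fac, levels = dyad_factor_levels())
  fac <- droplevels(fac)
  jd <- matrix[idx]
  data.frame(
    dyad_id = ifelse(within, sa, paste(pmin(sa, sb), pmax(sa, sb),
                                       sep = "__")),
    singer_a = sa, singer_b = sb,
    contrib_a = i, contrib_b = j,
    distance_type = ifelse(within, "within", "between"),
    category_factor = fac,
    jd = jd, jd_sqrt = sqrt(jd),
    stringsAsFactors = FALSE
  )
}

#' Thin a dyadic distance dataset
#'
#' The full dyadic expansion reuses every contribution in `n - 1` records,
#' so records are not independent. `"random"` thinning subsamples records
#' for speed; `"disjoint"` thinning greedily keeps records whose two
#' contributions have not been used by an earlier kept record, yielding
#' records with pairwise-disjoint contributions (at most `n/2` of them) —
#' useful when near-independence matters, e.g. for calibration studies.
#'
#' @param records Dyad dataset from [build_dyad_dataset()].
#' @param mode `"random"` or `"disjoint"`.
#' @param n For `"random"`: number of records to keep.
#' @param seed Integer seed for the record shuffle/sample.
#' @return A subset of `records`.
#' @export
thin_dyad_records <- function(records, mode = c("random", "disjoint"),
                              n = NULL, seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "random") {
      if (is.null(n)) stop("`n` is required for random thinning")
      records[sample(nrow(records), min(n, nrow(records))), , drop = FALSE]
    } else {
      ord <- sample(nrow(records))
      used <- logical(max(records$contrib_b))
      keep <- logical(nrow(records))
      for (r in ord) {
        a <- records$contrib_a[r]; b <- records$contrib_b[r]
        if (!used[a] && !used[b]) {
          used[a] <- used[b] <- TRUE
          keep[r] <- TRUE
        }
      }
      records[keep, , drop = FALSE]
    }
  })
}
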