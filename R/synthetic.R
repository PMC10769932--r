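# Synthetic corpora with the statistical structure the analyses assume:
# per-category first-order Markov phrase emission, group/singer layout
# mirroring a wild indri study population, and rank-coupled duet diversity.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw a random row-stochastic transition matrix
#'
#' Rows are drawn independently from a symmetric Dirichlet distribution.
#' The concentration parameter controls the entropy of the resulting
#' chain: small values give peaked (stereotyped, low-entropy) rows, large
#' values give near-uniform (flexible, high-entropy) rows.
#'
#' @param alphabet_size Number of states (>= 2); defaults to the 6-symbol
#'   phrase alphabet.
#' @param concentration Positive Dirichlet concentration.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return `alphabet_size x alphabet_size` row-stochastic matrix with
#'   dimnames from [phrase_alphabet()] when `alphabet_size == 6`.
#' @export
make_transition_matrix <- function(alphabet_size = 6, concentration, seed) {
  if (alphabet_size < 2) stop("alphabet_size must be >= 2")
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be a positive real")
  }
  P <- with_seed(seed, {
    g <- matrix(rgamma(alphabet_size^2, shape = concentration),
                nrow = alphabet_size)
    g / rowSums(g)
  })
  if (alphabet_size == 6) dimnames(P) <- list(phrase_alphabet(),
                                              phrase_alphabet())
  P
}

#' Configuration for a synthetic song corpus
#'
#' Describes a simulated study population: groups each holding one
#' dominant female, one dominant male, and a number of non-dominants;
#' per-category first-order Markov phrase emission; per-contribution
#' length distributions; and a duet-coupling parameter inducing
#' rank covariation between the two dominants' per-song diversity levels.
#'
#' @param n_groups Number of groups (default 10, the number of analyzed
#'   wild groups the generator emulates).
#' @param n_nondominants_per_group Integer (recycled) or vector of length
#'   `n_groups`; offspring/subordinates per group (default 2).
#' @param songs_per_group Songs per group (default 60).
#' @param concentrations Named numeric vector of Dirichlet concentrations
#'   per category used to draw each category's transition matrix.
#' @param transition_matrices Optional named list of explicit 6x6
#'   row-stochastic matrices per category, overriding `concentrations`
#'   (forces `matrix_level = "category"`).
#' @param matrix_level `"singer"` (default): every singer draws their own
#'   transition matrix from their category's Dirichlet concentration,
#'   giving each individual a vocal signature (the within- vs
#'   between-individual contrast the distance analysis measures).
#'   `"category"`: all singers of a category share one matrix, an
#'   exchangeable-corpus regime useful for null calibration.
#' @param length_model `"geometric"` (default) or `"negative_binomial"`;
#'   contribution lengths are `1 +` the chosen count distribution, so all
#'   lengths are >= 1.
#' @param length_mean Mean contribution length in tokens (default 12).
#' @param length_size Dispersion (`size`) for the negative binomial.
#' @param duet_coupling Correlation `rho` in \[-1, 1\] of the per-song
#'   latent diversity levels of the two dominants (default 0.6).
#' @param coupling_w_max Maximum repetition-mixing weight reached at the
#'   lowest latent diversity level (default 0.5); a song at that extreme
#'   mixes the singer's matrix halfway toward pure repetition of their
#'   anchor phrase. 0 disables the richness channel of the modulation.
#' @param coupling_length_sigma Log-scale effect of the latent diversity
#'   level on the singer's expected contribution length (default 0.4):
#'   low-diversity songs are longer, more repetitive; high-diversity
#'   songs are concise. 0 disables the length channel. Both channels off
#'   (together with `duet_coupling = 0`) give unmodulated dominants.
#' @param p_dominant_male_sing Probability the dominant male contributes
#'   to a song (female always sings; default 1).
#' @param p_nondominant_sing Per-non-dominant probability of joining a
#'   song as a chorus member (default 0.3).
#' @param seed Integer RNG seed.
#' @return A validated list of class `indri_synth_config`.
#' @export
synthetic_config <- function(n_groups = 10,
                             n_nondominants_per_group = 2,
                             songs_per_group = 60,
                             concentrations = c(dominant_female = 1.0,
                                                dominant_male = 0.8,
                                                non_dominant = 1.3),
                             transition_matrices = NULL,
                             matrix_level = c("singer", "category"),
                             length_model = c("geometric",
                                              "negative_binomial"),
                             length_mean = 12,
                             length_size = 5,
                             duet_coupling = 0.6,
                             coupling_w_max = 0.5,
                             coupling_length_sigma = 0.4,
                             p_dominant_male_sing = 1,
                             p_nondominant_sing = 0.3,
                             seed = 1L) {
  length_model <- match.arg(length_model)
  matrix_level <- match.arg(matrix_level)
  if (!is.null(transition_matrices)) matrix_level <- "category"
  stopifnot(n_groups >= 1, songs_per_group >= 1, length_mean >= 1,
            duet_coupling >= -1, duet_coupling <= 1,
            coupling_w_max >= 0, coupling_w_max < 1,
            coupling_length_sigma >= 0)
  n_nd <- rep_len(n_nondominants_per_group, n_groups)
  stopifnot(all(n_nd >= 0))
  if (is.null(transition_matrices)) {
    stopifnot(all(singer_categories() %in% names(concentrations)),
              all(concentrations > 0))
  } else {
    stopifnot(all(singer_categories() %in% names(transition_matrices)))
    for (P in transition_matrices[singer_categories()]) {
      stopifnot(is.matrix(P), nrow(P) == 6, ncol(P) == 6, all(P >= 0),
                all(abs(rowSums(P) - 1) < 1e-12))
    }
  }
  structure(list(
    n_groups = as.integer(n_groups),
    n_nondominants_per_group = as.integer(n_nd),
    songs_per_group = as.integer(songs_per_group),
    concentrations = concentrations,
    transition_matrices = transition_matrices,
    matrix_level = matrix_level,
    length_model = length_model,
    length_mean = length_mean,
    length_size = length_size,
    duet_coupling = duet_coupling,
    coupling_w_max = coupling_w_max,
    coupling_length_sigma = coupling_length_sigma,
    p_dominant_male_sing = p_dominant_male_sing,
    p_nondominant_sing = p_nondominant_sing,
    seed = as.integer(seed)
  ), class = "indri_synth_config")
}

sample_length <- function(config, mean_len = config$length_mean) {
  if (config$length_model == "geometric") {
    1L + rgeom(1L, prob = 1 / max(mean_len, 1))
  } else {
    1L + rnbinom(1L, size = config$length_size, mu = max(mean_len - 1, 0))
  }
}

#' Sample a token sequence from a first-order Markov chain
#'
#' @param P Row-stochastic transition matrix with state names as dimnames
#'   (or states taken from `1..k`).
#' @param n Sequence length (>= 1).
#' @param init Initial state distribution; `NULL` (default) uses the
#'   stationary distribution of `P`, avoiding transient bias.
#' @return Character vector of `n` state labels.
#' @export
sample_markov_sequence <- function(P, n, init = NULL) {
  stopifnot(n >= 1)
  k <- nrow(P)
  states <- rownames(P)
  if (is.null(states)) states <- as.character(seq_len(k))
  if (is.null(init)) init <- stationary_distribution(P)
  s <- integer(n)
  s[1L] <- sample.int(k, 1L, prob = init)
  if (n > 1L) {
    for (t in 2:n) s[t] <- sample.int(k, 1L, prob = P[s[t - 1L], ])
  }
  states[s]
}

# Per-song diversity modulation: mix the singer's matrix toward pure
# repetition of their anchor phrase (the modal state of their stationary
# distribution). w = 0 leaves P; w -> 1 collapses the song onto runs of
# the anchor, so richness -- and hence normalized diversity -- falls
# monotonically in w.
mix_toward_repetition <- function(P, w, anchor) {
  R <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  R[, anchor] <- 1
  (1 - w) * P + w * R
}

modal_state <- function(P) {
  which.max(stationary_distribution(P, on_reducible = "largest"))
}

#' Generate a synthetic song corpus
#'
#' Simulates a study population per the configuration: each group holds a
#' dominant female, a dominant male, and the configured non-dominants.
#' Every song contains the dominant female's contribution, the dominant
#' male's with probability `p_dominant_male_sing` (a duet), and each
#' non-dominant's with probability `p_nondominant_sing` (chorus). Each
#' contribution is a first-order Markov sample from the singer's
#' transition matrix at its sampled length. Positive `duet_coupling`
#' draws, per song, a correlated pair of latent diversity levels for the
#' two dominants; low levels pull a singer's emission toward repetition
#' of their anchor phrase, inducing rank covariation of the pair's
#' per-song diversity. Reproducible: identical configurations give
#' identical corpora.
#'
#' @param config A [synthetic_config()].
#' @return An [indri_corpus()]; `provenance` records the serialized
#'   configuration.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "indri_synth_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  cats <- singer_categories()
  draw_P <- function(conc) {
    g <- matrix(rgamma(36L, shape = conc), 6L, 6L)
    g <- g / rowSums(g)
    dimnames(g) <- list(phrase_alphabet(), phrase_alphabet())
    g
  }
  cat_P <- config$transition_matrices
  if (is.null(cat_P) && config$matrix_level == "category") {
    cat_P <- lapply(setNames(cats, cats),
                    function(cc) draw_P(config$concentrations[[cc]]))
  }
  singer_P <- function(category) {
    if (config$matrix_level == "category") cat_P[[category]]
    else draw_P(config$concentrations[[category]])
  }
  rho <- config$duet_coupling
  singers <- list(); rows <- list()
  for (g in seq_len(config$n_groups)) {
    gid <- sprintf("G%02d", g)
    df_id <- paste0(gid, "_DF"); dm_id <- paste0(gid, "_DM")
    nd_ids <- if (config$n_nondominants_per_group[g] > 0) {
      sprintf("%s_ND%d", gid, seq_len(config$n_nondominants_per_group[g]))
    } else character(0)
    singers[[g]] <- data.frame(
      singer_id = c(df_id, dm_id, nd_ids),
      sex = c("female", "male", rep("unrecorded", length(nd_ids))),
      status = c("dominant", "dominant",
                 rep("non_dominant", length(nd_ids))),
      group_id = gid, stringsAsFactors = FALSE
    )
    P <- c(setNames(list(singer_P("dominant_female"),
                         singer_P("dominant_male")), c(df_id, dm_id)),
           setNames(lapply(nd_ids, function(x) singer_P("non_dominant")),
                    nd_ids))
    for (s in seq_len(config$songs_per_group)) {
      song <- sprintf("%s_S%03d", gid, s)
      # rank-coupled latent diversity levels for the dominant pair:
      # high latent level -> the singer's own matrix; low level -> the
      # song collapses toward repetition of the singer's anchor phrase
      zf <- rnorm(1L)
      zm <- rho * zf + sqrt(1 - rho^2) * rnorm(1L)
      emit <- function(sid, Psing, z) {
        # high latent level: the singer's own matrix, concise contribution;
        # low level: pulled toward long runs of the anchor phrase
        if (is.na(z)) {
          Peff <- Psing
          len <- sample_length(config)
        } else {
          w <- config$coupling_w_max * (1 - stats::pnorm(z))
          Peff <- if (w > 0) {
            mix_toward_repetition(Psing, w, modal_state(Psing))
          } else Psing
          len <- sample_length(config,
                               config$length_mean *
                                 exp(-config$coupling_length_sigma * z))
        }
        toks <- sample_markov_sequence(Peff, len)
        list(song_id = song, singer_id = sid, tokens = toks)
      }
      rows[[length(rows) + 1L]] <- emit(df_id, P[[df_id]], zf)
      if (runif(1L) <= config$p_dominant_male_sing) {
        rows[[length(rows) + 1L]] <- emit(dm_id, P[[dm_id]], zm)
      }
      for (nd in nd_ids) {
        if (runif(1L) <= config$p_nondominant_sing) {
          rows[[length(rows) + 1L]] <- emit(nd, P[[nd]], NA_real_)
        }
      }
    }
  }
  contributions <- data.frame(
    song_id = vapply(rows, `[[`, character(1), "song_id"),
    singer_id = vapply(rows, `[[`, character(1), "singer_id"),
    stringsAsFactors = FALSE
  )
  contributions$tokens <- lapply(rows, `[[`, "tokens")
  prov <- jsonlite::toJSON(
    c(config[setdiff(names(config), "transition_matrices")],
      list(explicit_matrices = !is.null(config$transition_matrices))),
    auto_unbox = TRUE, digits = NA)
  indri_corpus(do.call(rbind, singers), contributions,
               provenance = as.character(prov))
}
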