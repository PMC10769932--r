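# First-order Markov model of phrase concatenation: empirical transition
# matrices, stationary distributions, and entropy rates (analytic and
# simulation-based).

#' Empirical first-order transition matrix
#'
#' Counts transitions between consecutive tokens, pooled across the given
#' sequences; transitions never cross sequence (contribution) boundaries.
#' Probabilities are row-normalized counts, optionally with add-alpha
#' smoothing.
#'
#' @param sequences A list of token vectors (or one token vector).
#' @param states `"observed"` (default) restricts the state set to tokens
#'   actually seen; `"full"` uses the whole 6-symbol phrase alphabet.
#' @param alpha Add-alpha smoothing constant applied to every cell before
#'   normalization (default 0 = off). Positive alpha makes the chain
#'   irreducible.
#' @param singer_id Optional label used in error messages.
#' @return Object of class `transition_matrix`: list with `states`,
#'   `counts` (integer matrix), `probs` (row-stochastic matrix; rows with
#'   no observed outgoing transition are zero when `alpha = 0`), and
#'   `n_transitions`.
#' @export
estimate_transition_matrix <- function(sequences,
                                       states = c("observed", "full"),
                                       alpha = 0, singer_id = NULL) {
  states <- match.arg(states)
  if (!is.list(sequences)) sequences <- list(sequences)
  toks <- unlist(sequences, use.names = FALSE)
  st <- if (states == "full") phrase_alphabet() else {
    phrase_alphabet()[phrase_alphabet() %in% toks]
  }
  if (length(st) == 0L) st <- sort(unique(toks))
  k <- length(st)
  counts <- matrix(0L, k, k, dimnames = list(st, st))
  for (s in sequences) {
    if (length(s) < 2L) next
    i <- match(s[-length(s)], st)
    j <- match(s[-1L], st)
    for (q in seq_along(i)) counts[i[q], j[q]] <- counts[i[q], j[q]] + 1L
  }
  n_trans <- sum(counts)
  if (n_trans == 0L) {
    stop("no observed transitions",
         if (!is.null(singer_id)) paste0(" for singer '", singer_id, "'"),
         " (all sequences have length 1)")
  }
  num <- counts + alpha
  rs <- rowSums(num)
  probs <- num
  nz <- rs > 0
  probs[nz, ] <- probs[nz, , drop = FALSE] / rs[nz]
  structure(list(states = st, counts = counts, probs = probs,
                 n_transitions = n_trans),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d states, %d transitions\n",
              length(x$states), x$n_transitions))
  print(round(x$probs, 3))
  invisible(x)
}

as_prob_matrix <- function(tm) {
  if (inherits(tm, "transition_matrix")) tm$probs else as.matrix(tm)
}

# Recurrent communicating classes of a stochastic matrix: strongly
# connected components of the P > 0 digraph with no edges leaving them.
recurrent_classes <- function(P) {
  g <- igraph::graph_from_adjacency_matrix((P > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  ncl <- max(comp)
  recurrent <- logical(ncl)
  for (cl in seq_len(ncl)) {
    idx <- which(comp == cl)
    out_mass <- sum(P[idx, -idx, drop = FALSE])
    recurrent[cl] <- out_mass == 0
  }
  lapply(which(recurrent), function(cl) which(comp == cl))
}

#' Stationary distribution of a Markov chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1`, as the dominant left eigenvector,
#' with a power-iteration fallback (tolerance 1e-12, at most 1e5
#' iterations). For chains with transient states but a single recurrent
#' communicating class, the distribution is computed on that class and
#' zero-padded. Reducible chains with several recurrent classes have no
#' unique stationary distribution: by default a diagnostic naming the
#' classes is raised; `on_reducible = "largest"` instead restricts to the
#' largest recurrent class (by observed transition mass when counts are
#' available, else by size), the usual pragmatic handling for sparse
#' empirical chains.
#'
#' @param tm A `transition_matrix` or a row-stochastic numeric matrix.
#' @param on_reducible `"error"` (default) or `"largest"`.
#' @return Named probability vector over the chain's states.
#' @export
stationary_distribution <- function(tm,
                                    on_reducible = c("error", "largest")) {
  on_reducible <- match.arg(on_reducible)
  P <- as_prob_matrix(tm)
  k <- nrow(P)
  if (k == 1L) return(setNames(1, rownames(P)))
  rc <- recurrent_classes(P)
  if (length(rc) == 0L) stop("chain has no recurrent class (rows with no ",
                             "outgoing transitions?)")
  if (length(rc) > 1L && on_reducible == "largest") {
    mass <- if (inherits(tm, "transition_matrix")) {
      vapply(rc, function(idx) sum(tm$counts[idx, idx, drop = FALSE]),
             numeric(1))
    } else lengths(rc)
    rc <- rc[which.max(mass)]
  }
  if (length(rc) > 1L) {
    labs <- vapply(rc, function(idx) {
      paste(if (is.null(rownames(P))) idx else rownames(P)[idx],
            collapse = ",")
    }, character(1))
    stop("reducible chain with ", length(rc), " recurrent classes {",
         paste(labs, collapse = "} {"),
         "}: no unique stationary distribution")
  }
  idx <- rc[[1L]]
  Q <- P[idx, idx, drop = FALSE]
  pi_sub <- tryCatch({
    e <- eigen(t(Q))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    v <- v / sum(v)
    if (any(v < -1e-9)) stop("negative component")
    pmax(v, 0) / sum(pmax(v, 0))
  }, error = function(e) {
    v <- rep(1 / length(idx), length(idx))
    for (it in seq_len(1e5)) {
      v2 <- as.vector(v %*% Q)
      if (max(abs(v2 - v)) < 1e-12) return(v2 / sum(v2))
      v <- v2
    }
    v / sum(v)
  })
  out <- numeric(k)
  out[idx] <- pi_sub
  names(out) <- rownames(P)
  out
}

#' Entropy rate of a first-order Markov chain
#'
#' The stationary-weighted average conditional entropy of the next symbol
#' given the current one:
#' `H = -sum_i pi_i sum_j P_ij log(P_ij)` with `0 log 0 = 0`. Higher
#' values mean a less predictable, more flexible sequence; `H` is bounded
#' by `log(k)` for a `k`-state chain, attained by iid-uniform emission.
#'
#' @inheritParams stationary_distribution
#' @param pi Stationary distribution; computed from `tm` when `NULL`.
#' @param log_base Logarithm base: `exp(1)` (default) gives nats, `2`
#'   gives bits.
#' @return Non-negative entropy rate.
#' @export
entropy_rate <- function(tm, pi = NULL, log_base = exp(1)) {
  P <- as_prob_matrix(tm)
  if (is.null(pi)) pi <- stationary_distribution(tm)
  if (length(pi) != nrow(P)) stop("dimension mismatch between pi and P")
  lp <- ifelse(P > 0, log(P), 0)
  row_H <- -rowSums(P * lp)
  sum(pi * row_H) / log(log_base)
}

#' Simulation-based entropy rate
#'
#' Mirrors the simulation procedure for entropy estimation: simulate long
#' realizations of the chain, re-estimate the transition matrix from each,
#' and average the plug-in entropy rates. Converges to the analytic rate
#' as `chain_length` grows.
#'
#' @inheritParams entropy_rate
#' @param chain_length Length of each simulated realization.
#' @param n_reps Number of replicate chains.
#' @param seed Integer seed (reproducible).
#' @return List with `entropy_rate` (mean over replicates), `se`
#'   (Monte-Carlo standard error; `NA` when `n_reps = 1`), `n_reps`,
#'   `chain_length`, `method = "simulated"`.
#' @export
simulate_entropy_rate <- function(tm, chain_length = 1e5, n_reps = 10,
                                  seed = 1L, log_base = exp(1)) {
  P <- as_prob_matrix(tm)
  if (is.null(rownames(P))) {
    dimnames(P) <- list(as.character(seq_len(nrow(P))),
                        as.character(seq_len(nrow(P))))
  }
  pi0 <- stationary_distribution(tm, on_reducible = "largest")
  hs <- with_seed(seed, vapply(seq_len(n_reps), function(r) {
    s <- sample_markov_sequence(P, chain_length, init = pi0)
    tm_hat <- estimate_transition_matrix(list(s))
    entropy_rate(tm_hat, log_base = log_base)
  }, numeric(1)))
  list(entropy_rate = mean(hs),
       se = if (n_reps > 1) stats::sd(hs) / sqrt(n_reps) else NA_real_,
       n_reps = n_reps, chain_length = chain_length, method = "simulated")
}

#' Per-singer entropy rates over a corpus
#'
#' Pools each singer's contributions into one empirical transition matrix
#' (transitions never span contribution boundaries) and computes the
#' entropy rate, analytically by default or via [simulate_entropy_rate()].
#' Singers whose pooled contributions contain no transition (only
#' length-1 contributions) are dropped with a warning.
#'
#' @param corpus An [indri_corpus()].
#' @param method `"analytic"` (default) or `"simulated"`.
#' @param states,alpha Passed to [estimate_transition_matrix()].
#' @param log_base Logarithm base (default nats).
#' @param chain_length,n_reps,seed Simulation settings for
#'   `method = "simulated"`.
#' @return Data frame with one row per singer: `singer_id`, `category`,
#'   `group_id`, `entropy_rate`, `n_transitions`, `n_states`, `method`.
#' @export
entropy_table <- function(corpus, method = c("analytic", "simulated"),
                          states = "observed", alpha = 0,
                          log_base = exp(1), chain_length = 1e5,
                          n_reps = 10, seed = 1L) {
  method <- match.arg(method)
  validate_corpus(corpus)
  rows <- list()
  for (i in seq_len(nrow(corpus$singers))) {
    sid <- corpus$singers$singer_id[i]
    seqs <- corpus$contributions$tokens[corpus$contributions$singer_id == sid]
    if (length(seqs) == 0L) next
    tm <- tryCatch(
      estimate_transition_matrix(seqs, states = states, alpha = alpha,
                                 singer_id = sid),
      error = function(e) {
        warning(conditionMessage(e), "; singer dropped from entropy table")
        NULL
      })
    if (is.null(tm)) next
    pi_hat <- stationary_distribution(tm, on_reducible = "largest")
    h <- if (method == "analytic") {
      entropy_rate(tm, pi = pi_hat, log_base = log_base)
    } else {
      simulate_entropy_rate(tm, chain_length = chain_length,
                            n_reps = n_reps, seed = seed,
                            log_base = log_base)$entropy_rate
    }
    rows[[length(rows) + 1L]] <- data.frame(
      singer_id = sid,
      category = singer_category(corpus$singers[i, ]),
      group_id = corpus$singers$group_id[i],
      entropy_rate = h,
      n_transitions = tm$n_transitions,
      n_states = length(tm$states),
      method = method,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
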