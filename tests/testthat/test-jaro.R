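test_that("jaro_similarity matches hand-computed values", {
  s <- c("SU", "DP3", "DP2", "DP3")
  expect_equal(jaro_similarity(s, s)$similarity, 1.0)
  expect_equal(jaro_similarity("SU", "DP2")$similarity, 0.0)
  r <- jaro_similarity(c("DP2", "DP3", "DP4", "DP5", "DP6", "SU"),
                       c("DP2", "DP3", "DP4", "DP6", "DP5", "SU"))
  expect_equal(r$matches, 6L)
  expect_equal(r$transpositions, 1)
  expect_equal(r$similarity, 17 / 18)
  expect_error(jaro_similarity(character(0), "SU"), "empty")
})

test_that("jaro_similarity satisfies symmetry, range and the Jaro formula", {
  set.seed(71)
  for (i in 1:150) {
    a <- random_sequence(); b <- random_sequence()
    r_ab <- jaro_similarity(a, b)
    r_ba <- jaro_similarity(b, a)
    expect_equal(r_ab$similarity, r_ba$similarity)
    expect_gte(r_ab$similarity, 0)
    expect_lte(r_ab$similarity, 1)
    expect_lte(r_ab$transpositions, r_ab$matches)
    if (r_ab$matches > 0) {
      m <- r_ab$matches; t <- r_ab$transpositions
      expect_equal(r_ab$similarity,
                   (m / length(a) + m / length(b) + (m - t) / m) / 3)
    } else {
      expect_equal(r_ab$similarity, 0)
    }
    if (identical(a, b)) expect_equal(r_ab$similarity, 1)
  }
})

test_that("single-token substitution in otherwise identical strings is < 1", {
  set.seed(72)
  for (i in 1:25) {
    a <- random_sequence(10)
    b <- a
    pos <- sample(length(a), 1)
    b[pos] <- setdiff(phrase_alphabet(), a[pos])[1]
    expect_lt(jaro_similarity(a, b)$similarity, 1)
  }
})

test_that("Winkler prefix boost is optional and monotone", {
  a <- c("SU", "DP2", "DP3", "DP4", "DP6")
  b <- c("SU", "DP2", "DP3", "DP5", "DP4")
  plain <- jaro_similarity(a, b)$similarity
  boost <- jaro_similarity(a, b, winkler_p = 0.1)$similarity
  expect_gt(boost, plain)
  # no shared prefix: boost is inert
  expect_equal(jaro_similarity(rev(a), b, winkler_p = 0.1)$similarity,
               jaro_similarity(rev(a), b)$similarity)
})

test_that("character-level mode reproduces character matching", {
  a <- c("DP3", "DP5")
  b <- c("DP5", "DP3")
  tok <- jaro_similarity("DP3", "DP5")
  expect_equal(tok$similarity, 0)  # distinct tokens share nothing
  chr <- jaro_similarity("DP3", "DP5", level = "character")
  expect_gt(chr$similarity, 0)     # "DP" prefix overweighted at char level
  oracle <- jaro_oracle(strsplit("DP3|DP5", "")[[1]],
                        strsplit("DP5|DP3", "")[[1]])
  expect_equal(jaro_similarity(a, b, level = "character")$similarity,
               oracle$similarity)
})

test_that("pairwise matrix is square, symmetric, unit-diagonal, consistent", {
  co <- tiny_corpus()
  m <- pairwise_jaro_matrix(co)
  n <- nrow(co$contributions)
  expect_equal(dim(m), c(n, n))
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(1, n))
  for (idx in list(c(1, 2), c(3, 9), c(5, 12))) {
    expect_equal(m[idx[1], idx[2]],
                 jaro_similarity(co$contributions$tokens[[idx[1]]],
                                 co$contributions$tokens[[idx[2]]])$similarity)
  }
  expect_error(pairwise_jaro_matrix(list(c("SU"))), "at least 2")
})

test_that("dyad dataset enumerates unordered pairs with the 9-level factor", {
  co <- tiny_corpus()
  m <- pairwise_jaro_matrix(co)
  dd <- build_dyad_dataset(m, co)
  n <- nrow(co$contributions)
  expect_equal(nrow(dd), n * (n - 1) / 2)
  expect_setequal(levels(dd$category_factor), dyad_factor_levels())
  expect_equal(nlevels(dd$category_factor), 9)

  # within <=> same singer <=> W* factor level
  within <- dd$distance_type == "within"
  expect_equal(within, dd$singer_a == dd$singer_b)
  expect_equal(within, grepl("^W", dd$category_factor))

  # two contributions of one dominant female pair up as WDF
  f1 <- dd[dd$singer_a == "F1" & dd$singer_b == "F1", ]
  expect_equal(as.character(unique(f1$category_factor)), "WDF")
  expect_equal(unique(f1$distance_type), "within")

  expect_equal(dd$jd_sqrt^2, dd$jd, tolerance = 1e-12)
  expect_true(all(dd$jd >= 0 & dd$jd <= 1))
})

test_that("four contributions give six dyad records", {
  co <- tiny_corpus()
  keep <- co$contributions[1:4, ]
  co4 <- indri_corpus(co$singers, keep)
  dd <- build_dyad_dataset(pairwise_jaro_matrix(co4), co4)
  expect_equal(nrow(dd), 6)
})

test_that("record thinning subsamples and builds disjoint designs", {
  co <- tiny_corpus()
  dd <- build_dyad_dataset(pairwise_jaro_matrix(co), co)
  rnd <- thin_dyad_records(dd, "random", n = 10, seed = 2)
  expect_equal(nrow(rnd), 10)
  dis <- thin_dyad_records(dd, "disjoint", seed = 2)
  used <- c(dis$contrib_a, dis$contrib_b)
  expect_equal(anyDuplicated(used), 0)
  expect_lte(nrow(dis), nrow(co$contributions) / 2)
})

test_that("disjoint thinning restores near-nominal mixed-model calibration", {
  # full dyadic expansion reuses contributions across records, which
  # inflates the LRT; contribution-disjoint records should not
  ps_full <- numeric(25); ps_thin <- numeric(25)
  for (r in 1:25) {
    P <- make_transition_matrix(6, 1.0, seed = 9000 + r)
    cfg <- synthetic_config(
      n_groups = 4, n_nondominants_per_group = 2, songs_per_group = 6,
      transition_matrices = list(dominant_female = P, dominant_male = P,
                                 non_dominant = P),
      coupling_w_max = 0, coupling_length_sigma = 0,
      p_nondominant_sing = 0.5, seed = 9100 + r)
    co <- generate_corpus(cfg)
    dd <- build_dyad_dataset(pairwise_jaro_matrix(co), co)
    fit_full <- suppressWarnings(suppressMessages(
      fit_distance_lmm(dd, posthoc = FALSE)))
    dt <- thin_dyad_records(dd, "disjoint", seed = r)
    fit_thin <- suppressWarnings(suppressMessages(
      fit_distance_lmm(dt, posthoc = FALSE)))
    ps_full[r] <- fit_full$p_value
    ps_thin[r] <- fit_thin$p_value
  }
  expect_lte(mean(ps_thin < 0.05), 0.2)
  expect_lt(mean(ps_thin < 0.05), mean(ps_full < 0.05))
})
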