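# coinpocket module: weighted Gonnet sums, score cascade, neighbor ranking

toy_profile <- function(weights) {
  structure(list(target_name = "P", site = "cofactor",
                 weights = weights, n_complexes = 1,
                 mode = "max", rescaled = TRUE),
            class = "contact_profile")
}

test_that("gonnet_pfp: identity rows, gap rule, explicit per-column sum", {
  p <- toy_profile(c("1" = 1.0, "2" = 0.5, "3" = 0.25))
  expect_equal(gonnet_pfp("ACD", "ACD", p), 1.75)  # S(a,a) = 1, sum of weights
  # gap in the other row at the only profile column
  p1 <- toy_profile(c("2" = 1.0))
  expect_equal(gonnet_pfp("ACD", "A-D", p1), 0)
  # brute-force per-column oracle from the raw table
  M <- gonnet_matrix()
  want <- 1.0 * 1 +
    0.5 * M["C", "V"] / sqrt(M["C", "C"] * M["V", "V"]) +
    0.25 * M["D", "E"] / sqrt(M["D", "D"] * M["E", "E"])
  expect_equal(gonnet_pfp("ACD", "AVE", p), want, tolerance = 1e-12)
  expect_error(gonnet_pfp("ACD", "AC", p), "different lengths")
  expect_error(gonnet_pfp("ACD", "ACD", toy_profile(c("9" = 1))), "out of")
})

test_that("score_matrix refuses degenerate populations", {
  aln2 <- pocketmap:::new_master_alignment(c("a", "b"), c("ACDE", "ACDF"))
  expect_error(score_matrix(aln2, list(toy_profile(c("1" = 1)))), "degenerate")
  aln3 <- pocketmap:::new_master_alignment(c("a", "b", "c"),
                                           c("ACDE", "ACDE", "ACDE"))
  expect_error(score_matrix(aln3, list(toy_profile(c("1" = 1)))),
               "degenerate profile")
})

random_toy_alignment <- function(n, len, seed) {
  set.seed(seed)
  rows <- replicate(n, paste(sample(pocketmap:::AA_LETTERS, len, TRUE),
                             collapse = ""))
  pocketmap:::new_master_alignment(paste0("s", seq_len(n)), rows)
}

random_toy_profiles <- function(len, k, seed) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    cols <- sort(sample(len, 4))
    pr <- toy_profile(setNames(round(runif(4, 0.1, 1), 3), cols))
    pr$target_name <- paste0("P", i)
    pr
  })
}

test_that("score_matrix equals the brute-force oracle on toy inputs", {
  for (seed in 1:5) {
    n <- sample(4:6, 1)
    aln <- random_toy_alignment(n, 12, seed)
    profiles <- random_toy_profiles(12, sample(2:3, 1), seed + 100)
    got <- score_matrix(aln, profiles)
    want <- brute_score_matrix(aln, profiles)
    expect_equal(got$normalized, want$normalized, tolerance = 1e-9)
    expect_equal(got$averaged, want$averaged, tolerance = 1e-9)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
})

test_that("score stages satisfy their invariants", {
  aln <- random_toy_alignment(6, 15, 3)
  profiles <- random_toy_profiles(15, 3, 4)
  sc <- score_matrix(aln, profiles)
  for (m in c(sc$raw, sc$zscored, list(sc$averaged, sc$normalized, sc$distance))) {
    expect_equal(m, t(m), tolerance = 1e-12)
  }
  for (z in sc$zscored) {
    pop <- z[upper.tri(z)]
    expect_equal(mean(pop), 0, tolerance = 1e-9)
    expect_equal(sd(pop), 1, tolerance = 1e-9)
  }
  off <- upper.tri(sc$normalized)
  expect_true(all(sc$normalized[off] >= -1e-12 & sc$normalized[off] <= 1 + 1e-12))
  expect_equal(sc$normalized[off] + sc$distance[off], rep(1, sum(off)))
  expect_true(all(diag(sc$normalized) == 1))
  # self-pair raw score dominates the row (S(a,a)=1 >= S(a,b), weights >= 0)
  for (m in sc$raw) {
    for (i in seq_len(nrow(m))) expect_true(all(m[i, i] >= m[i, ] - 1e-12))
  }
})

test_that("rank_neighbors sorts, breaks ties alphabetically, caps k", {
  m <- matrix(c(1, .9, .2, .5,
                .9, 1, .5, .5,
                .2, .5, 1, .1,
                .5, .5, .1, 1), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  nb <- rank_neighbors(m, "A", k = 10)
  expect_equal(nb$name, c("B", "D", "C"))
  # tie at 0.5 between B and C for target D -> B first
  nbd <- rank_neighbors(m, "D", k = 2)
  expect_equal(nbd$name, c("A", "B"))
  expect_equal(rank_neighbors(m, "A", k = 2)$name, c("B", "D"))
  expect_equal(nb$similarity_2dp, round(nb$similarity, 2))
  expect_error(rank_neighbors(m, "Z"), "unknown target")
})

test_that("planted partners are recovered at rank 1 (smoke, full run in acceptance)", {
  hits <- 0; total <- 0
  for (seed in 1:5) {
    pa <- make_planted_alignment(10, 120, list(c(1, 2), c(3, 4), c(5, 6)),
                                 site_columns = 1:20, background_rate = 0.8,
                                 seed = seed)
    prof <- toy_profile(setNames(rep(1, 20), pa$site_columns))
    sc <- score_matrix(pa$alignment, list(prof))
    for (r in seq_len(nrow(pa$truth))) {
      for (who in c("a", "b")) {
        target <- pa$truth[[who]][r]
        partner <- pa$truth[[if (who == "a") "b" else "a"]][r]
        total <- total + 1
        if (rank_neighbors(sc, target, 1)$name == partner) hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("classic whole-pocket baseline builds a binary union profile", {
  pa <- make_planted_alignment(5, 30, list(c(1, 2)), 5:12, 0.5, seed = 2)
  dir <- tempfile(); dir.create(dir)
  man <- build_synthetic_manifest(pa$alignment, pa$site_columns, dir, seed = 2)
  cxs <- list(); maps <- list()
  for (r in seq_len(nrow(man))) {
    cx <- load_complex(man$path[r], "A", "LIG", site = "cofactor",
                       complex_id = man$complex_id[r],
                       target_name = man$target[r])
    cxs[[r]] <- cx
    maps[[r]] <- map_structure_to_columns(cx, pa$alignment, man$alignment_row[r])
  }
  sc <- classic_pocket_scores(pa$alignment, cxs, maps)
  expect_s3_class(sc, "score_matrix_set")
  expect_equal(length(sc$raw), 1)   # single pooled binary profile
  raw <- sc$raw[[1]]
  expect_equal(raw, t(raw))
  # self-pair similarity dominates each row (binary weights, S(a,a)=1)
  for (i in seq_len(nrow(raw))) expect_true(all(raw[i, i] >= raw[i, ] - 1e-12))
  # the planted pair, identical at all pocket columns, is recovered
  expect_equal(rank_neighbors(sc, "S1", 1)$name, "S2")
})
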