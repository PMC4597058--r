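test_that("enrichment score hits its closed-form extremes", {
  ranked <- sprintf("g%03d", 1:100)
  expect_equal(ks_enrichment(ranked, "g001"), 0.99)
  expect_equal(ks_enrichment(ranked, "g100"), -1)
  # tagged = whole list: V(j) = j, so a = 0 and b = 1/n
  for (n in c(5, 17)) {
    full <- sprintf("g%d", 1:n)
    expect_equal(ks_enrichment(full, full), -1 / n, tolerance = 1e-12)
  }
  expect_error(ks_enrichment(ranked, "absent"), "overlap")
})

test_that("enrichment matches the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:300) {
    t_len <- sample(5:60, 1)
    ranked <- sample(sprintf("g%03d", 1:80), t_len)
    tagged <- sample(ranked, sample(1:t_len, 1))
    es <- ks_enrichment(ranked, tagged)
    expect_equal(es, oracle_ks(ranked, tagged), tolerance = 1e-12)
    expect_true(es >= -1 && es <= 1)
  }
})

test_that("reversing the ranking mirrors the enrichment score", {
  # the discrete statistic is antisymmetric up to the step size: exactly
  # es_rev = -es - 1/t away from ties of the two inner maxima, and
  # within 2/t of that everywhere (position j maps to t + 1 - j, which
  # shifts both maxima by one step)
  set.seed(111)
  ranked <- sprintf("g%03d", 1:50)
  t_len <- length(ranked)
  inner_max <- function(tags) {
    v <- sort(which(ranked %in% tags))
    j <- seq_along(v)
    c(a = max(j / length(v) - v / t_len),
      b = max(v / t_len - (j - 1) / length(v)))
  }
  for (rep in 1:100) {
    tags <- sample(ranked, sample(1:10, 1))
    es <- ks_enrichment(ranked, tags)
    es_rev <- ks_enrichment(rev(ranked), tags)
    m <- inner_max(tags)
    if (abs(m["a"] - m["b"]) > 2 / t_len + 1e-9) {
      expect_equal(es_rev, -es - 1 / t_len, tolerance = 1e-12)
    } else {
      # near a tie of the two maxima only the magnitude is pinned
      expect_lte(abs(abs(es_rev) - abs(es)), 1 / t_len + 1e-12)
    }
  }
})

test_that("connectivity score follows the opposite-sign rule", {
  # 10 proteins ranked g01 (top) .. g10 (bottom)
  prof <- drug_profile("d", stats::setNames(10:1, sprintf("g%02d", 1:10)))
  # treatment-like: up genes at the bottom, down genes at the top
  sig <- disease_signature("dz", up = c("g09", "g10"), down = c("g01", "g02"))
  cs <- connectivity_score(prof, sig)
  expect_lt(cs$es_up, 0)
  expect_gt(cs$es_down, 0)
  expect_equal(cs$score, cs$es_up - cs$es_down, tolerance = 1e-12)
  expect_lt(cs$score, 0)

  # both sets at the top: same sign, zero score
  sig2 <- disease_signature("dz2", up = c("g01", "g02"),
                            down = c("g03", "g04"))
  cs2 <- connectivity_score(prof, sig2)
  expect_gt(cs2$es_up * cs2$es_down, 0)
  expect_equal(cs2$score, 0)

  # no overlap on one side gives a null result with a reason
  sig3 <- disease_signature("dz3", up = "absent", down = "g01")
  cs3 <- connectivity_score(prof, sig3)
  expect_true(is.na(cs3$score))
  expect_match(cs3$reason, "up set")
})

test_that("same-sign zero rule holds across random pairings", {
  set.seed(121)
  pool <- sprintf("g%02d", 1:30)
  for (rep in 1:100) {
    prof <- random_profile("d", pool, sample(10:25, 1))
    genes <- sample(pool, 8)
    sig <- disease_signature("z", genes[1:4], genes[5:8])
    cs <- connectivity_score(prof, sig)
    if (is.na(cs$score)) next
    if (cs$es_up * cs$es_down > 0) {
      expect_identical(cs$score, 0)
    } else if (sign(cs$es_up) != sign(cs$es_down)) {
      expect_equal(cs$score, cs$es_up - cs$es_down, tolerance = 1e-12)
    }
  }
})

test_that("permutation p-values use the add-one one-sided rule", {
  set.seed(131)
  pool <- lapply(sprintf("d%02d", 1:12), random_profile,
                 sprintf("g%02d", 1:20), 10)
  sig <- disease_signature("z", sprintf("g%02d", 1:3), sprintf("g%02d", 4:6))
  # a score below every attainable permuted score
  expect_equal(permutation_p(-3, pool, sig, n_permutations = 200, seed = 1),
               1 / 201, tolerance = 1e-12)
  # observed 0 against a pool that never overlaps: every permutation ties
  empty_pool <- lapply(c("e1", "e2"), function(id)
    drug_profile(id, c(zzz1 = 1, zzz2 = 0.5)))
  expect_equal(suppressWarnings(
    permutation_p(0, empty_pool, sig, n_permutations = 50, seed = 1)), 1)
  expect_error(permutation_p(0, pool[1], sig), "at least 2")
  expect_warning(permutation_p(0, pool[1:3], sig, n_permutations = 10,
                               seed = 1), "fewer than 10")
})

test_that("star ratings follow the score bins with the p-value override", {
  expect_equal(star_rating(-0.35, 0.01), 5L)
  expect_equal(star_rating(-0.15, 0.01), 3L)
  expect_equal(star_rating(-0.5, 0.2), 1L)
  expect_equal(star_rating(0.2, 0.01), 1L)
  expect_true(is.na(star_rating(NA, 0.01)))
})

test_that("candidate ranking is deterministic and id-ordered on ties", {
  set.seed(141)
  pool <- sprintf("g%02d", 1:20)
  base <- random_profile("d01", pool, 12)
  clone <- drug_profile("d02", base$scores,
                        stats::setNames(base$signs, base$ranked))
  others <- lapply(sprintf("d%02d", 3:12), random_profile, pool, 10)
  profs <- c(list(base, clone), others)
  sig <- disease_signature("z", base$ranked[11:12], base$ranked[1:2])
  r1 <- rank_candidates(profs, sig, n_permutations = 100, seed = 5)
  r2 <- rank_candidates(profs, sig, n_permutations = 100, seed = 5)
  expect_identical(r1, r2)
  i1 <- which(r1$drug_id == "d01")
  i2 <- which(r1$drug_id == "d02")
  expect_equal(r1$score[i1], r1$score[i2])
  expect_equal(r1$stars, star_rating(r1$score, r1$p_value))

  far <- disease_signature("w", "absent1", "absent2")
  expect_equal(nrow(rank_candidates(profs, far, n_permutations = 10,
                                    seed = 1)), 0L)
})

test_that("planted treatment drugs rank near the top for their disease", {
  g <- synth_generate(synth_config(seed = 4))
  map <- build_map(g$evidence, g$ppi)
  tr <- g$truth$true_indications
  for (s in g$signatures[1:2]) {
    rc <- rank_candidates(map$profiles, s, n_permutations = 100, seed = 17)
    td <- tr$drug_id[tr$disease_id == s$disease_id]
    top10pct <- rc$drug_id[seq_len(ceiling(0.1 * length(map$profiles)))]
    expect_gt(length(intersect(td, top10pct)), 0L)
    # planted pairs score below the background median
    bg <- rc$score[!(rc$drug_id %in% td)]
    expect_lt(stats::median(rc$score[rc$drug_id %in% td]),
              stats::median(bg))
  }
})
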