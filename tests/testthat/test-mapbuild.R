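test_that("evidence aggregation sums signed probabilities per pair", {
  one <- data.frame(drug_id = "d", protein_id = "p", prob = 0.8, sign = 1L,
                    source = "s")
  res <- aggregate_confidence(one)
  expect_equal(res$conf, 0.8)
  expect_equal(res$net_sign, 1L)
  expect_equal(res$n_evidence, 1L)

  cancel <- data.frame(drug_id = "d", protein_id = "p",
                       prob = c(0.5, 0.5), sign = c(1L, -1L), source = "s")
  res2 <- aggregate_confidence(cancel)
  expect_equal(nrow(res2), 0L)
  expect_equal(attr(res2, "n_zero_dropped"), 1L)

  three <- data.frame(drug_id = "d", protein_id = "p",
                      prob = c(0.9, 0.3, 0.4), sign = c(1L, -1L, 1L),
                      source = "s")
  res3 <- aggregate_confidence(three)
  expect_equal(res3$conf, 0.9 - 0.3 + 0.4)
  expect_equal(res3$n_evidence, 3L)
})

test_that("aggregation is linear and sign-correct", {
  set.seed(21)
  for (rep in 1:20) {
    ev <- random_evidence(25)
    base <- aggregate_confidence(ev)
    doubled <- aggregate_confidence(rbind(ev, ev))
    shared <- merge(base, doubled, by = c("drug_id", "protein_id"))
    expect_equal(shared$conf.y, 2 * shared$conf.x, tolerance = 1e-12)

    all_up <- ev
    all_up$sign <- 1L
    expect_true(all(aggregate_confidence(all_up)$net_sign == 1L))
    all_dn <- ev
    all_dn$sign <- -1L
    expect_true(all(aggregate_confidence(all_dn)$net_sign == -1L))
  }
})

test_that("protein weight follows the log-confidence formula", {
  e1 <- data.frame(protein_a = "p", protein_b = "q", conf = 1.0)
  expect_equal(protein_weight(e1, k = 2)$weight, c(0, 0))

  e2 <- data.frame(protein_a = c("p", "p"), protein_b = c("q", "r"),
                   conf = c(0.9, 0.9))
  w <- protein_weight(e2, k = 2)
  wp <- w$weight[w$protein_id == "p"]
  expect_equal(wp, 2 * log(1.8) - log(2), tolerance = 1e-12)
  expect_equal(wp, 0.48242, tolerance = 1e-4)

  expect_error(protein_weight(e1, k = 0), "positive")
  expect_error(protein_weight(e1, k = -1), "positive")
})

test_that("adding a full-confidence neighbor never decreases a weight", {
  set.seed(31)
  for (rep in 1:20) {
    pp <- random_ppi(12, n_proteins = 8)
    w0 <- protein_weight(pp, k = 2)
    target <- sample(w0$protein_id, 1)
    extra <- data.frame(protein_a = target, protein_b = "NEW", conf = 1.0)
    w1 <- protein_weight(rbind(pp, extra), k = 2)
    expect_gte(w1$weight[w1$protein_id == target] + 1e-12,
               w0$weight[w0$protein_id == target])
  }
})

test_that("pharmacology scores multiply confidence by weight and rank", {
  effects <- data.frame(drug_id = "d",
                        protein_id = c("A", "B", "C"),
                        conf = c(0.8, -1.0, 1.0),
                        net_sign = c(1L, -1L, 1L),
                        n_evidence = 1L)
  weights <- data.frame(protein_id = c("A", "C"),
                        weight = c(2 * log(1.8) - log(2), 0.5),
                        degree = c(2L, 1L), sum_conf = c(1.8, 0.6))
  prof <- p_score(effects, weights)[["d"]]
  expect_equal(unname(prof$scores["A"]), 0.38594, tolerance = 1e-4)
  # B is absent from the network: weight 0, retained at score 0
  expect_equal(unname(prof$scores["B"]), 0)
  expect_equal(prof$ranked, c("C", "A", "B"))
  expect_equal(prof$signs[prof$ranked == "B"], -1L)
})

test_that("map construction matches a hand tally and is deterministic", {
  ev_path <- write_lines_tmp(c(
    "drug_id\tprotein_id\taction\tscore\tsource",
    "d1\tP1\tactivation\t0.9\ts",
    "d1\tP2\tinhibition\t0.6\ts",
    "d1\tP3\tactivation\t0.5\ts",
    "d2\tP1\tinhibition\t0.7\ts",
    "d2\tP2\tactivation\t0.8\ts",
    "d2\tP3\tinhibition\t0.4\ts"))
  pp_path <- write_lines_tmp(c(
    "protein_a\tprotein_b\tconf",
    "P1\tP2\t0.9", "P2\tP3\t0.8"))
  map <- build_map(ev_path, pp_path)
  expect_equal(map$summary$n_drugs, 2L)
  expect_equal(map$summary$n_proteins, 3L)
  expect_equal(map$summary$n_effects, 6L)
  expect_equal(map$summary$n_stimulatory, 3L)
  expect_equal(map$summary$n_inhibitory, 3L)
  expect_equal(map$summary$n_stimulatory + map$summary$n_inhibitory,
               map$summary$n_effects)
  expect_length(map$profiles, 2L)

  # byte-identical rerun
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  write_map(build_map(ev_path, pp_path), d1)
  write_map(build_map(ev_path, pp_path), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("empty evidence yields an empty map, not an error", {
  ev_path <- write_lines_tmp("drug_id\tprotein_id\taction\tscore\tsource")
  pp_path <- write_lines_tmp(c("protein_a\tprotein_b\tconf",
                               "P1\tP2\t0.5"))
  map <- build_map(ev_path, pp_path)
  expect_length(map$profiles, 0L)
  expect_equal(map$summary$n_effects, 0L)
  expect_equal(map$summary$n_stimulatory, 0L)
})

test_that("map construction agrees with a naive re-computation", {
  set.seed(41)
  for (rep in 1:10) {
    ev <- random_evidence(40, n_drugs = 5, n_proteins = 9)
    pp <- random_ppi(14, n_proteins = 9)
    eff <- aggregate_confidence(ev)
    expect_equal(eff, oracle_aggregate(ev), ignore_attr = TRUE,
                 tolerance = 1e-12)
    w <- protein_weight(pp, k = 2)
    expect_equal(w, oracle_weight(pp, k = 2), ignore_attr = TRUE,
                 tolerance = 1e-12)
    profs <- p_score(eff, w)
    wmap <- stats::setNames(w$weight, w$protein_id)
    for (i in seq_len(nrow(eff))) {
      wt <- wmap[eff$protein_id[i]]
      if (is.na(wt)) wt <- 0
      expect_equal(
        unname(profs[[eff$drug_id[i]]]$scores[eff$protein_id[i]]),
        oracle_pscore_one(eff$conf[i], unname(wt)), tolerance = 1e-12)
    }
  }
})
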