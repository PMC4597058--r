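# Independent brute-force re-implementations of the scoring cores, written
# as plain loops straight from the definitions.  They deliberately share no
# code with the package internals.

oracle_aggregate <- function(evidence) {
  out <- list()
  for (i in seq_len(nrow(evidence))) {
    key <- paste(evidence$drug_id[i], evidence$protein_id[i])
    if (is.null(out[[key]])) out[[key]] <- c(conf = 0, n = 0)
    out[[key]]["conf"] <- out[[key]]["conf"] +
      evidence$prob[i] * evidence$sign[i]
    out[[key]]["n"] <- out[[key]]["n"] + 1
  }
  keys <- names(out)
  df <- data.frame(
    drug_id = vapply(strsplit(keys, " "), `[[`, character(1), 1),
    protein_id = vapply(strsplit(keys, " "), `[[`, character(1), 2),
    conf = vapply(out, `[[`, numeric(1), "conf"),
    n_evidence = as.integer(vapply(out, `[[`, numeric(1), "n")),
    stringsAsFactors = FALSE)
  df <- df[df$conf != 0, , drop = FALSE]
  df$net_sign <- ifelse(df$conf > 0, 1L, -1L)
  df <- df[order(df$drug_id, df$protein_id, method = "radix"),
           c("drug_id", "protein_id", "conf", "net_sign", "n_evidence")]
  rownames(df) <- NULL
  df
}

oracle_weight <- function(edges, k = 2) {
  prots <- sort(unique(c(edges$protein_a, edges$protein_b)), method = "radix")
  res <- data.frame(protein_id = prots, weight = NA_real_,
                    degree = NA_integer_, sum_conf = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(prots)) {
    s <- 0
    n <- 0
    for (j in seq_len(nrow(edges))) {
      if (edges$protein_a[j] == prots[i] || edges$protein_b[j] == prots[i]) {
        s <- s + edges$conf[j]
        n <- n + 1
      }
    }
    res$weight[i] <- k * log(s) - log(n)
    res$degree[i] <- n
    res$sum_conf[i] <- s
  }
  res
}

oracle_pscore_one <- function(effects_row_conf, weight) {
  effects_row_conf * weight
}

oracle_tanimoto <- function(signs_x, signs_y) {
  union_p <- unique(c(names(signs_x), names(signs_y)))
  n_same <- 0
  n_opp <- 0
  for (p in union_p) {
    if (!is.na(signs_x[p]) && !is.na(signs_y[p])) {
      if (signs_x[[p]] == signs_y[[p]]) n_same <- n_same + 1 else
        n_opp <- n_opp + 1
    }
  }
  list(sim = (n_same - n_opp) / length(union_p),
       n_same = n_same, n_opp = n_opp, n_union = length(union_p))
}

oracle_ks <- function(ranked, tagged) {
  v <- c()
  for (pos in seq_along(ranked)) {
    if (ranked[pos] %in% tagged) v <- c(v, pos)
  }
  n <- length(v)
  t_len <- length(ranked)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(n)) {
    a <- max(a, j / n - v[j] / t_len)
    b <- max(b, v[j] / t_len - (j - 1) / n)
  }
  if (a > b) a else -b
}

oracle_trapezoid <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  total
}
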