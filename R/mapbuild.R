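# Construction of the directional connectivity map: aggregate signed
# evidence per drug-protein pair, weight proteins by their interaction
# neighborhood, and combine both into a pharmacology score (P-Score)
# whose per-drug ranking is the map's query interface.

#' Aggregate signed evidence per drug-protein pair
#'
#' For each (drug, protein) pair, the aggregate confidence is the
#' probability-weighted sum of its evidence,
#' `conf = sum_i prob_i * sign_i`, where `sign_i` is +1 for activation
#' and -1 for inhibition.  Pairs whose evidence balances to exactly zero
#' carry no direction and are dropped (and counted): the map stores only
#' directed effects.
#'
#' @param evidence data.frame as returned by [read_evidence].
#' @return data.frame with columns `drug_id`, `protein_id`, `conf`,
#'   `net_sign` (+1/-1, the sign of `conf`), `n_evidence`; attribute
#'   `n_zero_dropped` counts exactly-balanced pairs removed.
#' @export
aggregate_confidence <- function(evidence) {
  if (nrow(evidence) == 0L) {
    out <- data.frame(drug_id = character(), protein_id = character(),
                      conf = numeric(), net_sign = integer(),
                      n_evidence = integer(), stringsAsFactors = FALSE)
    attr(out, "n_zero_dropped") <- 0L
    return(out)
  }
  key <- paste(evidence$drug_id, evidence$protein_id, sep = "\r")
  conf <- rowsum(evidence$prob * evidence$sign, key, reorder = TRUE)
  n_ev <- rowsum(rep(1L, nrow(evidence)), key, reorder = TRUE)
  ids <- strsplit(rownames(conf), "\r", fixed = TRUE)
  out <- data.frame(
    drug_id = vapply(ids, `[[`, character(1L), 1L),
    protein_id = vapply(ids, `[[`, character(1L), 2L),
    conf = as.numeric(conf),
    n_evidence = as.integer(n_ev),
    stringsAsFactors = FALSE
  )
  zero <- out$conf == 0
  out <- out[!zero, , drop = FALSE]
  out$net_sign <- ifelse(out$conf > 0, 1L, -1L)
  ord <- order(out$drug_id, out$protein_id, method = "radix")
  out <- out[ord, c("drug_id", "protein_id", "conf", "net_sign",
                    "n_evidence")]
  rownames(out) <- NULL
  attr(out, "n_zero_dropped") <- sum(zero)
  out
}

#' Network-derived protein weights
#'
#' Weights each protein by its interaction neighborhood:
#' `weight(p) = k * ln(sum_q conf(p,q)) - ln(degree(p))`, where the sum
#' and degree run over the protein's partners in the undirected PPI edge
#' list and `k` is an empirical constant (default 2).  Proteins absent
#' from the network (degree 0) get weight 0: an effect on a protein with
#' no known network context carries no ranking signal.  Negative weights
#' can arise for weakly-connected proteins and are kept as-is.
#'
#' @param edges data.frame as returned by [read_ppi] (deduplicated,
#'   undirected).
#' @param k Positive multiplier on the log summed confidence.
#' @return data.frame with columns `protein_id`, `weight`, `degree`,
#'   `sum_conf`, one row per protein appearing in `edges`.
#' @export
protein_weight <- function(edges, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive number", call. = FALSE)
  }
  prot <- c(edges$protein_a, edges$protein_b)
  conf <- c(edges$conf, edges$conf)
  if (length(prot) == 0L) {
    return(data.frame(protein_id = character(), weight = numeric(),
                      degree = integer(), sum_conf = numeric(),
                      stringsAsFactors = FALSE))
  }
  sum_conf <- rowsum(conf, prot, reorder = TRUE)
  degree <- rowsum(rep(1L, length(prot)), prot, reorder = TRUE)
  out <- data.frame(
    protein_id = rownames(sum_conf),
    weight = k * log(as.numeric(sum_conf)) - log(as.numeric(degree)),
    degree = as.integer(degree),
    sum_conf = as.numeric(sum_conf),
    stringsAsFactors = FALSE
  )
  ord <- order(out$protein_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pharmacology scores and ranked per-drug profiles
#'
#' The pharmacology score of a drug-protein pair is the product of the
#' aggregated signed confidence and the protein's network weight,
#' `p_score = conf * weight`.  Proteins without a network weight use the
#' degree-0 default of 0 and are retained in the profile (they still
#' occupy ranks).  One ranked profile is produced per drug.
#'
#' @param effects data.frame from [aggregate_confidence].
#' @param weights data.frame from [protein_weight].
#' @return Named list of [drug_profile] objects, keyed and ordered by
#'   drug id.
#' @export
p_score <- function(effects, weights) {
  w <- setNames(weights$weight, weights$protein_id)
  wp <- w[effects$protein_id]
  wp[is.na(wp)] <- 0
  score <- effects$conf * as.numeric(wp)
  drugs <- sort(unique(effects$drug_id), method = "radix")
  out <- lapply(drugs, function(d) {
    i <- which(effects$drug_id == d)
    drug_profile(d,
                 scores = setNames(score[i], effects$protein_id[i]),
                 signs = setNames(effects$net_sign[i],
                                  effects$protein_id[i]))
  })
  names(out) <- drugs
  out
}

#' Build a directional connectivity map
#'
#' Deterministic composition of the construction pipeline: read evidence
#' and PPI inputs, aggregate signed evidence per pair, weight proteins by
#' network context, and score every effect.  The summary mirrors the
#' usual database-statistics breakdown: drugs, proteins, total effects,
#' and the stimulatory/inhibitory split.
#'
#' @param evidence Path to an evidence TSV, or a data.frame as returned
#'   by [read_evidence].
#' @param ppi Path to a PPI TSV, or a data.frame as returned by
#'   [read_ppi].
#' @param k Weight constant passed to [protein_weight].
#' @return List with elements `profiles` (named list of [drug_profile]),
#'   `effects`, `weights` (data.frames), and `summary` (named list of
#'   counts: `n_drugs`, `n_proteins`, `n_effects`, `n_stimulatory`,
#'   `n_inhibitory`, `n_zero_dropped`).
#' @export
build_map <- function(evidence, ppi, k = 2) {
  if (is.character(evidence)) evidence <- read_evidence(evidence)
  if (is.character(ppi)) ppi <- read_ppi(ppi)
  effects <- aggregate_confidence(evidence)
  weights <- protein_weight(ppi, k = k)
  profiles <- p_score(effects, weights)
  summary <- list(
    n_drugs = length(unique(effects$drug_id)),
    n_proteins = length(unique(effects$protein_id)),
    n_effects = nrow(effects),
    n_stimulatory = sum(effects$net_sign == 1L),
    n_inhibitory = sum(effects$net_sign == -1L),
    n_zero_dropped = attr(effects, "n_zero_dropped")
  )
  list(profiles = profiles, effects = effects, weights = weights,
       summary = summary)
}
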