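# Kolmogorov-Smirnov connectivity scoring of disease signatures against
# ranked drug profiles, permutation significance, and star ratings.
# Candidate treatments are drugs whose profile anti-correlates with the
# disease signature: up-regulated disease genes near the bottom of the
# drug's ranking and down-regulated genes near the top give a negative
# connectivity score.

#' Kolmogorov-Smirnov enrichment score of a tagged set in a ranking
#'
#' Let `t` be the length of the ranked list, `n` the number of tagged
#' identifiers present in it, and `V(j)` the 1-based position of the
#' j-th tagged member (positions sorted ascending).  With
#' `a = max_j [ j/n - V(j)/t ]` and `b = max_j [ V(j)/t - (j-1)/n ]`,
#' the enrichment score is `a` if `a > b`, else `-b`.  Scores lie in
#' `[-1, 1]`: positive when the tagged set concentrates at the top of
#' the ranking, negative at the bottom.
#'
#' @param ranked Character vector: the full ranked list (best first).
#' @param tagged Character vector of identifiers; members absent from
#'   `ranked` are ignored (positions exist only for ranked members).
#' @return The enrichment score.
#' @export
ks_enrichment <- function(ranked, tagged) {
  t_len <- length(ranked)
  if (t_len == 0L) stop("empty ranking", call. = FALSE)
  v <- which(ranked %in% tagged)
  n <- length(v)
  if (n == 0L) {
    stop("no overlap between tagged set and ranking", call. = FALSE)
  }
  j <- seq_len(n)
  a <- max(j / n - v / t_len)
  b <- max(v / t_len - (j - 1) / n)
  if (a > b) a else -b
}

#' Connectivity score of a drug profile against a disease signature
#'
#' Computes enrichment scores separately for the signature's up- and
#' down-regulated sets against the drug's ranked profile.  When the two
#' enrichment scores share an algebraic sign the connectivity score is
#' 0; otherwise it is `es_up - es_down`.  A treatment-like pattern (up
#' genes at the bottom of the ranking, down genes at the top) therefore
#' yields a negative score.  If either signature side has no overlap
#' with the profile the result is null (`NA` scores with a reason).
#'
#' @param profile A [drug_profile].
#' @param signature A [disease_signature].
#' @return List with `drug_id`, `disease_id`, `es_up`, `es_down`,
#'   `score`, and `reason` (`NA` unless the result is null).
#' @export
connectivity_score <- function(profile, signature) {
  ranked <- profile$ranked
  null_result <- function(reason) {
    list(drug_id = profile$drug_id, disease_id = signature$disease_id,
         es_up = NA_real_, es_down = NA_real_, score = NA_real_,
         reason = reason)
  }
  if (!any(signature$up %in% ranked)) {
    return(null_result("no overlap with up set"))
  }
  if (!any(signature$down %in% ranked)) {
    return(null_result("no overlap with down set"))
  }
  es_up <- ks_enrichment(ranked, signature$up)
  es_down <- ks_enrichment(ranked, signature$down)
  score <- if (sign(es_up) == sign(es_down)) 0 else es_up - es_down
  list(drug_id = profile$drug_id, disease_id = signature$disease_id,
       es_up = es_up, es_down = es_down, score = score, reason = NA_character_)
}

#' Permutation p-value for a connectivity score
#'
#' Draws `n_permutations` profiles uniformly with replacement from a
#' pool of other drugs' profiles, recomputes the connectivity score
#' against the same signature, and returns a one-sided add-one p-value
#' in the direction of the observed score's sign: for `observed < 0`,
#' `p = (#\{perm <= observed\} + 1) / (n_permutations + 1)`; otherwise
#' `p = (#\{perm >= observed\} + 1) / (n_permutations + 1)`.  Null
#' permutation scores (no overlap) count as 0.  The pool should exclude
#' the observed drug.
#'
#' @param observed Observed connectivity score.
#' @param pool List of [drug_profile] objects to draw from (>= 2).
#' @param signature The [disease_signature] scored.
#' @param n_permutations Number of random draws (default 200).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (callers that score many pairs seed once).
#' @return The permutation p-value, in `[1/(n_permutations+1), 1]`.
#' @export
permutation_p <- function(observed, pool, signature, n_permutations = 200,
                          seed = NULL) {
  if (length(pool) < 2L) {
    stop("permutation pool must contain at least 2 profiles", call. = FALSE)
  }
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  if (length(pool) < 10L) {
    warning("permutation pool has fewer than 10 profiles; ",
            "p-values will be coarse", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(pool), n_permutations, replace = TRUE)
  perm <- vapply(idx, function(i) {
    s <- connectivity_score(pool[[i]], signature)$score
    if (is.na(s)) 0 else s
  }, numeric(1L))
  hits <- if (observed < 0) sum(perm <= observed) else sum(perm >= observed)
  (hits + 1) / (n_permutations + 1)
}

#' Star rating for a drug-disease connectivity result
#'
#' Bins the connectivity score into the 1-5 star scale used to grade
#' repositioning candidates: 5 stars for score < -0.3, 4 for
#' [-0.3, -0.2), 3 for [-0.2, -0.1), 2 for [-0.1, 0), and 1 star when
#' the score is >= 0 or the p-value is >= 0.05 (the significance
#' override applies to every bin).
#'
#' @param score Connectivity score(s).
#' @param p_value Permutation p-value(s), recycled against `score`.
#' @return Integer vector of star counts in 1..5 (`NA` for `NA` input).
#' @export
star_rating <- function(score, p_value) {
  n <- max(length(score), length(p_value))
  score <- rep_len(score, n)
  p_value <- rep_len(p_value, n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(score) & !is.na(p_value)
  s <- score[ok]
  p <- p_value[ok]
  stars <- ifelse(s >= 0 | p >= 0.05, 1L,
           ifelse(s < -0.3, 5L,
           ifelse(s < -0.2, 4L,
           ifelse(s < -0.1, 3L, 2L))))
  out[ok] <- stars
  out
}

#' Rank candidate treatment drugs for a disease signature
#'
#' Scores every profile with overlap against the signature, attaches a
#' permutation p-value (pool = all other profiles, sampled with
#' replacement), a star rating, and a candidate flag (`score < 0` and
#' `p < 0.05`).  Results are sorted ascending by score (most negative,
#' most treatment-like first), ties broken by p-value then drug id.
#'
#' @param profiles List of >= 2 [drug_profile] objects.
#' @param signature A [disease_signature].
#' @param n_permutations Permutations per drug-disease pair.
#' @param seed Integer seed, set once before the scoring loop.
#' @return data.frame with columns `disease_id`, `drug_id`, `es_up`,
#'   `es_down`, `score`, `p_value`, `stars`, `candidate`; zero rows if
#'   no profile overlaps the signature.
#' @export
rank_candidates <- function(profiles, signature, n_permutations = 200,
                            seed = NULL) {
  if (length(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  ids <- vapply(profiles, `[[`, character(1L), "drug_id")
  profiles <- profiles[order(ids, method = "radix")]
  ids <- sort(ids, method = "radix")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_along(profiles)) {
    cs <- connectivity_score(profiles[[i]], signature)
    if (is.na(cs$score)) next
    p <- permutation_p(cs$score, profiles[-i], signature,
                       n_permutations = n_permutations, seed = NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      disease_id = signature$disease_id, drug_id = ids[i],
      es_up = cs$es_up, es_down = cs$es_down, score = cs$score,
      p_value = p, stars = star_rating(cs$score, p),
      candidate = cs$score < 0 & p < 0.05,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(disease_id = character(), drug_id = character(),
                      es_up = numeric(), es_down = numeric(),
                      score = numeric(), p_value = numeric(),
                      stars = integer(), candidate = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  ord <- order(out$score, out$p_value, out$drug_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
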