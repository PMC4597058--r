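# Signed-Tanimoto drug-drug similarity over interacting-protein sets,
# the significant-pair network filter, and scale-free degree diagnostics
# for the bipartite drug-protein network.

#' Signed Tanimoto similarity between two drug profiles
#'
#' Overlap-based similarity where shared proteins acted on in the same
#' direction add and shared proteins acted on in opposite directions
#' subtract, normalized by the size of the protein union:
#' `sim = (n_same - n_opp) / n_union`, in `[-1, 1]`.  A value of 1 means
#' the drugs share all interacting proteins with identical directions;
#' -1 means shared proteins with uniformly opposite directions.
#' Directions are the net signs of the aggregated evidence confidence
#' (not the P-Score sign, so a negative network weight cannot flip a
#' drug's pharmacological direction).
#'
#' @param profile_x,profile_y [drug_profile] objects.
#' @return One-row data.frame with columns `drug_x`, `drug_y`, `sim`,
#'   `n_same`, `n_opp`, `n_union`.
#' @export
signed_tanimoto <- function(profile_x, profile_y) {
  stopifnot(inherits(profile_x, "drug_profile"),
            inherits(profile_y, "drug_profile"))
  px <- profile_x$ranked
  py <- profile_y$ranked
  n_union <- length(union(px, py))
  if (n_union == 0L) {
    stop("similarity undefined: both profiles are empty", call. = FALSE)
  }
  shared <- intersect(px, py)
  sx <- setNames(profile_x$signs, px)[shared]
  sy <- setNames(profile_y$signs, py)[shared]
  n_same <- sum(sx == sy)
  n_opp <- length(shared) - n_same
  data.frame(drug_x = profile_x$drug_id, drug_y = profile_y$drug_id,
             sim = (n_same - n_opp) / n_union,
             n_same = n_same, n_opp = n_opp, n_union = n_union,
             stringsAsFactors = FALSE)
}

# Signed sparse incidence matrix (drugs x proteins) over a profile list.
.sign_matrix <- function(profiles) {
  ids <- vapply(profiles, `[[`, character(1L), "drug_id")
  prot <- sort(unique(unlist(lapply(profiles, `[[`, "ranked"))),
               method = "radix")
  i <- rep(seq_along(profiles),
           vapply(profiles, function(p) length(p$ranked), integer(1L)))
  j <- match(unlist(lapply(profiles, `[[`, "ranked")), prot)
  x <- as.numeric(unlist(lapply(profiles, `[[`, "signs")))
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(profiles), length(prot)),
                       dimnames = list(ids, prot))
}

#' All pairwise signed-Tanimoto similarities
#'
#' Computes one [signed_tanimoto] record per unordered drug pair,
#' `n*(n-1)/2` in total, via sparse cross-products.  Output is ordered
#' lexicographically by `(drug_x, drug_y)` with `drug_x < drug_y`.
#' Pairs whose protein union is empty get `sim = NA` (no data, as
#' opposed to orthogonal) and are counted.
#'
#' @param profiles List of two or more [drug_profile] objects.
#' @return data.frame with the [signed_tanimoto] columns; attribute
#'   `n_undefined` counts NA-similarity pairs.
#' @export
all_pairs <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  ids <- vapply(profiles, `[[`, character(1L), "drug_id")
  if (anyDuplicated(ids)) stop("duplicate drug ids", call. = FALSE)
  profiles <- profiles[order(ids, method = "radix")]
  S <- .sign_matrix(profiles)
  A <- abs(S)
  dot <- as.matrix(Matrix::tcrossprod(S))     # n_same - n_opp
  shared <- as.matrix(Matrix::tcrossprod(A))  # n_same + n_opp
  deg <- Matrix::rowSums(A)
  ut <- which(upper.tri(dot), arr.ind = TRUE)
  i <- ut[, 1L]
  j <- ut[, 2L]
  n_union <- deg[i] + deg[j] - shared[ut]
  sim <- ifelse(n_union > 0, dot[ut] / n_union, NA_real_)
  ids <- rownames(dot)
  out <- data.frame(drug_x = ids[i], drug_y = ids[j], sim = sim,
                    n_same = as.integer((shared[ut] + dot[ut]) / 2),
                    n_opp = as.integer((shared[ut] - dot[ut]) / 2),
                    n_union = as.integer(n_union),
                    stringsAsFactors = FALSE)
  ord <- order(out$drug_x, out$drug_y, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(is.na(sim))
  out
}

#' Filter similarity records down to the significant-pair network
#'
#' Keeps pairs that (a) share at least `min_overlap` proteins regardless
#' of direction agreement and (b) have similarity at or above the
#' `1 - top_fraction` quantile of the similarity distribution.  The
#' quantile is computed on the full input (before the overlap filter) by
#' linear interpolation; ties at the threshold are all kept.
#'
#' @param records data.frame from [all_pairs].
#' @param min_overlap Minimum shared-protein count (`n_same + n_opp`).
#' @param top_fraction Upper tail fraction of the similarity
#'   distribution to keep, in (0, 1].
#' @return Subset of `records`; attribute `sim_threshold` records the
#'   quantile used.
#' @export
significant_pairs <- function(records, min_overlap = 2,
                              top_fraction = 0.05) {
  if (nrow(records) == 0L) stop("no similarity records", call. = FALSE)
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  thr <- quantile(records$sim, probs = 1 - top_fraction, na.rm = TRUE,
                  names = FALSE, type = 7)
  keep <- !is.na(records$sim) &
    (records$n_same + records$n_opp) >= min_overlap &
    records$sim >= thr
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sim_threshold") <- thr
  out
}

#' Log-log linear fit of a degree frequency distribution
#'
#' Ordinary least squares of `log10(count)` on `log10(degree)` over the
#' non-empty degree bins; a high R-squared diagnoses power-law
#' (scale-free) behavior.
#'
#' @param degree Positive integer degrees (bin positions).
#' @param count Positive counts per bin.
#' @return List with `slope`, `r_squared`, `n_points`, `available`.
#' @export
loglog_fit <- function(degree, count) {
  keep <- count > 0 & degree > 0
  degree <- degree[keep]
  count <- count[keep]
  if (length(unique(degree)) < 3L) {
    return(list(slope = NA_real_, r_squared = NA_real_,
                n_points = length(degree), available = FALSE))
  }
  fit <- lm(log10(count) ~ log10(degree))
  list(slope = unname(coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       n_points = length(degree),
       available = TRUE)
}

#' Degree-distribution diagnostics for the bipartite drug-protein map
#'
#' Tabulates drug degrees (proteins per drug) and protein degrees (drugs
#' per protein) over a profile collection, then fits each frequency
#' distribution on the log-log scale with [loglog_fit].
#'
#' @param profiles List of [drug_profile] objects.
#' @return data.frame with one row per side (`drug`, `protein`) and
#'   columns `side`, `slope`, `r_squared`, `n_points`, `available`.
#' @export
degree_fit <- function(profiles) {
  drug_deg <- vapply(profiles, function(p) length(p$ranked), integer(1L))
  prot_deg <- table(unlist(lapply(profiles, `[[`, "ranked")))
  one <- function(side, deg) {
    tab <- table(deg)
    f <- loglog_fit(as.integer(names(tab)), as.integer(tab))
    data.frame(side = side, slope = f$slope, r_squared = f$r_squared,
               n_points = f$n_points, available = f$available,
               stringsAsFactors = FALSE)
  }
  rbind(one("drug", drug_deg), one("protein", as.integer(prot_deg)))
}
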