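# Guilt-by-association indication transfer over the drug similarity
# network, leave-one-out cross-validation, and ROC/AUC/partial-AUC
# computation.  Confusion counts are pooled (micro-averaged) across
# drugs: one overall sensitivity/specificity per neighborhood size N.

# Named similarity vector from `drug` to every partner in `records`.
.neighbor_sims <- function(drug, records) {
  ix <- records$drug_x == drug
  iy <- records$drug_y == drug
  partners <- c(records$drug_y[ix], records$drug_x[iy])
  sims <- c(records$sim[ix], records$sim[iy])
  setNames(sims, partners)
}

#' Guilt-by-association indication prediction for one drug
#'
#' Ranks every other gold-standard drug by descending similarity to the
#' query (ties broken lexicographically by drug id; drugs without a
#' similarity record to the query rank last) and predicts the union of
#' the known indications of the top `n_neighbors` drugs.  The query's
#' own indications are never consulted; only drugs present in the gold
#' standard can donate indications.
#'
#' @param drug Query drug id.
#' @param similarities data.frame from [all_pairs].
#' @param indications data.frame with columns `drug_id`, `disease_id`.
#' @param n_neighbors Number of most-similar drugs whose indications are
#'   transferred (N >= 1).
#' @return List with `drug_id`, `n_neighbors`, `predicted_diseases`
#'   (character vector, sorted), `neighbors` (the donor drugs used).
#' @export
gba_predict <- function(drug, similarities, indications, n_neighbors) {
  if (n_neighbors < 1L) stop("n_neighbors must be >= 1", call. = FALSE)
  donors <- setdiff(sort(unique(indications$drug_id), method = "radix"),
                    drug)
  if (length(donors) == 0L) {
    return(list(drug_id = drug, n_neighbors = n_neighbors,
                predicted_diseases = character(), neighbors = character()))
  }
  sims <- .neighbor_sims(drug, similarities)
  s <- sims[donors]
  s[is.na(s)] <- -Inf
  ord <- order(-s, donors, method = "radix")
  top <- donors[ord][seq_len(min(n_neighbors, length(donors)))]
  pred <- sort(unique(indications$disease_id[indications$drug_id %in% top]),
               method = "radix")
  list(drug_id = drug, n_neighbors = n_neighbors,
       predicted_diseases = pred, neighbors = top)
}

#' Trapezoid area under a curve
#'
#' Standard trapezoid-rule integral of a piecewise-linear curve given by
#' points sorted by non-decreasing x; callers append the (0,0) and (1,1)
#' ROC anchors before integration.
#'
#' @param x,y Numeric vectors of equal length; `x` must be sorted
#'   non-decreasingly (an unsorted `x` is a contract violation).
#' @return The integral as a single number.
#' @export
auc_trapezoid <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("need >= 2 points with matching x and y", call. = FALSE)
  }
  if (is.unsorted(x)) stop("x must be sorted non-decreasingly",
                           call. = FALSE)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Interpolated y at x0 on a piecewise-linear curve; for vertical
# segments (duplicated x) the last point at that x is used, matching the
# right-continuous reading of an ROC step.
.interp_at <- function(x, y, x0) {
  i <- max(which(x <= x0))
  if (x[i] == x0) return(y[i])
  j <- i + 1L
  y[i] + (x0 - x[i]) * (y[j] - y[i]) / (x[j] - x[i])
}

# Normalized partial AUC over specificity >= 0.9, i.e. x in [0, 0.1],
# divided by the window width 0.1 so a perfect classifier scores 1.
.pauc_spec90 <- function(x, y, window = 0.1) {
  y_cut <- .interp_at(x, y, window)
  keep <- x < window
  xs <- c(x[keep], window)
  ys <- c(y[keep], y_cut)
  auc_trapezoid(xs, ys) / window
}

#' Leave-one-out ROC for guilt-by-association indication transfer
#'
#' For each neighborhood size N in `n_grid`, holds out each gold-standard
#' drug's indications in turn, predicts them from its top-N most similar
#' gold drugs via [gba_predict], and pools confusion counts over all
#' (drug, disease) cells: TP/FN over the held-out indications, FP/TN over
#' the complement of the disease universe (all diseases in the gold
#' standard).  Sensitivity is non-decreasing and specificity
#' non-increasing in N since prediction sets only grow.
#'
#' @param similarities data.frame from [all_pairs].
#' @param indications Gold-standard data.frame (`drug_id`, `disease_id`);
#'   must cover at least 2 drugs and 2 diseases.
#' @param n_grid Integer vector of neighborhood sizes; default
#'   `1:(n_drugs - 1)`.
#' @return Object of class `roc_curve`: list with `by_n` (data.frame of
#'   N, TP, FP, TN, FN, sensitivity, specificity), `points` (data.frame
#'   of `one_minus_specificity`, `sensitivity`, anchors (0,0) and (1,1)
#'   included), `auc`, and `pauc_spec90` (partial AUC over specificity
#'   >= 0.9, normalized by the 0.1 window).
#' @export
loo_roc <- function(similarities, indications, n_grid = NULL) {
  drugs <- sort(unique(indications$drug_id), method = "radix")
  diseases <- sort(unique(indications$disease_id), method = "radix")
  if (length(drugs) < 2L || length(diseases) < 2L) {
    stop("degenerate gold standard: need >= 2 drugs and >= 2 diseases",
         call. = FALSE)
  }
  n_max <- length(drugs) - 1L
  if (is.null(n_grid)) n_grid <- seq_len(n_max)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 1L | n_grid > n_max)) {
    stop("n_grid values must be in 1..", n_max, call. = FALSE)
  }
  ind_idx <- split(match(indications$disease_id, diseases),
                   factor(indications$drug_id, levels = drugs))
  n_dis <- length(diseases)
  tot <- matrix(0, nrow = length(n_grid), ncol = 4L,
                dimnames = list(NULL, c("TP", "FP", "TN", "FN")))
  for (d in drugs) {
    own <- ind_idx[[d]]
    donors <- setdiff(drugs, d)
    sims <- .neighbor_sims(d, similarities)
    s <- sims[donors]
    s[is.na(s)] <- -Inf
    ranked_donors <- donors[order(-s, donors, method = "radix")]
    pred <- logical(n_dis)
    gi <- 1L
    for (r in seq_len(n_max)) {
      pred[ind_idx[[ranked_donors[r]]]] <- TRUE
      while (gi <= length(n_grid) && n_grid[gi] == r) {
        tp <- sum(pred[own])
        npred <- sum(pred)
        tot[gi, "TP"] <- tot[gi, "TP"] + tp
        tot[gi, "FN"] <- tot[gi, "FN"] + length(own) - tp
        tot[gi, "FP"] <- tot[gi, "FP"] + npred - tp
        tot[gi, "TN"] <- tot[gi, "TN"] + n_dis - npred - (length(own) - tp)
        gi <- gi + 1L
      }
      if (gi > length(n_grid)) break
    }
  }
  by_n <- data.frame(N = n_grid, tot,
                     sensitivity = tot[, "TP"] / (tot[, "TP"] + tot[, "FN"]),
                     specificity = tot[, "TN"] / (tot[, "TN"] + tot[, "FP"]))
  x <- c(0, 1 - by_n$specificity, 1)
  y <- c(0, by_n$sensitivity, 1)
  ord <- order(x, y)
  x <- x[ord]
  y <- y[ord]
  structure(list(by_n = by_n,
                 points = data.frame(one_minus_specificity = x,
                                     sensitivity = y),
                 auc = auc_trapezoid(x, y),
                 pauc_spec90 = .pauc_spec90(x, y)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve>", nrow(x$by_n), "neighborhood sizes; AUC =",
      format(x$auc, digits = 4), "; pAUC(spec>=0.9) =",
      format(x$pauc_spec90, digits = 4), "\n")
  invisible(x)
}
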