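# The per-drug ranked profile: protein -> pharmacology score, plus the
# net direction of each drug-protein effect.  Ranking is descending by
# score with a lexicographic (C-locale) tie-break on protein id so that
# output is identical across runs and platforms.

#' Construct a drug profile
#'
#' A drug profile maps each protein the drug acts on to its pharmacology
#' score (P-Score) and carries the net direction (+1 activation, -1
#' inhibition) of each effect.  The derived `ranked` list orders proteins
#' by descending score, breaking ties lexicographically by protein id.
#'
#' @param drug_id Drug identifier.
#' @param scores Named numeric vector, protein id -> score.
#' @param signs Named integer vector (+1/-1) over the same proteins; the
#'   net sign of the aggregated evidence confidence, used for signed
#'   similarity.  Defaults to `sign(scores)` with zeros mapped to +1.
#' @return Object of class `drug_profile` with elements `drug_id`,
#'   `scores`, `signs`, `ranked`.
#' @export
drug_profile <- function(drug_id, scores, signs = NULL) {
  if (length(scores) == 0L) stop("profile must score at least one protein",
                                 call. = FALSE)
  ids <- names(scores)
  if (is.null(ids) || any(ids == "")) {
    stop("scores must be a named vector of protein ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate protein ids in profile",
                               call. = FALSE)
  if (is.null(signs)) {
    signs <- ifelse(scores < 0, -1L, 1L)
    names(signs) <- ids
  } else {
    if (!setequal(names(signs), ids)) {
      stop("signs must cover exactly the scored proteins", call. = FALSE)
    }
    signs <- signs[ids]
    if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1/-1",
                                          call. = FALSE)
  }
  ord <- order(-scores, ids, method = "radix")
  structure(list(drug_id = drug_id,
                 scores = scores[ord],
                 signs = as.integer(signs[ord]),
                 ranked = ids[ord]),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("<drug_profile>", x$drug_id, "-", length(x$ranked), "proteins; top:",
      paste(head(x$ranked, 3L), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.drug_profile <- function(x) length(x$ranked)

#' Write a ranked drug profile (RNK-style)
#'
#' Serializes the profile as a headerless two-column TSV (protein id,
#' score) in ranked order: descending score, lexicographic tie-break.
#' Scores are written at full double precision so the file round-trips
#' bit-exactly through [read_ranked_profile].
#'
#' @param profile A [drug_profile].
#' @param path Output path.
#' @export
write_ranked_profile <- function(profile, path) {
  stopifnot(inherits(profile, "drug_profile"))
  lines <- paste(profile$ranked, .fmt_num(profile$scores), sep = "\t")
  tryCatch(writeLines(lines, path, useBytes = TRUE),
           error = function(e) stop("cannot write ranked profile to ", path,
                                    ": ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a ranked drug profile written by [write_ranked_profile]
#'
#' @param path Path to the two-column TSV.
#' @param drug_id Drug id to attach (RNK files do not carry one);
#'   defaults to the file name without extension.
#' @return A [drug_profile].  Net signs are recovered from the score
#'   signs (zero scores map to +1), so a profile whose sign structure
#'   differs from its score signs does not survive RNK serialization;
#'   the map-summary TSV written by [build_map] preserves signs exactly.
#' @export
read_ranked_profile <- function(path, drug_id = NULL) {
  if (is.null(drug_id)) drug_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  sc <- .parse_numeric(vapply(fields, `[[`, character(1L), 2L),
                       seq_along(lines), "score", path)
  drug_profile(drug_id, setNames(sc, ids))
}
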