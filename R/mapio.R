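# On-disk layout of a built map: per-drug RNK files under profiles/, a
# map-summary TSV with one row per scored effect, and a JSON of the
# database-style counts.  The map TSV (not the RNK files) is the
# authoritative serialization: it preserves the net evidence sign, which
# RNK score signs cannot when a protein's network weight is negative.

#' Write a built map to a directory
#'
#' @param map List returned by [build_map].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_map <- function(map, out_dir) {
  dir.create(file.path(out_dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  for (p in map$profiles) {
    write_ranked_profile(p, file.path(out_dir, "profiles",
                                      paste0(p$drug_id, ".rnk")))
  }
  eff <- map$effects
  w <- setNames(map$weights$weight, map$weights$protein_id)
  wp <- as.numeric(w[eff$protein_id])
  wp[is.na(wp)] <- 0
  map_path <- file.path(out_dir, "map.tsv")
  lines <- c("drug_id\tprotein_id\tconf\tweight\tp_score",
             paste(eff$drug_id, eff$protein_id, .fmt_num(eff$conf),
                   .fmt_num(wp), .fmt_num(eff$conf * wp), sep = "\t"))
  writeLines(lines, map_path, useBytes = TRUE)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(map$summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(map = map_path, summary = summary_path,
                 profiles_dir = file.path(out_dir, "profiles")))
}

#' Read drug profiles back from a map directory
#'
#' Reconstructs the ranked profiles from the map-summary TSV written by
#' [write_map] (scores are the pharmacology scores, signs the net
#' evidence signs).
#'
#' @param map_dir Directory containing `map.tsv`.
#' @return Named list of [drug_profile] objects.
#' @export
read_map_profiles <- function(map_dir) {
  path <- file.path(map_dir, "map.tsv")
  parsed <- .read_tsv_body(path, c("drug_id", "protein_id", "conf",
                                   "weight", "p_score"))
  rows <- seq_along(parsed$fields)
  lines <- parsed$line_numbers
  drug <- .field(parsed, rows, "drug_id")
  prot <- .field(parsed, rows, "protein_id")
  conf <- .parse_numeric(.field(parsed, rows, "conf"), lines, "conf", path)
  ps <- .parse_numeric(.field(parsed, rows, "p_score"), lines, "p_score",
                       path)
  drugs <- sort(unique(drug), method = "radix")
  out <- lapply(drugs, function(d) {
    i <- which(drug == d)
    drug_profile(d, scores = setNames(ps[i], prot[i]),
                 signs = setNames(ifelse(conf[i] > 0, 1L, -1L), prot[i]))
  })
  names(out) <- drugs
  out
}
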