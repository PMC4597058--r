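# Readers/writers for the tabular and gene-set formats used across the
# toolkit.  All TSVs are tab-delimited UTF-8 with one header line; lines
# starting with '#' are comments.  Identifiers are opaque, case-sensitive
# strings; readers validate numeric fields and report line numbers rather
# than silently coercing.

# Read a TSV into a list of character matrices plus original line numbers.
.read_tsv_body <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no header line in ", path, call. = FALSE)
  }
  header <- strsplit(lines[idx[1L]], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(required_cols, header)
  if (length(missing) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  body_idx <- idx[-1L]
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  list(header = header, fields = fields, line_numbers = body_idx)
}

.field <- function(parsed, rows, col) {
  j <- match(col, parsed$header)
  vapply(parsed$fields[rows], function(f) {
    if (length(f) < j) "" else f[[j]]
  }, character(1L))
}

# Numeric parse with a line-numbered error; never coerces bad values to NA.
.parse_numeric <- function(x, lines, what, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad)) {
    stop("malformed ", what, " at line ", lines[which(bad)[1L]],
         " of ", path, ": '", x[which(bad)[1L]], "'", call. = FALSE)
  }
  v
}

.check_unit_interval <- function(v, lines, what, path) {
  bad <- !(v > 0 & v <= 1)
  if (any(bad)) {
    stop(what, " outside (0,1] at line ", lines[which(bad)[1L]],
         " of ", path, ": ", v[which(bad)[1L]], call. = FALSE)
  }
  invisible(v)
}

#' Read drug-protein evidence records
#'
#' Parses a tab-separated evidence table with columns `drug_id`,
#' `protein_id`, `action`, `score`, `source` (one row per evidence item,
#' in the style of STITCH chemical-protein "actions" dumps).  Only the
#' directional actions `activation` (sign +1) and `inhibition` (sign -1)
#' enter the map; rows with any other action label (binding, catalysis,
#' ...) are skipped and counted.  Duplicate rows are kept as independent
#' evidence items: the aggregation step sums over the number of evidence.
#'
#' @param path Path to the evidence TSV.
#' @return A data.frame with columns `drug_id`, `protein_id`, `prob`
#'   (confidence in (0,1]), `sign` (+1/-1) and `source`, with attribute
#'   `n_skipped` giving the number of non-directional rows dropped.
#' @export
read_evidence <- function(path) {
  parsed <- .read_tsv_body(path, c("drug_id", "protein_id", "action",
                                   "score", "source"))
  n <- length(parsed$fields)
  action <- .field(parsed, seq_len(n), "action")
  keep <- action %in% c("activation", "inhibition")
  rows <- which(keep)
  lines <- parsed$line_numbers[rows]
  prob <- .parse_numeric(.field(parsed, rows, "score"), lines, "score", path)
  .check_unit_interval(prob, lines, "score", path)
  drug_id <- .field(parsed, rows, "drug_id")
  protein_id <- .field(parsed, rows, "protein_id")
  if (any(drug_id == "" | protein_id == "")) {
    bad <- which(drug_id == "" | protein_id == "")[1L]
    stop("empty identifier at line ", lines[bad], " of ", path,
         call. = FALSE)
  }
  out <- data.frame(
    drug_id = drug_id,
    protein_id = protein_id,
    prob = prob,
    sign = ifelse(action[rows] == "activation", 1L, -1L),
    source = .field(parsed, rows, "source"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Read a protein-protein interaction edge list
#'
#' Parses a TSV with columns `protein_a`, `protein_b`, `conf` into an
#' undirected, deduplicated edge list.  Edges are canonicalized so that
#' `protein_a` sorts before `protein_b`; self-loops are dropped and
#' counted, as are duplicate edges (first occurrence wins).
#'
#' @param path Path to the PPI TSV.
#' @return data.frame with columns `protein_a`, `protein_b`, `conf`, and
#'   attributes `n_self_loops` and `n_duplicates`.
#' @export
read_ppi <- function(path) {
  parsed <- .read_tsv_body(path, c("protein_a", "protein_b", "conf"))
  rows <- seq_along(parsed$fields)
  lines <- parsed$line_numbers
  a <- .field(parsed, rows, "protein_a")
  b <- .field(parsed, rows, "protein_b")
  conf <- .parse_numeric(.field(parsed, rows, "conf"), lines, "conf", path)
  .check_unit_interval(conf, lines, "conf", path)
  loop <- a == b
  a2 <- pmin(a[!loop], b[!loop])
  b2 <- pmax(a[!loop], b[!loop])
  key <- paste(a2, b2, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(
    protein_a = a2[!dup],
    protein_b = b2[!dup],
    conf = conf[!loop][!dup],
    stringsAsFactors = FALSE
  )
  ord <- order(out$protein_a, out$protein_b, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- sum(loop)
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Read a drug-indication gold standard
#'
#' Parses a TSV with columns `drug_id`, `disease_id` into a deduplicated
#' association table (the evaluable gold standard for guilt-by-association
#' transfer).
#'
#' @param path Path to the indication TSV.
#' @return data.frame with columns `drug_id`, `disease_id`; attribute
#'   `n_duplicates` counts removed duplicate pairs.
#' @export
read_indications <- function(path) {
  parsed <- .read_tsv_body(path, c("drug_id", "disease_id"))
  rows <- seq_along(parsed$fields)
  drug <- .field(parsed, rows, "drug_id")
  dis <- .field(parsed, rows, "disease_id")
  if (any(drug == "" | dis == "")) {
    bad <- which(drug == "" | dis == "")[1L]
    stop("empty identifier at line ", parsed$line_numbers[bad], " of ",
         path, call. = FALSE)
  }
  key <- paste(drug, dis, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(drug_id = drug[!dup], disease_id = dis[!dup],
                    stringsAsFactors = FALSE)
  ord <- order(out$drug_id, out$disease_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Construct a disease signature
#'
#' A disease signature is a pair of disjoint, non-empty identifier sets:
#' genes/proteins up-regulated and down-regulated in the disease state.
#'
#' @param disease_id Disease identifier.
#' @param up,down Character vectors of gene/protein identifiers.
#' @return An object of class `disease_signature`.
#' @export
disease_signature <- function(disease_id, up, down) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(up) == 0L || length(down) == 0L) {
    stop("signature '", disease_id, "' must have non-empty up and down sets",
         call. = FALSE)
  }
  if (length(intersect(up, down)) > 0L) {
    stop("signature '", disease_id, "' has genes in both up and down sets",
         call. = FALSE)
  }
  structure(list(disease_id = disease_id, up = up, down = down),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("<disease_signature>", x$disease_id, ":", length(x$up), "up /",
      length(x$down), "down genes\n")
  invisible(x)
}

#' Read disease signatures from a GMT file
#'
#' Each line holds a set name followed by its member identifiers,
#' tab-separated.  Up- and down-regulated sets for a disease are paired by
#' the suffixes `_UP` and `_DN` on the set name; a suffix without its
#' partner is a format error.  Identifiers present in both sides of a pair
#' are removed from both (the sets must be disjoint) and counted.
#'
#' @param path Path to the GMT file.
#' @return Named list of [disease_signature] objects (names are disease
#'   ids); attribute `n_ambiguous` counts genes removed for appearing in
#'   both sets of a pair.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, character(1L), 1L)
  genes <- lapply(fields, function(f) unique(f[-1L][f[-1L] != ""]))
  is_up <- grepl("_UP$", nm)
  is_dn <- grepl("_DN$", nm)
  if (any(!is_up & !is_dn)) {
    stop("set name without _UP/_DN suffix: ", nm[which(!is_up & !is_dn)[1L]],
         call. = FALSE)
  }
  base <- sub("_(UP|DN)$", "", nm)
  up_map <- setNames(genes[is_up], base[is_up])
  dn_map <- setNames(genes[is_dn], base[is_dn])
  unmatched <- c(setdiff(names(up_map), names(dn_map)),
                 setdiff(names(dn_map), names(up_map)))
  if (length(unmatched) > 0L) {
    stop("unpaired _UP/_DN signature for disease: ",
         paste(sort(unmatched), collapse = ", "), call. = FALSE)
  }
  n_ambiguous <- 0L
  diseases <- sort(names(up_map), method = "radix")
  out <- lapply(diseases, function(d) {
    both <- intersect(up_map[[d]], dn_map[[d]])
    n_ambiguous <<- n_ambiguous + length(both)
    disease_signature(d, setdiff(up_map[[d]], both),
                      setdiff(dn_map[[d]], both))
  })
  names(out) <- diseases
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

# -- writers -----------------------------------------------------------------

.fmt_num <- function(x) {
  # full double precision so write -> read round-trips bit-exactly
  sprintf("%.17g", x)
}

#' Write an evidence table
#' @param evidence data.frame as returned by [read_evidence].
#' @param path Output path.
#' @export
write_evidence <- function(evidence, path) {
  lines <- c("drug_id\tprotein_id\taction\tscore\tsource",
             paste(evidence$drug_id, evidence$protein_id,
                   ifelse(evidence$sign > 0, "activation", "inhibition"),
                   .fmt_num(evidence$prob), evidence$source, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a PPI edge list
#' @param ppi data.frame as returned by [read_ppi].
#' @param path Output path.
#' @export
write_ppi <- function(ppi, path) {
  lines <- c("protein_a\tprotein_b\tconf",
             paste(ppi$protein_a, ppi$protein_b, .fmt_num(ppi$conf),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a drug-indication table
#' @param indications data.frame with columns `drug_id`, `disease_id`.
#' @param path Output path.
#' @export
write_indications <- function(indications, path) {
  lines <- c("drug_id\tdisease_id",
             paste(indications$drug_id, indications$disease_id, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write disease signatures as a GMT file
#' @param signatures List of [disease_signature] objects.
#' @param path Output path.
#' @export
write_signatures <- function(signatures, path) {
  lines <- unlist(lapply(signatures, function(s) {
    c(paste(c(paste0(s$disease_id, "_UP"), s$up), collapse = "\t"),
      paste(c(paste0(s$disease_id, "_DN"), s$down), collapse = "\t"))
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
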