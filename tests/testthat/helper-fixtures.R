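# Fixture builders: everything is generated in code at test time.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

evidence_fixture <- function() {
  write_lines_tmp(c(
    "# synthetic evidence fixture",
    "drug_id\tprotein_id\taction\tscore\tsource",
    "CID1\tP1\tactivation\t0.8\tstitch",
    "CID1\tP2\tinhibition\t0.5\tstitch",
    "CID2\tP1\tbinding\t0.9\tstitch",
    "CID2\tP3\tactivation\t0.4\tcurated"))
}

ppi_fixture <- function() {
  write_lines_tmp(c(
    "protein_a\tprotein_b\tconf",
    "P1\tP2\t0.9",
    "P2\tP1\t0.9",
    "P1\tP1\t0.5",
    "P2\tP3\t0.7",
    "P3\tP4\t0.6"))
}

# random drug profile with +/-1 signs; scores distinct unless tie requested
random_profile <- function(drug_id, protein_pool, size) {
  prot <- sample(protein_pool, size)
  scores <- stats::setNames(round(stats::rnorm(size), 6), prot)
  signs <- stats::setNames(sample(c(-1L, 1L), size, replace = TRUE), prot)
  drug_profile(drug_id, scores, signs)
}

# random evidence table over small universes
random_evidence <- function(n_rows, n_drugs = 6, n_proteins = 8) {
  data.frame(
    drug_id = sample(sprintf("D%d", seq_len(n_drugs)), n_rows,
                     replace = TRUE),
    protein_id = sample(sprintf("P%d", seq_len(n_proteins)), n_rows,
                        replace = TRUE),
    prob = round(stats::runif(n_rows, 0.05, 1), 6),
    sign = sample(c(-1L, 1L), n_rows, replace = TRUE),
    source = "rand",
    stringsAsFactors = FALSE)
}

# random undirected edge list without self-loops or duplicates
random_ppi <- function(n_edges, n_proteins = 10) {
  prots <- sprintf("P%d", seq_len(n_proteins))
  pairs <- t(utils::combn(prots, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  data.frame(protein_a = pairs[pick, 1], protein_b = pairs[pick, 2],
             conf = round(stats::runif(length(pick), 0.05, 1), 6),
             stringsAsFactors = FALSE)
}
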