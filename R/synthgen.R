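# Synthetic benchmark generator.  Emits evidence, PPI, signature and
# indication files with planted drug-disease structure: true treatment
# drugs inhibit most of their disease's up-module and activate its
# down-module (so their ranked profiles anti-correlate with the
# signature), and drugs treating the same disease share signed targets
# (so indications cluster on the similarity network).  Degree
# distributions on both sides of the bipartite drug-protein network are
# heavy-tailed: power-law target counts per drug, preferential
# attachment in target choice, and a preferential-attachment PPI.

#' Synthetic benchmark configuration
#'
#' Collects and validates all generator knobs.  Defaults describe a
#' desk-scale benchmark: 50 drugs, 300 proteins, 5 diseases with
#' 10-gene up/down modules sampled from PPI hubs, small treatment
#' cohorts (3 drugs per disease), head-heavy per-drug target counts
#' whose upper tail goes to the indicated (well-studied) drugs, and
#' evidence whose direction agrees with the pair's intended sign 90%
#' of the time.  See the package vignette for the rationale behind
#' each default.
#'
#' @param n_drugs,n_proteins,n_diseases Universe sizes.
#' @param targets_alpha,targets_min,targets_max Truncated power-law on
#'   the number of non-planted targets per drug: P(x) proportional to
#'   `x^-targets_alpha` on `targets_min:targets_max`.
#' @param ppi_attachment Edges added per new node in the
#'   preferential-attachment PPI.
#' @param evidence_per_pair Mean of the shifted-Poisson count of
#'   evidence rows per drug-protein pair (>= 1).
#' @param prob_range Two-element vector in (0,1]: uniform range of
#'   per-evidence confidences and PPI edge confidences.
#' @param sign_consistency Probability in (0.5, 1] that an evidence
#'   item's direction agrees with its pair's intended sign.
#' @param module_size Genes per disease module side (up and down each).
#' @param drugs_per_disease True treatment drugs per disease (the gold
#'   standard holds `n_diseases * drugs_per_disease` pairs before
#'   noise).
#' @param treatment_inhibition_fraction Fraction of a disease's
#'   up-module its true drugs inhibit (and of the down-module they
#'   activate).
#' @param indication_noise Fraction of gold pairs re-assigned to a
#'   random other disease (rounded down).
#' @param planted_evidence_boost Extra mean evidence items for planted
#'   (true-pharmacology) drug-protein pairs on top of
#'   `evidence_per_pair`; genuine interactions are better documented
#'   than incidental ones.
#' @param seed Integer seed; the same seed and config give
#'   byte-identical output files.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 50, n_proteins = 300, n_diseases = 5,
                         targets_alpha = 1.8, targets_min = 1,
                         targets_max = 150, ppi_attachment = 4,
                         evidence_per_pair = 2, prob_range = c(0.4, 0.95),
                         sign_consistency = 0.9, module_size = 10,
                         drugs_per_disease = 3,
                         treatment_inhibition_fraction = 0.7,
                         indication_noise = 0.1,
                         planted_evidence_boost = 3, seed = 1) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_proteins = as.integer(n_proteins),
              n_diseases = as.integer(n_diseases),
              targets_alpha = targets_alpha,
              targets_min = as.integer(targets_min),
              targets_max = as.integer(targets_max),
              ppi_attachment = as.integer(ppi_attachment),
              evidence_per_pair = evidence_per_pair,
              prob_range = as.numeric(prob_range),
              sign_consistency = sign_consistency,
              module_size = as.integer(module_size),
              drugs_per_disease = as.integer(drugs_per_disease),
              treatment_inhibition_fraction = treatment_inhibition_fraction,
              indication_noise = indication_noise,
              planted_evidence_boost = planted_evidence_boost,
              seed = as.integer(seed))
  with(cfg, {
    if (n_drugs < 2L || n_proteins < 2L || n_diseases < 1L) {
      stop("universe sizes must be positive (>= 2 drugs/proteins)",
           call. = FALSE)
    }
    if (2L * module_size * n_diseases > n_proteins) {
      stop("module_size too large: disease modules are disjoint and need ",
           "2 * module_size * n_diseases <= n_proteins", call. = FALSE)
    }
    if (drugs_per_disease * n_diseases > n_drugs) {
      stop("drugs_per_disease * n_diseases exceeds n_drugs", call. = FALSE)
    }
    if (targets_min < 1L || targets_min > targets_max) {
      stop("invalid targets_min/targets_max", call. = FALSE)
    }
    if (targets_alpha <= 0) stop("targets_alpha must be positive",
                                 call. = FALSE)
    if (length(prob_range) != 2L || prob_range[1L] <= 0 ||
        prob_range[2L] > 1 || prob_range[1L] > prob_range[2L]) {
      stop("prob_range must be within (0,1]", call. = FALSE)
    }
    if (sign_consistency <= 0.5 || sign_consistency > 1) {
      stop("sign_consistency must be in (0.5, 1]", call. = FALSE)
    }
    if (treatment_inhibition_fraction < 0 ||
        treatment_inhibition_fraction > 1) {
      stop("treatment_inhibition_fraction must be in [0, 1]", call. = FALSE)
    }
    if (indication_noise < 0 || indication_noise >= 1) {
      stop("indication_noise must be in [0, 1)", call. = FALSE)
    }
    if (evidence_per_pair < 1) stop("evidence_per_pair must be >= 1",
                                    call. = FALSE)
    if (planted_evidence_boost < 0) {
      stop("planted_evidence_boost must be >= 0", call. = FALSE)
    }
    if (ppi_attachment < 1L) stop("ppi_attachment must be >= 1",
                                  call. = FALSE)
  })
  structure(cfg, class = "synth_config")
}

.synth_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

# Disease modules are drawn preferentially by PPI degree: disease genes
# and druggable targets are typically well-connected proteins, and the
# network weight (hence |P-Score|) of a hub exceeds that of a leaf, so
# planted effects dominate the extremes of the ranked profiles.  All
# module genes are drawn in one weighted draw without replacement and
# partitioned randomly over diseases, keeping modules hub-enriched but
# disjoint across diseases (distinct diseases get distinct signatures).
.sample_modules <- function(cfg, proteins, ppi_degree) {
  m <- cfg$module_size
  picked <- sample(proteins, 2L * m * cfg$n_diseases,
                   prob = ppi_degree + 1)
  modules <- vector("list", cfg$n_diseases)
  for (k in seq_len(cfg$n_diseases)) {
    block <- picked[(k - 1L) * 2L * m + seq_len(2L * m)]
    modules[[k]] <- list(up = block[seq_len(m)],
                         down = block[m + seq_len(m)])
  }
  modules
}

# Shared generative core: everything up to and including evidence and
# the PPI is drawn identically for the planted and null variants under
# the same seed, so paired runs have identical marginals.
.synth_core <- function(cfg) {
  set.seed(cfg$seed)
  drugs <- .synth_ids("D", cfg$n_drugs)
  proteins <- .synth_ids("P", cfg$n_proteins)
  diseases <- .synth_ids("DIS", cfg$n_diseases)

  # preferential-attachment PPI over the protein universe (drawn first:
  # disease modules are sampled preferentially from its hubs)
  g <- igraph::sample_pa(cfg$n_proteins, power = 1,
                         m = cfg$ppi_attachment, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- proteins[pmin(el[, 1L], el[, 2L])]
  b <- proteins[pmax(el[, 1L], el[, 2L])]
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key) & a != b
  ppi <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    conf = runif(sum(keep), cfg$prob_range[1L],
                                 cfg$prob_range[2L]),
                    stringsAsFactors = FALSE)
  ord <- order(ppi$protein_a, ppi$protein_b, method = "radix")
  ppi <- ppi[ord, , drop = FALSE]
  rownames(ppi) <- NULL
  ppi_degree <- setNames(rep(0L, cfg$n_proteins), proteins)
  dtab <- table(c(ppi$protein_a, ppi$protein_b))
  ppi_degree[names(dtab)] <- as.integer(dtab)

  modules <- .sample_modules(cfg, proteins, ppi_degree)
  names(modules) <- diseases

  gold_drugs <- sample(drugs, cfg$drugs_per_disease * cfg$n_diseases)
  drug_disease <- setNames(rep(diseases, each = cfg$drugs_per_disease),
                           gold_drugs)
  true_ind <- data.frame(drug_id = gold_drugs,
                         disease_id = unname(drug_disease),
                         stringsAsFactors = FALSE)

  # intended signed targets per drug
  n_planted <- round(cfg$treatment_inhibition_fraction * cfg$module_size)
  vals <- cfg$targets_min:cfg$targets_max
  n_extra <- if (length(vals) == 1L) {
    rep(vals, cfg$n_drugs)
  } else {
    sample(vals, cfg$n_drugs, replace = TRUE,
           prob = vals^(-cfg$targets_alpha))
  }
  # popularity bias: drugs with known indications are the well-studied
  # ones and carry the largest recorded target counts, so the gold
  # drugs take the upper tail of the drawn counts (shuffled among them)
  if (length(gold_drugs) > 0L) {
    ord_counts <- sort(n_extra, decreasing = TRUE)
    gi <- match(gold_drugs, drugs)
    top <- ord_counts[seq_along(gi)]
    rest <- ord_counts[-seq_along(gi)]
    n_extra[gi] <- sample(top, length(top))
    n_extra[-gi] <- sample(rest, length(rest))
  }
  deg <- setNames(rep(0, cfg$n_proteins), proteins)
  targets <- vector("list", cfg$n_drugs)
  names(targets) <- drugs
  planted_flag <- vector("list", cfg$n_drugs)
  for (i in seq_along(drugs)) {
    d <- drugs[i]
    sgn <- integer(0)
    tgt <- character(0)
    if (!is.na(drug_disease[d]) && n_planted > 0L) {
      mod <- modules[[drug_disease[d]]]
      up_t <- sample(mod$up, n_planted)
      down_t <- sample(mod$down, n_planted)
      tgt <- c(up_t, down_t)
      sgn <- c(rep(-1L, n_planted), rep(1L, n_planted))  # inhibit up, activate down
    }
    avail <- setdiff(proteins, tgt)
    extra <- sample(avail, min(n_extra[i], length(avail)),
                    prob = deg[avail] + 1)
    n_pl_i <- length(tgt)
    tgt <- c(tgt, extra)
    sgn <- c(sgn, sample(c(-1L, 1L), length(extra), replace = TRUE))
    targets[[i]] <- setNames(sgn, tgt)
    planted_flag[[i]] <- c(rep(TRUE, n_pl_i),
                           rep(FALSE, length(extra)))
    deg[tgt] <- deg[tgt] + 1
  }

  # evidence rows
  pair_drug <- rep(drugs, vapply(targets, length, integer(1L)))
  pair_prot <- unlist(lapply(targets, names), use.names = FALSE)
  pair_sign <- unlist(targets, use.names = FALSE)
  pair_planted <- unlist(planted_flag, use.names = FALSE)
  # genuine pharmacology is better documented than incidental binding:
  # planted pairs draw extra evidence items on top of the base mean
  ev_mean <- cfg$evidence_per_pair - 1 +
    ifelse(pair_planted, cfg$planted_evidence_boost, 0)
  n_ev <- 1L + rpois(length(pair_drug), ev_mean)
  ev_drug <- rep(pair_drug, n_ev)
  ev_prot <- rep(pair_prot, n_ev)
  ev_intended <- rep(pair_sign, n_ev)
  flip <- rbinom(length(ev_drug), 1L, 1 - cfg$sign_consistency) == 1L
  ev_sign <- ifelse(flip, -ev_intended, ev_intended)
  evidence <- data.frame(
    drug_id = ev_drug, protein_id = ev_prot,
    prob = runif(length(ev_drug), cfg$prob_range[1L], cfg$prob_range[2L]),
    sign = as.integer(ev_sign), source = "synth",
    stringsAsFactors = FALSE)

  list(drugs = drugs, proteins = proteins, diseases = diseases,
       ppi_degree = ppi_degree,
       modules = modules, true_ind = true_ind, targets = targets,
       evidence = evidence, ppi = ppi)
}

.modules_to_signatures <- function(modules) {
  out <- lapply(names(modules), function(d) {
    disease_signature(d, modules[[d]]$up, modules[[d]]$down)
  })
  names(out) <- names(modules)
  out[sort(names(out), method = "radix")]
}

.write_synth <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    evidence = file.path(out_dir, "evidence.tsv"),
    ppi = file.path(out_dir, "ppi.tsv"),
    signatures = file.path(out_dir, "signatures.gmt"),
    indications = file.path(out_dir, "indications.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_evidence(result$evidence, paths$evidence)
  write_ppi(result$ppi, paths$ppi)
  write_signatures(result$signatures, paths$signatures)
  write_indications(result$indications, paths$indications)
  truth <- result$truth
  jsonlite::write_json(
    list(true_indications = truth$true_indications,
         modules = lapply(truth$modules, function(m)
           list(up = m$up, down = m$down)),
         intended_signs = lapply(truth$intended_signs, function(s)
           as.list(s))),
    paths$truth, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  paths
}

#' Generate a synthetic benchmark with planted drug-disease structure
#'
#' Draws the full input suite: signed evidence records, a
#' preferential-attachment PPI, disease signatures, and an indication
#' gold standard, together with the ground truth needed for recovery
#' tests.  True treatment drugs inhibit
#' `treatment_inhibition_fraction` of their disease's up-module and
#' activate the same share of the down-module; drugs treating the same
#' disease therefore share signed targets.
#'
#' @param config A [synth_config].
#' @param out_dir Optional directory; when given, the files
#'   `evidence.tsv`, `ppi.tsv`, `signatures.gmt`, `indications.tsv` and
#'   `truth.json` are written there.
#' @return List with in-memory `evidence`, `ppi`, `signatures`,
#'   `indications` data, `truth` (true indications before noise, disease
#'   modules, intended per-pair signs) and, if written, `paths`.
#' @export
synth_generate <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  core <- .synth_core(config)
  indications <- core$true_ind
  n_noise <- floor(config$indication_noise * nrow(indications))
  if (n_noise > 0L && length(core$diseases) > 1L) {
    pick <- sample(nrow(indications), n_noise)
    for (r in pick) {
      others <- setdiff(core$diseases, indications$disease_id[r])
      indications$disease_id[r] <- sample(others, 1L)
    }
  }
  ord <- order(indications$drug_id, indications$disease_id, method = "radix")
  indications <- indications[ord, , drop = FALSE]
  rownames(indications) <- NULL
  result <- list(
    evidence = core$evidence, ppi = core$ppi,
    signatures = .modules_to_signatures(core$modules),
    indications = indications,
    truth = list(true_indications = core$true_ind,
                 modules = core$modules,
                 intended_signs = core$targets),
    config = config)
  if (!is.null(out_dir)) result$paths <- .write_synth(result, out_dir)
  result
}

#' Null variant: same marginals, planted structure destroyed
#'
#' Re-runs the generative core with the same seed (so drug target sets,
#' evidence rows and the PPI are identical to [synth_generate]) but
#' replaces the disease signatures with freshly drawn random modules of
#' the same sizes and re-assigns each gold-standard drug a uniformly
#' random disease, independent of its targets.  Used to calibrate
#' permutation p-values and the guilt-by-association AUC under the null.
#'
#' @inheritParams synth_generate
#' @return Same shape as [synth_generate].
#' @export
synth_null_variant <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  core <- .synth_core(config)
  # continue the RNG stream past the shared core before breaking
  # structure: signatures become uniform random gene sets of the same
  # sizes, and the gold standard's disease column is permuted across
  # drugs (disease multiplicities are preserved)
  null_modules <- .sample_modules(config, core$proteins,
                                  rep(0L, length(core$proteins)))
  names(null_modules) <- core$diseases
  indications <- core$true_ind
  indications$disease_id <- sample(indications$disease_id)
  ord <- order(indications$drug_id, indications$disease_id, method = "radix")
  indications <- indications[ord, , drop = FALSE]
  rownames(indications) <- NULL
  result <- list(
    evidence = core$evidence, ppi = core$ppi,
    signatures = .modules_to_signatures(null_modules),
    indications = indications,
    truth = list(true_indications = indications,
                 modules = null_modules,
                 intended_signs = core$targets),
    config = config)
  if (!is.null(out_dir)) result$paths <- .write_synth(result, out_dir)
  result
}

#' Read a flat key:value synthetic-benchmark config file
#'
#' Each non-comment line is `key: value`, with keys matching the
#' [synth_config] arguments; `prob_range` takes two comma-separated
#' values.  Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @param seed Optional seed overriding the file's value.
#' @return A [synth_config].
#' @export
read_synth_config <- function(path, seed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1L)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]],
                     call. = FALSE)
  keys <- vapply(kv, `[[`, character(1L), 2L)
  vals <- vapply(kv, `[[`, character(1L), 3L)
  known <- names(formals(synth_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- lapply(seq_along(keys), function(i) {
    as.numeric(strsplit(vals[i], ",", fixed = TRUE)[[1L]])
  })
  names(args) <- keys
  if (!is.null(seed)) args$seed <- seed
  do.call(synth_config, args)
}
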