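# Overall genome relatedness indices: AGIOS (mean nucleotide identity of
# orthologous ORFs), AAI (mean protein identity), fragment-based digital
# DDH, and basic genome statistics.

#' Basic genome statistics
#'
#' @param g A `genome_record`.
#' @return One-row tibble: `strain_id`, `total_bp`, `gc_percent` (N excluded
#'   from the denominator), `n_scaffolds`, `n_genes`, `coding_bp` (sum of
#'   annotated gene spans, not de-duplicated; flagged with a warning if it
#'   exceeds `total_bp`).
#' @export
genome_stats <- function(g) {
  stopifnot(inherits(g, "genome_record"))
  freq <- Biostrings::letterFrequency(Biostrings::BStringSet(g$scaffolds$seq),
                                      letters = c("A", "C", "G", "T"))
  acgt <- colSums(freq)
  coding <- sum(g$genes$end - g$genes$start + 1L)
  total <- sum(nchar(g$scaffolds$seq))
  if (coding > total) warn("coding_bp exceeds total_bp (overlapping annotations)")
  tibble(strain_id = g$strain_id,
         total_bp = total,
         gc_percent = 100 * (acgt[["C"]] + acgt[["G"]]) / sum(acgt),
         n_scaffolds = nrow(g$scaffolds),
         n_genes = nrow(g$genes),
         coding_bp = coding)
}

#' @method glance genome_record
#' @export
glance.genome_record <- function(x, ...) genome_stats(x)

#' Average genomic identity of orthologous sequences (AGIOS)
#'
#' The unweighted arithmetic mean of the per-pair nucleotide identities of
#' the globally aligned orthologous ORFs, as a percentage. A length-weighted
#' variant is available but off by default.
#'
#' @param table An `ortholog_table` with nucleotide identities.
#' @param weighted Weight pairs by their alignment length instead of the
#'   plain mean over ORFs (default `FALSE`, the plain reading of a mean
#'   percentage among orthologous ORFs).
#' @return Percentage in 0-100.
#' @export
agios <- function(table, weighted = FALSE) {
  keep <- !is.na(table$nucleotide_identity)
  vals <- table$nucleotide_identity[keep]
  if (length(vals) == 0L) abort("no orthologs with nucleotide identity")
  if (weighted) {
    w <- table$alignment_length[keep]
    return(100 * sum(vals * w) / sum(w))
  }
  100 * mean(vals)
}

#' Average amino acid identity (AAI)
#'
#' The unweighted mean of the per-pair protein identities over the ortholog
#' table, as a percentage.
#'
#' @param table An `ortholog_table`.
#' @return Percentage in 0-100.
#' @export
aai <- function(table) {
  vals <- table$protein_identity
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) abort("no orthologs")
  100 * mean(vals)
}

#' Digital DDH logistic model
#'
#' Maps the fragment-alignment distance `d` (one minus the fraction of
#' identical positions over total HSP length) to a dDDH percentage through
#' `100 / (1 + exp(slope * (d - midpoint)))`. The default coefficients place
#' the 70% dDDH species boundary near d = 0.05, consistent with the
#' conventional 95-96% ANI boundary, give the identity limit (d = 0) a
#' value above 99% and unrelated genomes the lower plateau. The version tag
#' is recorded in every comparison result.
#'
#' @param midpoint Distance at which the logistic crosses 50% (default
#'   0.06).
#' @param slope Steepness of the logistic (default 80).
#' @param version Version tag recorded with results.
#' @return A `ddh_model` list.
#' @export
ddh_model <- function(midpoint = 0.06, slope = 80, version = "ogri-logistic-1") {
  structure(list(midpoint = midpoint, slope = slope, version = version),
            class = "ddh_model")
}

ddh_from_distance <- function(d, model) {
  100 / (1 + exp(model$slope * (d - model$midpoint)))
}

#' Fragment-based digital DNA-DNA hybridization
#'
#' Cuts the scaffolds of genome `a` into consecutive fragments of
#' `fragment_bp`, maps each fragment against genome `b` with the seeded
#' local search (both strands), and over the fragments with a qualifying
#' HSP computes the distance `d = 1 - (identical positions / total HSP
#' length)`, transformed to a dDDH percentage by the logistic `model`.
#'
#' @param a,b `genome_record`s (or sequence tibbles of scaffolds).
#' @param fragment_bp Fragment length (default 1020).
#' @param model A [ddh_model()].
#' @param k,band Seeding parameters passed to [local_search()].
#' @param min_hsp_score Minimum local-alignment score for a fragment hit to
#'   enter the statistic (default 50); filters spurious short seeded hits
#'   between unrelated genomes.
#' @param min_fragment_bp Trailing fragments shorter than this are dropped
#'   (default 200).
#' @return dDDH percentage (0-100) with attributes `distance`,
#'   `n_fragments`, `n_fragments_hit` and `model_version`. No mapped
#'   fragment gives 0 with a warning.
#' @export
fragment_ddh <- function(a, b, fragment_bp = 1020, model = ddh_model(),
                         k = 11, band = 32, min_hsp_score = 50,
                         min_fragment_bp = 200) {
  scaf_a <- if (inherits(a, "genome_record")) a$scaffolds else a
  scaf_b <- if (inherits(b, "genome_record")) b$scaffolds else b
  stopifnot(nrow(scaf_a) > 0L, nrow(scaf_b) > 0L)
  # concatenate target scaffolds; the N spacer cannot seed across junctions
  target <- paste(scaf_b$seq, collapse = strrep("N", k + 39L))
  idx <- build_kmer_index(target, k)
  fragments <- unlist(map(scaf_a$seq, function(s) {
    starts <- seq.int(1L, nchar(s), by = fragment_bp)
    frags <- substring(s, starts, pmin(starts + fragment_bp - 1L, nchar(s)))
    frags[nchar(frags) >= min_fragment_bp]
  }))
  ident_sum <- 0
  len_sum <- 0
  n_hit <- 0L
  for (frag in fragments) {
    hits <- local_search(frag, target, k = k, band = band,
                         min_score = min_hsp_score, max_clusters = 5,
                         .index = idx)
    if (nrow(hits) == 0L) next
    best <- hits[1, ]
    ident_sum <- ident_sum + best$identity * best$aligned_columns
    len_sum <- len_sum + best$aligned_columns
    n_hit <- n_hit + 1L
  }
  if (n_hit == 0L) {
    warn("no fragment mapped; dDDH reported as 0")
    return(structure(0, distance = NA_real_, n_fragments = length(fragments),
                     n_fragments_hit = 0L, model_version = model$version))
  }
  d <- 1 - ident_sum / len_sum
  structure(ddh_from_distance(d, model), distance = d,
            n_fragments = length(fragments), n_fragments_hit = n_hit,
            model_version = model$version)
}

#' Compare two annotated genomes
#'
#' Runs the full pairwise comparison: reciprocal-best-hit orthology, AGIOS,
#' AAI and fragment-based dDDH.
#'
#' @param a,b `genome_record`s.
#' @param min_identity,min_coverage Ortholog thresholds (defaults 0.30,
#'   0.70).
#' @param fragment_bp dDDH fragment length (default 1020).
#' @param model [ddh_model()] for the dDDH mapping.
#' @return A `comparison_result`: one-row tibble with `strain_a`,
#'   `strain_b`, `n_orthologs`, `agios`, `aai`, `ddh`, `ddh_distance`,
#'   `ddh_model_version`.
#' @export
compare_genomes <- function(a, b, min_identity = 0.30, min_coverage = 0.70,
                            fragment_bp = 1020, model = ddh_model()) {
  ot <- find_orthologs(a, b, min_identity, min_coverage)
  ddh <- fragment_ddh(a, b, fragment_bp = fragment_bp, model = model)
  ddh_distance <- attr(ddh, "distance")
  ddh_version <- attr(ddh, "model_version")
  res <- tibble(strain_a = a$strain_id, strain_b = b$strain_id,
                n_orthologs = nrow(ot),
                agios = if (nrow(ot)) agios(ot) else NA_real_,
                aai = if (nrow(ot)) aai(ot) else NA_real_,
                ddh = as.numeric(ddh),
                ddh_distance = ddh_distance,
                ddh_model_version = ddh_version)
  class(res) <- c("comparison_result", class(res))
  res
}

#' @method tidy comparison_result
#' @export
tidy.comparison_result <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, c("n_orthologs", "agios", "aai", "ddh")],
                      dplyr::everything(),
                      names_to = "metric", values_to = "value") %>%
    mutate(strain_a = x$strain_a, strain_b = x$strain_b, .before = 1)
}

#' @method glance comparison_result
#' @export
glance.comparison_result <- function(x, ...) as_tibble(x)

#' Multi-genome comparison matrix
#'
#' Compares every genome pair and lays the results out in the conventional
#' square-table form: numbers of orthologous proteins in the upper-right
#' triangle, AGIOS percentages in the lower-left, protein counts on the
#' diagonal.
#'
#' @param genomes List of `genome_record`s.
#' @param ... Passed to [compare_genomes()].
#' @return List with `pairs` (tibble of all `comparison_result` rows) and
#'   `matrix` (character matrix in the table layout).
#' @export
comparison_matrix <- function(genomes, ...) {
  n <- length(genomes)
  stopifnot(n >= 2L)
  ids <- map_chr(genomes, "strain_id")
  rows <- list()
  mat <- matrix("", n, n, dimnames = list(ids, ids))
  diag(mat) <- map_chr(genomes, function(g) as.character(nrow(g$proteins)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cr <- compare_genomes(genomes[[i]], genomes[[j]], ...)
      rows[[length(rows) + 1L]] <- cr
      mat[i, j] <- as.character(cr$n_orthologs)
      mat[j, i] <- sprintf("%.1f", cr$agios)
    }
  }
  list(pairs = bind_rows(rows), matrix = mat)
}
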