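# Reciprocal-best-hit orthology between two proteomes: an exact-alignment
# reimplementation of the pairwise ortholog detection step, with the
# identity (30%) and coverage (0.7) floors applied to global alignments of
# k-mer-prefiltered candidate pairs.

proteome_tbl <- function(x) {
  if (inherits(x, "genome_record")) return(x$proteins)
  stopifnot(is.data.frame(x))
  tbl <- as_tibble(x)
  if (!"gene_id" %in% names(tbl) && "id" %in% names(tbl)) {
    tbl <- rename(tbl, gene_id = "id")
  }
  stopifnot(all(c("gene_id", "seq") %in% names(tbl)))
  tbl
}

protein_kmers <- function(tbl, kmer) {
  res <- map2(tbl$gene_id, tbl$seq, function(id, s) {
    n <- nchar(s)
    if (n < kmer) return(NULL)
    tibble(gene_id = id,
           kmer = unique(substring(s, 1:(n - kmer + 1L), kmer:n)))
  })
  bind_rows(res)
}

#' Candidate ortholog pairs by shared protein k-mers
#'
#' A deterministic prefilter replacing heuristic database seeding: every
#' cross-proteome pair sharing at least `min_shared` distinct exact k-mers
#' becomes a candidate for alignment. On small inputs the candidate set is a
#' superset of all pairs passing the downstream identity floor.
#'
#' @param proteome_a,proteome_b Protein tibbles (`gene_id`, `seq`) or
#'   `genome_record`s.
#' @param kmer K-mer length (default 4).
#' @param min_shared Minimum distinct shared k-mers (default 2).
#' @return Tibble with `id_a`, `id_b` and `shared_kmers`.
#' @export
candidate_pairs <- function(proteome_a, proteome_b, kmer = 4, min_shared = 2) {
  pa <- proteome_tbl(proteome_a); pb <- proteome_tbl(proteome_b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    return(tibble(id_a = character(), id_b = character(), shared_kmers = integer()))
  }
  ka <- protein_kmers(pa, kmer); kb <- protein_kmers(pb, kmer)
  inner_join(ka, kb, by = "kmer", suffix = c("_a", "_b"),
             relationship = "many-to-many") %>%
    count(.data$gene_id_a, .data$gene_id_b, name = "shared_kmers") %>%
    filter(.data$shared_kmers >= min_shared) %>%
    rename(id_a = "gene_id_a", id_b = "gene_id_b") %>%
    arrange(.data$id_a, .data$id_b)
}

# Count-based alignment statistics for one batch of queries against one
# subject: nmatch/nmismatch give matches and both-non-gap columns without
# materialising the gapped strings (which dominates runtime otherwise).
align_stats_batch <- function(queries, subject, scoring) {
  mat <- scheme_matrix(scoring)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  matches <- Biostrings::nmatch(aln)
  tibble(matches = matches,
         aligned_columns = matches + Biostrings::nmismatch(aln),
         len_q = nchar(queries), len_t = nchar(subject),
         score = Biostrings::score(aln))
}

# Fast nucleotide identity over aligned columns for one CDS pair.
nuc_identity_fast <- function(a, b, scoring) {
  mat <- scheme_matrix(scoring)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  matches <- Biostrings::nmatch(aln)
  cols <- matches + Biostrings::nmismatch(aln)
  c(identity = matches / cols, length = cols)
}

#' Best hits from one proteome into another
#'
#' Globally aligns every candidate pair and keeps, per query, the single
#' highest-scoring hit among those with identity at or above `min_identity`
#' and coverage of both sequences at or above `min_coverage` (the thresholds
#' that stand in for a database-search E-value cutoff). Score ties go to the
#' lexicographically smallest target id.
#'
#' @param proteome_a,proteome_b Protein tibbles or `genome_record`s; hits
#'   run from a into b.
#' @param min_identity Identity floor on aligned columns (default 0.30).
#' @param min_coverage Coverage floor, applied to both sequences
#'   (default 0.70).
#' @param candidates Optional precomputed [candidate_pairs()] table.
#' @param scoring Protein [scoring_scheme()] (default BLOSUM62, gap
#'   -10/-0.5).
#' @return Tibble of hit records: `query_id`, `target_id`, `identity`,
#'   `coverage_query`, `coverage_target`, `score`.
#' @export
best_hits <- function(proteome_a, proteome_b, min_identity = 0.30,
                      min_coverage = 0.70, candidates = NULL,
                      scoring = scoring_scheme("protein")) {
  pa <- proteome_tbl(proteome_a); pb <- proteome_tbl(proteome_b)
  empty <- tibble(query_id = character(), target_id = character(),
                  identity = numeric(), coverage_query = numeric(),
                  coverage_target = numeric(), score = numeric())
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    warn("empty proteome: no hits")
    return(empty)
  }
  if (is.null(candidates)) candidates <- candidate_pairs(pa, pb)
  if (nrow(candidates) == 0L) return(empty)
  seq_a <- setNames(pa$seq, pa$gene_id)
  seq_b <- setNames(pb$seq, pb$gene_id)
  hits <- candidates %>%
    group_by(.data$id_b) %>%
    group_split_stats(seq_a, seq_b, scoring) %>%
    mutate(identity = .data$matches / .data$aligned_columns,
           coverage_query = .data$aligned_columns / .data$len_q,
           coverage_target = .data$aligned_columns / .data$len_t) %>%
    filter(.data$identity >= min_identity,
           .data$coverage_query >= min_coverage,
           .data$coverage_target >= min_coverage) %>%
    select(query_id = "id_a", target_id = "id_b", "identity",
           "coverage_query", "coverage_target", "score")
  hits %>%
    arrange(.data$query_id, desc(.data$score), .data$target_id) %>%
    group_by(.data$query_id) %>%
    slice(1) %>%
    ungroup()
}

# one vectorized alignment call per distinct target
group_split_stats <- function(grouped, seq_a, seq_b, scoring) {
  parts <- dplyr::group_split(grouped)
  bind_rows(map(parts, function(g) {
    st <- align_stats_batch(unname(seq_a[g$id_a]), seq_b[g$id_b[1]], scoring)
    bind_cols(g[, c("id_a", "id_b")], st)
  }))
}

#' Reciprocal best hits and the ortholog table
#'
#' Orthologs are the pairs (x, y) where y is x's best hit and x is y's best
#' hit. For each pair the corresponding CDS are globally aligned and the
#' nucleotide identity recorded (the AGIOS input); a gene without a CDS
#' keeps the pair with `nucleotide_identity` `NA` and a warning.
#'
#' @param hits_ab,hits_ba [best_hits()] tables for the two directions.
#' @param genome_a,genome_b `genome_record`s (for CDS lookup); omit both to
#'   skip nucleotide identities.
#' @param scoring Nucleotide [scoring_scheme()] for the CDS alignments.
#' @return An `ortholog_table` tibble: `gene_id_a`, `gene_id_b`,
#'   `protein_identity`, `nucleotide_identity`; attributes `strain_a`,
#'   `strain_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, genome_a = NULL,
                                 genome_b = NULL,
                                 scoring = default_nuc_scheme()) {
  ab <- select(hits_ab, gene_id_a = "query_id", gene_id_b = "target_id",
               protein_identity = "identity")
  ba <- select(hits_ba, gene_id_b = "query_id", gene_id_a = "target_id")
  pairs <- inner_join(ab, ba, by = c("gene_id_a", "gene_id_b")) %>%
    arrange(.data$gene_id_a)
  pairs$nucleotide_identity <- NA_real_
  pairs$alignment_length <- NA_integer_
  if (!is.null(genome_a) && !is.null(genome_b) && nrow(pairs) > 0L) {
    cds_a <- setNames(genome_a$cds$seq, genome_a$cds$gene_id)
    cds_b <- setNames(genome_b$cds$seq, genome_b$cds$gene_id)
    missing_cds <- !(pairs$gene_id_a %in% names(cds_a)) |
      !(pairs$gene_id_b %in% names(cds_b))
    if (any(missing_cds)) {
      warn(paste0("no CDS for pair(s): ",
                  paste(pairs$gene_id_a[missing_cds], collapse = ", "),
                  "; nucleotide identity left NA"))
    }
    for (i in which(!missing_cds)) {
      st <- nuc_identity_fast(cds_a[[pairs$gene_id_a[i]]],
                              cds_b[[pairs$gene_id_b[i]]], scoring)
      pairs$nucleotide_identity[i] <- st[["identity"]]
      pairs$alignment_length[i] <- as.integer(st[["length"]])
    }
  }
  structure(pairs,
            strain_a = if (!is.null(genome_a)) genome_a$strain_id else NA_character_,
            strain_b = if (!is.null(genome_b)) genome_b$strain_id else NA_character_,
            class = c("ortholog_table", class(pairs)))
}

#' Find orthologs between two annotated genomes
#'
#' Convenience wrapper: candidate pairs and best hits in both directions,
#' then [reciprocal_best_hits()] with nucleotide identities.
#'
#' @param genome_a,genome_b `genome_record`s.
#' @inheritParams best_hits
#' @return An `ortholog_table` (see [reciprocal_best_hits()]).
#' @export
find_orthologs <- function(genome_a, genome_b, min_identity = 0.30,
                           min_coverage = 0.70,
                           scoring = scoring_scheme("protein")) {
  cand <- candidate_pairs(genome_a, genome_b)
  hits_ab <- best_hits(genome_a, genome_b, min_identity, min_coverage,
                       candidates = cand, scoring = scoring)
  cand_rev <- tibble(id_a = cand$id_b, id_b = cand$id_a,
                     shared_kmers = cand$shared_kmers) %>%
    arrange(.data$id_a, .data$id_b)
  hits_ba <- best_hits(genome_b, genome_a, min_identity, min_coverage,
                       candidates = cand_rev, scoring = scoring)
  reciprocal_best_hits(hits_ab, hits_ba, genome_a, genome_b)
}

#' Write an ortholog table as TSV
#'
#' @param ot An `ortholog_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(ot, path) {
  write.table(as.data.frame(ot), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
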