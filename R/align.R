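# Pairwise alignment primitives: global Needleman-Wunsch under affine gaps
# (the AGIOS engine) and a seeded, banded local search for dDDH fragments.
# The dynamic programming itself is Biostrings::pairwiseAlignment; this
# module owns the scoring conventions, identity/coverage bookkeeping and the
# k-mer seeding strategy.

#' Alignment scoring scheme
#'
#' Affine-gap scoring: a gap of length L costs `gap_open + L * gap_extend`
#' (both penalties non-positive). Nucleotide schemes use a match/mismatch
#' pair; protein schemes a named substitution matrix (default BLOSUM62).
#' Defaults mirror common EMBOSS-needle practice; ambiguity characters
#' (N/X) always score as mismatches and never count as identities.
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param match,mismatch Match/mismatch scores (nucleotide schemes).
#' @param substitution_matrix Name of a protein matrix (e.g. `"BLOSUM62"`),
#'   or a numeric matrix.
#' @param gap_open,gap_extend Non-positive gap penalties.
#' @return A `scoring_scheme` list.
#' @export
#' @examples
#' scoring_scheme("nucleotide", match = 1, mismatch = -1)
scoring_scheme <- function(alphabet = c("nucleotide", "protein"),
                           match = 1, mismatch = -1,
                           substitution_matrix = if (alphabet == "protein") "BLOSUM62" else NULL,
                           gap_open = -10, gap_extend = -0.5) {
  alphabet <- match.arg(alphabet)
  if (gap_open > 0 || gap_extend > 0) abort("gap penalties must be non-positive")
  if (alphabet == "protein" && is.null(substitution_matrix)) {
    abort("protein schemes need a substitution matrix")
  }
  structure(list(alphabet = alphabet, match = match, mismatch = mismatch,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

default_nuc_scheme <- function() {
  scoring_scheme("nucleotide", match = 1, mismatch = -1,
                 gap_open = -10, gap_extend = -0.5)
}

default_local_scheme <- function() {
  scoring_scheme("nucleotide", match = 1, mismatch = -1,
                 gap_open = -5, gap_extend = -2)
}

.matrix_cache <- new.env(parent = emptyenv())

# Substitution matrix for a scheme, honouring the rule that ambiguity codes
# never match anything (including themselves). Named protein matrices and
# nucleotide match/mismatch matrices are cached per session.
scheme_matrix <- function(s) {
  if (s$alphabet == "protein") {
    m <- s$substitution_matrix
    if (is.character(m)) {
      key <- paste0("protein_", m)
      if (is.null(.matrix_cache[[key]])) {
        e <- new.env()
        utils::data(list = m, package = "Biostrings", envir = e)
        .matrix_cache[[key]] <- get(m, envir = e)
      }
      m <- .matrix_cache[[key]]
    }
    return(m)
  }
  key <- paste0("nuc_", s$match, "_", s$mismatch)
  if (is.null(.matrix_cache[[key]])) {
    m <- matrix(s$mismatch, length(NUC_CHARS), length(NUC_CHARS),
                dimnames = list(NUC_CHARS, NUC_CHARS))
    for (u in c("A", "C", "G", "T")) m[u, u] <- s$match
    .matrix_cache[[key]] <- m
  }
  .matrix_cache[[key]]
}

residue_match <- function(chars_a, chars_b, alphabet) {
  ambiguous <- if (alphabet == "nucleotide") {
    !(chars_a %in% c("A", "C", "G", "T")) | !(chars_b %in% c("A", "C", "G", "T"))
  } else {
    chars_a %in% c("X", "-") | chars_b %in% c("X", "-")
  }
  chars_a == chars_b & !ambiguous & chars_a != "-"
}

new_pairwise_alignment <- function(a_gapped, b_gapped, score, alphabet) {
  ca <- strsplit(a_gapped, "")[[1]]
  cb <- strsplit(b_gapped, "")[[1]]
  both <- ca != "-" & cb != "-"
  matches <- sum(residue_match(ca, cb, alphabet) & both)
  aligned_columns <- sum(both)
  len_a <- sum(ca != "-"); len_b <- sum(cb != "-")
  structure(list(a_gapped = a_gapped, b_gapped = b_gapped, score = score,
                 identity_fraction = if (aligned_columns > 0) matches / aligned_columns else NA_real_,
                 matches = matches, aligned_columns = aligned_columns,
                 coverage_a = aligned_columns / len_a,
                 coverage_b = aligned_columns / len_b,
                 alphabet = alphabet),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.4g, identity %.2f%%, %d aligned columns\n",
              x$score, 100 * x$identity_fraction, x$aligned_columns))
  if (nchar(x$a_gapped) <= 80) cat(x$a_gapped, "\n", x$b_gapped, "\n", sep = "")
  invisible(x)
}

#' @method tidy pairwise_alignment
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble(score = x$score, identity_fraction = x$identity_fraction,
         aligned_columns = x$aligned_columns,
         coverage_a = x$coverage_a, coverage_b = x$coverage_b)
}

seq_chr <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x$seq
  } else {
    toupper(as.character(x))
  }
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' Optimal global alignment under affine gap scoring, used for the AGIOS
#' nucleotide identities and the protein identities behind AAI and the
#' best-hit search. Tie-breaking among co-optimal alignments is
#' deterministic (the score is unique in any case).
#'
#' @param a,b Sequences: character strings or one-row sequence tibbles of the
#'   same alphabet.
#' @param scoring A [scoring_scheme()]; defaults to match/mismatch +1/-1 for
#'   nucleotides.
#' @return A `pairwise_alignment`: gapped strings, score, identity fraction,
#'   aligned columns and per-sequence coverage.
#' @export
#' @examples
#' global_align("ACGT", "AGT")
global_align <- function(a, b, scoring = default_nuc_scheme()) {
  sa <- seq_chr(a); sb <- seq_chr(b)
  if (!nzchar(sa) || !nzchar(sb)) abort("cannot align empty sequences")
  if (is.data.frame(a) && is.data.frame(b) && !identical(a$alphabet, b$alphabet)) {
    abort("alphabet mismatch between sequences")
  }
  mat <- scheme_matrix(scoring)
  cls <- if (scoring$alphabet == "protein") Biostrings::AAString else Biostrings::BString
  aln <- Biostrings::pairwiseAlignment(
    cls(sa), cls(sb), type = "global", substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  new_pairwise_alignment(as.character(Biostrings::alignedPattern(aln)),
                         as.character(Biostrings::alignedSubject(aln)),
                         Biostrings::score(aln), scoring$alphabet)
}

#' Percent identity of a pairwise alignment
#'
#' @param aln A `pairwise_alignment`.
#' @param mode Denominator: `"aligned_columns"` (columns where both
#'   sequences have a residue; the default) or `"shorter_seq"` (length of
#'   the shorter input). Ambiguity characters never count as matches.
#' @return Percentage in 0-100.
#' @export
percent_identity <- function(aln, mode = c("aligned_columns", "shorter_seq")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "pairwise_alignment"))
  denom <- if (mode == "aligned_columns") {
    aln$aligned_columns
  } else {
    min(sum(strsplit(aln$a_gapped, "")[[1]] != "-"),
        sum(strsplit(aln$b_gapped, "")[[1]] != "-"))
  }
  if (denom == 0) abort("zero denominator: no aligned columns")
  100 * aln$matches / denom
}

# 2-bit k-mer codes over A/C/G/T; windows containing any other character
# (N, IUPAC codes) get NA and never seed.
kmer_codes <- function(seq, k) {
  x <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(x)
  if (n < k) return(numeric(0))
  code <- numeric(n - k + 1L)
  for (j in seq_len(k)) {
    code <- code * 4 + x[j:(n - k + j)]
  }
  code
}

build_kmer_index <- function(target, k) {
  codes <- kmer_codes(target, k)
  idx <- data.table::data.table(code = codes, tpos = seq_along(codes))
  idx <- idx[!is.na(idx$code)]
  data.table::setkey(idx, code)
  idx
}

empty_hits <- function() {
  tibble(strand = character(), score = numeric(), identity = numeric(),
         aligned_columns = integer(),
         query_start = integer(), query_end = integer(),
         target_start = integer(), target_end = integer(),
         n_seeds = integer())
}

local_hits_one_strand <- function(query, target, idx, k, band, scoring,
                                  strand, max_clusters) {
  qcodes <- kmer_codes(query, k)
  q <- data.table::data.table(code = qcodes, qpos = seq_along(qcodes))
  q <- q[!is.na(q$code)]
  if (nrow(q) == 0L) return(empty_hits())
  seeds <- idx[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(seeds) == 0L) return(empty_hits())
  seeds$diag <- seeds$tpos - seeds$qpos
  seeds <- seeds[order(seeds$diag), ]
  cluster <- cumsum(c(1L, diff(seeds$diag) > band))
  groups <- split(seeds, cluster)
  groups <- groups[order(-vapply(groups, nrow, integer(1)))]
  groups <- head(groups, max_clusters)
  qlen <- nchar(query); tlen <- nchar(target)
  mat <- scheme_matrix(scoring)
  out <- map(groups, function(g) {
    wstart <- max(1L, min(g$diag) + 1L - band)
    wend <- min(tlen, max(g$diag) + qlen + band + k)
    window <- substr(target, wstart, wend)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::BString(query), Biostrings::BString(window), type = "local",
      substitutionMatrix = mat,
      gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
    matches <- Biostrings::nmatch(aln)
    cols <- matches + Biostrings::nmismatch(aln)
    qr <- Biostrings::pattern(aln); tr <- Biostrings::subject(aln)
    tibble(strand = strand, score = Biostrings::score(aln),
           identity = if (cols > 0) matches / cols else NA_real_,
           aligned_columns = as.integer(cols),
           query_start = BiocGenerics::start(qr), query_end = BiocGenerics::end(qr),
           target_start = wstart - 1L + BiocGenerics::start(tr),
           target_end = wstart - 1L + BiocGenerics::end(tr),
           n_seeds = nrow(g))
  })
  bind_rows(out)
}

#' Seeded local search (HSP-like hits)
#'
#' Finds local alignments of a nucleotide query in a target by anchoring
#' banded local extensions on shared exact k-mers, the workhorse of the
#' fragment-based digital DDH. Both strands are searched; overlapping hits
#' are merged keeping the higher score; hits are sorted by score.
#'
#' @param query,target Nucleotide sequences (strings or one-row tibbles).
#' @param k Seed k-mer size (default 11).
#' @param band Diagonal band width for clustering seeds (default 32).
#' @param scoring A nucleotide [scoring_scheme()] (default +1/-1, gap
#'   -5/-2).
#' @param both_strands Also search the reverse complement of the query.
#' @param min_score Drop hits scoring below this (default 0 keeps all).
#' @param max_clusters Extend at most this many seed clusters per strand.
#' @param .index Optional precomputed target index from an internal call
#'   (used by [fragment_ddh()] to reuse one index across fragments).
#' @return Tibble of hits: strand, score, identity, aligned_columns,
#'   query/target coordinates (1-based, query coordinates on the original
#'   query orientation), and the number of supporting seeds.
#' @export
local_search <- function(query, target, k = 11, band = 32,
                         scoring = default_local_scheme(),
                         both_strands = TRUE, min_score = 0,
                         max_clusters = 25, .index = NULL) {
  q <- seq_chr(query); t <- seq_chr(target)
  if (k > nchar(q)) {
    warn("k exceeds query length; no hits")
    return(empty_hits())
  }
  idx <- if (is.null(.index)) build_kmer_index(t, k) else .index
  hits <- local_hits_one_strand(q, t, idx, k, band, scoring, "+", max_clusters)
  if (both_strands) {
    rc <- reverse_complement(q)
    h2 <- local_hits_one_strand(rc, t, idx, k, band, scoring, "-", max_clusters)
    if (nrow(h2)) {
      # report query coordinates on the original orientation
      qlen <- nchar(q)
      h2 <- mutate(h2, qs = qlen - .data$query_end + 1L,
                   qe = qlen - .data$query_start + 1L,
                   query_start = .data$qs, query_end = .data$qe) %>%
        select(-"qs", -"qe")
    }
    hits <- bind_rows(hits, h2)
  }
  hits <- filter(hits, .data$score >= min_score)
  if (nrow(hits) <= 1L) return(arrange(hits, desc(.data$score)))
  hits <- arrange(hits, desc(.data$score), .data$target_start)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    overlap <- hits$target_start[i] <= hits$target_end[prior] &
      hits$target_end[i] >= hits$target_start[prior]
    if (any(overlap)) keep[i] <- FALSE
  }
  hits[keep, ]
}
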