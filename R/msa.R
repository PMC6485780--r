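# Multiple-alignment handling: site-coverage column filtering and Kimura
# 2-parameter distances under pairwise deletion, the distance stage feeding
# the neighbor-joining tree.

#' Build a multiple-alignment table
#'
#' An alignment is a tibble with columns `taxon` and `seq`, all rows of
#' equal (gapped) length and unique taxa.
#'
#' @param taxon Character vector of taxon labels.
#' @param seq Character vector of equal-length gapped sequences.
#' @return An alignment tibble.
#' @export
msa_tbl <- function(taxon, seq) {
  stopifnot(length(taxon) == length(seq))
  seq <- toupper(seq)
  if (anyDuplicated(taxon)) abort("taxa must be unique")
  if (length(unique(nchar(seq))) > 1L) abort("alignment rows differ in length")
  tibble(taxon = as.character(taxon), seq = seq)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (equal-length, gapped) FASTA file.
#' @return An alignment tibble (`taxon`, `seq`).
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path, "nucleotide")
  msa_tbl(seqs$id, seqs$seq)
}

msa_char_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seq, ""))
  rownames(m) <- msa$taxon
  m
}

#' Filter alignment columns by site coverage
#'
#' Retains exactly the columns where the fraction of taxa carrying an
#' unambiguous base (not a gap, not N or another IUPAC ambiguity code) is at
#' least `min_coverage`. This is the "partial deletion, 95% site coverage"
#' filter of MEGA: one global column filter, after which remaining
#' gap/ambiguous cells are handled per pair (pairwise deletion).
#'
#' @param msa An alignment tibble.
#' @param min_coverage Minimum fraction of covered rows per column
#'   (default 0.95).
#' @return The filtered alignment tibble (row order preserved).
#' @export
coverage_filter <- function(msa, min_coverage = 0.95) {
  m <- msa_char_matrix(msa)
  covered <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  keep <- colMeans(covered) >= min_coverage
  if (!any(keep)) {
    abort("coverage filter removed every column; lower min_coverage")
  }
  msa_tbl(msa$taxon,
          unname(apply(m[, keep, drop = FALSE], 1, paste, collapse = "")))
}

#' Transition/transversion counts for a pair of aligned taxa
#'
#' Pairwise deletion: columns where either row carries a gap or an ambiguity
#' code are skipped. Transitions are A<->G and C<->T; every other differing
#' pair is a transversion.
#'
#' @param msa An alignment tibble.
#' @param taxon_i,taxon_j Taxon labels present in `msa`.
#' @return A `pair_counts` list: `P` (transition proportion), `Q`
#'   (transversion proportion), `n_sites` (compared sites).
#' @export
pair_counts <- function(msa, taxon_i, taxon_j) {
  stopifnot(taxon_i %in% msa$taxon, taxon_j %in% msa$taxon)
  a <- strsplit(msa$seq[msa$taxon == taxon_i], "")[[1]]
  b <- strsplit(msa$seq[msa$taxon == taxon_j], "")[[1]]
  counts_from_chars(a, b)
}

counts_from_chars <- function(a, b) {
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  n <- sum(use)
  if (n == 0L) abort("no comparable sites for this pair")
  a <- a[use]; b <- b[use]
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                  (a == "C" & b == "T") | (a == "T" & b == "C"))
  structure(list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n_sites = n),
            class = "pair_counts")
}

#' Kimura 2-parameter distance
#'
#' Closed form `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` from the
#' transition proportion P and transversion proportion Q. Saturated pairs
#' (a non-positive log argument) are reported as `Inf` with a warning.
#'
#' @param P A `pair_counts` object, or the transition proportion.
#' @param Q Transversion proportion (ignored when `P` is a `pair_counts`).
#' @return Non-negative distance (substitutions per site), possibly `Inf`.
#' @export
#' @examples
#' k2p_distance(0.1, 0.05)
k2p_distance <- function(P, Q = NULL) {
  if (inherits(P, "pair_counts")) {
    Q <- P$Q; P <- P$P
  }
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  t1 <- 1 - 2 * P - Q
  t2 <- 1 - 2 * Q
  if (t1 <= 0 || t2 <= 0) {
    warn("saturated pair: K2P distance undefined, reporting Inf")
    return(Inf)
  }
  max(0, -0.5 * log(t1 * sqrt(t2)))
}

#' Standard error of the K2P distance estimate
#'
#' The large-sample standard error of the closed-form K2P estimator
#' (delta method), used by the parameter-recovery checks.
#'
#' @param P,Q Transition and transversion proportions.
#' @param n_sites Number of compared sites.
#' @return Standard error of the distance estimate.
#' @export
k2p_se <- function(P, Q, n_sites) {
  c1 <- 1 / (1 - 2 * P - Q)
  c2 <- 1 / (1 - 2 * Q)
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n_sites
  sqrt(v)
}

#' K2P distance matrix from an alignment
#'
#' Applies the site-coverage filter once, then computes the K2P distance for
#' every taxon pair under pairwise deletion of remaining gap/ambiguous
#' cells. Saturated pairs become `Inf` entries with a warning (the
#' neighbor-joining stage refuses such matrices).
#'
#' @param msa An alignment tibble (3 or more taxa).
#' @param min_coverage Column filter threshold (default 0.95); `0` disables
#'   filtering.
#' @return Symmetric numeric matrix with taxa as dimnames.
#' @export
k2p_distance_matrix <- function(msa, min_coverage = 0.95) {
  if (nrow(msa) < 3L) abort("need at least 3 taxa")
  filtered <- if (min_coverage > 0) coverage_filter(msa, min_coverage) else msa
  k2p_matrix_from_chars(msa_char_matrix(filtered))
}

k2p_matrix_from_chars <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  acgt <- c("A", "C", "G", "T")
  ok <- matrix(m %in% acgt, nrow = n)
  ints <- matrix(match(m, acgt), nrow = n)  # A1 C2 G3 T4, NA otherwise
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      nn <- sum(use)
      if (nn == 0L) abort("no comparable sites for a pair")
      ai <- ints[i, use]; bj <- ints[j, use]
      diff <- ai != bj
      # transitions: A(1)<->G(3), C(2)<->T(4): |ai-bj| == 2
      ts <- diff & abs(ai - bj) == 2L
      dij <- withCallingHandlers(
        k2p_distance(sum(ts) / nn, sum(diff & !ts) / nn),
        warning = function(w) invokeRestart("muffleWarning"))
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (any(!is.finite(d))) warn("distance matrix contains saturated (infinite) entries")
  d
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param dm Square numeric matrix with taxon dimnames.
#' @param path Output path.
#' @param format `"tsv"` (headered square matrix) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon = rownames(dm), dm, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(sprintf("%5d", nrow(dm)),
               vapply(seq_len(nrow(dm)), function(i) {
                 paste0(formatC(rownames(dm)[i], width = -10),
                        paste(sprintf("%.6f", dm[i, ]), collapse = " "))
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Tidy a distance matrix into long form
#'
#' @param x Square distance matrix.
#' @param ... Unused.
#' @return Tibble with `taxon_a`, `taxon_b`, `distance` (upper triangle).
#' @export
tidy_distance_matrix <- function(x, ...) {
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble(taxon_a = rownames(x)[ut[, 1]], taxon_b = colnames(x)[ut[, 2]],
         distance = x[ut])
}
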