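# Neighbor-joining tree construction with nonparametric bootstrap supports.
# The agglomeration is implemented here (canonical Saitou-Nei NJ with
# deterministic lexicographic tie-breaking and non-negative branch
# clamping); trees are returned as ape "phylo" objects.

fmt_len <- function(x) sprintf("%.12g", x)

quote_label <- function(x) {
  needs <- grepl("[][ \t,;:()']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: iteratively joins the pair
#' minimizing the Q-criterion, with branch lengths from the standard
#' formulas. Ties are broken deterministically by the lexicographically
#' smallest taxon labels of the candidate clusters. Negative branch lengths
#' are clamped to zero with the difference moved to the sister branch, so
#' the joined pair's path length is preserved.
#'
#' @param dm Symmetric numeric distance matrix (taxon dimnames, zero
#'   diagonal, finite entries, 3 or more taxa).
#' @return An unrooted `ape::phylo` tree (trifurcating root).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) abort("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(dm))) abort("distance matrix has non-finite entries (saturated pairs?)")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-8) abort("distance matrix is not symmetric")

  # placeholder tip names while assembling newick (real labels, possibly
  # containing metacharacters, are substituted into the parsed tree)
  real_labels <- rownames(dm)
  frag <- sprintf("tip%d", seq_len(n))  # newick fragment per active cluster
  rep_lab <- rownames(dm)               # lexicographic representative
  D <- unname(dm)

  while (length(frag) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Qc <- (m - 2) * D - outer(r, r, "+")
    diag(Qc) <- Inf
    qmin <- min(Qc)
    cand <- which(Qc <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(rep_lab[cand[k, 1]], rep_lab[cand[k, 2]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_len(li), frag[j], fmt_len(lj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[, i] + D[, j] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- max(0, (d12 + d13 - d23) / 2)
  l2 <- max(0, (d12 + d23 - d13) / 2)
  l3 <- max(0, (d13 + d23 - d12) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], fmt_len(l1), frag[2], fmt_len(l2), frag[3], fmt_len(l3))
  tree <- ape::read.tree(text = newick)
  tree$tip.label <- real_labels[as.integer(sub("^tip", "", tree$tip.label))]
  tree
}

# Canonical bipartition keys of the internal edges of an unrooted phylo.
# Each split is identified by the sorted labels of the side not containing
# the reference taxon (the lexicographically smallest label overall).
tree_splits <- function(phy) {
  labs <- phy$tip.label
  ref <- min(labs)
  parts <- ape::prop.part(phy)
  n <- length(labs)
  keys <- map_chr(parts, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  })
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the coverage-filtered alignment, then resamples
#' alignment columns with replacement `replicates` times (the filter is
#' applied once, not per replicate), rebuilds the NJ tree per replicate, and
#' labels each internal bipartition of the original tree with the percentage
#' of replicates containing it. Replicates with a saturated pair are skipped
#' with a warning and the denominator adjusted.
#'
#' @param msa An alignment tibble.
#' @param replicates Bootstrap replicates (default 500); `0` returns the
#'   original tree without supports.
#' @param seed Integer seed for reproducible resampling.
#' @param min_coverage Site-coverage filter threshold (default 0.95).
#' @return An `ape::phylo` with `node.label` holding supports in 0-100
#'   (empty for the root); attribute `replicates_used` records the
#'   denominator.
#' @export
nj_bootstrap <- function(msa, replicates = 500, seed = 1, min_coverage = 0.95) {
  filtered <- if (min_coverage > 0) coverage_filter(msa, min_coverage) else msa
  chars <- msa_char_matrix(filtered)
  base_tree <- nj_tree(suppress_saturation_warning(k2p_matrix_from_chars(chars)))
  if (replicates == 0) return(base_tree)

  base_keys <- tree_splits(base_tree)
  counts <- setNames(rep(0L, sum(!is.na(base_keys))), base_keys[!is.na(base_keys)])
  used <- 0L
  skipped <- 0L
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
      dm <- try(suppress_saturation_warning(
        k2p_matrix_from_chars(chars[, cols, drop = FALSE])), silent = TRUE)
      if (inherits(dm, "try-error") || any(!is.finite(dm))) {
        skipped <- skipped + 1L
        next
      }
      rep_keys <- tree_splits(nj_tree(dm))
      used <- used + 1L
      seen <- intersect(names(counts), rep_keys)
      counts[seen] <- counts[seen] + 1L
    }
  })
  if (skipped > 0L) {
    warn(sprintf("%d bootstrap replicate(s) skipped (saturated pairs); supports based on %d",
                 skipped, used))
  }
  support <- ifelse(is.na(base_keys), "",
                    sprintf("%d", round(100 * counts[base_keys] / max(used, 1L))))
  base_tree$node.label <- unname(support)
  attr(base_tree, "replicates_used") <- used
  base_tree
}

suppress_saturation_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
}

#' Serialize a tree to Newick
#'
#' Standard Newick with branch lengths; internal node labels (bootstrap
#' supports) are written after the closing parenthesis; labels containing
#' spaces or Newick metacharacters are single-quoted; the string ends with
#' `;`.
#'
#' @param tree An `ape::phylo`.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node_lab <- tree$node.label
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node) {
    if (node <= ntip) return(quote_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(e) {
      child <- tree$edge[e, 2]
      len <- if (is.null(tree$edge.length)) "" else
        paste0(":", fmt(tree$edge.length[e]))
      paste0(rec(child), len)
    }, character(1))
    lab <- if (!is.null(node_lab)) {
      l <- node_lab[node - ntip]
      if (is.na(l)) "" else quote_label(as.character(l))
    } else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(rec(root), ";")
}
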