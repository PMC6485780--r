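# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the alignment oracle enumerates every gapped
# alignment recursively; the tree oracles go through ape/phangorn.

# Exhaustive enumeration of all global alignments under affine gaps
# (gap of length L costs gap_open + L * gap_extend, end gaps penalized),
# feasible for sequences up to ~6 residues.
enum_align_score <- function(a, b, match, mismatch, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= la) { # gap in b
      cost <- gap_extend + if (prev != "ga") gap_open else 0
      best <- max(best, cost + rec(i + 1L, j, "ga"))
    }
    if (j <= lb) { # gap in a
      cost <- gap_extend + if (prev != "gb") gap_open else 0
      best <- max(best, cost + rec(i, j + 1L, "gb"))
    }
    best
  }
  rec(1L, 1L, "m")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Random additive distance matrix from a random unrooted tree with known
# branch lengths; returns the matrix and the generating tree.
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- sort(tr$tip.label)
  dm <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(dm))
  list(dm = dm[ord, ord], tree = tr)
}

# Least-squares branch lengths of `dm` on topology `tr`: the residual is ~0
# iff the matrix is additive on that topology. The pair-path/edge incidence
# matrix comes from root paths (path edges = symmetric difference), cheap
# enough to enumerate every topology for 6 taxa.
ls_tree_residual <- function(tr, dm) {
  taxa <- rownames(dm)
  n <- length(taxa)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tr$Nnode)
  edge_of <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  edge_of[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  root_path <- function(node) {
    edges <- integer(0)
    while (node != root) {
      edges <- c(edges, edge_of[node])
      node <- parent[node]
    }
    edges
  }
  tip_paths <- lapply(seq_len(ntip), root_path)
  tip_idx <- match(taxa, tr$tip.label)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(tr$edge))
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    pi <- tip_paths[[tip_idx[pairs[r, 1]]]]
    pj <- tip_paths[[tip_idx[pairs[r, 2]]]]
    A[r, c(setdiff(pi, pj), setdiff(pj, pi))] <- 1
    d[r] <- dm[pairs[r, 1], pairs[r, 2]]
  }
  fit <- qr.coef(qr(A), d)
  fit[is.na(fit)] <- 0
  sqrt(sum((A %*% fit - d)^2))
}

# Newick parser independent of the package writer.
parse_newick <- function(s) ape::read.tree(text = s)

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

random_dna_seeded <- function(n, seed) {
  withr::with_seed(seed, random_dna(n))
}
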