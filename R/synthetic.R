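# Forward simulator: annotated ancestor genomes, K2P sequence evolution and
# diverged genome pairs with exact ground truth (realized substitutions,
# per-gene identities, deleted genes), so every downstream estimator can be
# checked by parameter recovery. All generators are pure functions of
# (parameters, seed).

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

random_sense_codons <- function(n_codons, gc) {
  codons <- character(n_codons)
  todo <- seq_len(n_codons)
  while (length(todo)) {
    b <- matrix(random_bases(3 * length(todo), gc), ncol = 3)
    codons[todo] <- paste0(b[, 1], b[, 2], b[, 3])
    todo <- todo[codons[todo] %in% STOP_CODONS]
  }
  codons
}

#' Simulate an annotated ancestor genome
#'
#' Scaffolds carry non-overlapping protein-coding genes on both strands;
#' every CDS starts with ATG, ends with a stop codon and contains no
#' internal stop; base composition targets `gc`. Deterministic given the
#' seed.
#'
#' @param n_genes Number of genes (default 200).
#' @param gene_len_mean Mean gene length in bp, including start and stop
#'   (default 900).
#' @param intergenic_mean Mean intergenic spacer length in bp (default 150).
#' @param gc Target G+C fraction (default 0.40).
#' @param n_scaffolds Number of scaffolds the genes are split across
#'   (default 1).
#' @param strain_id Strain identifier (default "ancestor").
#' @param seed Integer seed.
#' @return A `genome_record`.
#' @export
simulate_ancestor <- function(n_genes = 200, gene_len_mean = 900,
                              intergenic_mean = 150, gc = 0.40,
                              n_scaffolds = 1, strain_id = "ancestor",
                              seed = 1) {
  stopifnot(n_genes >= 1, gene_len_mean >= 99, intergenic_mean >= 1,
            gc > 0, gc < 1, n_scaffolds >= 1)
  if (n_scaffolds > n_genes) abort("more scaffolds than genes: infeasible packing")
  withr::with_seed(as.integer(seed), {
    n_codons <- pmax(30L, stats::rpois(n_genes, gene_len_mean / 3 - 2L)) + 2L
    cds <- vapply(n_codons, function(nc) {
      paste0("ATG", paste(random_sense_codons(nc - 2L, gc), collapse = ""),
             sample(STOP_CODONS, 1))
    }, character(1))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    scaffold_of <- sort(rep_len(seq_len(n_scaffolds), n_genes))
    genes <- vector("list", n_genes)
    scaffolds <- character(n_scaffolds)
    gi <- 0L
    for (s in seq_len(n_scaffolds)) {
      parts <- character(0)
      pos <- 0L
      for (g in which(scaffold_of == s)) {
        gi <- gi + 1L
        spacer <- paste(random_bases(10L + stats::rpois(1, intergenic_mean), gc),
                        collapse = "")
        parts <- c(parts, spacer)
        pos <- pos + nchar(spacer)
        gene_seq <- if (strand[g] == "+") cds[g] else reverse_complement(cds[g])
        genes[[gi]] <- tibble(gene_id = sprintf("gene%04d", g),
                              scaffold_id = sprintf("scf%02d", s),
                              start = pos + 1L, end = pos + nchar(gene_seq),
                              strand = strand[g])
        parts <- c(parts, gene_seq)
        pos <- pos + nchar(gene_seq)
      }
      tail_spacer <- paste(random_bases(10L + stats::rpois(1, intergenic_mean), gc),
                           collapse = "")
      scaffolds[s] <- paste(c(parts, tail_spacer), collapse = "")
    }
    scaffold_tbl <- seq_tbl(sprintf("scf%02d", seq_len(n_scaffolds)), scaffolds)
    load_genome(scaffold_tbl, bind_rows(genes), strain_id)
  })
}

k2p_event_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.5 - 0.5 * e1
  c(ts = p_ts, tv = p_tv, same = 1 - p_ts - p_tv)
}

#' Expected transition/transversion difference proportions under K2P
#'
#' Closed-form expected P and Q between two sequences separated by total
#' distance `d` with transition/transversion rate ratio `kappa`.
#'
#' @param d K2P distance (expected substitutions per site).
#' @param kappa Transition/transversion rate ratio (alpha/beta).
#' @return Named vector with `P` and `Q`.
#' @export
k2p_expected_pq <- function(d, kappa = 2) {
  p <- k2p_event_probs(d, kappa)
  c(P = unname(p["ts"]), Q = unname(p["tv"]))
}

evolve_chars <- function(x_int, d, kappa) {
  n <- length(x_int)
  probs <- k2p_event_probs(d, kappa)
  u <- runif(n)
  v <- runif(n)
  new <- x_int
  ok <- !is.na(x_int)
  is_ts <- ok & u < probs["ts"]
  is_tv <- ok & u >= probs["ts"] & u < probs["ts"] + probs["tv"]
  new[is_ts] <- (x_int[is_ts] + 2L) %% 4L
  new[is_tv] <- (x_int[is_tv] + ifelse(v[is_tv] < 0.5, 1L, 3L)) %% 4L
  new
}

#' Evolve a sequence under the Kimura 2-parameter model
#'
#' Applies the continuous-time K2P substitution process independently per
#' site for branch length `d` (transition rate alpha, each transversion
#' beta, scaled so the expected number of substitutions per site is `d`).
#' Non-ACGT characters are left untouched.
#'
#' @param seq Nucleotide sequence (string or one-row tibble).
#' @param d Branch length (expected substitutions per site).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with `seq` (evolved string), `P` and `Q` (realized
#'   transition/transversion difference proportions vs the input) and
#'   `n_sites`.
#' @export
evolve_k2p <- function(seq, d, kappa = 2, seed = NULL) {
  stopifnot(d >= 0, kappa > 0)
  s <- seq_chr(seq)
  run <- function() {
    chars <- strsplit(s, "")[[1]]
    x <- match(chars, c("A", "C", "G", "T")) - 1L
    new <- evolve_chars(x, d, kappa)
    out <- chars
    ok <- !is.na(x)
    out[ok] <- c("A", "C", "G", "T")[new[ok] + 1L]
    diff <- ok & new != x
    ts <- diff & (new - x) %% 4L == 2L
    n <- sum(ok)
    list(seq = paste(out, collapse = ""),
         P = sum(ts) / n, Q = sum(diff & !ts) / n, n_sites = n)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

codon_split <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# Re-evolve codons whose evolved state is an in-frame stop (purifying
# selection): redraw the three sites from the ancestral codon until the
# result is a sense codon; after 50 failures keep the ancestral codon.
fix_internal_stops <- function(scaffold, anc_scaffold, genes, t, kappa) {
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    ev <- substr(scaffold, g$start, g$end)
    cds <- if (g$strand == "+") ev else reverse_complement(ev)
    codons <- codon_split(cds)
    nc <- length(codons)
    internal <- which(codons[-nc] %in% STOP_CODONS)
    if (length(internal) == 0L) next
    anc_seq <- substr(anc_scaffold, g$start, g$end)
    anc_cds <- if (g$strand == "+") anc_seq else reverse_complement(anc_seq)
    anc_codons <- codon_split(anc_cds)
    for (ci in internal) {
      fixed <- anc_codons[ci]
      for (try in seq_len(50L)) {
        cand <- evolve_k2p(anc_codons[ci], t, kappa)$seq
        if (!cand %in% STOP_CODONS) { fixed <- cand; break }
      }
      codons[ci] <- fixed
    }
    new_cds <- paste(codons, collapse = "")
    new_gene <- if (g$strand == "+") new_cds else reverse_complement(new_cds)
    substr(scaffold, g$start, g$end) <- new_gene
  }
  scaffold
}

evolve_genome_seqs <- function(ancestor, t, kappa) {
  realized <- list()
  seqs <- ancestor$scaffolds$seq
  for (i in seq_along(seqs)) {
    ev <- evolve_k2p(seqs[i], t, kappa)
    genes_here <- filter(ancestor$genes,
                         .data$scaffold_id == ancestor$scaffolds$id[i])
    fixed <- fix_internal_stops(ev$seq, seqs[i], genes_here, t, kappa)
    seqs[i] <- fixed
    realized[[i]] <- counts_from_chars(strsplit(seqs[i], "")[[1]],
                                       strsplit(ancestor$scaffolds$seq[i], "")[[1]])
  }
  n <- sum(map_dbl(realized, "n_sites"))
  list(seqs = seqs,
       P = sum(map_dbl(realized, ~ .x$P * .x$n_sites)) / n,
       Q = sum(map_dbl(realized, ~ .x$Q * .x$n_sites)) / n)
}

# Rebuild one scaffold from alternating intergenic/gene segments, dropping
# deleted genes and applying small intergenic indels; returns the new
# scaffold string and updated gene coordinates.
rebuild_scaffold <- function(scaffold, genes, delete_ids, indel_rate, gc) {
  genes <- arrange(genes, .data$start)
  if (nrow(genes) > 1L && any(genes$start[-1] <= genes$end[-nrow(genes)])) {
    abort("overlapping genes: cannot rebuild scaffold")
  }
  bounds <- c(0L, rbind(genes$start - 1L, genes$end), nchar(scaffold))
  parts <- character(0)
  new_genes <- list()
  pos <- 0L
  prev_end <- 0L
  for (gi in seq_len(nrow(genes))) {
    inter <- substr(scaffold, prev_end + 1L, genes$start[gi] - 1L)
    inter <- apply_indels(inter, indel_rate, gc)
    parts <- c(parts, inter)
    pos <- pos + nchar(inter)
    prev_end <- genes$end[gi]
    gene_seq <- substr(scaffold, genes$start[gi], genes$end[gi])
    if (genes$gene_id[gi] %in% delete_ids) next
    parts <- c(parts, gene_seq)
    new_genes[[length(new_genes) + 1L]] <-
      mutate(genes[gi, ], start = pos + 1L, end = pos + nchar(gene_seq))
    pos <- pos + nchar(gene_seq)
  }
  tail_seg <- apply_indels(substr(scaffold, prev_end + 1L, nchar(scaffold)),
                           indel_rate, gc)
  list(seq = paste(c(parts, tail_seg), collapse = ""),
       genes = bind_rows(new_genes))
}

apply_indels <- function(segment, indel_rate, gc) {
  if (indel_rate <= 0 || nchar(segment) == 0L) return(segment)
  n_events <- stats::rpois(1, nchar(segment) * indel_rate)
  for (e in seq_len(n_events)) {
    len <- nchar(segment)
    if (len == 0L) break
    size <- sample(1:10, 1)
    at <- sample(len, 1)
    if (runif(1) < 0.5) {
      segment <- paste0(substr(segment, 1, at),
                        paste(random_bases(size, gc), collapse = ""),
                        substr(segment, at + 1L, len))
    } else {
      segment <- paste0(substr(segment, 1, at - 1L),
                        substr(segment, at + size, len))
    }
  }
  segment
}

#' Simulate a diverged, annotated genome pair with ground truth
#'
#' Both descendants evolve independently from the ancestor for `d/2` each
#' under K2P (point substitutions only within genes, keeping per-gene
#' identity analytic); a fraction of genes is deleted from descendant B and
#' optional small indels are applied to intergenic regions of B, with
#' annotations updated to stay consistent. The returned truth object holds
#' the realized per-gene identities (computed by direct positionwise
#' comparison of the homologous CDS), the deleted gene set and the realized
#' substitution proportions.
#'
#' @param ancestor A `genome_record`, e.g. from [simulate_ancestor()].
#' @param d Total pairwise divergence between the descendants.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param gene_loss_fraction Fraction of genes deleted from descendant B
#'   (exactly `round(fraction * n_genes)` genes; default 0).
#' @param indel_rate Expected intergenic indel events per bp in descendant B
#'   (default 0).
#' @param gc G+C fraction for inserted bases (default 0.40).
#' @param seed Integer seed.
#' @return List with `genome_a`, `genome_b` (`genome_record`s) and `truth`
#'   (a `simulation_truth`).
#' @export
make_pair <- function(ancestor, d, kappa = 2, gene_loss_fraction = 0,
                      indel_rate = 0, gc = 0.40, seed = 1) {
  stopifnot(inherits(ancestor, "genome_record"),
            gene_loss_fraction >= 0, gene_loss_fraction < 1)
  withr::with_seed(as.integer(seed), {
    ev_a <- evolve_genome_seqs(ancestor, d / 2, kappa)
    ev_b <- evolve_genome_seqs(ancestor, d / 2, kappa)
    n_del <- round(gene_loss_fraction * nrow(ancestor$genes))
    deleted <- sort(sample(ancestor$genes$gene_id, n_del))

    scaf_a <- seq_tbl(ancestor$scaffolds$id, ev_a$seqs)
    genome_a <- load_genome(scaf_a, ancestor$genes,
                            paste0(ancestor$strain_id, "_A"))

    parts_b <- map(seq_len(nrow(ancestor$scaffolds)), function(i) {
      genes_here <- filter(ancestor$genes,
                           .data$scaffold_id == ancestor$scaffolds$id[i])
      rebuild_scaffold(ev_b$seqs[i], genes_here, deleted, indel_rate, gc)
    })
    scaf_b <- seq_tbl(ancestor$scaffolds$id, map_chr(parts_b, "seq"))
    genome_b <- load_genome(scaf_b, bind_rows(map(parts_b, "genes")),
                            paste0(ancestor$strain_id, "_B"))

    shared <- intersect(genome_a$cds$gene_id, genome_b$cds$gene_id)
    cds_a <- setNames(genome_a$cds$seq, genome_a$cds$gene_id)
    cds_b <- setNames(genome_b$cds$seq, genome_b$cds$gene_id)
    gene_identity <- map(shared, function(id) {
      a <- strsplit(cds_a[[id]], "")[[1]]
      b <- strsplit(cds_b[[id]], "")[[1]]
      tibble(gene_id = id, identity = mean(a == b), n_subst = sum(a != b))
    }) %>% bind_rows()

    truth <- structure(
      list(d_true = d, kappa = kappa, seed = as.integer(seed),
           deleted_genes = deleted,
           realized = tibble(descendant = c("A", "B"),
                             P = c(ev_a$P, ev_b$P), Q = c(ev_a$Q, ev_b$Q)),
           gene_identity = gene_identity,
           mean_gene_identity = mean(gene_identity$identity)),
      class = "simulation_truth")
    list(genome_a = genome_a, genome_b = genome_b, truth = truth)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> d = %g, kappa = %g, %d genes deleted, mean gene identity %.4f\n",
              x$d_true, x$kappa, length(x$deleted_genes), x$mean_gene_identity))
  invisible(x)
}

#' Simulate a two-clade 16S-like alignment
#'
#' Two clades separated by a set of fixed diagnostic substitutions, with
#' small within-clade divergence: the standard positive control for
#' bootstrap support of the between-clade split.
#'
#' @param n_per_clade Taxa per clade (default 5).
#' @param n_sites Alignment length (default 1200).
#' @param n_diagnostic Number of fixed diagnostic sites separating the
#'   clades (default 50).
#' @param within_d Within-clade divergence from the clade consensus
#'   (default 0.02).
#' @param gc G+C fraction of the root sequence (default 0.5).
#' @param seed Integer seed.
#' @return An alignment tibble with taxa `A1..An`, `B1..Bn`.
#' @export
simulate_two_clade_msa <- function(n_per_clade = 5, n_sites = 1200,
                                   n_diagnostic = 50, within_d = 0.02,
                                   gc = 0.5, seed = 1) {
  withr::with_seed(as.integer(seed), {
    root <- random_bases(n_sites, gc)
    diagnostic <- sample(n_sites, n_diagnostic)
    other <- root
    # diagnostic sites get the transition partner: guaranteed different
    map_ts <- c(A = "G", G = "A", C = "T", T = "C")
    other[diagnostic] <- map_ts[other[diagnostic]]
    taxa <- c(paste0("A", seq_len(n_per_clade)), paste0("B", seq_len(n_per_clade)))
    seqs <- c(
      map_chr(seq_len(n_per_clade), function(i)
        evolve_k2p(paste(root, collapse = ""), within_d)$seq),
      map_chr(seq_len(n_per_clade), function(i)
        evolve_k2p(paste(other, collapse = ""), within_d)$seq))
    msa_tbl(taxa, seqs)
  })
}
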