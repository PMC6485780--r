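# Shared fixture: a small diverged pair with known gene loss.
fixture_pair <- local({
  anc <- simulate_ancestor(n_genes = 24, gene_len_mean = 600, seed = 301)
  make_pair(anc, d = 0.1, kappa = 2, gene_loss_fraction = 0.125, seed = 302)
})

test_that("candidate pairs contain all self-pairs and planted orthologs", {
  g <- fixture_pair$genome_a
  cand <- candidate_pairs(g, g)
  expect_true(all(g$proteins$gene_id %in%
                    cand$id_a[cand$id_a == cand$id_b]))

  # planted orthologs (the evolved pair) are retained
  cand_ab <- candidate_pairs(fixture_pair$genome_a, fixture_pair$genome_b)
  shared <- intersect(fixture_pair$genome_a$proteins$gene_id,
                      fixture_pair$genome_b$proteins$gene_id)
  expect_true(all(shared %in%
                    cand_ab$id_a[cand_ab$id_a == cand_ab$id_b]))
})

test_that("two unrelated random proteins share almost no 4-mers", {
  withr::local_seed(73)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p1 <- tibble::tibble(gene_id = "p1",
                       seq = paste(sample(aa20, 100, TRUE), collapse = ""))
  p2 <- tibble::tibble(gene_id = "p2",
                       seq = paste(sample(aa20, 100, TRUE), collapse = ""))
  # direct k-mer count oracle
  kmers <- function(s) unique(substring(s, 1:(nchar(s) - 3), 4:nchar(s)))
  n_shared <- length(intersect(kmers(p1$seq), kmers(p2$seq)))
  cand <- candidate_pairs(p1, p2, kmer = 4, min_shared = 2)
  expect_equal(nrow(cand), as.integer(n_shared >= 2))
})

test_that("a proteome's best hits against itself are the identity pairing", {
  g <- fixture_pair$genome_a
  hits <- best_hits(g, g)
  expect_equal(nrow(hits), nrow(g$proteins))
  expect_equal(hits$query_id, hits$target_id)
  expect_true(all(hits$identity == 1))
})

test_that("identity and coverage floors exclude decoys and truncations", {
  base <- fixture_pair$genome_a$proteins[1:6, ]
  # decoys: unrelated proteins of the same lengths (identity ~5-15%)
  withr::local_seed(79)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  decoys <- tibble::tibble(
    gene_id = paste0("decoy", 1:6),
    seq = vapply(nchar(base$seq),
                 function(n) paste(sample(aa20, n, TRUE), collapse = ""),
                 character(1)))
  hits <- best_hits(base, decoys)
  expect_equal(nrow(hits), 0L)

  # a protein truncated to half its ortholog fails the 0.70 coverage floor
  trunc <- tibble::tibble(gene_id = base$gene_id[1],
                          seq = substr(base$seq[1], 1,
                                       nchar(base$seq[1]) %/% 2))
  expect_equal(nrow(best_hits(base[1, ], trunc)), 0L)
  # but an identical full-length copy passes
  expect_equal(nrow(best_hits(base[1, ], base[1, ])), 1L)
})

test_that("reciprocal best hits are symmetric and track gene loss exactly", {
  ot <- find_orthologs(fixture_pair$genome_a, fixture_pair$genome_b)
  expected_n <- nrow(fixture_pair$genome_a$genes) -
    length(fixture_pair$truth$deleted_genes)
  expect_equal(nrow(ot), expected_n)
  expect_false(any(fixture_pair$truth$deleted_genes %in% ot$gene_id_b))

  # symmetry: swapping A and B yields the same pair set with ids swapped
  ot_rev <- find_orthologs(fixture_pair$genome_b, fixture_pair$genome_a)
  expect_equal(
    dplyr::arrange(tibble::tibble(a = ot$gene_id_a, b = ot$gene_id_b), a, b),
    dplyr::arrange(tibble::tibble(a = ot_rev$gene_id_b, b = ot_rev$gene_id_a), a, b))

  # RBH pairs are a subset of best hits in both directions
  hits_ab <- best_hits(fixture_pair$genome_a, fixture_pair$genome_b)
  expect_true(all(paste(ot$gene_id_a, ot$gene_id_b) %in%
                    paste(hits_ab$query_id, hits_ab$target_id)))

  # one-to-one
  expect_false(anyDuplicated(ot$gene_id_a) > 0)
  expect_false(anyDuplicated(ot$gene_id_b) > 0)
})

test_that("self-comparison gives the identity ortholog table", {
  g <- fixture_pair$genome_a
  ot <- find_orthologs(g, g)
  expect_equal(nrow(ot), nrow(g$proteins))
  expect_equal(ot$gene_id_a, ot$gene_id_b)
  expect_true(all(ot$protein_identity == 1))
  expect_true(all(ot$nucleotide_identity == 1))
})

test_that("ortholog tables write as headered TSV", {
  ot <- find_orthologs(fixture_pair$genome_a, fixture_pair$genome_b)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_table(ot, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(ot))
  expect_true(all(c("gene_id_a", "gene_id_b", "protein_identity",
                    "nucleotide_identity") %in% names(back)))
})
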