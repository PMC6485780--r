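test_that("ancestor simulation is deterministic and structurally valid", {
  g1 <- simulate_ancestor(n_genes = 25, seed = 11)
  g2 <- simulate_ancestor(n_genes = 25, seed = 11)
  expect_identical(g1$scaffolds$seq, g2$scaffolds$seq)
  expect_identical(g1$genes, g2$genes)
  g3 <- simulate_ancestor(n_genes = 25, seed = 12)
  expect_false(identical(g1$scaffolds$seq, g3$scaffolds$seq))

  # every CDS starts ATG, ends with a stop, no internal stops
  expect_true(all(startsWith(g1$cds$seq, "ATG")))
  expect_true(all(substring(g1$cds$seq, nchar(g1$cds$seq) - 2) %in%
                    c("TAA", "TAG", "TGA")))
  expect_false(any(grepl("*", g1$proteins$seq, fixed = TRUE)))
  expect_equal(nrow(g1$excluded), 0L)
  # protein length = cds/3 - 1 (stop trimmed)
  expect_equal(nchar(g1$proteins$seq), nchar(g1$cds$seq) / 3 - 1)

  # multi-scaffold packing
  g4 <- simulate_ancestor(n_genes = 20, n_scaffolds = 4, seed = 13)
  expect_equal(nrow(g4$scaffolds), 4L)
  expect_error(simulate_ancestor(n_genes = 2, n_scaffolds = 5, seed = 1),
               "infeasible")
})

test_that("realized GC tracks the requested composition", {
  g <- simulate_ancestor(n_genes = 120, gene_len_mean = 900, gc = 0.40,
                         seed = 17)
  expect_gt(genome_stats(g)$total_bp, 90000)
  expect_lt(abs(genome_stats(g)$gc_percent - 40), 2)
})

test_that("loading the generator's own FASTA output reproduces its proteins", {
  g <- simulate_ancestor(n_genes = 10, seed = 19)
  dir <- withr::local_tempdir()
  files <- write_genome(g, dir)
  g2 <- load_genome(files[["scaffold_fasta"]], files[["gene_table"]], "again")
  expect_equal(g2$proteins$seq, g$proteins$seq)
})

test_that("K2P evolution leaves d=0 untouched and matches expectations", {
  s <- random_dna(5000)
  ev0 <- evolve_k2p(s, 0, seed = 23)
  expect_identical(ev0$seq, s)
  expect_equal(c(ev0$P, ev0$Q), c(0, 0))

  # realized P and Q lie inside a 4-sigma binomial band of the analytic
  # expectations for (d, kappa)
  n <- 100000
  s2 <- random_dna(n)
  for (d in c(0.05, 0.2)) {
    for (kappa in c(1, 4)) {
      ev <- evolve_k2p(s2, d, kappa, seed = 29)
      exp_pq <- k2p_expected_pq(d, kappa)
      expect_lt(abs(ev$P - exp_pq["P"]),
                4 * sqrt(exp_pq["P"] * (1 - exp_pq["P"]) / n))
      expect_lt(abs(ev$Q - exp_pq["Q"]),
                4 * sqrt(exp_pq["Q"] * (1 - exp_pq["Q"]) / n))
    }
  }
})

test_that("K2P estimator recovery across replicates has small relative bias", {
  # scaled-down version of the recovery study (the acceptance script runs
  # the full 100 kb x 20 seeds design)
  d_hat <- vapply(1:8, function(i) {
    ev <- evolve_k2p(random_dna(20000), d = 0.1, kappa = 2, seed = 100 + i)
    k2p_distance(ev$P, ev$Q)
  }, numeric(1))
  expect_lt(abs(mean(d_hat) - 0.1) / 0.1, 0.03)
})

test_that("non-ACGT characters are preserved, never mutated", {
  s <- "ANGNNCGT"
  ev <- evolve_k2p(s, 0.9, seed = 31)
  expect_equal(gsub("[ACGT]", ".", ev$seq), gsub("[ACGT]", ".", s))
})

test_that("make_pair bookkeeping matches the genomes it returns", {
  anc <- simulate_ancestor(n_genes = 30, seed = 37)
  pair <- make_pair(anc, d = 0.08, gene_loss_fraction = 0.2, indel_rate = 0.002,
                    seed = 38)
  expect_equal(length(pair$truth$deleted_genes), 6L)
  expect_equal(nrow(pair$genome_b$genes), 24L)
  expect_equal(nrow(pair$genome_a$genes), 30L)

  # truth identities recomputable from the returned CDS
  for (i in sample(nrow(pair$truth$gene_identity), 5)) {
    id <- pair$truth$gene_identity$gene_id[i]
    a <- strsplit(pair$genome_a$cds$seq[pair$genome_a$cds$gene_id == id], "")[[1]]
    b <- strsplit(pair$genome_b$cds$seq[pair$genome_b$cds$gene_id == id], "")[[1]]
    expect_equal(mean(a == b), pair$truth$gene_identity$identity[i])
  }

  # determinism
  pair2 <- make_pair(anc, d = 0.08, gene_loss_fraction = 0.2,
                     indel_rate = 0.002, seed = 38)
  expect_identical(pair$genome_b$scaffolds$seq, pair2$genome_b$scaffolds$seq)
  expect_identical(pair$truth$gene_identity, pair2$truth$gene_identity)

  # descendants carry no internal stops (purifying resampling)
  expect_equal(nrow(pair$genome_a$excluded), 0L)
  expect_equal(nrow(pair$genome_b$excluded), 0L)
})

test_that("pipeline end-to-end on a close pair plus distant outgroups", {
  # A, B close; C, D distant: NJ must put AB|CD with near-certain support
  withr::local_seed(43)
  root <- random_dna(1500)
  inner <- evolve_k2p(root, 0.15)$seq
  msa <- msa_tbl(c("A", "B", "C", "D"),
                 c(evolve_k2p(inner, 0.01)$seq, evolve_k2p(inner, 0.01)$seq,
                   evolve_k2p(root, 0.15)$seq, evolve_k2p(root, 0.15)$seq))
  tr <- nj_bootstrap(msa, replicates = 100, seed = 44)
  splits <- ogri:::tree_splits(tr)
  idx <- which(!is.na(splits))
  expect_length(idx, 1)
  expect_true(splits[idx] %in% c("A|B", "C|D"))
  expect_gte(as.numeric(tr$node.label[idx]), 95)
})
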