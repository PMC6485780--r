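fixture_small_pair <- local({
  anc <- simulate_ancestor(n_genes = 20, gene_len_mean = 600,
                           intergenic_mean = 100, seed = 401)
  make_pair(anc, d = 0.12, gene_loss_fraction = 0.1, seed = 402)
})

test_that("genome statistics count bases and genes correctly", {
  g1 <- genome_record("x", seq_tbl("s", "GGCC"),
                      genes = tibble::tibble(gene_id = character(),
                                             scaffold_id = character(),
                                             start = integer(), end = integer(),
                                             strand = character()),
                      cds = tibble::tibble(gene_id = character(), seq = character()),
                      proteins = tibble::tibble(gene_id = character(), seq = character()))
  st <- genome_stats(g1)
  expect_equal(st$total_bp, 4L)
  expect_equal(st$gc_percent, 100)

  g2 <- genome_record("y", seq_tbl("s", "ACGT"), g1$genes, g1$cds, g1$proteins)
  expect_equal(genome_stats(g2)$gc_percent, 50)

  # N excluded from the GC denominator
  g3 <- genome_record("z", seq_tbl("s", "ACGTNNNN"), g1$genes, g1$cds, g1$proteins)
  expect_equal(genome_stats(g3)$gc_percent, 50)

  full <- genome_stats(fixture_small_pair$genome_a)
  expect_equal(full$total_bp, sum(nchar(fixture_small_pair$genome_a$scaffolds$seq)))
  expect_equal(full$n_genes, nrow(fixture_small_pair$genome_a$genes))
  expect_equal(full$coding_bp,
               sum(fixture_small_pair$genome_a$genes$end -
                     fixture_small_pair$genome_a$genes$start + 1L))
  expect_identical(glance(fixture_small_pair$genome_a), full)
})

test_that("AGIOS and AAI are the stated means with the stated errors", {
  fake <- tibble::tibble(gene_id_a = c("a", "b"), gene_id_b = c("a", "b"),
                         protein_identity = c(0.5, 0.9),
                         nucleotide_identity = c(0.8, 0.6),
                         alignment_length = c(100L, 300L))
  expect_equal(agios(fake), 70)
  expect_equal(aai(fake), 70)
  expect_equal(agios(fake, weighted = TRUE), 100 * (0.8 * 100 + 0.6 * 300) / 400)
  expect_equal(aai(tibble::tibble(protein_identity = c(0.5, 0.7, 0.9))), 70)
  expect_error(agios(tibble::tibble(nucleotide_identity = numeric())),
               "no orthologs")
})

test_that("AGIOS tracks generator truth and self-comparison is exactly 100", {
  ot_self <- find_orthologs(fixture_small_pair$genome_a,
                            fixture_small_pair$genome_a)
  expect_equal(agios(ot_self), 100)
  expect_equal(aai(ot_self), 100)

  ot <- find_orthologs(fixture_small_pair$genome_a, fixture_small_pair$genome_b)
  truth <- 100 * fixture_small_pair$truth$mean_gene_identity
  expect_lt(abs(agios(ot) - truth), 0.5)
  # AGIOS/100 ~ 1 - realized substitution fraction within genes
  expect_lt(abs(agios(ot) / 100 -
                  (1 - sum(fixture_small_pair$truth$gene_identity$n_subst) /
                     sum(nchar(fixture_small_pair$genome_a$cds$seq[
                       match(fixture_small_pair$truth$gene_identity$gene_id,
                             fixture_small_pair$genome_a$cds$gene_id)])))),
            0.005)
})

test_that("dDDH sits at the plateaus for self and unrelated genomes", {
  g <- fixture_small_pair$genome_a
  self <- fragment_ddh(g, g)
  expect_gte(as.numeric(self), 99)

  # two independent random genomes: no planted homology
  r1 <- simulate_ancestor(n_genes = 15, gene_len_mean = 600, seed = 403)
  r2 <- simulate_ancestor(n_genes = 15, gene_len_mean = 600, seed = 404)
  unrel <- suppressWarnings(fragment_ddh(r1, r2))
  expect_lte(as.numeric(unrel), 25)
})

test_that("dDDH decreases strictly along a divergence series", {
  anc <- simulate_ancestor(n_genes = 15, gene_len_mean = 600, seed = 405)
  ddh <- vapply(c(0.02, 0.05, 0.10, 0.20), function(d) {
    pair <- make_pair(anc, d = d, seed = 406)
    as.numeric(fragment_ddh(pair$genome_a, pair$genome_b))
  }, numeric(1))
  expect_true(all(diff(ddh) < 0))
})

test_that("compare_genomes bundles the indices and records the model version", {
  cr <- compare_genomes(fixture_small_pair$genome_a, fixture_small_pair$genome_b)
  expect_s3_class(cr, "comparison_result")
  expect_equal(cr$n_orthologs, 18L)
  expect_true(cr$agios > 80 && cr$agios < 100)
  # neutral codon evolution: most nucleotide changes alter the protein,
  # so per-pair protein identity falls below nucleotide identity
  expect_true(cr$aai < cr$agios)
  expect_equal(cr$ddh_model_version, ddh_model()$version)
  td <- tidy(cr)
  expect_equal(nrow(td), 4L)
  expect_s3_class(autoplot(cr), "ggplot")
})

test_that("identity limit: d = 0 gives AGIOS = AAI = 100 and dDDH at the top", {
  anc <- simulate_ancestor(n_genes = 12, gene_len_mean = 450, seed = 407)
  pair <- make_pair(anc, d = 0, seed = 408)
  cr <- compare_genomes(pair$genome_a, pair$genome_b)
  expect_equal(cr$agios, 100)
  expect_equal(cr$aai, 100)
  expect_gte(cr$ddh, 99)
})
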