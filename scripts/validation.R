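#!/usr/bin/env Rscript

# Validation against the deposited accessions (network required; hours of
# runtime). Downloads the 16S sequences and genome assemblies, recomputes
# the pipeline's statistics and prints them next to the published reference
# values. This is a validation aid, not part of the desk-scale acceptance
# checks: it needs internet access and (for the genome comparisons) the
# `prodigal` gene caller on PATH to produce the gene-coordinate tables the
# pipeline consumes.
#
#   Rscript scripts/validation.R [--workdir DIR] [--skip-genomes]

suppressPackageStartupMessages({
  library(ogri)
  library(dplyr)
})

args <- commandArgs(trailingOnly = TRUE)
workdir <- if ("--workdir" %in% args) args[which(args == "--workdir") + 1L] else "scratch/validation"
skip_genomes <- "--skip-genomes" %in% args
dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

fetch <- function(url, dest) {
  if (!file.exists(dest)) {
    message("fetching ", url)
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}

ena_fasta <- function(accession, dest) {
  fetch(paste0("https://www.ebi.ac.uk/ena/browser/api/fasta/", accession),
        dest)
}
ncbi_fasta <- function(accession, dest) {
  fetch(paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=fasta&retmode=text&id=", accession),
        dest)
}

## 16S identity: LT223702 (query strain) vs NR_126185 (closest species) ------
q16 <- read_fasta(ena_fasta("LT223702", file.path(workdir, "LT223702.fasta")),
                  "nucleotide")
r16 <- read_fasta(ncbi_fasta("NR_126185",
                             file.path(workdir, "NR_126185.fasta")),
                  "nucleotide")
id16 <- percent_identity(global_align(q16[1, ], r16[1, ]), "aligned_columns")
cat(sprintf("16S identity LT223702 vs NR_126185: %.2f%% (reference 96.57%%, tolerance +/-0.3 for aligner differences)\n",
            id16))
print(classify_16s(id16))

## Genome statistics of the query assembly -----------------------------------
# Reference values: 4,548,390 bp, 39.8% G+C, 11 scaffolds.
asm_path <- ena_fasta("FLKH01", file.path(workdir, "FLKH01.fasta"))

call_genes <- function(fasta, out_tsv) {
  # prodigal gff -> the headered TSV gene table the pipeline consumes
  gff <- paste0(out_tsv, ".gff")
  status <- system2("prodigal", c("-i", fasta, "-f", "gff", "-o", gff,
                                  "-q", "-p", "single"))
  if (status != 0) stop("prodigal failed; is it on PATH?")
  lines <- readLines(gff)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  genes <- dplyr::bind_rows(lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    tibble::tibble(gene_id = sprintf("cds%05d", i),
                   scaffold_id = sub("\\s.*$", "", p[1]),
                   start = as.integer(p[4]), end = as.integer(p[5]),
                   strand = p[7])
  }))
  write_gene_table(genes, out_tsv)
  out_tsv
}

if (!skip_genomes) {
  genes_q <- call_genes(asm_path, file.path(workdir, "FLKH01_genes.tsv"))
  gq <- load_genome(asm_path, genes_q, "Marseille-P2481")
  print(genome_stats(gq))
  cat("reference: 4,548,390 bp; 39.8% G+C; 11 scaffolds\n")

  ## Pairwise comparisons against the comparator assemblies ------------------
  comparators <- c(GL = "ARIY01", GO = "FOTR01", GM = "CZRP01", GK = "FRCZ01",
                   GB = "BAVS01", GU = "FOGL01", GH = "APML01", BA = "ALPT01",
                   BC = "AP006627")
  reference <- tibble::tribble(
    ~strain_b, ~orthologs, ~agios, ~ddh, ~aai,
    "GL", 2103, 72.3, 20.5, 68.72,
    "GO", 2112, 72.1, 19.8, 68.19,
    "GM", 2004, 72.0, 21.6, 68.18,
    "GK", 2027, 71.8, 20.1, 67.90,
    "GB", 1461, 71.0, 19.1, 68.08,
    "GU", 1982, 70.0, 21.4, 64.69,
    "GH", 1695, 69.8, 19.3, 64.37,
    "BA", 1539, 64.5, 23.6, 51.72,
    "BC", 1578, 62.9, 28.67, 50.73)
  rows <- list()
  for (code in names(comparators)) {
    acc <- comparators[[code]]
    fasta <- ena_fasta(acc, file.path(workdir, paste0(acc, ".fasta")))
    genes <- call_genes(fasta, file.path(workdir, paste0(acc, "_genes.tsv")))
    gb <- load_genome(fasta, genes, code)
    cr <- compare_genomes(gq, gb)
    rows[[code]] <- cr
    print(as.data.frame(cr))
  }
  computed <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(reference, computed, by = "strain_b")
  print(out)
  cat("reference tolerances: AGIOS/AAI/dDDH +/-1.5 points, ortholog counts +/-5% (tooling differences: database search vs exact alignment)\n")
}
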