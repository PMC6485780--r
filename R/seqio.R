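# Sequence and genome I/O: FASTA in/out, gene tables, assembled genome records.

NUC_CHARS <- c("A", "C", "G", "T", "N", "-",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
PROT_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U", "*", "-")

#' Build a sequence table
#'
#' The atom of all I/O in the package is a tibble with one row per sequence
#' and columns `id`, `desc`, `seq`, `alphabet`. `seq_tbl()` constructs one
#' with validation; most users will get these tables from [read_fasta()].
#'
#' @param id Character vector of identifiers (no whitespace).
#' @param seq Character vector of residues (uppercased on construction).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param desc Optional descriptions (free text).
#' @return A tibble with columns `id`, `desc`, `seq`, `alphabet`.
#' @export
#' @examples
#' seq_tbl("a", "ACGT")
seq_tbl <- function(id, seq, alphabet = c("nucleotide", "protein"), desc = "") {
  alphabet <- match.arg(alphabet)
  if (length(id) == 0L) {
    return(tibble(id = character(), desc = character(),
                  seq = character(), alphabet = character()))
  }
  seq <- toupper(seq)
  stopifnot(length(id) == length(seq))
  if (any(grepl("\\s", id))) abort("sequence ids must not contain whitespace")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (any(!nzchar(seq))) {
    abort(paste0("empty sequence body for record(s): ",
                 paste(id[!nzchar(seq)], collapse = ", ")))
  }
  allowed <- if (alphabet == "nucleotide") NUC_CHARS else PROT_CHARS
  bad <- vapply(strsplit(seq, ""), function(ch) any(!ch %in% allowed), logical(1))
  if (any(bad)) {
    abort(paste0("residues outside the ", alphabet, " alphabet in: ",
                 paste(id[bad], collapse = ", ")))
  }
  tibble(id = as.character(unname(id)),
         desc = rep_len(as.character(desc), length(id)),
         seq = unname(seq), alphabet = alphabet)
}

#' Read a FASTA file into a sequence table
#'
#' Wraps the Biostrings FASTA reader. Residues are uppercased, records keep
#' their file order, and the first whitespace-delimited token of each header
#' becomes the `id` (the remainder the `desc`). CR/LF line endings are
#' tolerated. IUPAC ambiguity codes are preserved on read; downstream
#' distance and identity code treats them as excluded sites, never matches.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A sequence tibble (see [seq_tbl()]); empty, with a warning, for an
#'   empty file.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(seq_tbl(character(), character(), alphabet))
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  bodies <- toupper(gsub("\r", "", as.character(set), fixed = TRUE))
  if (any(!nzchar(bodies))) {
    abort(paste0("record with empty body: ",
                 paste(ids[!nzchar(bodies)], collapse = ", ")))
  }
  seq_tbl(ids, bodies, alphabet, descs)
}

#' Write a sequence table to FASTA
#'
#' @param seqs A sequence tibble (columns `id`, `seq`, optional `desc`).
#' @param path Output path.
#' @param wrap Line width for the sequence body (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60) {
  stopifnot(is.data.frame(seqs), wrap >= 1)
  if (anyDuplicated(seqs$id)) abort("duplicate ids; refusing to write FASTA")
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(seqs) == 0L) return(invisible(path))
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  header <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  lines <- unlist(map2(header, seqs$seq, function(h, s) {
    starts <- seq.int(1L, nchar(s), by = wrap)
    c(paste0(">", h), substring(s, starts, pmin(starts + wrap - 1L, nchar(s))))
  }))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a gene-coordinate table
#'
#' A headered TSV with columns `gene_id`, `scaffold_id`, `start`, `end`,
#' `strand`. Coordinates are 1-based and inclusive (GFF convention).
#'
#' @param path Path to the TSV.
#' @return A tibble of gene annotations.
#' @export
read_gene_table <- function(path) {
  tab <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              colClasses = c(start = "integer", end = "integer")))
  need <- c("gene_id", "scaffold_id", "start", "end", "strand")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(paste0("gene table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(tab$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  tab[need]
}

#' Write a gene-coordinate table
#'
#' @param genes Tibble with columns `gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes[, c("gene_id", "scaffold_id", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_cds <- function(cds, genetic_code = "11") {
  code <- Biostrings::getGeneticCode(genetic_code)
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     genetic.code = code,
                                     if.fuzzy.codon = "X"))
}

#' Assemble an annotated genome record
#'
#' Combines scaffolds and a gene-coordinate table into a `genome_record`:
#' CDS are extracted (reverse-complemented on the `-` strand) and translated
#' with the bacterial genetic code (NCBI table 11 by default); the trailing
#' stop codon is trimmed from the protein. Genes whose length is not a
#' multiple of 3 or whose translation contains an internal stop are flagged
#' and excluded with a warning; a coordinate outside its scaffold is an
#' error.
#'
#' @param scaffold_fasta Path to the scaffold FASTA, or a sequence tibble.
#' @param gene_table Path to the gene TSV, or a gene tibble
#'   (see [read_gene_table()]).
#' @param strain_id Strain identifier.
#' @param genetic_code NCBI genetic code id (default `"11"`, bacterial).
#' @return A `genome_record`: list with `strain_id`, `scaffolds`, `genes`,
#'   `cds`, `proteins` and `excluded` tibbles.
#' @export
load_genome <- function(scaffold_fasta, gene_table, strain_id,
                        genetic_code = "11") {
  scaffolds <- if (is.data.frame(scaffold_fasta)) scaffold_fasta else
    read_fasta(scaffold_fasta, "nucleotide")
  genes <- if (is.data.frame(gene_table)) as_tibble(gene_table) else
    read_gene_table(gene_table)
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in gene table")
  scaf_len <- setNames(nchar(scaffolds$seq), scaffolds$id)
  unknown <- setdiff(genes$scaffold_id, scaffolds$id)
  if (length(unknown)) {
    abort(paste0("gene table references unknown scaffold(s): ",
                 paste(unknown, collapse = ", ")))
  }
  bad_coord <- genes$start < 1L | genes$end > scaf_len[genes$scaffold_id] |
    genes$start > genes$end
  if (any(bad_coord)) {
    abort(paste0("gene coordinates outside scaffold for: ",
                 paste(genes$gene_id[bad_coord], collapse = ", ")))
  }
  cds <- substring(scaffolds$seq[match(genes$scaffold_id, scaffolds$id)],
                   genes$start, genes$end)
  minus <- genes$strand == "-"
  if (any(minus)) cds[minus] <- reverse_complement(cds[minus])

  excluded <- tibble(gene_id = character(), reason = character())
  bad_len <- nchar(cds) %% 3L != 0L
  if (any(bad_len)) {
    warn(paste0("excluding gene(s) with length not divisible by 3: ",
                paste(genes$gene_id[bad_len], collapse = ", ")))
    excluded <- bind_rows(excluded, tibble(gene_id = genes$gene_id[bad_len],
                                           reason = "length_not_multiple_of_3"))
    genes <- genes[!bad_len, ]; cds <- cds[!bad_len]
  }
  prot <- translate_cds(cds, genetic_code)
  # trailing stop trimmed; internal stop disqualifies the gene
  prot <- sub("\\*$", "", prot)
  internal_stop <- grepl("*", prot, fixed = TRUE)
  if (any(internal_stop)) {
    warn(paste0("excluding gene(s) with internal stop codon: ",
                paste(genes$gene_id[internal_stop], collapse = ", ")))
    excluded <- bind_rows(excluded,
                          tibble(gene_id = genes$gene_id[internal_stop],
                                 reason = "internal_stop"))
    genes <- genes[!internal_stop, ]
    cds <- cds[!internal_stop]
    prot <- prot[!internal_stop]
  }
  genome_record(strain_id, scaffolds, genes,
                cds = tibble(gene_id = genes$gene_id, seq = cds),
                proteins = tibble(gene_id = genes$gene_id, seq = prot),
                excluded = excluded)
}

#' Construct a genome record from in-memory tables
#'
#' @param strain_id Strain identifier.
#' @param scaffolds Sequence tibble of nucleotide scaffolds.
#' @param genes Gene-annotation tibble.
#' @param cds,proteins Tibbles with `gene_id`, `seq` (one entry per gene).
#' @param excluded Tibble of excluded genes (`gene_id`, `reason`).
#' @return A `genome_record`.
#' @export
genome_record <- function(strain_id, scaffolds, genes, cds, proteins,
                          excluded = tibble(gene_id = character(),
                                            reason = character())) {
  stopifnot(identical(sort(genes$gene_id), sort(cds$gene_id)),
            identical(sort(genes$gene_id), sort(proteins$gene_id)))
  structure(list(strain_id = strain_id, scaffolds = scaffolds,
                 genes = as_tibble(genes), cds = as_tibble(cds),
                 proteins = as_tibble(proteins), excluded = excluded),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d scaffold(s), %s bp, %d gene(s)\n",
              x$strain_id, nrow(x$scaffolds),
              format(sum(nchar(x$scaffolds$seq)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Write a genome record to disk
#'
#' Writes the scaffold FASTA, the gene table TSV and a JSON manifest
#' (strain id, file names, basic statistics) under `dir`; the pair of files
#' round-trips through [load_genome()].
#'
#' @param g A `genome_record`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_genome <- function(g, dir) {
  stopifnot(inherits(g, "genome_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(g$strain_id, ".fasta"))
  tsv <- file.path(dir, paste0(g$strain_id, "_genes.tsv"))
  manifest <- file.path(dir, paste0(g$strain_id, "_manifest.json"))
  write_fasta(g$scaffolds, fasta)
  write_gene_table(g$genes, tsv)
  jsonlite::write_json(list(strain_id = g$strain_id,
                            scaffold_fasta = basename(fasta),
                            gene_table = basename(tsv),
                            n_scaffolds = nrow(g$scaffolds),
                            total_bp = sum(nchar(g$scaffolds$seq)),
                            n_genes = nrow(g$genes)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(scaffold_fasta = fasta, gene_table = tsv, manifest = manifest))
}
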