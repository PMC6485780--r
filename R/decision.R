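# Taxonomic demarcation rules: the 16S identity screen and the
# genomic-index thresholds that turn relatedness values into a species
# verdict.

#' Demarcation thresholds
#'
#' Defaults: 16S species boundary 98.65% and genus boundary 95%; dDDH
#' species boundary 70%; AAI species boundary 95% (the lower edge of the
#' conventional 95-96% band, conservative toward declaring conspecificity).
#' Boundary equality always resolves to the non-novel side.
#'
#' @param s16_species,s16_genus 16S rRNA identity thresholds (percent).
#' @param ddh_species dDDH species threshold (percent).
#' @param aai_species AAI species threshold (percent).
#' @return A `thresholds` list.
#' @export
thresholds <- function(s16_species = 98.65, s16_genus = 95,
                       ddh_species = 70, aai_species = 95) {
  stopifnot(0 < s16_genus, s16_genus < s16_species, s16_species <= 100,
            0 < ddh_species, ddh_species <= 100,
            0 < aai_species, aai_species <= 100)
  structure(list(s16_species = s16_species, s16_genus = s16_genus,
                 ddh_species = ddh_species, aai_species = aai_species),
            class = "thresholds")
}

VERDICTS <- c("same_species", "new_species_same_genus", "possible_new_genus",
              "inconclusive")

taxonomic_call <- function(verdict, evidence, narrative, provisional = FALSE) {
  stopifnot(verdict %in% VERDICTS)
  structure(list(verdict = verdict, evidence = evidence,
                 narrative = narrative, provisional = provisional),
            class = "taxonomic_call")
}

#' @export
print.taxonomic_call <- function(x, ...) {
  cat(sprintf("<taxonomic_call> %s%s\n", x$verdict,
              if (isTRUE(x$provisional)) " (provisional)" else ""))
  cat(x$narrative, "\n")
  print(x$evidence)
  invisible(x)
}

#' @method tidy taxonomic_call
#' @export
tidy.taxonomic_call <- function(x, ...) x$evidence

evidence_row <- function(metric, value, threshold, direction, passed) {
  tibble(metric = metric, value = value, threshold = threshold,
         direction = direction, passed = passed)
}

#' Classify a strain from its 16S rRNA identity
#'
#' Identity at or above the species threshold supports conspecificity (a
#' hypothesis flagged as requiring genomic confirmation); identity strictly
#' between the genus and species thresholds proposes a new species within
#' the genus; identity at or below the genus threshold flags a possible new
#' genus.
#'
#' @param identity 16S identity with the closest named species (percent).
#' @param t [thresholds()].
#' @return A `taxonomic_call`.
#' @export
#' @examples
#' classify_16s(96.57)
classify_16s <- function(identity, t = thresholds()) {
  if (!is.finite(identity) || identity < 0 || identity > 100) {
    abort("16S identity must be a percentage in [0, 100]")
  }
  if (identity >= t$s16_species) {
    taxonomic_call(
      "same_species",
      evidence_row("16S_identity", identity, t$s16_species, ">=", TRUE),
      sprintf(paste0("16S identity %.2f%% is at or above the %.2f%% species",
                     " threshold: conspecific hypothesis, requires genomic",
                     " confirmation."), identity, t$s16_species),
      provisional = TRUE)
  } else if (identity > t$s16_genus) {
    taxonomic_call(
      "new_species_same_genus",
      bind_rows(
        evidence_row("16S_identity", identity, t$s16_species, "<", TRUE),
        evidence_row("16S_identity", identity, t$s16_genus, ">", TRUE)),
      sprintf(paste0("16S identity %.2f%% lies between the %.2f%% genus and",
                     " %.2f%% species thresholds: proposed new species",
                     " within the genus."),
              identity, t$s16_genus, t$s16_species))
  } else {
    taxonomic_call(
      "possible_new_genus",
      evidence_row("16S_identity", identity, t$s16_genus, "<=", TRUE),
      sprintf("16S identity %.2f%% is at or below the %.2f%% genus threshold: possible new genus.",
              identity, t$s16_genus))
  }
}

#' Classify a genome pair from its relatedness indices
#'
#' dDDH and AAI both below their species thresholds declare a distinct
#' species; both at or above declare conspecificity; a conflicting signal
#' (one above, one below) is reported as inconclusive with both facts in the
#' evidence, never auto-resolved.
#'
#' @param cr A `comparison_result` (or anything with `ddh` and `aai`
#'   fields).
#' @param t [thresholds()].
#' @return A `taxonomic_call`.
#' @export
classify_genomic <- function(cr, t = thresholds()) {
  ddh <- cr$ddh; aai <- cr$aai
  other <- if (!is.null(cr$strain_b)) paste0(" vs ", cr$strain_b) else ""
  ev <- bind_rows(
    evidence_row("dDDH", ddh, t$ddh_species, "<", ddh < t$ddh_species),
    evidence_row("AAI", aai, t$aai_species, "<", aai < t$aai_species))
  if (ddh < t$ddh_species && aai < t$aai_species) {
    taxonomic_call("new_species_same_genus", ev,
                   sprintf("dDDH %.2f%% < %.4g%% and AAI %.2f%% < %.4g%%%s: distinct species.",
                           ddh, t$ddh_species, aai, t$aai_species, other))
  } else if (ddh >= t$ddh_species && aai >= t$aai_species) {
    taxonomic_call("same_species", ev,
                   sprintf("dDDH %.2f%% and AAI %.2f%%%s are at or above the species thresholds: same species.",
                           ddh, aai, other))
  } else {
    taxonomic_call("inconclusive", ev,
                   sprintf("conflicting signals%s: dDDH %.2f%% vs %.4g%% and AAI %.2f%% vs %.4g%%.",
                           other, ddh, t$ddh_species, aai, t$aai_species))
  }
}

#' Combined species report
#'
#' Combines the 16S call and the per-comparator genomic calls into an
#' overall verdict: the most specific call supported by every line of
#' evidence. Unanimous genomic evidence dominates the 16S screen (the role
#' digital DDH plays in place of wet-lab hybridization); contradictions are
#' reported as inconclusive. With no genomic calls the 16S verdict is
#' returned, flagged provisional.
#'
#' @param strain Strain identifier.
#' @param s16 The 16S `taxonomic_call`.
#' @param genomic List of genomic `taxonomic_call`s (possibly empty).
#' @param tree Optional `ape::phylo` placing the strain (its Newick string
#'   is embedded in the report).
#' @return A `species_report` list: `strain`, `overall`, `provisional`,
#'   `calls`, `evidence`, `narrative`, `newick`.
#' @export
species_report <- function(strain, s16, genomic = list(), tree = NULL) {
  stopifnot(inherits(s16, "taxonomic_call"))
  genomic_names <- if (length(genomic)) paste0("genomic_", seq_along(genomic)) else NULL
  calls <- c(list(`16S` = s16), setNames(genomic, genomic_names))
  provisional <- FALSE
  if (length(genomic) == 0L) {
    overall <- s16$verdict
    provisional <- TRUE
    why <- "no genomic comparisons: 16S call reported provisionally"
  } else {
    gv <- unique(map_chr(genomic, "verdict"))
    if (length(gv) > 1L || "inconclusive" %in% gv) {
      overall <- "inconclusive"
      why <- "genomic comparisons disagree or are individually inconclusive"
    } else if (gv == "new_species_same_genus") {
      if (s16$verdict == "possible_new_genus") {
        overall <- "possible_new_genus"
        why <- "genomic indices separate the strain from every comparator and 16S falls below the genus bound"
      } else {
        overall <- "new_species_same_genus"
        why <- "all dDDH and AAI values fall below the species thresholds"
      }
    } else { # genomic says same_species
      if (s16$verdict == "same_species") {
        overall <- "same_species"
        why <- "16S and genomic indices agree on conspecificity"
      } else {
        overall <- "inconclusive"
        why <- "genomic indices indicate conspecificity but the 16S screen does not"
      }
    }
  }
  evidence <- bind_rows(imap(calls, function(cl, nm) {
    mutate(cl$evidence, call = nm, .before = 1)
  }))
  narrative <- c(sprintf("Strain %s: overall verdict %s (%s).", strain, overall, why),
                 map_chr(calls, "narrative"))
  structure(list(strain = strain, overall = overall, provisional = provisional,
                 calls = calls, evidence = evidence, narrative = narrative,
                 newick = if (!is.null(tree)) to_newick(tree) else NULL),
            class = "species_report")
}

#' @export
print.species_report <- function(x, ...) {
  cat(sprintf("<species_report> %s: %s%s\n", x$strain, x$overall,
              if (x$provisional) " (provisional)" else ""))
  for (line in x$narrative) cat(" ", line, "\n")
  invisible(x)
}

#' @method tidy species_report
#' @export
tidy.species_report <- function(x, ...) x$evidence

#' @method glance species_report
#' @export
glance.species_report <- function(x, ...) {
  tibble(strain = x$strain, overall = x$overall, provisional = x$provisional,
         n_genomic_calls = length(x$calls) - 1L)
}

#' Write a species report to disk
#'
#' Writes `<strain>_report.json` (machine-readable: verdict, evidence,
#' narrative, Newick) and `<strain>_report.txt` (the narrative). Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param report A `species_report`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_species_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, paste0(report$strain, "_report.json"))
  txt_path <- file.path(dir, paste0(report$strain, "_report.txt"))
  jsonlite::write_json(
    list(strain = report$strain, overall = report$overall,
         provisional = report$provisional,
         evidence = report$evidence, narrative = report$narrative,
         newick = report$newick),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(report$narrative, txt_path)
  invisible(c(json = json_path, text = txt_path))
}
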