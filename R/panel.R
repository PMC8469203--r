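## Packaged reference panel: the curated 36-taxon but-gene target table
## and the six-cluster degenerate primer panel, shipped as TSV fixtures
## under inst/extdata and loaded here.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "butqPCR")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}

.readPanelTsv <- function(path, required) {
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "",
                      na.strings = NULL, comment.char = "#"),
    error = function(e) stop("malformed fixture ", path, ": ",
                             conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("fixture ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != length(names(df)))
  # a trailing empty field drops off strsplit(); tolerate one short
  bad <- bad[nf[bad] != length(names(df)) - 1L]
  if (length(bad)) {
    stop("fixture ", path, ": wrong field count at line ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Load the curated but-gene target table
#'
#' Returns the packaged table of human-gut butyrate producers carrying
#' the butyryl-CoA:acetate CoA-transferase (but) gene: 36 records of
#' taxon (including strain), NCBI nucleotide and protein accession, and
#' -- where recoverable from the study text -- the primer cluster (A-F)
#' the taxon belongs to. Unassignable records carry an empty cluster
#' label.
#'
#' @return data.frame with columns `taxon`, `nt_accession`,
#'   `prot_accession`, `cluster`.
#' @examples
#' nrow(loadReferencePanel())  # 36
#' @export
loadReferencePanel <- function() {
  df <- .readPanelTsv(.extdata("targets.tsv"),
                      c("taxon", "nt_accession", "prot_accession",
                        "cluster"))
  if (any(!nzchar(df$taxon)) || any(!nzchar(df$nt_accession))) {
    stop("targets fixture: empty taxon or accession")
  }
  key <- paste(df$taxon, df$nt_accession)
  if (anyDuplicated(key)) {
    stop("targets fixture: duplicate (taxon, nt_accession) pair")
  }
  ok <- df$cluster %in% c("", LETTERS[1:6])
  if (!all(ok)) stop("targets fixture: invalid cluster label")
  df
}

#' Load the packaged six-cluster degenerate primer panel
#'
#' The six degenerate primer pairs (clusters A-F) targeting the but
#' gene, with their expected product lengths.
#'
#' @return a [PrimerPanel-class] with six [PrimerPair-class] entries.
#' @examples
#' panel <- loadPrimerPanel()
#' pairDegeneracy(panel[["A"]])  # 8
#' @export
loadPrimerPanel <- function() {
  df <- .readPanelTsv(.extdata("primers.tsv"),
                      c("cluster", "fwd", "rev", "expected_len"))
  PrimerPanel(lapply(seq_len(nrow(df)), function(i) {
    PrimerPair(df$cluster[i], df$fwd[i], df$rev[i],
               as.integer(df$expected_len[i]))
  }))
}

#' Write a primer panel to TSV
#'
#' Emits the same schema the packaged `primers.tsv` fixture uses, so a
#' de-novo designed panel can be reloaded with the same reader.
#'
#' @param panel a [PrimerPanel-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writePrimerPanel <- function(panel, path) {
  stopifnot(is(panel, "PrimerPanel"))
  df <- as.data.frame(panel)[, c("cluster", "fwd", "rev", "expected_len")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a primer panel from TSV
#'
#' @param path TSV in the `primers.tsv` schema (columns cluster, fwd,
#'   rev, expected_len).
#' @return a [PrimerPanel-class].
#' @export
readPrimerPanel <- function(path) {
  df <- .readPanelTsv(path, c("cluster", "fwd", "rev", "expected_len"))
  PrimerPanel(lapply(seq_len(nrow(df)), function(i) {
    PrimerPair(df$cluster[i], df$fwd[i], df$rev[i],
               as.integer(df$expected_len[i]))
  }))
}

#' Download manifest for the target-table accessions
#'
#' The package performs no network access; users who want to validate
#' the panel against the real templates can feed this manifest of NCBI
#' nucleotide accessions to their retrieval tool of choice and pass the
#' resulting FASTA to [predictAmplicons()] / [offtargetScreen()].
#'
#' @param path optional file to write the manifest to (one accession
#'   per line).
#' @return character vector of unique nucleotide accessions, invisibly
#'   when `path` is given.
#' @export
accessionManifest <- function(path = NULL) {
  acc <- unique(loadReferencePanel()$nt_accession)
  if (!is.null(path)) {
    writeLines(acc, path)
    return(invisible(acc))
  }
  acc
}
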