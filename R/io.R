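# Readers and writers: UniRef-style FASTA, de novo read CSV, annotation TSV,
# and deterministic report tables. FASTA I/O is delegated to Biostrings;
# header parsing of the UniRef dialect (TaxID=<int> token) lives here.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y")

#' Parse a UniRef-dialect protein FASTA
#'
#' One record per entry. The accession is the first whitespace-delimited
#' header token; the taxid is parsed from a \code{TaxID=<int>} token. Records
#' lacking a TaxID are kept with \code{taxid = NA} and a warning (they are
#' excluded from taxonomic analyses downstream, never silently dropped).
#'
#' @param path FASTA file path; any line wrapping is accepted.
#' @return A data.frame of class \code{protein_db} with columns
#'   \code{accession}, \code{description}, \code{taxid}, \code{sequence},
#'   \code{supplement} (tag for merged supplement records, \code{NA} here).
#' @export
parse_uniref_fasta <- function(path) {
  if (!file.exists(path))
    ww_stop(sprintf("cannot read FASTA: %s", path), "ww_io_failure")
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  accession <- sub("\\s.*$", "", headers)
  if (any(!nzchar(accession))) {
    bad <- which(!nzchar(accession))[1]
    ww_stop(sprintf("FASTA header without accession (entry %d)", bad),
            "ww_format_error")
  }
  taxid_str <- regmatches(headers, regexpr("TaxID=[0-9]+", headers))
  taxid <- rep(NA_integer_, length(headers))
  has <- grepl("TaxID=[0-9]+", headers)
  taxid[has] <- as.integer(sub("TaxID=", "",
                               regmatches(headers,
                                          regexpr("TaxID=[0-9]+", headers))))
  if (any(!has))
    ww_warn(sprintf("%d FASTA record(s) lack a TaxID= token; kept with NA taxid",
                    sum(!has)), "ww_missing_taxid")
  description <- sub("^\\S+\\s*", "", headers)
  db <- data.frame(accession = accession, description = description,
                   taxid = taxid, sequence = toupper(as.character(seqs)),
                   supplement = NA_character_, stringsAsFactors = FALSE)
  if (anyDuplicated(db$accession))
    ww_stop("duplicate accessions in FASTA", "ww_format_error")
  if (any(!nzchar(db$sequence)))
    ww_stop("empty sequence in FASTA", "ww_format_error")
  class(db) <- c("protein_db", "data.frame")
  rownames(db) <- NULL
  db
}

#' Write proteins as UniRef-dialect FASTA
#'
#' Headers are \code{accession description}; sequences wrapped at 60
#' characters. A \code{TaxID=} token is appended when the record has a taxid
#' and the description does not already carry one.
#'
#' @param db a \code{protein_db} data.frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_uniref_fasta <- function(db, path) {
  desc <- db$description
  need_tax <- !is.na(db$taxid) & !grepl("TaxID=", desc)
  desc[need_tax] <- trimws(paste0(desc[need_tax], " TaxID=", db$taxid[need_tax]))
  hdr <- trimws(paste(db$accession, desc))
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Construct a protein database from vectors
#'
#' @param accession,sequence character vectors.
#' @param taxid integer vector (NA allowed).
#' @param description optional character vector.
#' @param supplement optional supplement tag per record.
#' @return A \code{protein_db} data.frame.
#' @export
protein_db <- function(accession, sequence, taxid = NA_integer_,
                       description = "", supplement = NA_character_) {
  db <- data.frame(accession = accession, description = description,
                   taxid = as.integer(taxid), sequence = toupper(sequence),
                   supplement = supplement, stringsAsFactors = FALSE)
  if (anyDuplicated(db$accession))
    ww_stop("duplicate accessions", "ww_validation_error")
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Parse a de novo peptide read CSV
#'
#' Expects at least columns \code{Peptide}, \code{ALC}, \code{Area} (an
#' optional \code{Sample} column carries the sample id). Modification
#' annotations in the peptide string are retained verbatim.
#'
#' @param path CSV path.
#' @param sample_id sample id to assign when the file has no Sample column.
#' @return data.frame with columns \code{peptide}, \code{alc}, \code{area},
#'   \code{sample_id}.
#' @export
parse_denovo_csv <- function(path, sample_id = NA_character_) {
  if (!file.exists(path))
    ww_stop(sprintf("cannot read de novo CSV: %s", path), "ww_io_failure")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("Peptide", "ALC", "Area"))
    if (!col %in% names(df))
      ww_stop(sprintf("de novo CSV missing required column '%s'", col),
              "ww_format_error")
  if (nrow(df) == 0L)
    return(data.frame(peptide = character(0), alc = numeric(0),
                      area = numeric(0), sample_id = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(peptide = as.character(df$Peptide),
                    alc = as.numeric(df$ALC),
                    area = as.numeric(df$Area),
                    sample_id = if ("Sample" %in% names(df))
                      as.character(df$Sample) else sample_id,
                    stringsAsFactors = FALSE)
  if (any(is.na(out$alc)) || any(out$alc < 0 | out$alc > 100))
    ww_stop("ALC values must lie in [0, 100]", "ww_validation_error")
  if (any(is.na(out$area)) || any(out$area < 0))
    ww_stop("Area values must be non-negative", "ww_validation_error")
  out
}

#' Write de novo reads as CSV
#'
#' @param reads data.frame with \code{peptide}, \code{alc}, \code{area} and
#'   optionally \code{sample_id}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_denovo_csv <- function(reads, path) {
  df <- data.frame(Peptide = reads$peptide, ALC = reads$alc,
                   Area = reads$area)
  if (!is.null(reads$sample_id)) df$Sample <- reads$sample_id
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read annotation lists (TSV: list_name, level, member)
#'
#' @param path TSV path.
#' @return Named list of annotation lists; each element has \code{level}
#'   (genus / family / protein_accession) and a character vector
#'   \code{members}.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path))
    ww_stop(sprintf("cannot read annotation TSV: %s", path), "ww_io_failure")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("list_name", "level", "member"))
    if (!col %in% names(df))
      ww_stop(sprintf("annotation TSV missing column '%s'", col),
              "ww_format_error")
  out <- lapply(split(df, df$list_name), function(d) {
    lv <- unique(d$level)
    if (length(lv) != 1L)
      ww_stop(sprintf("annotation list '%s' mixes levels", d$list_name[1]),
              "ww_validation_error")
    list(level = lv, members = unique(d$member))
  })
  out
}

#' Write a report table as TSV
#'
#' Tab-separated UTF-8 with a header row; numeric columns rendered with six
#' significant digits. Unless \code{sort_by} says otherwise, rows are sorted
#' by descending total area then ascending accession when those columns are
#' present, making repeated writes byte-identical.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param sort_by optional character vector of column names; prefix a name
#'   with \code{"-"} for descending order.
#' @return Invisibly, \code{path}.
#' @export
write_report_tsv <- function(table, path, sort_by = NULL) {
  df <- as.data.frame(table)
  if (is.null(sort_by)) {
    sort_by <- character(0)
    if ("overall_area" %in% names(df)) sort_by <- c(sort_by, "-overall_area")
    else if ("area" %in% names(df)) sort_by <- c(sort_by, "-area")
    if ("accession" %in% names(df)) sort_by <- c(sort_by, "accession")
  }
  if (length(sort_by) && nrow(df) > 1L) {
    keys <- lapply(sort_by, function(k) {
      desc <- startsWith(k, "-")
      col <- df[[sub("^-", "", k)]]
      if (desc) {
        if (is.numeric(col)) -col else -xtfrm(col)
      } else xtfrm(col)
    })
    df <- df[do.call(order, keys), , drop = FALSE]
  }
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(signif(x, 6), format = "g",
                                                 digits = 6))
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e)
                    ww_stop(sprintf("cannot write: %s", path), "ww_io_failure"))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
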