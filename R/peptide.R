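# In silico tryptic digestion and the peptide->protein index that both the
# de novo profiler and the two-round search are built on. De novo calls cannot
# distinguish isoleucine from leucine, so peptides are canonicalized with both
# residues rewritten to the unused letter "J" before any comparison; the
# optional one-substitution matching mode gives sequencing errors a realistic
# chance of producing (false) matches, which is what exercises the FDR
# machinery.

# canonical alphabet after I/L -> J collapse (X = unknown residue)
CANON_ALPHABET <- c("A","C","D","E","F","G","H","J","K","M","N","P","Q",
                    "R","S","T","V","W","Y","X")

#' Tryptic in silico digestion
#'
#' Cleaves after K or R except when the next residue is P, and returns all
#' products spanning 0..\code{missed_cleavages} internal missed sites whose
#' length lies within \code{[min_len, max_len]}, deduplicated.
#'
#' @param sequence amino-acid string (20-letter alphabet, X allowed).
#' @param missed_cleavages maximum internal missed cleavage sites.
#' @param min_len,max_len product length bounds.
#' @return Character vector of peptides (order of first occurrence).
#' @export
digest <- function(sequence, missed_cleavages = 0L, min_len = 6L,
                   max_len = 50L) {
  if (!nzchar(sequence))
    ww_stop("cannot digest an empty sequence", "ww_validation_error")
  if (grepl("[^A-Z]", sequence) ||
      grepl(sprintf("[^%s]", paste(c(AA_ALPHABET, "X"), collapse = "")),
            sequence))
    ww_stop("sequence contains non-amino-acid characters",
            "ww_validation_error")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  after <- which(chars %in% c("K", "R"))
  after <- after[after == n | chars[pmin(after + 1L, n)] != "P"]
  bounds <- unique(c(0L, after, n))
  k <- length(bounds)
  peps <- character(0)
  for (i in seq_len(k - 1L)) {
    jmax <- min(k, i + 1L + missed_cleavages)
    for (j in (i + 1L):jmax) {
      len <- bounds[j] - bounds[i]
      if (len >= min_len && len <= max_len)
        peps <- c(peps, substr(sequence, bounds[i] + 1L, bounds[j]))
    }
  }
  unique(peps)
}

#' Canonicalize a peptide string
#'
#' Strips modification annotations of the form \code{(+15.99)} (any
#' parenthesised token), uppercases, and rewrites I and L to J.
#'
#' @param peptide character vector of peptide strings.
#' @return Character vector of canonical peptides.
#' @export
canonicalize <- function(peptide) {
  if (any(!nzchar(peptide)))
    ww_stop("cannot canonicalize an empty peptide", "ww_validation_error")
  x <- gsub("\\([^)]*\\)", "", peptide)
  x <- toupper(gsub("[^A-Za-z]", "", x))
  chartr("IL", "JJ", x)
}

#' Build a canonical-peptide -> protein index
#'
#' Digests every record under the stored parameters and maps each canonical
#' digestion product to the accessions containing it.
#'
#' @param db a \code{protein_db} data.frame.
#' @param missed_cleavages,min_len,max_len digestion parameters.
#' @return An object of class \code{peptide_index}.
#' @export
build_index <- function(db, missed_cleavages = 1L, min_len = 6L,
                        max_len = 50L) {
  env <- new.env(parent = emptyenv(), size = max(29L, nrow(db) * 32L))
  for (i in seq_len(nrow(db))) {
    peps <- canonicalize(digest(db$sequence[i], missed_cleavages,
                                min_len, max_len))
    acc <- db$accession[i]
    for (p in unique(peps)) {
      cur <- env[[p]]
      env[[p]] <- if (is.null(cur)) acc else c(cur, acc)
    }
  }
  structure(list(map = env,
                 taxid = stats::setNames(db$taxid, db$accession),
                 params = list(missed_cleavages = missed_cleavages,
                               min_len = min_len, max_len = max_len)),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index> %d peptides, %d proteins (mc=%d, len %d-%d)\n",
              length(ls(x$map)), length(x$taxid),
              x$params$missed_cleavages, x$params$min_len, x$params$max_len))
  invisible(x)
}

#' Peptides stored in an index
#'
#' @param index a \code{peptide_index}.
#' @return Character vector of canonical peptides.
#' @export
index_peptides <- function(index) ls(index$map)

#' Look up a canonical peptide in the index
#'
#' With \code{max_subs = 0} an exact lookup; with \code{max_subs = 1} the
#' union of exact hits and hits at Hamming distance exactly one (same
#' length).
#'
#' @param index a \code{peptide_index}.
#' @param peptide one canonical peptide.
#' @param max_subs 0 or 1 substitutions tolerated.
#' @return Character vector of matched accessions (possibly empty).
#' @export
match_peptide <- function(index, peptide, max_subs = 0L) {
  if (!max_subs %in% c(0L, 1L))
    ww_stop("max_subs must be 0 or 1", "ww_validation_error")
  hits <- index$map[[peptide]]
  if (max_subs == 1L) {
    chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
    for (pos in seq_along(chars)) {
      orig <- chars[pos]
      for (a in CANON_ALPHABET) {
        if (a == orig) next
        chars[pos] <- a
        h <- index$map[[paste(chars, collapse = "")]]
        if (!is.null(h)) hits <- c(hits, h)
      }
      chars[pos] <- orig
    }
  }
  unique(hits %||% character(0))
}
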