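# Stage 1: taxonomic profiling of de novo reads. Reads passing the ALC filter
# are matched against the global reference index; each peptide is assigned the
# lowest common ancestor of its matched proteins' taxa, and peptides whose LCA
# resolves to (or below) family rank are accumulated into a per-sample family
# profile. Families supported by enough distinct peptides are "identified" and
# drive database focusing.

#' Filter de novo reads by ALC score
#'
#' Keeps reads whose average local confidence is greater than or equal to the
#' threshold (inclusive); input order preserved.
#'
#' @param reads data.frame with at least \code{alc}.
#' @param threshold ALC threshold in [0, 100]; default 70.
#' @return The filtered data.frame.
#' @export
filter_alc <- function(reads, threshold = 70) {
  if (threshold < 0 || threshold > 100)
    ww_stop("ALC threshold must lie in [0, 100]", "ww_validation_error")
  reads[reads$alc >= threshold, , drop = FALSE]
}

#' Profile one sample at family level
#'
#' Reads sharing a canonical peptide are merged (areas summed) before
#' matching. Each matched peptide gets the LCA over its matched records'
#' taxids; the peptide contributes to the family on the LCA's lineage when one
#' is defined (an LCA above family rank contributes to no family). Families
#' with at least \code{min_family_peptides} distinct peptides are flagged
#' identified.
#'
#' @param reads ALC-filtered de novo reads (\code{peptide}, \code{area},
#'   optionally \code{sample_id}).
#' @param index \code{peptide_index} over the global reference.
#' @param store a \code{taxonomy_store}.
#' @param min_family_peptides identification threshold on distinct peptides.
#' @param max_subs substitutions tolerated when matching (default exact).
#' @return A data.frame of class \code{family_profile} with columns
#'   \code{sample_id}, \code{family_taxid}, \code{family_name},
#'   \code{peptide_count}, \code{area}, \code{identified}; attributes
#'   \code{n_matched} and \code{n_unmatched} count merged peptides.
#' @export
profile_sample <- function(reads, index, store, min_family_peptides = 2L,
                           max_subs = 0L) {
  sample_id <- if (nrow(reads) && !is.null(reads$sample_id))
    reads$sample_id[1] else NA_character_
  empty <- data.frame(sample_id = character(0), family_taxid = integer(0),
                      family_name = character(0), peptide_count = integer(0),
                      area = numeric(0), identified = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("family_profile", "data.frame")
  if (nrow(reads) == 0L) {
    ww_warn("profile_sample: no reads after filtering", "ww_empty_profile")
    attr(empty, "n_matched") <- 0L
    attr(empty, "n_unmatched") <- 0L
    return(empty)
  }
  pep <- canonicalize(reads$peptide)
  area <- tapply(reads$area, pep, sum)
  peptides <- names(area)
  fam <- rep(NA_integer_, length(peptides))
  matched <- logical(length(peptides))
  for (i in seq_along(peptides)) {
    acc <- match_peptide(index, peptides[i], max_subs = max_subs)
    if (length(acc) == 0L) next
    tax <- unique(index$taxid[acc])
    tax <- tax[!is.na(tax)]
    if (length(tax) == 0L) next
    matched[i] <- TRUE
    node <- lca(store, tax)
    fam[i] <- rank_taxid(store, node, "family")
  }
  keep <- !is.na(fam)
  if (!any(keep)) {
    attr(empty, "n_matched") <- sum(matched)
    attr(empty, "n_unmatched") <- sum(!matched)
    empty$sample_id <- character(0)
    return(empty)
  }
  counts <- table(fam[keep])
  areas <- tapply(as.numeric(area)[keep], fam[keep], sum)
  fam_tax <- as.integer(names(counts))
  out <- data.frame(sample_id = sample_id, family_taxid = fam_tax,
                    family_name = taxon_name(store, fam_tax),
                    peptide_count = as.integer(counts),
                    area = as.numeric(areas),
                    stringsAsFactors = FALSE)
  out$identified <- out$peptide_count >= min_family_peptides
  out <- out[order(-out$peptide_count, out$family_taxid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("family_profile", "data.frame")
  attr(out, "n_matched") <- sum(matched)
  attr(out, "n_unmatched") <- sum(!matched)
  out
}

#' Families identified in a profile
#'
#' @param profile a \code{family_profile}.
#' @return Integer vector of family taxids flagged identified.
#' @export
identified_families <- function(profile) {
  profile$family_taxid[profile$identified]
}
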