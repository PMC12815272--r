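# Stage 4: protein grouping, unique-peptide accounting and top-3 peptide-area
# quantification. Grouping is parsimony-style: proteins with identical peptide
# evidence are merged, and a protein whose peptide set is a strict subset of
# another's is subsumed into that protein's group. Shared peptides contribute
# their area to every group they match (no razor assignment).

#' Group proteins by peptide evidence
#'
#' @param pep_sets named list: accession -> character vector of peptides
#'   (each protein must have at least one peptide).
#' @return List of groups, each a list with \code{members} (accessions,
#'   sorted) and \code{peptides} (the group's maximal peptide set).
#'   Deterministic: proteins are processed by decreasing peptide-set size,
#'   ties by ascending accession; a subsumable protein joins the earliest
#'   matching group.
#' @export
group_proteins <- function(pep_sets) {
  if (length(pep_sets) == 0L) return(list())
  if (any(lengths(pep_sets) == 0L))
    ww_stop("every protein must have at least one peptide",
            "ww_validation_error")
  pep_sets <- lapply(pep_sets, unique)
  ord <- order(-lengths(pep_sets), names(pep_sets))
  groups <- list()
  for (i in ord) {
    acc <- names(pep_sets)[i]
    peps <- pep_sets[[i]]
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(peps %in% groups[[g]]$peptides)) {
        groups[[g]]$members <- c(groups[[g]]$members, acc)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      groups[[length(groups) + 1L]] <- list(members = acc, peptides = peps)
  }
  lapply(groups, function(g) {
    g$members <- sort(g$members)
    g$peptides <- sort(g$peptides)
    g
  })
}

#' Unique peptides per protein group
#'
#' A peptide is unique to a group iff it occurs in the peptide set of exactly
#' one group.
#'
#' @param groups output of \code{\link{group_proteins}}.
#' @return Integer vector: unique-peptide count per group.
#' @export
count_unique_peptides <- function(groups) {
  if (length(groups) == 0L) return(integer(0))
  all_peps <- unlist(lapply(groups, `[[`, "peptides"))
  incidence <- table(all_peps)
  vapply(groups, function(g)
    sum(incidence[g$peptides] == 1L), integer(1))
}

#' Top-3 peptide area
#'
#' Sum of the three largest peptide areas (all of them when fewer than
#' three).
#'
#' @param areas non-negative numeric vector.
#' @return A single non-negative number (0 for an empty vector).
#' @export
top3_area <- function(areas) {
  if (any(areas < 0)) ww_stop("areas must be non-negative",
                              "ww_validation_error")
  if (length(areas) == 0L) return(0)
  sum(sort(areas, decreasing = TRUE)[seq_len(min(3L, length(areas)))])
}

#' Build the protein-group quantification table
#'
#' Combines per-sample search results: protein peptide sets are unioned
#' across samples, proteins grouped, and each group quantified per sample by
#' the top-3 area over its peptide set (peptide area = summed area of that
#' peptide's surviving matches in the sample). The group representative
#' ("top hit") is the member with the largest overall top-3 area, ties broken
#' by ascending accession; its taxonomic lineage annotates the row.
#'
#' @param results list of \code{search_result} objects (one per sample).
#' @param store a \code{taxonomy_store} for lineage annotation.
#' @return A data.frame of class \code{quant_table}: one row per protein
#'   group with columns \code{group_id}, \code{accession} (representative),
#'   \code{members}, \code{taxid}, \code{n_peptides}, \code{n_unique},
#'   one \code{area_<sample>} column per sample, \code{overall_area} and the
#'   seven canonical rank names. Attribute \code{sample_ids} lists samples.
#' @export
build_quant_table <- function(results, store) {
  surv <- do.call(rbind, lapply(results, function(r) {
    s <- r$survivors
    if (nrow(s) == 0L) return(NULL)
    data.frame(sample_id = r$sample_id, peptide = s$peptide, area = s$area,
               accessions = I(s$accessions), stringsAsFactors = FALSE)
  }))
  samples <- vapply(results, `[[`, character(1), "sample_id")
  if (is.null(surv) || nrow(surv) == 0L)
    ww_stop("no surviving matches to quantify", "ww_empty_input")
  # peptide area per (sample, peptide)
  pep_area <- stats::aggregate(area ~ sample_id + peptide, data = surv,
                               FUN = sum)
  # protein -> peptide union across samples
  pairs <- unique(data.frame(
    accession = unlist(surv$accessions),
    peptide = rep(surv$peptide, lengths(surv$accessions)),
    stringsAsFactors = FALSE))
  pep_sets <- split(pairs$peptide, pairs$accession)
  groups <- group_proteins(pep_sets)
  n_unique <- count_unique_peptides(groups)
  area_of <- function(peps, sid) {
    sel <- pep_area$sample_id == sid & pep_area$peptide %in% peps
    top3_area(pep_area$area[sel])
  }
  taxids <- stats::setNames(
    unlist(lapply(results, function(r) r$proteins$taxid)),
    unlist(lapply(results, function(r) r$proteins$accession)))
  rows <- lapply(seq_along(groups), function(g) {
    grp <- groups[[g]]
    member_overall <- vapply(grp$members, function(m) {
      peps <- pep_sets[[m]]
      sum(vapply(samples, function(s) area_of(peps, s), numeric(1)))
    }, numeric(1))
    rep_acc <- grp$members[order(-member_overall, grp$members)][1]
    sa <- vapply(samples, function(s) area_of(grp$peptides, s), numeric(1))
    row <- data.frame(group_id = g, accession = rep_acc,
                      members = paste(grp$members, collapse = ";"),
                      taxid = unname(taxids[rep_acc]),
                      n_peptides = length(grp$peptides),
                      n_unique = n_unique[g], stringsAsFactors = FALSE)
    for (i in seq_along(samples))
      row[[paste0("area_", samples[i])]] <- sa[i]
    row$overall_area <- sum(sa)
    row
  })
  qt <- do.call(rbind, rows)
  lin <- lapply(qt$taxid, function(t) {
    if (is.na(t) || !has_taxid(store, t))
      return(stats::setNames(rep(NA_character_, length(CANONICAL_RANKS)),
                             CANONICAL_RANKS))
    l <- lineage(store, t)
    stats::setNames(l$name, l$rank)
  })
  for (r in CANONICAL_RANKS)
    qt[[r]] <- vapply(lin, `[[`, character(1), r)
  qt <- qt[order(-qt$overall_area, qt$accession), , drop = FALSE]
  rownames(qt) <- NULL
  class(qt) <- c("quant_table", "data.frame")
  attr(qt, "sample_ids") <- samples
  qt
}

#' Post-identification filters
#'
#' Retains protein groups with at least \code{min_unique} unique peptides and
#' an overall top-3 area (summed across all samples) strictly greater than
#' \code{min_overall_area}; the table already holds one row (the top hit) per
#' protein group, so the surviving rows are the retained representatives.
#'
#' @param table a \code{quant_table}.
#' @param min_unique minimum unique peptides (inclusive; default 2).
#' @param min_overall_area overall-area threshold (strict; default 5e5).
#' @return The filtered \code{quant_table}.
#' @export
apply_paper_filters <- function(table, min_unique = 2L,
                                min_overall_area = 5e5) {
  keep <- table$n_unique >= min_unique & table$overall_area > min_overall_area
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("quant_table", "data.frame")
  attr(out, "sample_ids") <- attr(table, "sample_ids")
  out
}
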