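# Stage 2: focused database construction. From the global reference, keep
# exactly the records whose lineage family is among the identified families;
# supplements (e.g. the human reference proteome in round two) are merged in
# with a tag so provenance stays visible.

#' Select reference records by taxonomic family
#'
#' @param global a \code{protein_db} (the global reference).
#' @param families integer vector of family-rank taxids.
#' @param store a \code{taxonomy_store}.
#' @return A \code{protein_db} restricted to records whose lineage family is
#'   in \code{families} (records without a taxid are excluded); attribute
#'   \code{provenance} carries the driving family set.
#' @export
select_by_family <- function(global, families, store) {
  families <- unique(as.integer(families))
  if (length(families)) {
    for (f in families) {
      if (!has_taxid(store, f))
        ww_stop(sprintf("unknown family taxid: %d", f), "ww_unknown_taxon")
      if (store$rank[[as.character(f)]] != "family")
        ww_stop(sprintf("taxid %d is not family-rank", f),
                "ww_validation_error")
    }
  } else {
    ww_warn("select_by_family: empty family set, empty database returned",
            "ww_empty_selection")
  }
  fam <- rank_taxid(store, global$taxid, "family")
  out <- global[!is.na(fam) & fam %in% families, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_db", "data.frame")
  attr(out, "provenance") <- families
  out
}

#' Merge a supplement into a focused database
#'
#' Union by accession with first occurrence winning; supplement records are
#' flagged with \code{tag}.
#'
#' @param a a \code{protein_db} (the focused database).
#' @param b a \code{protein_db} of supplement records.
#' @param tag supplement tag, e.g. \code{"human_UP000005640"}.
#' @return Merged \code{protein_db}; attribute \code{n_deduplicated} counts
#'   supplement records dropped as duplicates.
#' @export
merge_databases <- function(a, b, tag = "supplement") {
  dup <- b$accession %in% a$accession
  add <- b[!dup, , drop = FALSE]
  if (nrow(add)) add$supplement <- tag
  out <- rbind(as.data.frame(a), as.data.frame(add))
  rownames(out) <- NULL
  class(out) <- c("protein_db", "data.frame")
  attr(out, "provenance") <- attr(a, "provenance")
  attr(out, "n_deduplicated") <- sum(dup)
  out
}
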