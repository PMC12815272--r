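# Taxonomic tree storage, lineage resolution and lowest-common-ancestor queries.
#
# The store is loaded from NCBI-taxdump-dialect nodes.dmp/names.dmp files so
# synthetic fixtures and real NCBI dumps share one reader. Lineages are
# reported at the seven canonical ranks only; intermediate "no rank" (and any
# other non-canonical) nodes are traversed silently.

#' Canonical taxonomic ranks, root to leaf
#'
#' @format Character vector of the seven named ranks used for lineage
#'   reporting and rank-level composition.
#' @export
CANONICAL_RANKS <- c("superkingdom", "phylum", "class", "order",
                     "family", "genus", "species")

#' Build a taxonomy store from node and name tables
#'
#' @param taxid integer vector of taxon identifiers.
#' @param parent_taxid integer vector of parent identifiers; the root points
#'   to itself.
#' @param rank character vector of rank labels (canonical ranks or
#'   \code{"no rank"}).
#' @param name character vector of scientific names.
#' @return An object of class \code{taxonomy_store}.
#' @export
taxonomy_store <- function(taxid, parent_taxid, rank, name) {
  taxid <- as.integer(taxid)
  parent_taxid <- as.integer(parent_taxid)
  if (anyDuplicated(taxid))
    ww_stop("duplicate taxids in taxonomy", "ww_validation_error")
  if (any(taxid <= 0L))
    ww_stop("taxids must be positive", "ww_validation_error")
  roots <- taxid[taxid == parent_taxid]
  if (length(roots) != 1L)
    ww_stop(sprintf("taxonomy must have exactly one root, found %d",
                    length(roots)), "ww_validation_error")
  key <- as.character(taxid)
  parent <- stats::setNames(parent_taxid, key)
  ranks <- stats::setNames(as.character(rank), key)
  names_ <- stats::setNames(as.character(name), key)
  store <- structure(
    list(taxid = taxid, parent = parent, rank = ranks, name = names_,
         root = roots),
    class = "taxonomy_store")
  # reject cycles up front: every node must reach the root
  for (t in taxid) {
    seen <- 0L
    cur <- t
    while (cur != store$root) {
      cur <- parent[[as.character(cur)]]
      seen <- seen + 1L
      if (seen > length(taxid))
        ww_stop(sprintf("cycle detected in taxonomy near taxid %d", t),
                "ww_validation_error")
    }
  }
  store
}

#' @export
print.taxonomy_store <- function(x, ...) {
  cat(sprintf("<taxonomy_store> %d taxa, root=%d\n", length(x$taxid), x$root))
  tab <- table(x$rank)
  cat("  ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

has_taxid <- function(store, taxid) {
  as.character(taxid) %in% names(store$parent)
}

#' Read an NCBI-dialect taxonomy dump
#'
#' Parses \code{nodes.dmp} (taxid, parent, rank) and \code{names.dmp}
#' (scientific names only) in the pipe-and-tab delimited taxdump dialect.
#'
#' @param nodes_path path to \code{nodes.dmp}.
#' @param names_path path to \code{names.dmp}.
#' @return A \code{taxonomy_store}.
#' @export
read_taxdump <- function(nodes_path, names_path) {
  for (p in c(nodes_path, names_path))
    if (!file.exists(p))
      ww_stop(sprintf("taxonomy file not found: %s", p), "ww_io_failure")
  split_dmp <- function(lines) {
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nf <- split_dmp(readLines(nodes_path))
  if (any(lengths(nf) < 3L))
    ww_stop(sprintf("malformed nodes file: %s", nodes_path), "ww_format_error")
  taxid <- suppressWarnings(
    vapply(nf, function(f) as.integer(f[[1]]), integer(1)))
  parent <- suppressWarnings(
    vapply(nf, function(f) as.integer(f[[2]]), integer(1)))
  if (anyNA(taxid) || anyNA(parent))
    ww_stop(sprintf("non-integer taxids in nodes file: %s", nodes_path),
            "ww_format_error")
  rank <- vapply(nf, function(f) f[[3]], character(1))
  mf <- split_dmp(readLines(names_path))
  is_sci <- vapply(mf, function(f) length(f) >= 4L &&
                     grepl("scientific name", f[[4]]), logical(1))
  mf <- mf[is_sci]
  nm_taxid <- suppressWarnings(
    vapply(mf, function(f) as.integer(f[[1]]), integer(1)))
  if (anyNA(nm_taxid))
    ww_stop(sprintf("non-integer taxids in names file: %s", names_path),
            "ww_format_error")
  nm <- vapply(mf, function(f) f[[2]], character(1))
  name <- stats::setNames(nm, as.character(nm_taxid))[as.character(taxid)]
  name[is.na(name)] <- ""
  taxonomy_store(taxid, parent, rank, unname(name))
}

#' Write a taxonomy store as nodes.dmp/names.dmp
#'
#' @param store a \code{taxonomy_store}.
#' @param nodes_path,names_path output paths.
#' @return Invisibly, the store.
#' @export
write_taxdump <- function(store, nodes_path, names_path) {
  key <- as.character(store$taxid)
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", store$taxid,
                   unname(store$parent[key]), unname(store$rank[key]))
  names_ <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", store$taxid,
                    unname(store$name[key]))
  writeLines(nodes, nodes_path)
  writeLines(names_, names_path)
  invisible(store)
}

# Path of taxids from a node up to (and including) the root.
ancestor_path <- function(store, taxid) {
  if (!has_taxid(store, taxid))
    ww_stop(sprintf("unknown taxid: %s", taxid), "ww_unknown_taxon")
  path <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    path <- c(path, cur)
    if (cur == store$root) break
    cur <- store$parent[[as.character(cur)]]
  }
  path
}

#' Canonical-rank lineage of a taxon
#'
#' Walks parent links from the query taxon to the root and reports the taxid
#' and scientific name at each of the seven canonical ranks; ranks not
#' encountered along the walk are \code{NA}.
#'
#' @param store a \code{taxonomy_store}.
#' @param taxid a taxid present in the store.
#' @return A data.frame with one row per canonical rank and columns
#'   \code{rank}, \code{taxid}, \code{name}.
#' @export
lineage <- function(store, taxid) {
  path <- ancestor_path(store, taxid)
  key <- as.character(path)
  ranks <- store$rank[key]
  out <- data.frame(rank = CANONICAL_RANKS,
                    taxid = NA_integer_, name = NA_character_,
                    stringsAsFactors = FALSE)
  hit <- match(ranks, CANONICAL_RANKS)
  keep <- !is.na(hit)
  out$taxid[hit[keep]] <- path[keep]
  out$name[hit[keep]] <- unname(store$name[key][keep])
  out
}

#' Lineage taxid at one rank for many taxa
#'
#' Vectorised helper: the canonical-rank ancestor of each taxid, or \code{NA}
#' where the rank is not on the taxon's path to the root.
#'
#' @param store a \code{taxonomy_store}.
#' @param taxids integer vector (NA allowed, propagated).
#' @param rank one canonical rank.
#' @return Integer vector of ancestor taxids at \code{rank}.
#' @export
rank_taxid <- function(store, taxids, rank) {
  rank <- match.arg(rank, CANONICAL_RANKS)
  vapply(taxids, function(t) {
    if (is.na(t) || !has_taxid(store, t)) return(NA_integer_)
    path <- ancestor_path(store, t)
    r <- store$rank[as.character(path)]
    i <- which(r == rank)
    if (length(i)) path[i[1]] else NA_integer_
  }, integer(1))
}

#' Scientific names for taxids
#'
#' @param store a \code{taxonomy_store}.
#' @param taxids integer vector (NA allowed).
#' @return Character vector of names (\code{NA} where taxid is NA/unknown).
#' @export
taxon_name <- function(store, taxids) {
  out <- rep(NA_character_, length(taxids))
  ok <- !is.na(taxids) & has_taxid(store, taxids)
  out[ok] <- unname(store$name[as.character(taxids[ok])])
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every input taxon.
#'
#' @param store a \code{taxonomy_store}.
#' @param taxids non-empty integer vector of taxids present in the store.
#' @return A single taxid.
#' @export
lca <- function(store, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L)
    ww_stop("lca() needs at least one taxid", "ww_empty_input")
  # paths ordered root -> node; LCA is the last element of the common prefix
  paths <- lapply(taxids, function(t) rev(ancestor_path(store, t)))
  if (length(paths) == 1L) return(paths[[1]][length(paths[[1]])])
  n <- min(lengths(paths))
  depth <- 0L
  for (i in seq_len(n)) {
    v <- paths[[1]][i]
    if (all(vapply(paths[-1], function(p) p[i] == v, logical(1))))
      depth <- i
    else break
  }
  paths[[1]][depth]
}
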