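# Independent brute-force oracles and small fixtures shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- fixed toy taxonomy: species 10/11 under genus 5, genus 5 under family 3;
#     a second branch under Eukaryota for cross-domain LCA checks.
toy_store <- function() {
  taxonomy_store(
    taxid  = c(1,  2,  3,  5, 10, 11,  4,  6, 12),
    parent = c(1,  1,  2,  3,  5,  5,  1,  4,  6),
    rank   = c("no rank", "superkingdom", "family", "genus", "species",
               "species", "superkingdom", "genus", "species"),
    name   = c("root", "Bacteria", "Toyfamilyaceae", "Toygenus",
               "Toy species one", "Toy species two", "Eukaryota",
               "Othergenus", "Other species"))
}

# exhaustive parent-walk ancestor enumeration (ancestors-or-self)
oracle_ancestors <- function(store, taxid) {
  out <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    out <- c(out, cur)
    if (cur == store$root) return(out)
    cur <- store$parent[[as.character(cur)]]
  }
}

# LCA by ancestor-set intersection, deepest = largest depth
oracle_lca <- function(store, taxids) {
  sets <- lapply(taxids, function(t) oracle_ancestors(store, t))
  common <- Reduce(intersect, sets)
  depths <- vapply(common, function(t) length(oracle_ancestors(store, t)),
                   integer(1))
  common[which.max(depths)]
}

# brute-force tryptic digestion: test every contiguous substring
oracle_digest <- function(seq, mc, min_len = 6L, max_len = 50L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_site <- function(p) p >= 1 && p < n && chars[p] %in% c("K", "R") &&
    chars[p + 1] != "P"
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len < min_len || len > max_len) next
      if (!(i == 1L || is_site(i - 1L))) next
      if (!(j == n || is_site(j))) next
      internal <- sum(vapply((i):(j - 1L), is_site, logical(1)))
      if (j == i) internal <- 0L
      if (internal <= mc) out <- c(out, substr(seq, i, j))
    }
  }
  unique(out)
}

# linear Hamming scan over all indexed peptides
oracle_hamming_match <- function(index, peptide, max_subs) {
  hits <- character(0)
  for (p in index_peptides(index)) {
    if (nchar(p) != nchar(peptide)) next
    d <- sum(strsplit(p, "")[[1]] != strsplit(peptide, "")[[1]])
    if (d <= max_subs) hits <- c(hits, index$map[[p]])
  }
  unique(hits)
}

# O(n^2) subset-closure grouping: maximal sets create groups (processing by
# decreasing size then accession); every protein joins the earliest group
# whose set contains its own.
oracle_group <- function(pep_sets) {
  pep_sets <- lapply(pep_sets, unique)
  ord <- names(pep_sets)[order(-lengths(pep_sets), names(pep_sets))]
  group_sets <- list()
  membership <- character(length(pep_sets))
  names(membership) <- names(pep_sets)
  for (acc in ord) {
    s <- pep_sets[[acc]]
    placed <- NA
    for (g in seq_along(group_sets))
      if (all(s %in% group_sets[[g]])) { placed <- g; break }
    if (is.na(placed)) {
      group_sets[[length(group_sets) + 1L]] <- s
      placed <- length(group_sets)
    }
    membership[acc] <- placed
  }
  unname(lapply(split(names(membership), membership), sort))
}

# small simulated study used by several test files (error-free, tiny)
tiny_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_families = 6L, proteins_per_family = c(3L, 5L),
             n_human_proteins = 8L, n_entrapment_families = 2L,
             protein_length = c(80L, 200L), reads_per_sample = 150L,
             error_rate = 0, n_sites = 2L, n_timepoints = 1L,
             n_replicates = 1L, ...)
}

tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(tiny_config())
    cache
  }
})

random_peptide <- function(n = 10L) {
  paste(sample(c("A","C","D","E","F","G","H","J","K","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}
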