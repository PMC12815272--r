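# Stage 5: dataset splits, rank-level composition, alpha/beta diversity,
# ordination, gut/pathogen categorization and disease-list association
# counts. Diversity and ordination lean on vegan (Shannon, Bray-Curtis) and
# stats::cmdscale (classical PCoA), behind the module's own surface.

#' Split the quantification table into microbial and human datasets
#'
#' Microbial: rows whose superkingdom is annotated and is not Eukaryota.
#' Human: rows with genus Homo. Rows can fall in neither (e.g. missing
#' superkingdom, non-human eukaryotes); never in both.
#'
#' @param table a \code{quant_table} with lineage columns.
#' @return List with elements \code{microbial} and \code{human}.
#' @export
split_datasets <- function(table) {
  microbial <- table[!is.na(table$superkingdom) &
                       table$superkingdom != "Eukaryota", , drop = FALSE]
  human <- table[!is.na(table$genus) & table$genus == "Homo", , drop = FALSE]
  keep_class <- function(x) {
    rownames(x) <- NULL
    class(x) <- c("quant_table", "data.frame")
    attr(x, "sample_ids") <- attr(table, "sample_ids")
    x
  }
  list(microbial = keep_class(microbial), human = keep_class(human))
}

#' Rank-level taxonomic composition per sample
#'
#' Aggregates abundance by the rank-level taxon of each row's lineage and
#' normalizes over classified rows; the unclassified-at-rank fraction is
#' reported separately, never folded into the proportions.
#'
#' @param table a \code{quant_table}.
#' @param rank one canonical rank (default \code{"genus"}).
#' @param weight \code{"area"} (per-sample top-3 areas) or \code{"count"}
#'   (number of protein groups detected in the sample).
#' @return A samples x taxa matrix of proportions (rows sum to 1 where any
#'   mass is classified) with attribute \code{unclassified}: the per-sample
#'   fraction of weight lacking a taxon at \code{rank}.
#' @export
composition <- function(table, rank = "genus", weight = c("area", "count")) {
  rank <- match.arg(rank, CANONICAL_RANKS)
  weight <- match.arg(weight)
  samples <- attr(table, "sample_ids")
  if (is.null(samples))
    ww_stop("quant_table lacks sample_ids attribute", "ww_validation_error")
  taxa <- sort(unique(table[[rank]][!is.na(table[[rank]])]))
  m <- matrix(0, nrow = length(samples), ncol = length(taxa),
              dimnames = list(samples, taxa))
  uncl <- stats::setNames(numeric(length(samples)), samples)
  for (s in samples) {
    a <- table[[paste0("area_", s)]]
    w <- if (weight == "area") a else as.numeric(a > 0)
    cls <- !is.na(table[[rank]])
    tot <- sum(w)
    if (tot > 0) uncl[s] <- sum(w[!cls]) / tot
    wc <- w[cls]
    if (sum(wc) > 0) {
      agg <- tapply(wc, table[[rank]][cls], sum)
      m[s, names(agg)] <- agg / sum(wc)
    }
  }
  attr(m, "unclassified") <- uncl
  attr(m, "rank") <- rank
  attr(m, "weight") <- weight
  m
}

#' Shannon diversity index
#'
#' H' = -sum p_i ln(p_i), natural log, with 0 ln 0 = 0, computed per sample.
#'
#' @param comp a samples x taxa composition matrix (rows are proportions).
#' @return data.frame with \code{sample_id} and \code{shannon}.
#' @export
shannon <- function(comp) {
  h <- vegan::diversity(comp, index = "shannon")
  data.frame(sample_id = rownames(comp), shannon = as.numeric(h),
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x_i + sum y_i) over a common
#' taxon universe.
#'
#' @param comp a samples x taxa abundance or proportion matrix.
#' @return Symmetric matrix of dissimilarities in [0, 1] with zero diagonal.
#' @export
bray_curtis <- function(comp) {
  as.matrix(vegan::vegdist(comp, method = "bray"))
}

#' Classical principal coordinate analysis
#'
#' Torgerson PCoA: double-centred squared dissimilarities, eigendecomposed;
#' coordinates come from the top-k non-negative eigenvalues and any negative
#' eigenvalues are reported but contribute no axis.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k number of output dimensions; must be < number of samples.
#' @return List with \code{points} (samples x k coordinates) and \code{eig}
#'   (all eigenvalues).
#' @export
pcoa <- function(d, k = 2L) {
  n <- nrow(as.matrix(d))
  if (k >= n)
    ww_stop("pcoa: k must be smaller than the number of samples",
            "ww_validation_error")
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    # degenerate input (e.g. all-zero dissimilarities): pad dropped axes
    pad <- matrix(0, nrow = n, ncol = k - ncol(pts))
    pts <- cbind(pts, pad)
    rownames(pts) <- rownames(as.matrix(d))
  }
  list(points = pts, eig = fit$eig)
}

#' Categorize microbial taxa by pathogen/gut annotation
#'
#' Each taxon is assigned to exactly one of \code{both} (on both lists),
#' \code{pathogen}, \code{gut} or \code{other}; fractions are weighted by the
#' taxon's mean abundance across samples and sum to one.
#'
#' @param comp a samples x taxa composition matrix (taxa named at the lists'
#'   level).
#' @param pathogen_list,gut_list annotation lists (elements of
#'   \code{\link{read_annotation_tsv}} output, or plain character vectors).
#' @return List with \code{assignment} (named character vector per taxon) and
#'   \code{fractions} (named numeric over the four categories).
#' @export
categorize_microbes <- function(comp, pathogen_list, gut_list) {
  members <- function(x) if (is.list(x)) x$members else x
  pat <- members(pathogen_list)
  gut <- members(gut_list)
  taxa <- colnames(comp)
  assignment <- ifelse(taxa %in% pat & taxa %in% gut, "both",
                ifelse(taxa %in% pat, "pathogen",
                ifelse(taxa %in% gut, "gut", "other")))
  names(assignment) <- taxa
  ab <- colMeans(comp)
  tot <- sum(ab)
  fractions <- stats::setNames(numeric(4),
                               c("pathogen", "gut", "both", "other"))
  if (tot > 0)
    for (cat in names(fractions))
      fractions[cat] <- sum(ab[assignment == cat]) / tot
  list(assignment = assignment, fractions = fractions)
}

#' Disease-list association counts
#'
#' Per disease list, the number of retained human protein groups whose
#' representative accession is on the list (a protein may count toward
#' several diseases).
#'
#' @param human a human \code{quant_table}.
#' @param disease_lists named list of annotation lists keyed by protein
#'   accession.
#' @return data.frame with \code{disease} and \code{n_proteins}.
#' @export
disease_associations <- function(human, disease_lists) {
  counts <- vapply(disease_lists, function(l) {
    members <- if (is.list(l)) l$members else l
    sum(human$accession %in% members)
  }, integer(1))
  data.frame(disease = names(disease_lists) %||% character(0),
             n_proteins = unname(counts), stringsAsFactors = FALSE)
}

#' Per-sample percentage heatmap matrix
#'
#' Each protein's top-3 area divided by the sample's summed area, times 100,
#' so every sample column sums to 100. Rows are sorted by ascending abundance
#' in a designated reference sample.
#'
#' @param human a non-empty human \code{quant_table}.
#' @param reference_sample sample id used for row ordering (default: first
#'   sample).
#' @return proteins x samples percentage matrix.
#' @export
normalize_heatmap <- function(human, reference_sample = NULL) {
  if (nrow(human) == 0L)
    ww_stop("normalize_heatmap: empty table", "ww_empty_input")
  samples <- attr(human, "sample_ids")
  reference_sample <- reference_sample %||% samples[1]
  if (!reference_sample %in% samples)
    ww_stop(sprintf("unknown reference sample: %s", reference_sample),
            "ww_validation_error")
  m <- sapply(samples, function(s) human[[paste0("area_", s)]])
  m <- matrix(m, nrow = nrow(human), dimnames = list(human$accession, samples))
  tot <- colSums(m)
  tot[tot == 0] <- 1   # all-zero sample stays all-zero rather than NaN
  pct <- sweep(m, 2, tot, "/") * 100
  pct[order(pct[, reference_sample]), , drop = FALSE]
}
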