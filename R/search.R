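# Stage 3: the two-round search. Round one matches the sample's peptides
# against the focused database (one missed cleavage, no score cut-off) purely
# to collect candidate proteins; round two rebuilds a database from those
# candidates plus the human reference proteome, matches with up to three
# missed cleavages, and filters peptide matches to a target-decoy FDR. The
# engine is sequence-level: scores travel with the reads (ALC-derived), and
# decoys are full sequence reversals.

DECOY_PREFIX <- "DECOY_"

is_decoy_accession <- function(acc) startsWith(acc, DECOY_PREFIX)

#' Round-one search: collect candidate proteins
#'
#' Exact-matches the sample's canonical peptides against the focused database
#' digested with one missed cleavage; every matched accession is returned,
#' with no score cut-off.
#'
#' @param sample_peptides data.frame with \code{peptide} (and anything else,
#'   ignored here).
#' @param focused a non-empty \code{protein_db}.
#' @param missed_cleavages round-one missed cleavages (default 1).
#' @return Character vector of matched accessions.
#' @export
round1 <- function(sample_peptides, focused, missed_cleavages = 1L) {
  if (nrow(focused) == 0L)
    ww_stop("round1: focused database is empty", "ww_empty_database")
  idx <- build_index(focused, missed_cleavages = missed_cleavages)
  peps <- unique(canonicalize(sample_peptides$peptide))
  hits <- unique(unlist(lapply(peps, function(p)
    match_peptide(idx, p, max_subs = 0L))))
  if (length(hits) == 0L)
    ww_warn("round1: no peptide matched the focused database", "ww_no_hits")
  hits %||% character(0)
}

#' Assemble the round-two database
#'
#' Records of the round-one hits plus the human reference proteome supplement
#' (tagged \code{"human_UP000005640"}).
#'
#' @param round1_hits accessions returned by \code{\link{round1}}.
#' @param focused the focused \code{protein_db} searched in round one.
#' @param human \code{protein_db} of the human proteome supplement.
#' @return A \code{protein_db}.
#' @export
build_round2_db <- function(round1_hits, focused, human) {
  if (!all(round1_hits %in% focused$accession))
    ww_stop("round1 hits must come from the focused database",
            "ww_validation_error")
  base <- focused[focused$accession %in% round1_hits, , drop = FALSE]
  class(base) <- c("protein_db", "data.frame")
  merge_databases(base, human, tag = "human_UP000005640")
}

#' Reverse-sequence decoys
#'
#' One decoy per target: the sequence reversed, the accession prefixed
#' \code{DECOY_}.
#'
#' @param db a \code{protein_db}.
#' @return A \code{protein_db} of decoy records.
#' @export
make_decoys <- function(db) {
  rev_seq <- as.character(Biostrings::reverse(Biostrings::AAStringSet(db$sequence)))
  protein_db(accession = paste0(DECOY_PREFIX, db$accession),
             sequence = rev_seq, taxid = db$taxid,
             description = "decoy (reversed)", supplement = "decoy")
}

#' Target-decoy FDR estimation at PSM level
#'
#' For a descending score threshold s, FDR(s) = #\{decoy >= s\} /
#' max(1, #\{target >= s\}); the lowest observed score with FDR(s) <= alpha is
#' chosen, and all target matches at or above it survive (ties at the
#' threshold are admitted; no +1 correction).
#'
#' @param matches data.frame with columns \code{label} ("target"/"decoy") and
#'   \code{score}.
#' @param alpha FDR level in (0, 1].
#' @return List with \code{threshold} (score; \code{Inf} when nothing
#'   passes), \code{survivors} (the surviving target rows) and
#'   \code{fdr_at_threshold}.
#' @export
estimate_fdr <- function(matches, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1)
    ww_stop("alpha must lie in (0, 1]", "ww_validation_error")
  is_t <- matches$label == "target"
  if (!any(is_t))
    ww_stop("estimate_fdr: no target matches", "ww_empty_input")
  cand <- sort(unique(matches$score))
  fdr <- vapply(cand, function(s) {
    nd <- sum(matches$score >= s & !is_t)
    nt <- sum(matches$score >= s & is_t)
    nd / max(1L, nt)
  }, numeric(1))
  ok <- which(fdr <= alpha)
  if (length(ok) == 0L) {
    return(list(threshold = Inf,
                survivors = matches[is_t & matches$score > Inf, , drop = FALSE],
                fdr_at_threshold = NA_real_))
  }
  threshold <- cand[min(ok)]
  list(threshold = threshold,
       survivors = matches[is_t & matches$score >= threshold, , drop = FALSE],
       fdr_at_threshold = fdr[min(ok)])
}

# Match every read against an index; one row per read (PSM level). Accession
# sets are stored as a list column; a match is a decoy iff all its hits are
# decoy accessions (target-decoy competition: decoy hits are dropped from
# mixed matches).
score_matches <- function(sample_peptides, idx, max_subs = 0L) {
  pep <- canonicalize(sample_peptides$peptide)
  acc <- lapply(pep, function(p) match_peptide(idx, p, max_subs = max_subs))
  hit <- lengths(acc) > 0L
  all_decoy <- vapply(acc, function(a)
    length(a) > 0L && all(is_decoy_accession(a)), logical(1))
  targets <- lapply(acc, function(a) a[!is_decoy_accession(a)])
  out <- data.frame(peptide = pep,
                    score = sample_peptides$score,
                    area = sample_peptides$area,
                    sample_id = sample_peptides$sample_id %||% NA_character_,
                    read_id = sample_peptides$read_id %||%
                      seq_len(nrow(sample_peptides)),
                    stringsAsFactors = FALSE)
  out$label <- ifelse(all_decoy, "decoy", "target")
  acc_out <- targets
  acc_out[all_decoy] <- acc[all_decoy]
  out$accessions <- acc_out
  out[hit, , drop = FALSE]
}

#' Round-two search with FDR filtering and protein calls
#'
#' Indexes the round-two database (which must already contain decoy records,
#' see \code{\link{make_decoys}}) at up to three missed cleavages, matches the
#' sample's reads, filters PSMs to the configured FDR, assembles per-protein
#' peptide sets from the survivors, and flags proteins significant when their
#' protein group holds at least two unique peptide sequences.
#'
#' @param sample_peptides data.frame with \code{peptide}, \code{score},
#'   \code{area} and optionally \code{sample_id} (one row per read/PSM).
#' @param db2 round-two \code{protein_db} including decoys.
#' @param missed_cleavages round-two missed cleavages (default 3).
#' @param max_subs substitutions tolerated in matching (default 0).
#' @param alpha PSM-level FDR (default 0.05).
#' @param min_unique unique peptides required for significance (default 2).
#' @return An object of class \code{search_result}: list with \code{psms}
#'   (all matched reads with labels), \code{survivors}, \code{threshold},
#'   \code{proteins} (accession, taxid, n_peptides, n_unique, significant),
#'   \code{peptides} (protein -> peptide list), \code{alpha},
#'   \code{sample_id}.
#' @export
round2 <- function(sample_peptides, db2, missed_cleavages = 3L,
                   max_subs = 0L, alpha = 0.05, min_unique = 2L) {
  if (!any(is_decoy_accession(db2$accession)))
    ww_stop("round2: db2 contains no decoy records; append make_decoys(db2)",
            "ww_validation_error")
  idx <- build_index(db2, missed_cleavages = missed_cleavages)
  psms <- score_matches(sample_peptides, idx, max_subs = max_subs)
  if (!any(psms$label == "target")) {
    fdr <- list(threshold = Inf, survivors = psms[0, , drop = FALSE],
                fdr_at_threshold = NA_real_)
  } else {
    fdr <- estimate_fdr(psms, alpha = alpha)
  }
  surv <- fdr$survivors
  pep_sets <- list()
  if (nrow(surv)) {
    pairs <- data.frame(
      accession = unlist(surv$accessions),
      peptide = rep(surv$peptide, lengths(surv$accessions)),
      stringsAsFactors = FALSE)
    pep_sets <- lapply(split(pairs$peptide, pairs$accession), unique)
  }
  if (length(pep_sets)) {
    groups <- group_proteins(pep_sets)
    uniq <- count_unique_peptides(groups)
    acc2group <- stats::setNames(
      rep(seq_along(groups), lengths(lapply(groups, `[[`, "members"))),
      unlist(lapply(groups, `[[`, "members")))
    accs <- names(pep_sets)
    proteins <- data.frame(
      accession = accs,
      taxid = unname(idx$taxid[accs]),
      n_peptides = lengths(pep_sets),
      n_unique = uniq[acc2group[accs]],
      stringsAsFactors = FALSE)
    proteins$significant <- proteins$n_unique >= min_unique
    proteins <- proteins[order(proteins$accession), , drop = FALSE]
    rownames(proteins) <- NULL
  } else {
    proteins <- data.frame(accession = character(0), taxid = integer(0),
                           n_peptides = integer(0), n_unique = integer(0),
                           significant = logical(0), stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_peptides$sample_id[1] %||% NA_character_,
                 psms = psms, survivors = surv, threshold = fdr$threshold,
                 fdr_at_threshold = fdr$fdr_at_threshold,
                 proteins = proteins, peptides = pep_sets, alpha = alpha),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> sample %s: %d PSMs, %d survive FDR %.3g (threshold %.4g), %d proteins (%d significant)\n",
    x$sample_id, nrow(x$psms), nrow(x$survivors), x$alpha, x$threshold,
    nrow(x$proteins), sum(x$proteins$significant)))
  invisible(x)
}

#' Entrapment evaluation of the second-round search
#'
#' Spikes the round-two database with proteins from taxa known to be absent
#' from the sample, reruns the search, and reports how many surviving matches
#' hit entrapment-only accessions — an empirical check on the FDR estimate.
#'
#' @param sample_peptides as in \code{\link{round2}}.
#' @param db2 round-two \code{protein_db} (without decoys; they are built
#'   here over targets + entrapment).
#' @param entrapment_db \code{protein_db} of foreign-taxa records.
#' @param ... passed to \code{\link{round2}}.
#' @return List with the underlying \code{result}, \code{n_survivors},
#'   \code{n_entrapment}, \code{entrapment_fraction} and
#'   \code{fdr_at_threshold}.
#' @export
entrapment_eval <- function(sample_peptides, db2, entrapment_db, ...) {
  spiked <- merge_databases(db2, entrapment_db, tag = "entrapment")
  spiked <- merge_databases(spiked, make_decoys(spiked), tag = "decoy")
  res <- round2(sample_peptides, spiked, ...)
  ent_acc <- entrapment_db$accession
  is_ent <- vapply(res$survivors$accessions, function(a)
    length(a) > 0L && all(a %in% ent_acc), logical(1))
  n_surv <- nrow(res$survivors)
  list(result = res, n_survivors = n_surv,
       n_entrapment = sum(is_ent),
       entrapment_fraction = if (n_surv) sum(is_ent) / n_surv else 0,
       fdr_at_threshold = res$fdr_at_threshold)
}
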