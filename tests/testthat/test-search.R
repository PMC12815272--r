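make_sample <- function(peptides, score = 90, area = 1e5, sample_id = "s1") {
  data.frame(peptide = peptides, score = score, area = area,
             alc = score, sample_id = sample_id, stringsAsFactors = FALSE)
}

test_that("round one collects matched accessions with no score cut-off", {
  db <- protein_db(c("P1", "P2"), c("CCCDDDKGGGEEEK", "WWWFFFKHHHMMMK"),
                   taxid = c(1L, 2L))
  expect_setequal(round1(make_sample(c("GGGEEEK"), score = 1), db), "P1")
  expect_warning(h <- round1(make_sample("QQQQQQK"), db), class = "ww_no_hits")
  expect_equal(h, character(0))
  expect_error(round1(make_sample("GGGEEEK"), db[0, ]),
               class = "ww_empty_database")
  # fixture sample agrees with a per-peptide index re-scan
  study <- tiny_study()
  reads <- filter_alc(study$samples[[1]]$reads, 70)
  g <- study$reference$global
  hits <- suppressWarnings(round1(reads, g))
  idx <- build_index(g, missed_cleavages = 1L)
  oracle <- unique(unlist(lapply(unique(canonicalize(reads$peptide)),
                                 function(p) match_peptide(idx, p))))
  expect_setequal(hits, oracle)
})

test_that("the round-two database is round-one hits plus the tagged human proteome", {
  study <- tiny_study()
  g <- study$reference$global
  hum <- study$reference$human
  hits <- g$accession[1:5]
  db2 <- build_round2_db(hits, g, hum)
  # human records already among the hits are not duplicated
  expect_equal(nrow(db2), 5L + nrow(hum) - length(intersect(hits,
                                                            hum$accession)))
  expect_true(all(db2$supplement[db2$accession %in% setdiff(hum$accession,
                                                            hits)] ==
                    "human_UP000005640"))
  # empty hits -> human proteome only
  db2e <- build_round2_db(character(0), g, hum)
  expect_setequal(db2e$accession, hum$accession)
  expect_error(build_round2_db("NOT_THERE", g, hum),
               class = "ww_validation_error")
})

test_that("decoys are reversed sequences with prefixed accessions", {
  db <- protein_db(c("P1", "P2"), c("ABCK", "MKRDE"), taxid = c(1L, 2L))
  d <- make_decoys(db)
  expect_equal(d$accession, c("DECOY_P1", "DECOY_P2"))
  expect_equal(d$sequence, c("KCBA", "EDRKM"))
  expect_equal(nrow(d), nrow(db))
  # decoy tryptic peptides differ from target peptides (non-palindromic)
  study <- tiny_study()
  g <- study$reference$global[1:10, ]
  dd <- make_decoys(g)
  t_peps <- unlist(lapply(g$sequence, digest, 1L, 6L, 50L))
  d_peps <- unlist(lapply(dd$sequence, digest, 1L, 6L, 50L))
  expect_lt(length(intersect(t_peps, d_peps)) / length(d_peps), 0.01)
})

test_that("FDR estimation picks the lowest threshold meeting alpha", {
  m <- data.frame(label = c("target", "target", "target", "target", "decoy"),
                  score = c(10, 9, 8, 7, 7.5))
  fit <- estimate_fdr(m, alpha = 0.05)
  expect_equal(fit$threshold, 8)
  expect_setequal(fit$survivors$score, c(10, 9, 8))
  # no decoys -> everything survives
  m2 <- m[m$label == "target", ]
  expect_equal(nrow(estimate_fdr(m2, 0.05)$survivors), 4L)
  # alpha = 1 admits everything with at least as many targets as decoys
  expect_equal(nrow(estimate_fdr(m, 1)$survivors), 4L)
  expect_error(estimate_fdr(m[m$label == "decoy", ], 0.05),
               class = "ww_empty_input")
  # monotonicity: survivors at alpha1 <= alpha2 are nested
  set.seed(41)
  big <- data.frame(label = sample(c("target", "decoy"), 300, TRUE,
                                   prob = c(.8, .2)),
                    score = stats::runif(300, 0, 100))
  prev <- character(0)
  for (a in c(0.01, 0.05, 0.2, 1)) {
    surv <- rownames(estimate_fdr(big, a)$survivors)
    expect_true(all(prev %in% surv))
    prev <- surv
  }
})

test_that("round two flags proteins significant only with two unique peptides", {
  # P1 has two unique peptides, P2 only one
  db <- protein_db(c("P1", "P2"),
                   c("CCCDDDKGGGEEEKAAATTTR", "WWWFFFKCCCDDDK"),
                   taxid = c(1L, 2L))
  db2 <- merge_databases(db, make_decoys(db), tag = "decoy")
  reads <- make_sample(c("GGGEEEK", "AAATTTR", "WWWFFFK", "CCCDDDK"))
  res <- round2(reads, db2, alpha = 0.05)
  prot <- res$proteins
  expect_true(prot$significant[prot$accession == "P1"])
  expect_false(prot$significant[prot$accession == "P2"])  # 1 unique + 1 shared
  expect_equal(prot$n_unique[prot$accession == "P1"], 2L)
  expect_error(round2(reads, db, alpha = 0.05),   # decoys missing
               class = "ww_validation_error")
})

test_that("error-free fixture reads make every well-supported protein significant", {
  study <- tiny_study()
  g <- study$reference$global
  sim <- study$samples[[1]]
  reads <- filter_alc(sim$reads, 70)
  db2 <- merge_databases(g, make_decoys(g), tag = "decoy")
  res <- round2(reads, db2, alpha = 0.05)
  # ground truth: proteins with >= 2 distinct emitted peptides unique to them
  idx3 <- build_index(g, missed_cleavages = 3L)
  emitted <- unique(canonicalize(reads$peptide))
  per_prot <- list()
  for (p in emitted) {
    acc <- match_peptide(idx3, p)
    if (length(acc) == 1L)
      per_prot[[acc]] <- c(per_prot[[acc]], p)
  }
  well_supported <- names(per_prot)[vapply(per_prot, function(x)
    length(unique(x)) >= 2L, logical(1))]
  sig <- res$proteins$accession[res$proteins$significant]
  expect_true(all(well_supported %in% sig))
})

test_that("entrapment hits are absent for exact matching of error-free reads", {
  study <- tiny_study()
  g <- study$reference$global
  reads <- filter_alc(study$samples[[1]]$reads, 70)
  ev <- entrapment_eval(reads, g, study$entrapment, alpha = 0.05,
                        max_subs = 0L)
  expect_equal(ev$n_entrapment, 0L)
  expect_gt(ev$n_survivors, 0L)
  # empty entrapment database -> zero entrapment hits by construction
  ev0 <- entrapment_eval(reads, g, study$entrapment[0, ], alpha = 0.05)
  expect_equal(ev0$n_entrapment, 0L)
})
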