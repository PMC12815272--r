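test_that("every generator output is deterministic under the seed", {
  cfg <- tiny_config(seed = 99L)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  s1 <- simulate_study(cfg, dir = d1)
  s2 <- simulate_study(cfg, dir = d2)
  for (f in c("nodes.dmp", "names.dmp", "global.fasta", "human.fasta",
              "entrapment.fasta", "reads_S1T1-1.csv",
              "ground_truth_composition.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the reference
  s3 <- make_reference(tiny_config(seed = 100L), s1$taxonomy)
  expect_false(identical(s3$global$sequence, s1$reference$global$sequence))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the taxonomy has the configured families and sound lineages", {
  cfg <- tiny_config()
  tx <- make_taxonomy(cfg)
  store <- tx$store
  fam_nodes <- store$taxid[store$rank[as.character(store$taxid)] == "family"]
  # community families plus reserved entrapment families
  expect_equal(length(fam_nodes),
               cfg$n_families + cfg$n_entrapment_families)
  expect_equal(sum(tx$families$kind != "entrapment"), cfg$n_families)
  expect_setequal(unique(tx$families$kind),
                  c("bacterial", "plant", "animal", "human", "entrapment"))
  # every species reaches the root and carries a family
  for (sp in tx$species$taxid) {
    anc <- oracle_ancestors(store, sp)
    expect_equal(anc[length(anc)], store$root)
    expect_true(any(store$rank[as.character(anc)] == "family"))
  }
  # one Homo genus with a Homo sapiens species
  expect_equal(sum(store$name == "Homo"), 1L)
  expect_equal(sum(store$name == "Homo sapiens"), 1L)
})

test_that("reference records resolve in the store and digest into peptides", {
  study <- tiny_study()
  g <- study$reference$global
  store <- study$taxonomy$store
  expect_true(all(vapply(g$taxid, function(t)
    !is.na(t) && t %in% store$taxid, logical(1))))
  for (s in g$sequence)
    expect_gte(length(digest(s, 0L, 6L, 50L)), 2L)
  # human supplement records are part of the global reference
  expect_true(all(study$reference$human$accession %in% g$accession))
  # truth table covers every record with its family
  expect_equal(nrow(study$reference$truth), nrow(g))
  expect_false(any(is.na(study$reference$truth$family_taxid)))
})

test_that("error-free reads are genuine tryptic peptides of their source protein", {
  study <- tiny_study()   # error_rate = 0
  g <- study$reference$global
  sim <- study$samples[[1]]
  expect_false(any(sim$provenance$is_error))
  seqs <- stats::setNames(g$sequence, g$accession)
  for (i in seq_len(nrow(sim$reads))) {
    src <- sim$provenance$accession[i]
    expect_true(sim$reads$peptide[i] %in%
                  oracle_digest(seqs[[src]], 1L, 6L, 50L))
  }
  # true family composition sums to one
  expect_equal(sum(sim$true_family_composition), 1)
})

test_that("errorful reads carry exactly one substitution and lower ALC", {
  cfg <- tiny_config(seed = 7L)
  cfg$error_rate <- 1
  tx <- make_taxonomy(cfg)
  ref <- make_reference(cfg, tx)
  sim <- simulate_sample(cfg, ref, tx, "S1T1-1")
  expect_true(all(sim$provenance$is_error))
  hd <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, sim$provenance$peptide_true, sim$provenance$peptide_emitted)
  expect_true(all(hd == 1L))
  expect_true(all(sim$reads$alc >= 0 & sim$reads$alc <= 100))
  # errorful ALC distribution sits well below the correct one
  cfg0 <- tiny_config(seed = 7L)
  sim0 <- simulate_sample(cfg0, make_reference(cfg0, make_taxonomy(cfg0)),
                          make_taxonomy(cfg0), "S1T1-1")
  expect_gt(mean(sim0$reads$alc), mean(sim$reads$alc))
})

test_that("entrapment proteins come from families absent from every community", {
  study <- tiny_study()
  ent <- study$entrapment
  store <- study$taxonomy$store
  ent_fams <- unique(rank_taxid(store, ent$taxid, "family"))
  comm_fams <- unique(study$reference$truth$family_taxid)
  expect_equal(length(intersect(ent_fams, comm_fams)), 0L)
  # no entrapment peptide collides with a community peptide (exact, canonical)
  ent_peps <- unique(canonicalize(unlist(lapply(ent$sequence, digest,
                                                1L, 6L, 50L))))
  com_peps <- unique(canonicalize(unlist(lapply(
    study$reference$global$sequence, digest, 1L, 6L, 50L))))
  expect_equal(length(intersect(ent_peps, com_peps)), 0L)
})
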