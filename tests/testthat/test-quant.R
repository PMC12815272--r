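test_that("grouping merges identical and subsumed peptide sets", {
  g <- group_proteins(list(P1 = c("a", "b", "c"), P2 = c("a", "b")))
  expect_equal(length(g), 1L)
  expect_equal(g[[1]]$members, c("P1", "P2"))
  g2 <- group_proteins(list(P1 = c("a", "b"), P2 = c("c", "d")))
  expect_equal(length(g2), 2L)
  expect_error(group_proteins(list(P1 = character(0))),
               class = "ww_validation_error")
  expect_equal(group_proteins(list()), list())
})

test_that("grouping agrees with the quadratic subset-closure oracle", {
  set.seed(51)
  peps <- paste0("pep", 1:12)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    sets <- lapply(seq_len(n), function(i)
      sample(peps, sample(1:6, 1)))
    names(sets) <- sprintf("P%02d", seq_len(n))
    got <- lapply(group_proteins(sets), `[[`, "members")
    want <- oracle_group(sets)
    norm <- function(x) x[order(vapply(x, `[`, character(1), 1))]
    expect_equal(norm(got), norm(want))
  }
})

test_that("unique peptides are those hitting exactly one group", {
  g <- group_proteins(list(P1 = c("a", "b", "s"), P2 = c("c", "d", "s")))
  expect_equal(count_unique_peptides(g), c(2L, 2L))  # s shared by both
  g2 <- group_proteins(list(P1 = c("a", "b")))
  expect_equal(count_unique_peptides(g2), 2L)
  # fixture check against a peptide -> group incidence oracle
  set.seed(52)
  sets <- lapply(1:30, function(i) sample(paste0("q", 1:15), sample(1:5, 1)))
  names(sets) <- sprintf("P%02d", 1:30)
  groups <- group_proteins(sets)
  inc <- table(unlist(lapply(groups, `[[`, "peptides")))
  oracle <- vapply(groups, function(g) sum(inc[g$peptides] == 1L), integer(1))
  expect_equal(count_unique_peptides(groups), oracle)
})

test_that("top-3 area sums the three largest peptide areas", {
  expect_equal(top3_area(c(10, 8, 5, 3)), 23)
  expect_equal(top3_area(7), 7)
  expect_equal(top3_area(numeric(0)), 0)
  expect_error(top3_area(c(1, -2)), class = "ww_validation_error")
  set.seed(53)
  for (i in 1:200) {
    v <- stats::rexp(sample(1:10, 1))
    expect_equal(top3_area(v),
                 sum(sort(v, decreasing = TRUE)[seq_len(min(3, length(v)))]))
    expect_equal(top3_area(v[sample.int(length(v))]), top3_area(v))  # permutation-invariant
    # monotone in every coordinate
    w <- v; w[1] <- w[1] + 1
    expect_gte(top3_area(w), top3_area(v))
  }
})

toy_quant <- function() {
  # 10 constructed rows covering both filter boundaries
  qt <- data.frame(
    group_id = 1:10,
    accession = sprintf("P%02d", 1:10),
    members = sprintf("P%02d", 1:10),
    taxid = NA_integer_,
    n_peptides = 5L,
    n_unique = c(2L, 2L, 1L, 0L, 3L, 2L, 1L, 5L, 2L, 4L),
    area_s1 = c(6e5, 5e5, 9e9, 9e9, 4e5, 5.1e5, 1e2, 5e5 + 1, 2e5, 0),
    stringsAsFactors = FALSE)
  qt$overall_area <- qt$area_s1
  class(qt) <- c("quant_table", "data.frame")
  attr(qt, "sample_ids") <- "s1"
  qt
}

test_that("the identification filters use >=2 unique and strictly >5E5 area", {
  qt <- toy_quant()
  kept <- apply_paper_filters(qt)
  # hand enumeration: rows 1 (6e5, 2u), 6 (5.1e5, 2u), 8 (5e5+1, 5u)
  expect_setequal(kept$accession, c("P01", "P06", "P08"))
  # boundary: exactly 5e5 is removed (strict >), exactly 2 unique is kept
  expect_false("P02" %in% kept$accession)
  expect_true("P01" %in% kept$accession)
  # 1 unique with huge area is removed
  expect_false("P03" %in% kept$accession)
  # idempotent
  expect_equal(as.data.frame(apply_paper_filters(kept)), as.data.frame(kept))
})

test_that("quantification aggregates survivors into grouped top-3 areas", {
  study <- tiny_study()
  g <- study$reference$global
  db2 <- merge_databases(g, make_decoys(g), tag = "decoy")
  results <- lapply(study$samples, function(s)
    round2(filter_alc(s$reads, 70), db2, alpha = 0.05))
  qt <- build_quant_table(results, study$taxonomy$store)
  samples <- attr(qt, "sample_ids")
  expect_setequal(samples, names(study$samples))
  # overall area equals the sum of per-sample areas
  per_sample <- as.matrix(qt[, paste0("area_", samples)])
  expect_equal(unname(rowSums(per_sample)), qt$overall_area)
  expect_true(all(per_sample >= 0))
  # representative is one of the members
  expect_true(all(mapply(function(a, m)
    a %in% strsplit(m, ";", fixed = TRUE)[[1]], qt$accession, qt$members)))
})

fake_result <- function(sample_id, peptide, area, accessions, proteins) {
  structure(list(sample_id = sample_id,
                 survivors = data.frame(peptide = peptide, area = area,
                                        accessions = I(accessions),
                                        stringsAsFactors = FALSE),
                 proteins = proteins), class = "search_result")
}

test_that("per-sample top-3 areas and lineage annotation match hand computation", {
  store <- toy_store()
  prot <- data.frame(accession = c("P1", "P2"), taxid = c(10L, 12L),
                     stringsAsFactors = FALSE)
  rA <- fake_result("A",
                    c("a", "b", "c", "d", "s", "e"),
                    c(10, 8, 5, 3, 2, 4),
                    list("P1", "P1", "P1", "P1", c("P1", "P2"), "P2"), prot)
  rB <- fake_result("B", c("a", "a"), c(1, 2), list("P1", "P1"), prot)
  qt <- build_quant_table(list(rA, rB), store)
  p1 <- qt[qt$accession == "P1", ]
  p2 <- qt[qt$accession == "P2", ]
  expect_equal(p1$area_A, 23)          # top-3 of {10, 8, 5, 3, 2}
  expect_equal(p1$area_B, 3)           # duplicate peptide areas summed
  expect_equal(p1$overall_area, 26)
  expect_equal(p2$area_A, 6)           # {2, 4}: fewer than 3 peptides
  expect_equal(p2$overall_area, 6)
  expect_equal(p1$n_unique, 4L)        # "s" is shared with P2
  expect_equal(p2$n_unique, 1L)
  expect_equal(p1$family, "Toyfamilyaceae")
  expect_equal(p1$genus, "Toygenus")
  expect_true(is.na(p2$family))        # species 12 has no family on its path
})
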