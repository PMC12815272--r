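mini_quant <- function() {
  qt <- data.frame(
    group_id = 1:4,
    accession = c("M1", "M2", "H1", "X1"),
    superkingdom = c("Bacteria", "Bacteria", "Eukaryota", NA),
    genus = c("GenA", "GenB", "Homo", "GenX"),
    family = c("FamA", "FamA", "Hominidae", NA),
    area_s1 = c(60, 30, 10, 5),
    area_s2 = c(10, 80, 20, 0),
    stringsAsFactors = FALSE)
  qt$overall_area <- qt$area_s1 + qt$area_s2
  class(qt) <- c("quant_table", "data.frame")
  attr(qt, "sample_ids") <- c("s1", "s2")
  qt
}

test_that("the microbial/human split follows superkingdom and genus rules", {
  ds <- split_datasets(mini_quant())
  expect_setequal(ds$microbial$accession, c("M1", "M2"))  # Bacteria only
  expect_setequal(ds$human$accession, "H1")               # genus Homo
  # missing superkingdom goes to neither; the split is disjoint
  expect_false("X1" %in% c(ds$microbial$accession, ds$human$accession))
  expect_equal(length(intersect(ds$microbial$accession, ds$human$accession)),
               0L)
})

test_that("composition normalizes classified mass and reports the rest", {
  qt <- mini_quant()
  comp <- composition(qt, rank = "genus", weight = "area")
  # hand aggregation for s1: GenA 60, GenB 30, Homo 10, GenX 5 (all classified)
  expect_equal(comp["s1", "GenA"], 60 / 105)
  expect_equal(sum(comp["s1", ]), 1)
  # family rank: X1 (NA family) becomes unclassified mass
  compf <- composition(qt, rank = "family", weight = "area")
  expect_equal(attr(compf, "unclassified")[["s1"]], 5 / 105)
  expect_equal(compf["s1", "FamA"], 90 / 100)
  expect_equal(sum(compf["s1", ]), 1)
  # count weighting: groups detected in the sample count once
  compc <- composition(qt, rank = "genus", weight = "count")
  expect_equal(compc["s2", "GenB"], 1 / 3)   # X1 has zero area in s2
  # single-protein edge: its taxon has p = 1
  one <- qt[1, ]; class(one) <- class(qt); attr(one, "sample_ids") <- "s1"
  expect_equal(unname(composition(one, "genus")["s1", "GenA"]), 1)
})

test_that("Shannon diversity matches its closed forms", {
  unif <- matrix(rep(1 / 4, 4), nrow = 1, dimnames = list("u", letters[1:4]))
  expect_equal(shannon(unif)$shannon, log(4), tolerance = 1e-12)
  single <- matrix(1, nrow = 1, dimnames = list("s", "a"))
  expect_equal(shannon(single)$shannon, 0)
  v <- matrix(c(0.5, 0.25, 0.25), nrow = 1, dimnames = list("x", letters[1:3]))
  expect_equal(shannon(v)$shannon, -sum(c(.5, .25, .25) * log(c(.5, .25, .25))))
  expect_equal(shannon(v)$shannon, 1.039721, tolerance = 1e-6)
  # uniform over n equals ln n across the range, and never exceeds it
  for (n in c(1, 2, 7, 50, 100)) {
    m <- matrix(rep(1 / n, n), nrow = 1,
                dimnames = list("u", paste0("t", 1:n)))
    expect_equal(shannon(m)$shannon, log(n), tolerance = 1e-12)
  }
})

test_that("Bray-Curtis has its hand values and metric-like properties", {
  m <- rbind(x = c(2, 0), y = c(1, 1), z = c(2, 0), w = c(0, 3))
  colnames(m) <- c("t1", "t2")
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 0.5)     # 1 - 2*min/(2+2)
  expect_equal(d["x", "z"], 0)       # identical vectors
  expect_equal(d["x", "w"], 1)       # disjoint supports
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("classical PCoA embeds dissimilarities faithfully", {
  # identical samples land on identical coordinates
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 1))
  d <- bray_curtis(m)
  ord <- pcoa(d, k = 2)
  expect_lt(max(abs(ord$points["a", ] - ord$points["b", ])), 1e-6)
  # three samples with all pairwise d = 1: embedded distances all equal
  d1 <- matrix(1, 3, 3) - diag(3)
  dimnames(d1) <- list(letters[1:3], letters[1:3])
  p <- pcoa(d1, k = 2)$points
  dd <- as.matrix(stats::dist(p))
  expect_equal(dd["a", "b"], dd["a", "c"], tolerance = 1e-8)
  expect_equal(dd["a", "b"], dd["b", "c"], tolerance = 1e-8)
  # Euclidean-embeddable input round-trips within 1e-8
  set.seed(61)
  pts <- matrix(stats::rnorm(5 * 3), 5, 3,
                dimnames = list(paste0("s", 1:5), NULL))
  de <- as.matrix(stats::dist(pts))
  back <- as.matrix(stats::dist(pcoa(de, k = 3)$points))
  expect_equal(unname(back), unname(de), tolerance = 1e-8)
  expect_error(pcoa(de, k = 5), class = "ww_validation_error")
})

test_that("microbe categorization respects both > pathogen/gut > other precedence", {
  comp <- matrix(c(.4, .3, .2, .1), nrow = 1,
                 dimnames = list("s1", c("GenA", "GenB", "GenC", "GenD")))
  cats <- categorize_microbes(comp,
                              pathogen_list = c("GenA", "GenB"),
                              gut_list = c("GenB", "GenC"))
  expect_equal(unname(cats$assignment),
               c("pathogen", "both", "gut", "other"))
  expect_equal(unname(cats$fractions["pathogen"]), .4)
  expect_equal(unname(cats$fractions["both"]), .3)
  expect_equal(sum(cats$fractions), 1)
})

test_that("disease association counts intersect representative accessions", {
  ds <- split_datasets(mini_quant())
  lists <- list(d_all = list(level = "protein_accession",
                             members = c("H1", "H9")),
                d_none = list(level = "protein_accession",
                              members = "Hnope"))
  counts <- disease_associations(ds$human, lists)
  expect_equal(counts$n_proteins[counts$disease == "d_all"], 1L)
  expect_equal(counts$n_proteins[counts$disease == "d_none"], 0L)
  expect_equal(disease_associations(ds$human, list())$disease, character(0))
})

test_that("heatmap normalization gives 100% columns sorted by the reference sample", {
  qt <- mini_quant()
  hum <- qt[c(1, 2, 3), ]   # treat three rows as the table under test
  class(hum) <- class(qt); attr(hum, "sample_ids") <- c("s1", "s2")
  hm <- normalize_heatmap(hum, reference_sample = "s1")
  expect_equal(unname(colSums(hm)), c(100, 100), tolerance = 1e-9)
  expect_false(is.unsorted(hm[, "s1"]))
  # single protein -> 100%
  one <- qt[1, ]; class(one) <- class(qt); attr(one, "sample_ids") <- "s1"
  expect_equal(unname(normalize_heatmap(one)[1, 1]), 100)
  expect_error(normalize_heatmap(hum[0, ]), class = "ww_empty_input")
})
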