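# Seeded synthetic-community generator with known ground truth. It emulates
# the study design the pipeline targets: two treatment-plant sites sampled at
# five time points in duplicate; a community of gut and environmental
# bacterial families plus plant/animal food-residue families; free human
# proteins; de novo reads whose ALC scores and sequence errors follow the
# correct/incorrect operating curve that the ALC filter and the FDR machinery
# are designed around. Every generator is deterministic under the config seed.

#' Simulation configuration
#'
#' @param seed master seed; all generator randomness derives from it.
#' @param n_families community family count (bacterial + plant + animal +
#'   Hominidae).
#' @param proteins_per_family inclusive integer range, proteins drawn per
#'   family.
#' @param n_human_proteins proteins under Homo sapiens (in the global
#'   reference and the human-proteome supplement).
#' @param n_entrapment_families extra families reserved for entrapment: in
#'   the taxonomy, never in any community.
#' @param protein_length inclusive sequence-length range.
#' @param community_meanlog,community_sdlog log-normal parameters of family
#'   abundances (skewed dominance: a few families carry most of the area).
#' @param reads_per_sample de novo reads emitted per sample.
#' @param alc_correct,alc_incorrect mean/sd of the ALC distributions for
#'   correct and errorful reads (clamped to [0, 100]).
#' @param error_rate fraction of reads carrying one residue substitution.
#' @param n_sites,n_timepoints,n_replicates sampling design (default
#'   2 x 5 x 2).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 20L,
                       proteins_per_family = c(5L, 15L),
                       n_human_proteins = 30L,
                       n_entrapment_families = 5L,
                       protein_length = c(100L, 600L),
                       community_meanlog = 0,
                       community_sdlog = 1,
                       reads_per_sample = 500L,
                       alc_correct = c(mean = 85, sd = 5),
                       alc_incorrect = c(mean = 65, sd = 10),
                       error_rate = 0.1,
                       n_sites = 2L, n_timepoints = 5L, n_replicates = 2L) {
  cfg <- as.list(environment())
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    ww_stop("error_rate must lie in [0, 1]", "ww_validation_error")
  for (f in c("n_families", "n_human_proteins", "reads_per_sample",
              "n_sites", "n_timepoints", "n_replicates"))
    if (cfg[[f]] <= 0)
      ww_stop(sprintf("%s must be positive", f), "ww_validation_error")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic sub-seed per generator stage, kept under 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' Sample identifiers of the simulated design
#'
#' @param config a \code{sim_config}.
#' @return Character vector like \code{"S1T1-1"}, sites x timepoints x
#'   replicates.
#' @export
sample_ids <- function(config) {
  ids <- character(0)
  for (s in seq_len(config$n_sites))
    for (t in seq_len(config$n_timepoints))
      for (r in seq_len(config$n_replicates))
        ids <- c(ids, sprintf("S%dT%d-%d", s, t, r))
  ids
}

#' Generate the fixture taxonomy
#'
#' A rooted tree: root -> superkingdoms (Bacteria, Eukaryota) -> phyla ->
#' class -> order -> families -> two genera each -> two species each.
#' Families split into bacterial (gut + environmental), plant and animal
#' groups plus Hominidae (genus Homo, species Homo sapiens); entrapment
#' families are additional bacterial families flagged in the returned map and
#' never drawn into a community.
#'
#' @param config a \code{sim_config}.
#' @return List with \code{store} (a \code{taxonomy_store}),
#'   \code{families} (data.frame taxid/name/kind, kind in
#'   bacterial/plant/animal/human/entrapment) and \code{species}
#'   (data.frame taxid/family_taxid).
#' @export
make_taxonomy <- function(config) {
  n_fam <- config$n_families
  if (n_fam < 4L)
    ww_stop("need at least 4 community families (bacterial/plant/animal/human)",
            "ww_validation_error")
  n_plant <- max(1L, round(n_fam * 0.15))
  n_animal <- max(1L, round(n_fam * 0.10))
  n_bact <- n_fam - n_plant - n_animal - 1L  # minus Hominidae
  taxid <- 0L
  rows <- list()
  add <- function(parent, rank, name) {
    taxid <<- taxid + 1L
    rows[[taxid]] <<- list(taxid = taxid,
                           parent = if (is.na(parent)) taxid else parent,
                           rank = rank, name = name)
    taxid
  }
  root <- add(NA, "no rank", "root")
  bact <- add(root, "superkingdom", "Bacteria")
  euk <- add(root, "superkingdom", "Eukaryota")
  # bacterial phyla round-robin over three phyla
  phyla <- vapply(1:3, function(i)
    add(bact, "phylum", sprintf("Bacteriphylum%02d", i)), integer(1))
  classes <- vapply(seq_along(phyla), function(i)
    add(phyla[i], "class", sprintf("Bactericlass%02d", i)), integer(1))
  orders <- vapply(seq_along(classes), function(i)
    add(classes[i], "order", sprintf("Bacteriorder%02d", i)), integer(1))
  fam_rows <- list()
  add_family <- function(parent_order, name, kind) {
    f <- add(parent_order, "family", name)
    for (g in 1:2) {
      gname <- sprintf("%s_genus%d", sub("aceae$|idae$", "", name), g)
      gid <- add(f, "genus", if (kind == "human" && g == 1) "Homo" else gname)
      for (s in 1:2) {
        sname <- if (kind == "human" && g == 1 && s == 1) "Homo sapiens"
                 else sprintf("%s species %d", gname, s)
        add(gid, "species", sname)
      }
    }
    fam_rows[[length(fam_rows) + 1L]] <<- list(taxid = f, name = name,
                                               kind = kind)
    f
  }
  for (i in seq_len(n_bact))
    add_family(orders[(i - 1L) %% 3L + 1L],
               sprintf("Bacterifamily%02daceae", i), "bacterial")
  # Eukaryota: plants under Streptophyta, animals + human under Chordata
  str_ph <- add(euk, "phylum", "Streptophyta")
  str_cl <- add(str_ph, "class", "Magnoliopsida")
  str_or <- add(str_cl, "order", "Plantorder01")
  for (i in seq_len(n_plant))
    add_family(str_or, sprintf("Plantfamily%02daceae", i), "plant")
  cho_ph <- add(euk, "phylum", "Chordata")
  cho_cl <- add(cho_ph, "class", "Mammalia")
  cho_or <- add(cho_cl, "order", "Animalorder01")
  for (i in seq_len(n_animal))
    add_family(cho_or, sprintf("Animalfamily%02didae", i), "animal")
  add_family(cho_or, "Hominidae", "human")
  for (i in seq_len(config$n_entrapment_families))
    add_family(orders[(i - 1L) %% 3L + 1L],
               sprintf("Entrapfamily%02daceae", i), "entrapment")
  df <- do.call(rbind, lapply(rows, as.data.frame))
  store <- taxonomy_store(df$taxid, df$parent, df$rank, df$name)
  families <- do.call(rbind, lapply(fam_rows, as.data.frame))
  species <- data.frame(
    taxid = store$taxid[store$rank[as.character(store$taxid)] == "species"])
  species$family_taxid <- rank_taxid(store, species$taxid, "family")
  list(store = store, families = families, species = species)
}

random_protein <- function(len) {
  # uniform residue draw with K/R boosted so tryptic peptides exist
  probs <- stats::setNames(rep(1, length(AA_ALPHABET)), AA_ALPHABET)
  probs[c("K", "R")] <- 2.5
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = probs),
        collapse = "")
}

generate_records <- function(config, n_per_family, fam_taxids, species,
                             acc_fmt) {
  recs <- list()
  k <- 0L
  for (i in seq_along(fam_taxids)) {
    fam <- fam_taxids[i]
    sp <- species$taxid[species$family_taxid == fam]
    for (j in seq_len(n_per_family[i])) {
      k <- k + 1L
      repeat {
        len <- sample(config$protein_length[1]:config$protein_length[2], 1)
        seq <- random_protein(len)
        # every record must yield >= 2 fully-tryptic peptides of length >= 6
        if (length(digest(seq, 0L, 6L, 50L)) >= 2L) break
      }
      recs[[k]] <- data.frame(
        accession = sprintf(acc_fmt, k),
        taxid = if (length(sp) == 1L) sp else sample(sp, 1),
        sequence = seq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

#' Generate the global reference proteome
#'
#' Random sequences (K/R-boosted residue draw, each digestible into at least
#' two fully-tryptic peptides) under correct species taxids, with UniRef-style
#' accessions. Human proteins (under Homo sapiens) are part of the global
#' reference and also returned separately as the human-proteome supplement.
#'
#' @param config a \code{sim_config}.
#' @param taxonomy output of \code{\link{make_taxonomy}}.
#' @return List with \code{global}, \code{human} (both \code{protein_db})
#'   and \code{truth} (accession, taxid, family_taxid, kind).
#' @export
make_reference <- function(config, taxonomy) {
  set.seed(derive_seed(config$seed, "reference"))
  fam <- taxonomy$families
  comm <- fam[fam$kind != "entrapment", , drop = FALSE]
  non_human <- comm[comm$kind != "human", , drop = FALSE]
  n_per <- sample(config$proteins_per_family[1]:config$proteins_per_family[2],
                  nrow(non_human), replace = TRUE)
  micro <- generate_records(config, n_per, non_human$taxid, taxonomy$species,
                            "UniRef90_P%05d")
  homo_sp <- taxonomy$store$taxid[
    taxonomy$store$name[as.character(taxonomy$store$taxid)] == "Homo sapiens"]
  hum_fam <- comm$taxid[comm$kind == "human"]
  human <- generate_records(
    config, config$n_human_proteins, hum_fam,
    data.frame(taxid = homo_sp, family_taxid = hum_fam), "UniRef90_H%05d")
  global_df <- rbind(micro, human)
  global <- protein_db(global_df$accession, global_df$sequence,
                       taxid = global_df$taxid,
                       description = "synthetic reference protein")
  human_db <- protein_db(human$accession, human$sequence, taxid = human$taxid,
                         description = "synthetic human proteome protein")
  truth <- data.frame(accession = global$accession, taxid = global$taxid,
                      stringsAsFactors = FALSE)
  truth$family_taxid <- rank_taxid(taxonomy$store, truth$taxid, "family")
  truth$kind <- fam$kind[match(truth$family_taxid, fam$taxid)]
  list(global = global, human = human_db, truth = truth)
}

#' Generate the entrapment database
#'
#' Proteins under the reserved entrapment families — taxa guaranteed absent
#' from every simulated community.
#'
#' @param config a \code{sim_config}.
#' @param taxonomy output of \code{\link{make_taxonomy}}.
#' @return A \code{protein_db}.
#' @export
make_entrapment <- function(config, taxonomy) {
  set.seed(derive_seed(config$seed, "entrapment"))
  fam <- taxonomy$families
  ent <- fam[fam$kind == "entrapment", , drop = FALSE]
  n_per <- sample(config$proteins_per_family[1]:config$proteins_per_family[2],
                  nrow(ent), replace = TRUE)
  df <- generate_records(config, n_per, ent$taxid, taxonomy$species,
                         "UniRef90_E%05d")
  protein_db(df$accession, df$sequence, taxid = df$taxid,
             description = "synthetic entrapment protein")
}

substitute_residue <- function(pep) {
  chars <- strsplit(pep, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), 1)
  chars[pos] <- sample(setdiff(AA_ALPHABET, chars[pos]), 1)
  paste(chars, collapse = "")
}

rclamp <- function(n, mean, sd) pmin(100, pmax(0, stats::rnorm(n, mean, sd)))

#' Simulate one sample's de novo reads
#'
#' The community is drawn log-normally over families with a site-level base
#' profile shared by all of a site's samples and a time-point perturbation
#' shared by replicates; within a family, protein abundances are Dirichlet.
#' Each read picks a protein proportionally to abundance, emits one of its
#' fully-tryptic peptides (up to one missed cleavage) with an area
#' proportional to abundance times log-normal noise; with probability
#' \code{error_rate} one residue is substituted and the ALC is drawn from the
#' "incorrect" distribution, otherwise from the "correct" one. The search
#' score travels with the read as the ALC.
#'
#' @param config a \code{sim_config}.
#' @param reference output of \code{\link{make_reference}}.
#' @param taxonomy output of \code{\link{make_taxonomy}}.
#' @param sample_id a sample id from \code{\link{sample_ids}} (format
#'   \code{"S<site>T<timepoint>-<replicate>"}).
#' @return List with \code{reads} (peptide, alc, area, score, sample_id),
#'   \code{provenance} (per read: source accession, true and emitted
#'   peptide, is_error) and \code{true_family_composition} (named over
#'   family taxids, sums to one).
#' @export
simulate_sample <- function(config, reference, taxonomy, sample_id) {
  site <- sub("^S([0-9]+)T.*$", "\\1", sample_id)
  timepoint <- sub("^S[0-9]+T([0-9]+)-.*$", "\\1", sample_id)
  truth <- reference$truth
  fams <- sort(unique(truth$family_taxid))
  # site-level base community, shared across the site's samples
  set.seed(derive_seed(config$seed, paste0("site", site)))
  base_w <- stats::rlnorm(length(fams), config$community_meanlog,
                          config$community_sdlog)
  # time-point perturbation, shared by replicates
  set.seed(derive_seed(config$seed, paste0("site", site, "tp", timepoint)))
  tp_w <- stats::rlnorm(length(fams), 0, 0.3)
  fam_w <- base_w * tp_w
  fam_comp <- stats::setNames(fam_w / sum(fam_w), fams)
  # within-family Dirichlet protein weights and replicate-level sampling
  set.seed(derive_seed(config$seed, sample_id))
  prot_w <- numeric(nrow(truth))
  for (f in fams) {
    i <- which(truth$family_taxid == f)
    g <- stats::rgamma(length(i), shape = 1)
    prot_w[i] <- fam_comp[as.character(f)] * g / sum(g)
  }
  n <- config$reads_per_sample
  pick <- sample(nrow(truth), n, replace = TRUE, prob = prot_w)
  peptide_true <- character(n)
  for (i in seq_len(n)) {
    peps <- digest(reference$global$sequence[pick[i]], 1L, 6L, 50L)
    peptide_true[i] <- peps[sample(length(peps), 1)]
  }
  is_error <- stats::runif(n) < config$error_rate
  peptide <- peptide_true
  peptide[is_error] <- vapply(peptide_true[is_error], substitute_residue,
                              character(1))
  alc <- numeric(n)
  alc[!is_error] <- rclamp(sum(!is_error), config$alc_correct[["mean"]],
                           config$alc_correct[["sd"]])
  alc[is_error] <- rclamp(sum(is_error), config$alc_incorrect[["mean"]],
                          config$alc_incorrect[["sd"]])
  area <- prot_w[pick] * 1e8 * stats::rlnorm(n, 0, 0.5)
  reads <- data.frame(peptide = peptide, alc = round(alc, 1), area = area,
                      score = round(alc, 1), sample_id = sample_id,
                      read_id = seq_len(n), stringsAsFactors = FALSE)
  provenance <- data.frame(read_id = seq_len(n),
                           accession = truth$accession[pick],
                           family_taxid = truth$family_taxid[pick],
                           peptide_true = peptide_true,
                           peptide_emitted = peptide, is_error = is_error,
                           stringsAsFactors = FALSE)
  list(reads = reads, provenance = provenance,
       true_family_composition = fam_comp)
}

#' Simulate the full study
#'
#' All samples of the sites x timepoints x replicates design, plus taxonomy,
#' reference, entrapment database and (optionally) files on disk.
#'
#' @param config a \code{sim_config}.
#' @param dir optional directory; when given, writes nodes.dmp/names.dmp,
#'   global/human/entrapment FASTA, one de novo CSV per sample, ground-truth
#'   TSVs and the config as key=value text.
#' @return List with \code{config}, \code{taxonomy}, \code{reference},
#'   \code{entrapment}, \code{samples} (named list of
#'   \code{\link{simulate_sample}} outputs) and \code{paths} (when written).
#' @export
simulate_study <- function(config, dir = NULL) {
  taxonomy <- make_taxonomy(config)
  reference <- make_reference(config, taxonomy)
  entrapment <- make_entrapment(config, taxonomy)
  ids <- sample_ids(config)
  samples <- lapply(ids, function(id)
    simulate_sample(config, reference, taxonomy, id))
  names(samples) <- ids
  out <- list(config = config, taxonomy = taxonomy, reference = reference,
              entrapment = entrapment, samples = samples)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      nodes = file.path(dir, "nodes.dmp"),
      names = file.path(dir, "names.dmp"),
      global = file.path(dir, "global.fasta"),
      human = file.path(dir, "human.fasta"),
      entrapment = file.path(dir, "entrapment.fasta"),
      config = file.path(dir, "sim_config.txt"))
    write_taxdump(taxonomy$store, paths$nodes, paths$names)
    write_uniref_fasta(reference$global, paths$global)
    write_uniref_fasta(reference$human, paths$human)
    write_uniref_fasta(entrapment, paths$entrapment)
    cfgv <- unlist(lapply(unclass(config), paste, collapse = ","))
    writeLines(paste0(names(cfgv), "=", cfgv), paths$config)
    paths$reads <- character(0)
    for (id in ids) {
      p <- file.path(dir, sprintf("reads_%s.csv", id))
      write_denovo_csv(samples[[id]]$reads, p)
      paths$reads[id] <- p
    }
    truth_path <- file.path(dir, "ground_truth_proteins.tsv")
    write_report_tsv(reference$truth, truth_path,
                     sort_by = "accession")
    comp <- do.call(rbind, lapply(ids, function(id) {
      fc <- samples[[id]]$true_family_composition
      data.frame(sample_id = id, family_taxid = as.integer(names(fc)),
                 proportion = as.numeric(fc), stringsAsFactors = FALSE)
    }))
    comp_path <- file.path(dir, "ground_truth_composition.tsv")
    write_report_tsv(comp, comp_path,
                     sort_by = c("sample_id", "family_taxid"))
    paths$truth <- truth_path
    paths$composition <- comp_path
    out$paths <- paths
  }
  out
}

#' Fixture annotation lists with known membership
#'
#' Deterministically marks a third of bacterial genera as potential
#' pathogens and half as gut genera (overlapping, so the "both" category is
#' populated), and builds three synthetic disease lists over human
#' accessions.
#'
#' @param config a \code{sim_config}.
#' @param taxonomy output of \code{\link{make_taxonomy}}.
#' @param reference output of \code{\link{make_reference}}.
#' @return Named list of annotation lists (\code{level}, \code{members}).
#' @export
make_annotations <- function(config, taxonomy, reference) {
  set.seed(derive_seed(config$seed, "annotations"))
  store <- taxonomy$store
  bact_fams <- taxonomy$families$taxid[taxonomy$families$kind == "bacterial"]
  genera <- store$taxid[store$rank[as.character(store$taxid)] == "genus"]
  genera <- genera[rank_taxid(store, genera, "family") %in% bact_fams]
  gnames <- sort(taxon_name(store, genera))
  n <- length(gnames)
  pathogen <- sort(sample(gnames, max(1L, n %/% 3L)))
  gut <- sort(sample(gnames, max(1L, n %/% 2L)))
  hacc <- reference$human$accession
  diseases <- list(
    breast_cancer = sort(sample(hacc, max(1L, length(hacc) %/% 4L))),
    diabetic_nephropathy = sort(sample(hacc, max(1L, length(hacc) %/% 5L))),
    ibd = sort(sample(hacc, max(1L, length(hacc) %/% 6L))))
  c(list(pathogen_genera = list(level = "genus", members = pathogen),
         gut_genera = list(level = "genus", members = gut)),
    lapply(diseases, function(m) list(level = "protein_accession",
                                      members = m)))
}

#' Write annotation lists as TSV
#'
#' @param annotations named list as returned by \code{\link{make_annotations}}.
#' @param path output TSV path (columns list_name, level, member).
#' @return Invisibly, \code{path}.
#' @export
write_annotation_tsv <- function(annotations, path) {
  df <- do.call(rbind, lapply(names(annotations), function(nm)
    data.frame(list_name = nm, level = annotations[[nm]]$level,
               member = annotations[[nm]]$members, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
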