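# End-to-end pipeline driver: profile -> focus -> round 1 -> round 2 ->
# quantify -> filter -> split -> diversity -> categorization -> reports.
# Every printed pipeline parameter is a named config key with its standard
# value as default (ALC >= 70, 1 then 3 missed cleavages, 5% PSM FDR,
# >= 2 unique peptides, overall top-3 area > 5e5).

#' Pipeline configuration
#'
#' @param taxonomy_nodes,taxonomy_names taxdump paths.
#' @param global_fasta,human_fasta reference FASTA paths.
#' @param sample_csvs named character vector of de novo CSV paths (names are
#'   sample ids).
#' @param annotations_tsv optional annotation-list TSV (pathogen/gut genera,
#'   disease accession lists).
#' @param out_dir report directory (created if missing).
#' @param alc ALC filter threshold (inclusive).
#' @param min_family_peptides distinct peptides for family identification.
#' @param fdr_alpha PSM-level FDR.
#' @param min_unique,min_overall_area post-identification filters.
#' @param mc_round1,mc_round2 missed cleavages per round.
#' @param max_subs substitutions tolerated in round-two matching.
#' @param composition_rank rank for diversity analyses.
#' @param weight composition weighting, \code{"area"} or \code{"count"}.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(taxonomy_nodes, taxonomy_names, global_fasta,
                            human_fasta, sample_csvs, annotations_tsv = NULL,
                            out_dir = "ww_reports", alc = 70,
                            min_family_peptides = 2L, fdr_alpha = 0.05,
                            min_unique = 2L, min_overall_area = 5e5,
                            mc_round1 = 1L, mc_round2 = 3L, max_subs = 0L,
                            composition_rank = "genus", weight = "area") {
  cfg <- as.list(environment())
  if (alc < 0 || alc > 100)
    ww_stop("config: alc must lie in [0, 100]", "ww_config_error")
  if (fdr_alpha <= 0 || fdr_alpha > 1)
    ww_stop("config: fdr_alpha must lie in (0, 1]", "ww_config_error")
  if (!max_subs %in% c(0L, 1L))
    ww_stop("config: max_subs must be 0 or 1", "ww_config_error")
  if (is.null(names(sample_csvs)) || any(!nzchar(names(sample_csvs))))
    ww_stop("config: sample_csvs must be a named vector (names = sample ids)",
            "ww_config_error")
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr, out_dir = NULL) {
  tryCatch(expr, error = function(e) {
    if (!is.null(out_dir) && dir.exists(out_dir))
      file.create(file.path(out_dir, "RUN.partial"))
    ww_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "ww_stage_error")
  })
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[wwproteome] ", fmt),
                                                ...))

#' Run the search stages for one sample
#'
#' Profile, focus, round one and round two for a single sample's reads,
#' against a prebuilt global index.
#'
#' @param reads de novo reads (\code{peptide}, \code{alc}, \code{area},
#'   \code{score}, \code{sample_id}).
#' @param global_index \code{peptide_index} over the global reference (round-
#'   one missed cleavages).
#' @param global \code{protein_db} global reference.
#' @param human \code{protein_db} human supplement.
#' @param store \code{taxonomy_store}.
#' @param params list with alc, min_family_peptides, fdr_alpha, min_unique,
#'   mc_round1, mc_round2, max_subs.
#' @return List with \code{profile}, \code{families}, \code{focused_n},
#'   \code{round1_hits} and \code{result} (a \code{search_result}).
#' @export
search_sample <- function(reads, global_index, global, human, store, params) {
  filtered <- filter_alc(reads, params$alc)
  profile <- profile_sample(filtered, global_index, store,
                            min_family_peptides = params$min_family_peptides)
  fams <- identified_families(profile)
  focused <- suppressWarnings(select_by_family(global, fams, store))
  if (nrow(focused) == 0L)
    ww_stop("no focused database (no families identified)",
            "ww_empty_database")
  hits <- suppressWarnings(round1(filtered, focused,
                                  missed_cleavages = params$mc_round1))
  db2 <- build_round2_db(hits, focused, human)
  db2d <- merge_databases(db2, make_decoys(db2), tag = "decoy")
  res <- round2(filtered, db2d, missed_cleavages = params$mc_round2,
                max_subs = params$max_subs, alpha = params$fdr_alpha,
                min_unique = params$min_unique)
  list(profile = profile, families = fams, focused_n = nrow(focused),
       round1_hits = hits, result = res)
}

#' Run the full pipeline in memory
#'
#' The driver behind \code{\link{run_pipeline}}, usable directly on a
#' simulated study.
#'
#' @param reads_by_sample named list of read data.frames.
#' @param global,human \code{protein_db} objects.
#' @param store \code{taxonomy_store}.
#' @param annotations optional named list of annotation lists.
#' @param params as in \code{\link{search_sample}} plus
#'   \code{min_overall_area}, \code{composition_rank}, \code{weight}.
#' @return List with per-sample \code{searches}, \code{quant} (filtered
#'   \code{quant_table}), \code{datasets}, \code{composition},
#'   \code{diversity}, \code{dissimilarity}, \code{ordination}, and (when
#'   annotations are given) \code{categories} and \code{disease_counts}.
#' @export
process_study <- function(reads_by_sample, global, human, store,
                          annotations = NULL, params = list()) {
  defaults <- list(alc = 70, min_family_peptides = 2L, fdr_alpha = 0.05,
                   min_unique = 2L, min_overall_area = 5e5, mc_round1 = 1L,
                   mc_round2 = 3L, max_subs = 0L,
                   composition_rank = "genus", weight = "area")
  params <- utils::modifyList(defaults, params)
  global_index <- stage("profile", build_index(
    global, missed_cleavages = params$mc_round1))
  searches <- list()
  for (id in names(reads_by_sample)) {
    searches[[id]] <- stage(paste0("search:", id), search_sample(
      reads_by_sample[[id]], global_index, global, human, store, params))
    log_stage("sample %s: %d reads -> %d families -> %d round1 hits -> %d proteins (%d significant)",
              id, nrow(reads_by_sample[[id]]),
              length(searches[[id]]$families),
              length(searches[[id]]$round1_hits),
              nrow(searches[[id]]$result$proteins),
              sum(searches[[id]]$result$proteins$significant))
  }
  results <- lapply(searches, `[[`, "result")
  quant_all <- stage("quantify", build_quant_table(results, store))
  quant <- stage("filter", apply_paper_filters(
    quant_all, min_unique = params$min_unique,
    min_overall_area = params$min_overall_area))
  log_stage("quant: %d groups -> %d after filters", nrow(quant_all),
            nrow(quant))
  datasets <- stage("split", split_datasets(quant))
  comp <- stage("composition", composition(
    datasets$microbial, rank = params$composition_rank,
    weight = params$weight))
  div <- stage("diversity", shannon(comp))
  bc <- stage("diversity", bray_curtis(comp))
  ord <- if (nrow(comp) >= 3L) stage("ordination", pcoa(bc, k = 2L)) else NULL
  out <- list(searches = searches, quant_all = quant_all, quant = quant,
              datasets = datasets, composition = comp, diversity = div,
              dissimilarity = bc, ordination = ord, params = params)
  if (!is.null(annotations)) {
    if (all(c("pathogen_genera", "gut_genera") %in% names(annotations)))
      out$categories <- stage("categorize", categorize_microbes(
        comp, annotations$pathogen_genera, annotations$gut_genera))
    disease <- annotations[vapply(annotations, function(a)
      identical(a$level, "protein_accession"), logical(1))]
    if (length(disease))
      out$disease_counts <- stage("disease", disease_associations(
        datasets$human, disease))
  }
  if (nrow(datasets$human))
    out$heatmap <- stage("heatmap", normalize_heatmap(datasets$human))
  out
}

#' Run the pipeline from files and write reports
#'
#' Loads taxonomy, references, annotation lists and per-sample de novo CSVs,
#' runs \code{\link{process_study}}, and writes the report TSVs plus a
#' machine-readable run manifest into \code{out_dir}. Reports are
#' deterministically sorted, so identical inputs give byte-identical outputs.
#'
#' @param config a \code{pipeline_config}.
#' @return Invisibly, the \code{\link{process_study}} result with
#'   \code{report_paths} attached.
#' @export
run_pipeline <- function(config) {
  for (p in c(config$taxonomy_nodes, config$taxonomy_names,
              config$global_fasta, config$human_fasta, config$sample_csvs))
    if (!file.exists(p))
      ww_stop(sprintf("input not found: %s", p), "ww_unknown_input")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  store <- stage("profile", read_taxdump(config$taxonomy_nodes,
                                         config$taxonomy_names),
                 config$out_dir)
  global <- stage("load", parse_uniref_fasta(config$global_fasta),
                  config$out_dir)
  human <- stage("load", parse_uniref_fasta(config$human_fasta),
                 config$out_dir)
  reads <- lapply(names(config$sample_csvs), function(id) {
    r <- parse_denovo_csv(config$sample_csvs[[id]], sample_id = id)
    r$score <- r$alc   # sequence-level engine: the ALC is the match score
    r
  })
  names(reads) <- names(config$sample_csvs)
  annotations <- if (!is.null(config$annotations_tsv))
    read_annotation_tsv(config$annotations_tsv) else NULL
  res <- process_study(reads, global, human, store, annotations,
                       params = config[c("alc", "min_family_peptides",
                                         "fdr_alpha", "min_unique",
                                         "min_overall_area", "mc_round1",
                                         "mc_round2", "max_subs",
                                         "composition_rank", "weight")])
  paths <- write_reports(res, config$out_dir)
  manifest <- list(
    inputs = lapply(config[c("taxonomy_nodes", "taxonomy_names",
                             "global_fasta", "human_fasta")], identity),
    samples = as.list(config$sample_csvs),
    parameters = res$params,
    outputs = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$report_paths <- paths
  unlink(file.path(config$out_dir, "RUN.partial"))
  invisible(res)
}

write_reports <- function(res, out_dir) {
  paths <- list()
  wr <- function(name, table, sort_by = NULL) {
    p <- file.path(out_dir, name)
    write_report_tsv(table, p, sort_by = sort_by)
    paths[[name]] <<- p
    p
  }
  profiles <- do.call(rbind, lapply(res$searches, `[[`, "profile"))
  wr("family_profile.tsv", profiles,
     sort_by = c("sample_id", "-peptide_count", "family_taxid"))
  psms <- do.call(rbind, lapply(res$searches, function(s) {
    p <- s$result$psms
    data.frame(sample_id = p$sample_id, peptide = p$peptide,
               accessions = vapply(p$accessions, paste, character(1),
                                   collapse = ";"),
               label = p$label, score = p$score, area = p$area,
               q_pass = p$label == "target" & p$score >= s$result$threshold,
               stringsAsFactors = FALSE)
  }))
  wr("psms.tsv", psms, sort_by = c("sample_id", "-score", "peptide"))
  prots <- do.call(rbind, lapply(names(res$searches), function(id) {
    d <- res$searches[[id]]$result$proteins
    if (nrow(d)) cbind(sample_id = id, d) else NULL
  }))
  wr("proteins.tsv", prots, sort_by = c("sample_id", "accession"))
  qt <- as.data.frame(res$quant)
  wr("quant.tsv", qt)
  comp_long <- as.data.frame(as.table(res$composition),
                             stringsAsFactors = FALSE)
  names(comp_long) <- c("sample_id", "taxon", "proportion")
  wr("composition.tsv", comp_long, sort_by = c("sample_id", "taxon"))
  wr("diversity.tsv", res$diversity, sort_by = "sample_id")
  bc <- as.data.frame(res$dissimilarity)
  bc <- cbind(sample_id = rownames(res$dissimilarity), bc)
  wr("bray_curtis.tsv", bc, sort_by = "sample_id")
  if (!is.null(res$ordination)) {
    ordn <- data.frame(sample_id = rownames(res$ordination$points),
                       axis1 = res$ordination$points[, 1],
                       axis2 = res$ordination$points[, 2])
    wr("pcoa.tsv", ordn, sort_by = "sample_id")
  }
  if (!is.null(res$categories)) {
    cat_df <- data.frame(category = names(res$categories$fractions),
                         fraction = as.numeric(res$categories$fractions))
    wr("categories.tsv", cat_df, sort_by = "category")
  }
  if (!is.null(res$disease_counts))
    wr("disease_counts.tsv", res$disease_counts, sort_by = "disease")
  if (!is.null(res$heatmap)) {
    hm <- cbind(accession = rownames(res$heatmap),
                as.data.frame(res$heatmap))
    wr("heatmap.tsv", hm, sort_by = character(0))
  }
  paths
}

#' FDR calibration experiment over simulation replicates
#'
#' For each replicate, simulates one sample with the configured sequence-error
#' rate, runs the full two-round search (error-tolerant matching makes wrong
#' sequences matchable), and measures the realized false-discovery proportion:
#' the fraction of FDR-surviving matches whose read carried a sequence error
#' (so the peptide call is wrong), using the simulator's per-read provenance.
#'
#' @param config a \code{sim_config}; its \code{error_rate} sets the operating
#'   point.
#' @param n_replicates number of simulation replicates.
#' @param max_subs matching tolerance for round two (1 exercises the error
#'   channel).
#' @param alpha PSM FDR.
#' @return data.frame with per-replicate \code{n_survivors}, \code{n_false},
#'   \code{fdp}, \code{threshold} and \code{fdr_at_threshold}.
#' @export
fdr_calibration_experiment <- function(config, n_replicates = 20L,
                                       max_subs = 1L, alpha = 0.05) {
  if (n_replicates < 1L)
    ww_stop("n_replicates must be at least 1", "ww_config_error")
  params <- list(alc = 70, min_family_peptides = 2L, fdr_alpha = alpha,
                 min_unique = 2L, mc_round1 = 1L, mc_round2 = 3L,
                 max_subs = max_subs)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fdr_rep", r))
    taxonomy <- make_taxonomy(cfg)
    reference <- make_reference(cfg, taxonomy)
    sim <- simulate_sample(cfg, reference, taxonomy, "S1T1-1")
    idx <- build_index(reference$global, missed_cleavages = params$mc_round1)
    s <- search_sample(sim$reads, idx, reference$global, reference$human,
                       taxonomy$store, params)
    surv <- s$result$survivors
    is_err <- sim$provenance$is_error[surv$read_id]
    data.frame(replicate = r, n_survivors = nrow(surv),
               n_false = sum(is_err),
               fdp = if (nrow(surv)) mean(is_err) else 0,
               threshold = s$result$threshold,
               fdr_at_threshold = s$result$fdr_at_threshold %||% NA_real_)
  })
  do.call(rbind, rows)
}

#' Entrapment experiment over simulation replicates
#'
#' For each replicate, simulates one sample (fresh seed), runs the search
#' stages, then reruns round two with the database spiked by the entrapment
#' proteins and reports the entrapment hit fraction next to the FDR estimate.
#'
#' @param config a \code{sim_config}; \code{error_rate} and the replicate
#'   count define the operating point.
#' @param n_replicates number of simulation replicates (>= 1).
#' @param max_subs matching mode for round two.
#' @param alpha PSM FDR.
#' @return data.frame with one row per replicate: \code{replicate},
#'   \code{n_survivors}, \code{n_entrapment}, \code{entrapment_fraction},
#'   \code{fdr_at_threshold}.
#' @export
entrapment_experiment <- function(config, n_replicates = 5L, max_subs = 0L,
                                  alpha = 0.05) {
  if (n_replicates < 1L)
    ww_stop("n_replicates must be at least 1", "ww_config_error")
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("entrap_rep", r))
    taxonomy <- make_taxonomy(cfg)
    reference <- make_reference(cfg, taxonomy)
    entrapment <- make_entrapment(cfg, taxonomy)
    sim <- simulate_sample(cfg, reference, taxonomy, "S1T1-1")
    params <- list(alc = 70, min_family_peptides = 2L, fdr_alpha = alpha,
                   min_unique = 2L, mc_round1 = 1L, mc_round2 = 3L,
                   max_subs = max_subs)
    idx <- build_index(reference$global, missed_cleavages = params$mc_round1)
    filtered <- filter_alc(sim$reads, params$alc)
    profile <- profile_sample(filtered, idx, taxonomy$store,
                              min_family_peptides = params$min_family_peptides)
    focused <- suppressWarnings(select_by_family(
      reference$global, identified_families(profile), taxonomy$store))
    hits <- suppressWarnings(round1(filtered, focused,
                                    missed_cleavages = params$mc_round1))
    db2 <- build_round2_db(hits, focused, reference$human)
    ev <- entrapment_eval(filtered, db2, entrapment,
                          missed_cleavages = params$mc_round2,
                          max_subs = max_subs, alpha = alpha)
    data.frame(replicate = r, n_survivors = ev$n_survivors,
               n_entrapment = ev$n_entrapment,
               entrapment_fraction = ev$entrapment_fraction,
               fdr_at_threshold = ev$fdr_at_threshold %||% NA_real_)
  })
  do.call(rbind, rows)
}
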