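#' Pipeline configuration
#'
#' Collects every stage threshold with its default, plus simulation settings
#' for the self-contained synthetic run. Defaults mirror the analysis the
#' package implements: detection >= 9000 genes, intensity floor 7.5, response
#' SD floor 0.5, soft power 5, minimum module size 50, merge height 0.2,
#' 1000 Bayesian-network iterations of 20 genes per module, 100 regulatory-
#' network bootstraps with MI floor 0.5, hub-subnetwork edge cutoff 0.4,
#' drug-screen score cutoff 0.7 at Padj 0.05, DBP/SBP group cutoffs 80/130,
#' and DE significance at |log2FC| > 1 with Padj < 0.01.
#'
#' @param seed Master RNG seed.
#' @param sim A [simulation_config()] for the synthetic cohort.
#' @param min_detected,min_log2,min_sd,outlier_k Preprocessing thresholds.
#' @param power,cut_height,min_size,merge_height Co-expression parameters.
#' @param bn_iterations,genes_per_module Bayesian-network parameters.
#' @param grn_bootstraps,mi_floor,dpi_tolerance Regulatory-network parameters.
#' @param weight_cutoff Hub-subnetwork edge-weight cutoff.
#' @param score_cutoff,padj_cutoff Drug-screen effectiveness rule.
#' @param dbp_cutoff,sbp_cutoff Two-group trait cutoffs (mmHg).
#' @param lfc_cutoff,de_padj_cutoff DE significance rule.
#' @param n_drugs,n_landmark,n_perm Drug-library/screen sizes.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = simulation_config(seed = seed),
                            min_detected = 9000, min_log2 = 7.5, min_sd = 0.5,
                            outlier_k = 3,
                            power = 5, cut_height = 0.995, min_size = 50,
                            merge_height = 0.2,
                            bn_iterations = 1000, genes_per_module = 20,
                            grn_bootstraps = 100, mi_floor = 0.5,
                            dpi_tolerance = 0,
                            weight_cutoff = 0.4,
                            score_cutoff = 0.7, padj_cutoff = 0.05,
                            dbp_cutoff = 80, sbp_cutoff = 130,
                            lfc_cutoff = 1, de_padj_cutoff = 0.01,
                            n_drugs = 50, n_landmark = 978, n_perm = 1000) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

.write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a paired cohort, applies the QC filters, builds the response
#' matrix, flags outliers, runs the moderated differential-response test,
#' detects co-expression modules and their trait correlations, learns the
#' bootstrapped Bayesian consensus network over modules and DBP, infers the
#' regulatory network with modes of regulation, scores per-patient TF
#' activities, calls hub genes of the module most correlated with DBP, and
#' screens a simulated drug library. Each stage writes its table under
#' `out_dir` along with a provenance JSON (parameters and seed).
#'
#' Note the detection filter uses a simulated negative-control distribution,
#' and `min_detected` is capped at the simulated gene count so the synthetic
#' run is self-consistent at any scale.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return A list with every stage's result.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  cohort <- stage("simulate", simulate_cohort(cfg$sim))
  truth <- cohort$truth

  set.seed(cfg$seed + 1L)
  neg_control <- stats::rnorm(2000, 5, 0.5)
  min_det <- min(cfg$min_detected, floor(0.9 * cfg$sim$n_genes))
  det_b <- stage("preprocess",
                 filter_samples_by_detection(cohort$baseline, neg_control,
                                             min_detected = min_det))
  det_s <- stage("preprocess",
                 filter_samples_by_detection(cohort$stimulated, neg_control,
                                             min_detected = min_det))
  # gene filters need both conditions in one container for the response SD
  combined <- stage("preprocess", expression_matrix(
    cbind(det_b$expr$values, det_s$expr$values),
    c(det_b$expr$condition, det_s$expr$condition),
    c(det_b$expr$patient_id, det_s$expr$patient_id)))
  gf <- stage("preprocess", filter_genes(combined, min_log2 = cfg$min_log2,
                                         min_sd = cfg$min_sd))
  keep_genes <- rownames(gf$expr$values)
  det_b$expr <- expression_matrix(det_b$expr$values[keep_genes, , drop = FALSE],
                                  det_b$expr$condition, det_b$expr$patient_id)
  det_s$expr <- expression_matrix(det_s$expr$values[keep_genes, , drop = FALSE],
                                  det_s$expr$condition, det_s$expr$patient_id)
  rm0 <- stage("respond", build_response_matrix(det_b$expr, det_s$expr))
  out_det <- stage("outliers", detect_outliers(rm0$response, k = cfg$outlier_k))
  resp <- out_det$response

  de <- stage("de", moderated_de(resp, lfc_cutoff = cfg$lfc_cutoff,
                                 padj_cutoff = cfg$de_padj_cutoff))
  groups <- tryCatch(
    group_response_comparison(resp, de, cohort$clinical, trait = "dbp",
                              cutoff = cfg$dbp_cutoff),
    error = function(e) NULL)

  adj <- stage("modules", soft_adjacency(resp, power = cfg$power))
  tomd <- stage("modules", topological_overlap(adj))
  mods <- stage("modules",
                detect_modules(tomd, resp, cut_height = cfg$cut_height,
                               min_size = cfg$min_size,
                               merge_height = cfg$merge_height))
  mt <- stage("modules", module_trait_matrix(mods$eigengenes, cohort$clinical,
                                             covariates = c("dbp", "sbp")))

  # gene-set collection from the planted modules plus random decoys
  set.seed(cfg$seed + 2L)
  genes <- rownames(resp)
  collection <- c(
    stats::setNames(lapply(setdiff(unique(truth$module_labels), "unassigned"),
                           function(m) intersect(
                             names(truth$module_labels)[truth$module_labels == m],
                             genes)),
                    paste0("PLANTED_", setdiff(unique(truth$module_labels),
                                               "unassigned"))),
    stats::setNames(lapply(1:10, function(i) sample(genes, 60)),
                    paste0("RANDOM_", 1:10)))

  dbp_cor <- mt[mt$covariate == "dbp", ]
  trait_mod <- dbp_cor$feature[which.max(abs(dbp_cor$r))]
  enr <- stage("enrich",
               overrepresentation(names(mods$labels)[mods$labels == trait_mod],
                                  de, collection, genes))

  bn <- stage("bn", bootstrap_consensus(resp, mods$labels, cohort$clinical,
                                        trait = "dbp",
                                        n_iter = cfg$bn_iterations,
                                        genes_per_module = cfg$genes_per_module,
                                        seed = cfg$seed + 3L))

  grn <- stage("grn", aracne_network(resp, truth$tf_ids,
                                     n_boot = cfg$grn_bootstraps,
                                     mi_floor = cfg$mi_floor,
                                     dpi_tolerance = cfg$dpi_tolerance,
                                     seed = cfg$seed + 4L))
  if (length(grn)) grn <- stage("grn", mode_of_regulation(grn, resp))

  act <- NULL
  if (length(grn)) {
    sig <- stage("activity", rank_signature(resp))
    act <- tryCatch(regulon_enrichment(sig, grn), error = function(e) NULL)
  }

  hubs <- stage("hubs", module_hubs(adj, mods$labels, trait_mod,
                                    weight_cutoff = cfg$weight_cutoff))
  # screen query: called hubs, padded to the 10 most central genes when the
  # Bonferroni rule calls fewer (a tiny query makes the K-S statistic unstable)
  hub_genes <- hubs$gene[hubs$hub]
  if (length(hub_genes) < 10) hub_genes <- utils::head(hubs$gene, 10)

  lib <- stage("screen", simulate_drug_library(cfg$sim, truth,
                                               n_drugs = cfg$n_drugs,
                                               n_landmark = cfg$n_landmark))
  hub_query <- stats::setNames(de$log2fc[match(hub_genes, de$gene)], hub_genes)
  screen <- stage("screen",
                  drug_screen(hub_query, lib,
                              cell_line_filter = c("HL60", "THP1", "NOMO1",
                                                   "SKM1", "PL21", "U266",
                                                   "HS27A"),
                              n_perm = cfg$n_perm,
                              score_cutoff = cfg$score_cutoff,
                              padj_cutoff = cfg$padj_cutoff,
                              seed = cfg$seed + 5L))

  result <- list(config = cfg, cohort = cohort, response = resp,
                 group_comparison = groups,
                 qc = list(gene_filters = gf$qc,
                           detection_baseline = det_b$qc,
                           detection_stimulated = det_s$qc,
                           pairing = rm0$qc, outliers = out_det$qc),
                 de = de, modules = mods, module_trait = mt,
                 trait_module = trait_mod, enrichment = enr, bn = bn,
                 regulons = grn, tf_activity = act, hubs = hubs,
                 drug_library = lib, screen = screen)

  if (!is.null(out_dir)) {
    .write_tsv(de, file.path(out_dir, "differential_response.tsv"))
    .write_tsv(data.frame(gene = names(mods$labels), module = mods$labels),
               file.path(out_dir, "module_labels.tsv"))
    .write_tsv(data.frame(module = rownames(mods$eigengenes),
                          mods$eigengenes, check.names = FALSE),
               file.path(out_dir, "eigengenes.tsv"))
    .write_tsv(mt, file.path(out_dir, "module_trait.tsv"))
    .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    .write_tsv(bn$edges, file.path(out_dir, "bn_edges.tsv"))
    if (nrow(bn$consensus))
      write_edge_table(data.frame(source = bn$consensus$from,
                                  target = bn$consensus$to,
                                  weight = bn$consensus$strength),
                       file.path(out_dir, "bn_consensus.sif"), dialect = "sif",
                       interaction = "influences")
    write_regulons(grn, file.path(out_dir, "regulons.tsv"))
    if (!is.null(act))
      .write_tsv(data.frame(tf = rownames(act$nes), act$nes,
                            check.names = FALSE),
                 file.path(out_dir, "tf_activity.tsv"))
    .write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
    .write_tsv(screen, file.path(out_dir, "drug_screen.tsv"))
    prov <- list(seed = cfg$seed,
                 parameters = cfg[setdiff(names(cfg), "sim")],
                 simulation = unclass(cfg$sim),
                 trait_module = trait_mod,
                 timestamp_omitted = TRUE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}
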