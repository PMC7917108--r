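# One-call orchestration: a flat configuration whose defaults are the
# thresholds used throughout (so any deviation is explicit), and a
# runner that executes the stages in dependency order over simulated or
# supplied inputs, writing TSV outputs plus a reproducibility manifest.

#' Pipeline configuration
#'
#' Every threshold defaults to the value used by the analysis the
#' package implements; overriding any of them is recorded in the run
#' manifest.
#'
#' @param seed Integer seed controlling all randomness.
#' @param min_length Minimum lncRNA length (nt).
#' @param drop_monoexonic_below_fpkm Mono-exonic reliability cutoff.
#' @param min_fpkm Stage detection threshold (mean FPKM, strict).
#' @param window Cis window (nt, inclusive boundary).
#' @param window_exclusive Use a strict cis boundary.
#' @param r_min,p_max Trans coexpression thresholds (strict).
#' @param q_max DE / enrichment significance threshold.
#' @param mfe_max Decoy energy cutoff (kcal/mol, strict).
#' @param expectation_max Target-prediction expectation cutoff
#'   (inclusive).
#' @param hsp_min Minimum complementarity-scored length.
#' @param evalue_max Homology E-value cutoff (strict).
#' @param pcc_basis `"stages"` or `"replicates"`.
#' @param seed_allow_gu Allow G:U in the decoy seed region.
#' @param check_upe Enable the target accessibility proxy.
#' @param sim A [sim_params()] list (defaults to `sim_params(seed)`).
#' @return List of class `run_config`.
#' @export
default_config <- function(seed = 1, min_length = 200,
                           drop_monoexonic_below_fpkm = 2,
                           min_fpkm = 0.1, window = 100000,
                           window_exclusive = FALSE, r_min = 0.95,
                           p_max = 0.01, q_max = 0.05, mfe_max = -25,
                           expectation_max = 3, hsp_min = 20,
                           evalue_max = 1e-5,
                           pcc_basis = c("stages", "replicates"),
                           seed_allow_gu = FALSE, check_upe = FALSE,
                           sim = NULL) {
  pcc_basis <- match.arg(pcc_basis)
  cfg <- as.list(environment())
  cfg$sim <- sim %||% sim_params(seed)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on simulated inputs
#'
#' Executes the stages in dependency order -- identification ->
#' (conservation | expression/DE) -> regulatory network -> ceRNA ->
#' enrichment -- on inputs generated from `config$sim`, writes every
#' stage output as TSV under `outdir`, and records a manifest (the
#' configuration, and an md5 checksum per output file) sufficient to
#' verify byte-identical reproduction. Output is a pure function of the
#' configuration.
#'
#' @param config A [default_config()] list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all stage results (`catalog`, `expr`,
#'   `de`, `detected`, `cis`, `trans`, `both`, `network`,
#'   `conservation`, `decoys`, `targets`, `cerna`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = default_config(),
                         outdir = tempfile("lncregnet_run_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$sim

  ann <- simulate_annotation(p)
  lnc_ids <- ann$truth$transcript_id
  mrna_ids <- ann$genes$gene_id
  sim_expr <- simulate_expression(
    lnc_ids, mrna_ids, p,
    low_expression =
      ann$truth$transcript_id[ann$truth$low_expression],
    pair_lnc = ann$truth$transcript_id[
      ann$truth$expected_outcome == "retained"])
  expr <- sim_expr$expr

  catalog <- identify_lncrnas(ann$transcripts, ann$genes, expr,
                              params = filter_params(
                                min_length = config$min_length,
                                drop_monoexonic_below_fpkm =
                                  config$drop_monoexonic_below_fpkm),
                              coding_labels = ann$coding_labels)
  retained <- catalog[catalog$retained, , drop = FALSE]

  de <- de_all_stages(expr, alpha_q = config$q_max)
  detected <- lapply(stage_order(expr), function(s)
    detect_expressed(expr, s, min_fpkm = config$min_fpkm))
  names(detected) <- stage_order(expr)
  specific <- stage_specific(detected)

  de_feats <- unique(de$feature_id[de$de])
  de_lnc <- intersect(retained$transcript_id, de_feats)
  de_mrna <- intersect(mrna_ids, de_feats)

  cis <- cis_targets(retained, ann$genes, window = config$window,
                     exclusive = config$window_exclusive)
  cis <- cis[cis$lncrna_id %in% de_lnc & cis$mrna_id %in% de_mrna, ]
  trans <- trans_targets(expr, de_lnc, de_mrna,
                         r_min = config$r_min, p_max = config$p_max,
                         basis = config$pcc_basis, de = de)
  both <- combine_cis_trans(cis, trans)
  all_edges <- bind_rows(cis, trans, both) %>%
    sa_pairs(retained, ann$genes)
  network <- reg_network(all_edges)

  spp <- simulate_species_sets(p)
  hits <- bind_rows(lapply(setdiff(names(spp$species), "sp1"),
                           function(s)
    homology_search(spp$species$sp1, spp$species[[s]],
                    max_evalue = config$evalue_max,
                    subject_species = s)))
  share <- homolog_share(spp$species$sp1, hits)
  presence <- family_presence(bind_rows(lapply(
    names(spp$species), function(s) {
      rec <- precursor_scan(spp$species[[s]], spp$hairpins,
                            max_evalue = config$evalue_max)
      if (nrow(rec) == 0) return(NULL)
      tibble(species = s, family = rec$family)
    })))
  uc <- unique_common(presence)

  cer <- simulate_cerna(p)
  decoys <- find_decoys(cer$mirnas, cer$lncrnas,
                        mfe_max = config$mfe_max,
                        seed_allow_gu = config$seed_allow_gu)
  targets <- predict_targets(cer$mirnas, cer$mrnas,
                             expectation_max = config$expectation_max,
                             hsp_min = config$hsp_min,
                             check_upe = config$check_upe)
  cerna <- build_triads(decoys, targets)

  # enrichment: background = genes detected in any stage; query = the
  # trans-regulated targets; terms group genes by planted profile
  background <- intersect(mrna_ids,
                          unique(unlist(detected, use.names = FALSE)))
  query <- intersect(unique(trans$mrna_id), background)
  term_map <- sim_expr$truth$profiles %>%
    filter(.data$feature_id %in% mrna_ids,
           .data$profile != "flat") %>%
    mutate(term_id = paste0("PROFILE:", .data$profile),
           term_name = paste0("planted ", .data$profile,
                              " response")) %>%
    select("term_id", "term_name", gene_id = "feature_id")
  enrichment <- if (length(query) > 0 && nrow(term_map) > 0)
    hypergeom_enrich(query, background, term_map,
                     alpha_q = config$q_max)
  else NULL

  # outputs + manifest
  readr::write_tsv(as_tibble(catalog)[, setdiff(names(catalog),
                                                "exons")],
                   file.path(outdir, "lncrna_catalog.tsv"))
  readr::write_tsv(as_tibble(de), file.path(outdir, "de_records.tsv"))
  readr::write_tsv(specific, file.path(outdir, "stage_specific.tsv"))
  readr::write_tsv(tidy(network) %>%
                     select(-dplyr::any_of("comparisons_present")),
                   file.path(outdir, "reg_edges.tsv"))
  write_reg_network(network, file.path(outdir, "regnet"))
  readr::write_tsv(hits, file.path(outdir, "homology_hits.tsv"))
  readr::write_tsv(presence, file.path(outdir, "family_presence.tsv"))
  readr::write_tsv(decoys, file.path(outdir, "decoy_hits.tsv"))
  readr::write_tsv(targets, file.path(outdir, "target_hits.tsv"))
  readr::write_tsv(tidy(cerna), file.path(outdir, "cerna_triads.tsv"))
  write_cerna_network(cerna, file.path(outdir, "cerna"))
  if (!is.null(enrichment))
    readr::write_tsv(as_tibble(enrichment),
                     file.path(outdir, "enrichment.tsv"))

  files <- sort(list.files(outdir, pattern = "\\.tsv$"))
  manifest <- list(
    package = "lncregnet",
    version = as.character(utils::packageVersion("lncregnet")),
    config = unclass(config)[setdiff(names(config), "sim")],
    sim = unclass(config$sim),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(catalog = catalog, expr = expr, de = de,
                 detected = detected, stage_specific = specific,
                 cis = cis, trans = trans, both = both,
                 network = network,
                 conservation = list(hits = hits, share = share,
                                     presence = presence,
                                     unique_common = uc,
                                     truth = spp$truth),
                 decoys = decoys, targets = targets, cerna = cerna,
                 enrichment = enrichment,
                 truth = list(annotation = ann$truth,
                              expression = sim_expr$truth,
                              cerna = cer$truth),
                 manifest = manifest, outdir = outdir))
}
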