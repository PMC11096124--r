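#' Validated run configuration
#'
#' Defaults reproduce the main-analysis settings: similarity threshold
#' `tau = 0.8`, L2G share minimum 0.5, GWAS/coloc P < 5e-8, eQTL P < 1e-5,
#' H4 >= 0.9, exome P < 1e-5, and the genetic-insight denominator filter on.
#'
#' @param bundle_dir directory holding the input tables (see
#'   [write_bundle()] for the layout).
#' @param out_dir output directory.
#' @param tau similarity threshold in `[0, 1]`.
#' @param share_min minimum L2G share in `[0, 1]`.
#' @param p_gwas,p_coloc,eqtl_p_max,h4_min,p_exome per-source thresholds.
#' @param insight_filter restrict RS denominators to indications with
#'   genetic insight (default `TRUE`).
#' @param seed integer seed (echoed into the manifest; the pipeline itself
#'   is deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(bundle_dir, out_dir, tau = 0.8, share_min = 0.5,
                       p_gwas = 5e-8, p_coloc = 5e-8, eqtl_p_max = 1e-5,
                       h4_min = 0.9, p_exome = 1e-5, insight_filter = TRUE,
                       seed = 1L) {
  if (tau < 0 || tau > 1)
    stop("validation failure: tau must be in [0, 1]")
  if (share_min < 0 || share_min > 1)
    stop("validation failure: share_min must be in [0, 1]")
  for (p in c(p_gwas, p_coloc, eqtl_p_max, p_exome))
    if (p <= 0 || p > 1) stop("validation failure: P thresholds in (0, 1]")
  if (h4_min < 0 || h4_min > 1)
    stop("validation failure: h4_min must be in [0, 1]")
  structure(list(bundle_dir = bundle_dir, out_dir = out_dir, tau = tau,
                 share_min = share_min, p_gwas = p_gwas, p_coloc = p_coloc,
                 eqtl_p_max = eqtl_p_max, h4_min = h4_min, p_exome = p_exome,
                 insight_filter = insight_filter, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file with any subset of the [run_config()] fields.
#' @param ... overrides.
#' @export
read_run_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
  else yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  nrow(df)
}

#' Run the full genetic-support pipeline on a bundle of input tables
#'
#' Executes the stages in order — similarity, evidence assembly, support
#' assignment, success statistics, universe/utilization — and writes every
#' intermediate and final table as tab-separated text to `out_dir`, plus a
#' `manifest.json` recording input checksums, the configuration echo and
#' per-stage row counts. Rerunning with the same config and inputs produces
#' byte-identical tables.
#'
#' @param config a [run_config()].
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- read_bundle(config$bundle_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # stage: similarity -------------------------------------------------------
  onto <- bundle$ontology
  indications <- unique(bundle$programs$indication_term)
  raw_traits <- unique(stats::na.omit(unlist(lapply(
    bundle$raw, function(t) if (!is.null(t)) t$trait_term))))
  if (!is.null(bundle$mappings$remap) && nrow(bundle$mappings$remap))
    raw_traits <- unique(remap_to_main_headings(raw_traits,
                                                bundle$mappings$remap))
  sim <- combined_similarity(onto, indications, raw_traits)
  counts$similarity <- write_tsv(sim, file.path(config$out_dir,
                                                "similarity.tsv"))

  # stage: evidence assembly ------------------------------------------------
  ev <- assemble_evidence(bundle$raw, p_gwas = config$p_gwas,
                          share_min = config$share_min,
                          p_coloc = config$p_coloc,
                          eqtl_p_max = config$eqtl_p_max,
                          h4_min = config$h4_min, p_exome = config$p_exome)
  assoc <- ev$associations
  counts$associations <- write_tsv(assoc, file.path(config$out_dir,
                                                    "associations.tsv"))
  dl <- do.call(rbind, lapply(names(ev$drop_logs), function(s)
    cbind(source = s, ev$drop_logs[[s]])))
  if (!is.null(dl))
    counts$drop_log <- write_tsv(dl, file.path(config$out_dir,
                                               "drop_log.tsv"))

  # stage: support ----------------------------------------------------------
  pairs <- collapse_to_pairs(bundle$programs)
  assignments <- assign_support(pairs, assoc, sim, tau = config$tau)
  assignments <- bin_covariates(assignments, assoc, sim, tau = config$tau)
  counts$support <- write_tsv(assignments,
                              file.path(config$out_dir, "support.tsv"))
  insight <- genetic_insight(indications, assoc, sim, tau = config$tau)
  counts$insight <- write_tsv(insight,
                              file.path(config$out_dir, "insight.tsv"))

  # stage: success statistics ----------------------------------------------
  key <- paste(pairs$gene, pairs$indication_term, sep = "\r")
  akey <- paste(assignments$gene, assignments$indication_term, sep = "\r")
  pairs$supported <- assignments$supported[match(key, akey)]
  pairs_used <- pairs
  if (isTRUE(config$insight_filter)) {
    ok <- insight$indication_term[insight$insight]
    pairs_used <- pairs[pairs$indication_term %in% ok, , drop = FALSE]
  }
  safe_rs <- function(st) tryCatch(relative_success(st), error = function(e)
    list(rs = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         p_g = NA_real_, p_s = NA_real_, degenerate = TRUE))
  trans <- list(c("preclinical", "I"), c("I", "II"), c("II", "III"),
                c("III", "launched"))
  stats_rows <- do.call(rbind, lapply(trans, function(tr) {
    st <- contingency_by_phase(pairs_used, tr[1], tr[2])
    rs <- safe_rs(st)
    data.frame(label = st$label, X_G = st$X_G, N_G = st$N_G,
               X_notG = st$X_notG, N_notG = st$N_notG, rs = rs$rs,
               ci_low = rs$ci_low, ci_high = rs$ci_high, p_g = rs$p_g,
               p_s = rs$p_s, degenerate = rs$degenerate)
  }))
  ost <- contingency_by_phase(pairs_used, "I", "launched",
                              label = "I->launched")
  ors <- safe_rs(ost)
  ov <- tryCatch(overall_success(pairs_used),
                 error = function(e) list(p_s = NA_real_))
  stats_rows <- rbind(stats_rows, data.frame(
    label = "I->launched", X_G = ost$X_G, N_G = ost$N_G,
    X_notG = ost$X_notG, N_notG = ost$N_notG, rs = ors$rs,
    ci_low = ors$ci_low, ci_high = ors$ci_high, p_g = ors$p_g,
    p_s = ov$p_s, degenerate = ors$degenerate))
  counts$stats <- write_tsv(stats_rows,
                            file.path(config$out_dir, "stats.tsv"))

  # stage: universe ---------------------------------------------------------
  # support over the whole possibility space: every gene with evidence is
  # scored against every indication (genes without evidence are unsupported)
  genes <- sort(unique(c(bundle$programs$gene, assoc$gene)))
  grid <- expand.grid(gene = sort(unique(assoc$gene)),
                      indication_term = indications,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  universe_asg <- assign_support(grid, assoc, sim, tau = config$tau)
  universe <- enumerate_universe(genes, indications, universe_asg,
                                 bundle$programs)
  util <- utilization_stats(universe)
  usum <- attr(universe, "summary")
  universe_row <- data.frame(
    total = usum$total, supported = usum$supported,
    supported_fraction = usum$supported_fraction, pursued = usum$pursued,
    pursued_and_supported = usum$pursued_and_supported,
    pursued_given_supported = util$pursued_given_supported,
    supported_given_pursued = util$supported_given_pursued,
    odds_ratio = util$odds_ratio, fisher_p = util$p_value)
  counts$universe <- write_tsv(universe_row,
                               file.path(config$out_dir, "universe.tsv"))

  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(list.files(config$bundle_dir,
                                              full.names = TRUE))),
    rows = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(similarity = sim, associations = assoc,
                 assignments = assignments, insight = insight,
                 pairs = pairs, stats = stats_rows, universe = universe,
                 utilization = util, manifest = manifest))
}
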