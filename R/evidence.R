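#' @title Source-specific evidence filters
#' @description Each filter applies one source's inclusion rules to raw
#'   association records and returns rows of the unified gene-trait evidence
#'   schema. Every filter attaches a `drop_log` attribute (data.frame with
#'   columns `rule`, `n`) whose counts sum to `nrow(input) - nrow(output)`.
#' @name evidence_filters
NULL

assoc_columns <- c("gene", "trait_term", "source", "p_value", "effect_beta",
                   "effect_or", "maf", "l2g_share", "h4", "eqtl_p",
                   "lead_chrom", "lead_pos", "year")

as_association <- function(df, source) {
  for (col in assoc_columns)
    if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  df$source <- rep(source, nrow(df))
  rownames(df) <- NULL
  df[assoc_columns]
}

drop_log <- function(...) {
  counts <- c(...)
  data.frame(rule = names(counts), n = unname(counts))
}

#' Filter Mendelian-catalogue records
#'
#' Retains records with phenotype mapping code 3 (molecular basis known) and a
#' phenotype ID, gene symbol and mapped trait term present; drops phenotype
#' labels containing "somatic", "susceptibility" or "response" (drug
#' response), labels flagged questionable ("?") or non-disease ("["), and
#' susceptibility-brace ("{") labels unless they mention cancer/neoplasm/
#' tumor/malignant without "somatic". Deduplicates on (gene_id, phenotype_id)
#' and then on (gene, trait_term). Label matching is case-insensitive fixed
#' substring matching at any position.
#'
#' @param records data.frame with columns `gene`, `phenotype_label`,
#'   `mapping_code`, `phenotype_id`, `gene_id`, `trait_term`, optionally
#'   `year`.
#' @return Unified association rows (source `"mendelian"`) with a `drop_log`
#'   attribute.
#' @export
filter_mendelian <- function(records) {
  r <- records
  has <- function(x, pat) grepl(tolower(pat), tolower(x), fixed = TRUE)
  n0 <- nrow(r)

  keep_code <- !is.na(r$mapping_code) & r$mapping_code == 3
  r1 <- r[keep_code, , drop = FALSE]
  miss <- is.na(r1$phenotype_id) | r1$phenotype_id == "" |
    is.na(r1$gene) | r1$gene == "" |
    is.na(r1$trait_term) | r1$trait_term == ""
  r2 <- r1[!miss, , drop = FALSE]

  lab <- r2$phenotype_label
  brace <- has(lab, "{")
  bad_somatic <- has(lab, "somatic")
  # brace labels spell the flag out as "susceptibility to"; they are governed
  # by the brace rule below, so the text rule applies to unbraced labels only
  bad_susc <- has(lab, "susceptibility") & !brace
  bad_resp <- has(lab, "response")
  bad_quest <- has(lab, "?")
  bad_nondis <- has(lab, "[")
  cancerish <- has(lab, "cancer") | has(lab, "neoplasm") |
    has(lab, "tumor") | has(lab, "malignant")
  bad_brace <- brace & !(cancerish & !bad_somatic)
  drop_lab <- bad_somatic | bad_susc | bad_resp | bad_quest | bad_nondis |
    bad_brace
  r3 <- r2[!drop_lab, , drop = FALSE]

  dup1 <- duplicated(r3[, c("gene_id", "phenotype_id")])
  r4 <- r3[!dup1, , drop = FALSE]
  dup2 <- duplicated(r4[, c("gene", "trait_term")])
  r5 <- r4[!dup2, , drop = FALSE]

  out <- as_association(
    data.frame(gene = r5$gene, trait_term = r5$trait_term,
               year = if ("year" %in% names(r5)) r5$year else NA),
    "mendelian")
  # attribute each dropped label to its first matching rule
  first_rule <- function(...) {
    rules <- list(...)
    taken <- rep(FALSE, length(rules[[1]]))
    vapply(rules, function(r) {
      n <- sum(r & !taken)
      taken <<- taken | r
      n
    }, numeric(1))
  }
  lab_counts <- first_rule(bad_somatic, bad_susc, bad_resp, bad_quest,
                           bad_nondis, bad_brace)
  attr(out, "drop_log") <- drop_log(
    mapping_code_not_3 = sum(!keep_code),
    missing_id_gene_or_term = sum(miss),
    label_somatic = lab_counts[1],
    label_susceptibility = lab_counts[2],
    label_response = lab_counts[3],
    label_questionable = lab_counts[4],
    label_non_disease = lab_counts[5],
    label_susceptibility_brace = lab_counts[6],
    duplicate_gene_phenotype = sum(dup1),
    duplicate_gene_trait = sum(dup2))
  out
}

#' Locus-to-gene shares for GWAS hits
#'
#' For each hit, a gene's L2G share is its score divided by the summed scores
#' of all potentially causal genes at that hit; shares sum to 1 per hit.
#'
#' @param scores data.frame with columns `hit_id`, `gene`, `l2g_score`
#'   (scores >= 0, positive sum per hit).
#' @return `scores` with an added `l2g_share` column.
#' @export
l2g_shares <- function(scores) {
  stopifnot(all(c("hit_id", "gene", "l2g_score") %in% names(scores)))
  if (any(scores$l2g_score < 0)) stop("L2G scores must be non-negative")
  tot <- tapply(scores$l2g_score, scores$hit_id, sum)
  if (any(tot == 0))
    stop("undefined L2G share: all-zero scores for hit(s) ",
         paste(names(tot)[tot == 0], collapse = ", "))
  scores$l2g_share <- scores$l2g_score /
    as.numeric(tot[as.character(scores$hit_id)])
  scores
}

#' Filter GWAS hits on significance and L2G share
#'
#' Retains gene-level hits with `p_value < p_max` (strict, as printed) and
#' `l2g_share >= share_min` (inclusive). `share_min` is sweepable to
#' reproduce the L2G-share sensitivity analysis.
#'
#' @param hits data.frame with at least `gene`, `trait_term`, `p_value`,
#'   `l2g_share`, `lead_chrom`, `lead_pos`; extra columns (`effect_beta`,
#'   `effect_or`, `maf`, `year`) are carried through.
#' @param p_max genome-wide significance threshold (default 5e-8).
#' @param share_min minimum L2G share in `[0, 1]` (default 0.5).
#' @export
filter_gwas <- function(hits, p_max = 5e-8, share_min = 0.5) {
  if (share_min < 0 || share_min > 1)
    stop("invalid config: share_min must be in [0, 1]")
  keep_p <- !is.na(hits$p_value) & hits$p_value < p_max
  keep_s <- !is.na(hits$l2g_share) & hits$l2g_share >= share_min
  out <- as_association(hits[keep_p & keep_s, , drop = FALSE], "gwas")
  attr(out, "drop_log") <- drop_log(
    p_value_not_below_threshold = sum(!keep_p),
    l2g_share_below_minimum = sum(keep_p & !keep_s))
  out
}

#' Filter colocalization records
#'
#' Retains records with GWAS `p_value < p_max`, `eqtl_p < eqtl_p_max` (both
#' strict) and posterior probability `h4 >= h4_min` (inclusive).
#'
#' @param records data.frame with `gene`, `trait_term`, `p_value`, `eqtl_p`,
#'   `h4` and optional carried columns.
#' @param p_max,eqtl_p_max,h4_min thresholds (defaults 5e-8, 1e-5, 0.9).
#' @export
filter_coloc <- function(records, p_max = 5e-8, eqtl_p_max = 1e-5,
                         h4_min = 0.9) {
  keep_p <- !is.na(records$p_value) & records$p_value < p_max
  keep_e <- !is.na(records$eqtl_p) & records$eqtl_p < eqtl_p_max
  keep_h <- !is.na(records$h4) & records$h4 >= h4_min
  out <- as_association(records[keep_p & keep_e & keep_h, , drop = FALSE],
                        "coloc")
  attr(out, "drop_log") <- drop_log(
    gwas_p_not_below_threshold = sum(!keep_p),
    eqtl_p_not_below_threshold = sum(keep_p & !keep_e),
    h4_below_minimum = sum(keep_p & keep_e & !keep_h))
  out
}

exome_models <- c("pLoF-SKAT", "pLoF-burden", "missenseLC-SKAT",
                  "missenseLC-burden")

#' Filter exome burden/SKAT records
#'
#' Retains records significant (`p_value < p_max`, strict) in any of the four
#' models (pLoF or missense|LC, each under SKAT or burden), then deduplicates
#' to one association per (gene, trait). Records with an unknown model label
#' are rejected and logged.
#'
#' @param records data.frame with `gene`, `trait_term`, `model`, `p_value`.
#' @param p_max threshold (default 1e-5).
#' @export
filter_exome <- function(records, p_max = 1e-5) {
  known <- records$model %in% exome_models
  r <- records[known, , drop = FALSE]
  keep_p <- !is.na(r$p_value) & r$p_value < p_max
  r2 <- r[keep_p, , drop = FALSE]
  dup <- duplicated(r2[, c("gene", "trait_term")])
  out <- as_association(r2[!dup, , drop = FALSE], "exome")
  attr(out, "drop_log") <- drop_log(
    unknown_model_label = sum(!known),
    p_value_not_below_threshold = sum(!keep_p),
    duplicate_gene_trait = sum(dup))
  out
}

#' Modal somatic-driver role per gene
#'
#' Assigns each gene its most frequent classification (oncogene /
#' tumour_suppressor) across cancer cohorts; exact ties are labelled
#' `"ambiguous"` and should be excluded from direction-of-effect analyses.
#'
#' @param records data.frame with columns `gene`, `cohort`, `role`.
#' @return data.frame with columns `gene`, `role`.
#' @export
somatic_roles <- function(records) {
  stopifnot(all(c("gene", "role") %in% names(records)))
  roles <- vapply(split(records$role, records$gene), function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
  }, character(1))
  data.frame(gene = names(roles), role = unname(roles))
}

#' Independent-locus count per GWAS trait
#'
#' Lead-variant positions are rounded to the nearest megabase (half-up) and
#' distinct (chromosome, megabase-bin) combinations are counted.
#'
#' @param associations unified association rows with `trait_term`,
#'   `lead_chrom`, `lead_pos`.
#' @return data.frame with columns `trait_term`, `n_loci`.
#' @export
gwas_locus_counts <- function(associations) {
  g <- associations[!is.na(associations$lead_pos) &
                      !is.na(associations$lead_chrom), , drop = FALSE]
  if (!nrow(g)) return(data.frame(trait_term = character(), n_loci = integer()))
  bin <- floor(g$lead_pos / 1e6 + 0.5)          # round half-up to nearest Mb
  key <- paste(g$trait_term, g$lead_chrom, bin, sep = "\r")
  u <- g[!duplicated(key), , drop = FALSE]
  counts <- table(u$trait_term)
  data.frame(trait_term = names(counts), n_loci = as.integer(counts))
}

#' Flag indications with "genetic insight"
#'
#' An indication has genetic insight if its genetics (or a similar trait's)
#' has been successfully studied: combined similarity >= `tau` to (1) a
#' Mendelian or somatic disease trait, or (2) a GWAS trait with at least
#' `min_loci` independently associated loci (lead positions rounded to the
#' nearest megabase).
#'
#' @param indications character vector of indication term IDs.
#' @param associations unified association table (all sources pooled).
#' @param similarity calibrated similarity table with `term_a` (indication),
#'   `term_b` (trait), `combined`.
#' @param tau similarity threshold (default 0.8, inclusive).
#' @param min_loci minimum independent loci for the GWAS clause (default 3).
#' @return data.frame with columns `indication_term`, `insight`.
#' @export
genetic_insight <- function(indications, associations, similarity,
                            tau = 0.8, min_loci = 3) {
  indications <- unique(indications)
  if (!all(indications %in% similarity$term_a))
    stop("missing similarity for indication(s): ",
         paste(setdiff(indications, similarity$term_a), collapse = ", "))
  mend_som <- unique(associations$trait_term[
    associations$source %in% c("mendelian", "somatic")])
  lc <- gwas_locus_counts(associations[associations$source == "gwas", ,
                                       drop = FALSE])
  gwas_ok <- lc$trait_term[lc$n_loci >= min_loci]
  qual <- unique(c(mend_som, gwas_ok))
  hit <- similarity$term_b %in% qual & similarity$combined >= tau
  flagged <- unique(similarity$term_a[hit])
  data.frame(indication_term = indications,
             insight = indications %in% flagged)
}

#' Assemble the unified evidence table from raw per-source tables
#'
#' Applies every source filter and row-binds the results. Somatic driver
#' records contribute one association per (gene, disease trait) with the
#' gene's modal role carried in the drop-log-free `somatic_roles` element.
#'
#' @param raw named list with elements `mendelian`, `gwas` (gene-level hits
#'   with `l2g_share` already computed, or with `hit_id`+`l2g_score` to be
#'   normalized here), `coloc`, `exome`, `somatic` (with `trait_term` per
#'   cohort record). Missing elements are skipped.
#' @param p_gwas,share_min,p_coloc,eqtl_p_max,h4_min,p_exome thresholds
#'   passed to the per-source filters.
#' @return list with `associations` (unified table), `roles` (somatic role
#'   map), `drop_logs` (per-source drop logs).
#' @export
assemble_evidence <- function(raw, p_gwas = 5e-8, share_min = 0.5,
                              p_coloc = 5e-8, eqtl_p_max = 1e-5,
                              h4_min = 0.9, p_exome = 1e-5) {
  out <- list(); logs <- list(); roles <- NULL
  if (!is.null(raw$mendelian)) {
    m <- filter_mendelian(raw$mendelian)
    out$mendelian <- m; logs$mendelian <- attr(m, "drop_log")
  }
  if (!is.null(raw$gwas)) {
    g <- raw$gwas
    if (!"l2g_share" %in% names(g)) g <- l2g_shares(g)
    g <- filter_gwas(g, p_max = p_gwas, share_min = share_min)
    out$gwas <- g; logs$gwas <- attr(g, "drop_log")
  }
  if (!is.null(raw$coloc)) {
    cl <- filter_coloc(raw$coloc, p_max = p_coloc, eqtl_p_max = eqtl_p_max,
                       h4_min = h4_min)
    out$coloc <- cl; logs$coloc <- attr(cl, "drop_log")
  }
  if (!is.null(raw$exome)) {
    ex <- filter_exome(raw$exome, p_max = p_exome)
    out$exome <- ex; logs$exome <- attr(ex, "drop_log")
  }
  if (!is.null(raw$somatic)) {
    roles <- somatic_roles(raw$somatic)
    s <- raw$somatic[!duplicated(raw$somatic[, c("gene", "trait_term")]), ,
                     drop = FALSE]
    out$somatic <- as_association(
      data.frame(gene = s$gene, trait_term = s$trait_term,
                 year = if ("year" %in% names(s)) s$year else NA), "somatic")
  }
  assoc <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  list(associations = assoc, roles = roles, drop_logs = logs)
}
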