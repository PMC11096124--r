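#' Configuration for the synthetic data generator
#'
#' The generator emulates every input the pipeline consumes — a drug-programme
#' table, five genetic-association source tables (with decoy records that
#' each violate exactly one filter rule), a rooted disease ontology with
#' annotation counts, and the auxiliary mapping tables — under known ground
#' truth: baseline phase-transition probabilities and a multiplicative
#' relative-success effect injected for genetically supported pairs.
#'
#' @param n_genes,n_indications,n_drugs positive counts.
#' @param ontology_terms total ontology terms (>= 3); default places each
#'   indication in its own disease group (`3 * n_indications + 12`).
#' @param baseline_ps ordered probabilities of the four phase transitions
#'   (preclinical->I, I->II, II->III, III->launch), each in `[0, 1]`.
#' @param injected_rs positive multiplier applied to each transition
#'   probability for supported pairs; capped so `p * injected_rs <= 1`.
#' @param support_prevalence probability a candidate gene-indication pair is
#'   genetically supported.
#' @param active_fraction probability a non-launched programme is censored as
#'   active at its highest phase.
#' @param seed integer seed (< 2^31 - 100); identical config + seed gives a
#'   byte-identical bundle.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 150, n_indications = 40, n_drugs = 500,
                         ontology_terms = NULL,
                         baseline_ps = c(0.6, 0.3, 0.5, 0.6),
                         injected_rs = 2, support_prevalence = 0.1,
                         active_fraction = 0.25, seed = 1) {
  if (is.null(ontology_terms)) ontology_terms <- 3 * n_indications + 12
  stopifnot(n_genes >= 1, n_indications >= 1, n_drugs >= 1)
  if (ontology_terms < 3)
    stop("invalid config: ontology_terms must be >= 3")
  if (length(baseline_ps) != 4 || any(baseline_ps < 0 | baseline_ps > 1))
    stop("invalid config: baseline_ps must be 4 probabilities in [0, 1]")
  if (injected_rs <= 0) stop("invalid config: injected_rs must be positive")
  if (support_prevalence < 0 || support_prevalence > 1 ||
      active_fraction < 0 || active_fraction > 1)
    stop("invalid config: prevalence/active fraction must be in [0, 1]")
  seed <- suppressWarnings(as.integer(seed))
  if (is.na(seed) || abs(seed) > 2^31 - 100)
    stop("invalid config: seed out of integer range")
  structure(list(n_genes = n_genes, n_indications = n_indications,
                 n_drugs = n_drugs, ontology_terms = ontology_terms,
                 baseline_ps = baseline_ps, injected_rs = injected_rs,
                 support_prevalence = support_prevalence,
                 active_fraction = active_fraction, seed = seed),
            class = "synth_config")
}

term_id <- function(i) sprintf("D%06d", i)
gene_id <- function(i) sprintf("GENE%04d", i)

synth_areas <- c("oncology", "cardiovascular", "metabolic", "neurology",
                 "immune", "respiratory")

#' Generate a random rooted disease-ontology DAG
#'
#' Structure: a root, a few top-level branch terms (therapy areas), disease
#' "group" terms each carrying an indication-like leaf and a trait-like leaf
#' (so high-similarity indication/trait pairs exist by construction — the two
#' leaves share a deep, low-count ancestor), and extra "far" trait leaves
#' hung directly under branches (low similarity to any indication). Leaves
#' get small positive annotation counts; internal terms get intrinsic count
#' 0, so every term's cumulative count (the IC input) is positive and the
#' root's cumulative count is the sum over leaves.
#'
#' @param config a [synth_config()].
#' @return an `ontology` object with a `meta` element: data.frame of `term`,
#'   `role` (root/branch/group/indication/trait/far_trait), `area`, `group`.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  T <- config$ontology_terms
  root <- term_id(1)
  edges <- NULL
  meta <- data.frame(term = root, role = "root", area = NA_character_,
                     group = NA_character_)
  counts <- c()
  nid <- 1L
  new_term <- function() { nid <<- nid + 1L; term_id(nid) }

  if (T < 7) {
    # degenerate flat ontology: root plus T-1 leaves
    for (i in seq_len(T - 1)) {
      leaf <- new_term()
      edges <- rbind(edges, data.frame(child = leaf, parent = root))
      role <- if (i %% 2 == 1) "indication" else "trait"
      meta <- rbind(meta, data.frame(term = leaf, role = role,
                                     area = "other", group = NA_character_))
      counts[leaf] <- sample(1:3, 1)
    }
  } else {
    n_branch <- max(2, min(length(synth_areas), floor((T - 1) / 10)))
    branches <- character(n_branch)
    for (b in seq_len(n_branch)) {
      branches[b] <- new_term()
      edges <- rbind(edges, data.frame(child = branches[b], parent = root))
      meta <- rbind(meta, data.frame(term = branches[b], role = "branch",
                                     area = synth_areas[b],
                                     group = NA_character_))
    }
    remaining <- T - 1 - n_branch
    n_group <- floor(remaining / 3)
    n_far <- remaining - 3 * n_group
    for (gidx in seq_len(n_group)) {
      b <- 1 + (gidx - 1) %% n_branch
      grp <- new_term()
      edges <- rbind(edges, data.frame(child = grp, parent = branches[b]))
      meta <- rbind(meta, data.frame(term = grp, role = "group",
                                     area = synth_areas[b], group = grp))
      for (role in c("indication", "trait")) {
        leaf <- new_term()
        edges <- rbind(edges, data.frame(child = leaf, parent = grp))
        meta <- rbind(meta, data.frame(term = leaf, role = role,
                                       area = synth_areas[b], group = grp))
        counts[leaf] <- 1
      }
    }
    for (fidx in seq_len(n_far)) {
      b <- 1 + (fidx - 1) %% n_branch
      leaf <- new_term()
      edges <- rbind(edges, data.frame(child = leaf, parent = branches[b]))
      meta <- rbind(meta, data.frame(term = leaf, role = "far_trait",
                                     area = synth_areas[b],
                                     group = NA_character_))
      counts[leaf] <- sample(2:5, 1)
    }
  }
  onto <- ontology(edges, counts)
  onto$meta <- meta
  onto
}

loguniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Generate per-source genetic-association tables with decoys
#'
#' Emits five raw source tables (`mendelian`, `gwas`, `coloc`, `exome`,
#' `somatic`). Passing records realize the intended gene-indication support
#' through the indication's paired trait term; decoy records each violate
#' exactly one filter rule (e.g. a Mendelian "somatic" label, a GWAS hit at
#' P = 1e-6, an L2G share of 0.3, H4 = 0.5, exome P = 1e-4). GWAS hits carry
#' lead-variant positions (supported traits get >= 3 loci in distinct
#' megabase bins), effect sizes (lognormal betas, lognormal odds ratios
#' around 1), MAF (loguniform on [1e-4, 0.5]), year and per-gene L2G score
#' triplets whose shares sum to 1 per hit.
#'
#' @param config a [synth_config()].
#' @param onto output of [generate_ontology()].
#' @param intended data.frame with `gene`, `indication_term`, `supported`
#'   (the candidate pool with intended support flags); when `NULL` a pool is
#'   sampled internally.
#' @return list with the five raw tables, `pass_lists` (per-source
#'   data.frames of the (gene, trait_term) pairs expected to survive the
#'   filters), `remap` (supplementary -> main heading table) and `intended`.
#' @export
generate_associations <- function(config, onto, intended = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  meta <- onto$meta
  inds <- meta$term[meta$role == "indication"]
  if (length(inds) < config$n_indications)
    stop("invalid config: ontology too small for n_indications ",
         "(", length(inds), " indication terms available)")
  inds <- inds[seq_len(config$n_indications)]
  genes <- gene_id(seq_len(config$n_genes))
  far <- meta$term[meta$role == "far_trait"]
  # paired trait term for each indication = its group sibling
  paired <- vapply(inds, function(i) {
    grp <- meta$group[meta$term == i]
    meta$term[meta$role == "trait" & meta$group == grp][1]
  }, character(1))
  names(paired) <- inds
  if (anyNA(paired))
    stop("ontology has no paired trait terms for some indications; ",
         "use a larger (grouped) ontology")

  if (is.null(intended)) {
    # candidate pairs that drug programmes may draw from, plus a wider set of
    # never-pursued pairs so supported gene-indication pairs exist outside
    # the pipeline (as in real data, where most are never pursued)
    n_pool <- max(20L, round(config$n_drugs / 2.5))
    pool <- unique(data.frame(
      gene = sample(genes, n_pool, replace = TRUE),
      indication_term = sample(inds, n_pool, replace = TRUE)))
    pool$in_pipeline <- TRUE
    n_extra <- max(10L, round(n_pool * 1.5))
    extra <- unique(data.frame(
      gene = sample(genes, n_extra, replace = TRUE),
      indication_term = sample(inds, n_extra, replace = TRUE)))
    extra$in_pipeline <- FALSE
    pool <- rbind(pool, extra)
    pool <- pool[!duplicated(pool[, c("gene", "indication_term")]), ,
                 drop = FALSE]
    pool$supported <- stats::runif(nrow(pool)) < config$support_prevalence
    intended <- pool
  }
  sup <- intended[intended$supported, , drop = FALSE]

  mend <- list(); gwas_hits <- list(); coloc <- list(); exome <- list()
  pass <- list(mendelian = list(), gwas = list(), coloc = list(),
               exome = list(), somatic = list())
  hid <- 0L
  add_gwas_hit <- function(g, trait, p, share_main, chrom, pos, year,
                           quantitative = TRUE, passes = TRUE) {
    hid <<- hid + 1L
    filler <- sample(setdiff(genes, g), 2)
    score_main <- share_main
    scores <- c(score_main, (1 - share_main) * c(0.7, 0.3))
    rows <- data.frame(
      hit_id = sprintf("hit%05d", hid),
      gene = c(g, filler), l2g_score = scores,
      trait_term = trait, p_value = p, lead_chrom = chrom, lead_pos = pos,
      effect_beta = if (quantitative) stats::rlnorm(1, -2, 0.8) else NA,
      effect_or = if (quantitative) NA else stats::rlnorm(1, 0, 0.3),
      maf = loguniform(1, 1e-4, 0.5), year = year)
    gwas_hits[[length(gwas_hits) + 1L]] <<- rows
    if (passes) pass$gwas[[length(pass$gwas) + 1L]] <<-
      data.frame(gene = g, trait_term = trait)
    invisible(NULL)
  }

  # --- passing records realizing intended support ---
  for (i in seq_len(nrow(sup))) {
    g <- sup$gene[i]; trait <- paired[[sup$indication_term[i]]]
    src <- sample(c("mendelian", "gwas", "coloc", "exome"), 1,
                  prob = c(0.3, 0.4, 0.15, 0.15))
    yr <- sample(2005:2020, 1)
    if (src == "mendelian") {
      mend[[length(mend) + 1L]] <- data.frame(
        gene = g, phenotype_label = paste("Syndrome", trait),
        mapping_code = 3, phenotype_id = paste0("MIM", 600000 + i),
        gene_id = paste0("MIM", 100000 + i), trait_term = trait, year = yr)
      pass$mendelian[[length(pass$mendelian) + 1L]] <-
        data.frame(gene = g, trait_term = trait)
    } else if (src == "gwas") {
      chrom <- sample(1:22, 1)
      for (k in 1:3)  # three independent loci, distinct megabase bins
        add_gwas_hit(g, trait, p = loguniform(1, 1e-12, 1e-9),
                     share_main = stats::runif(1, 0.7, 1), chrom = chrom,
                     pos = k * 3e6 + sample(0:4e5, 1), year = yr + k - 1,
                     quantitative = stats::runif(1) < 0.5)
    } else if (src == "coloc") {
      coloc[[length(coloc) + 1L]] <- data.frame(
        gene = g, trait_term = trait, p_value = loguniform(1, 1e-12, 1e-9),
        eqtl_p = loguniform(1, 1e-10, 1e-6),
        h4 = stats::runif(1, 0.9, 1), year = yr)
      pass$coloc[[length(pass$coloc) + 1L]] <-
        data.frame(gene = g, trait_term = trait)
    } else {
      exome[[length(exome) + 1L]] <- data.frame(
        gene = g, trait_term = trait, model = sample(exome_models, 1),
        p_value = loguniform(1, 1e-10, 1e-6), year = yr)
      pass$exome[[length(pass$exome) + 1L]] <-
        data.frame(gene = g, trait_term = trait)
    }
  }

  # --- background passing records on far traits (no support induced) ---
  n_bg <- max(5L, round(config$n_genes / 10))
  if (length(far)) {
    for (i in seq_len(n_bg)) {
      g <- sample(genes, 1); trait <- sample(far, 1)
      add_gwas_hit(g, trait, p = loguniform(1, 1e-12, 1e-9),
                   share_main = stats::runif(1, 0.6, 1),
                   chrom = sample(1:22, 1), pos = sample(1:2e8, 1),
                   year = sample(2008:2022, 1),
                   quantitative = stats::runif(1) < 0.5)
    }
  }
  # mendelian records for a spread of traits so indications have insight
  insight_inds <- inds[seq_len(max(1, floor(length(inds) * 0.6)))]
  for (ind in insight_inds) {
    g <- sample(genes, 1)
    mend[[length(mend) + 1L]] <- data.frame(
      gene = g, phenotype_label = paste("Disorder", paired[[ind]]),
      mapping_code = 3, phenotype_id = paste0("MIM", 700000 + match(ind, inds)),
      gene_id = paste0("MIM", 200000 + match(ind, inds)),
      trait_term = paired[[ind]], year = sample(2000:2015, 1))
    pass$mendelian[[length(pass$mendelian) + 1L]] <-
      data.frame(gene = g, trait_term = paired[[ind]])
  }

  # --- decoys: each violates exactly one filter rule ---
  dtrait <- if (length(far)) far[1] else paired[[1]]
  dg <- sample(genes, 12)
  mend_decoys <- data.frame(
    gene = dg[1:8],
    phenotype_label = c("Leukemia, acute myeloid, somatic",
                        "{Diabetes, susceptibility to}",
                        "Warfarin response", "?Cataract 12",
                        "[Blood group, Lewis]",
                        "{Hypertension, essential}",
                        "Plain phenotype, wrong code",
                        "Missing trait mapping"),
    mapping_code = c(3, 3, 3, 3, 3, 3, 2, 3),
    phenotype_id = paste0("MIM", 800001:800008),
    gene_id = paste0("MIM", 300001:300008),
    trait_term = c(dtrait, dtrait, dtrait, dtrait, dtrait, dtrait, dtrait, NA),
    year = 2010)
  # retained brace exception: cancer-related susceptibility flag
  mend_keep <- data.frame(
    gene = dg[9], phenotype_label = "{Colorectal cancer, susceptibility to}",
    mapping_code = 3, phenotype_id = "MIM800009", gene_id = "MIM300009",
    trait_term = dtrait, year = 2010)
  pass$mendelian[[length(pass$mendelian) + 1L]] <-
    data.frame(gene = dg[9], trait_term = dtrait)
  # exact duplicate of the retained record (dropped by dedupe)
  mend <- c(mend, list(mend_decoys, mend_keep, mend_keep))

  add_gwas_hit(dg[10], dtrait, p = 1e-6, share_main = 0.9,
               chrom = 1, pos = 5e6, year = 2015, passes = FALSE)
  # low-share decoy: target gene at share 0.3; its 0.49/0.21 fillers also fail
  hid <- hid + 1L
  filler <- sample(setdiff(genes, dg[11]), 2)
  gwas_hits[[length(gwas_hits) + 1L]] <- data.frame(
    hit_id = sprintf("hit%05d", hid), gene = c(dg[11], filler),
    l2g_score = c(0.3, 0.49, 0.21), trait_term = dtrait, p_value = 1e-9,
    lead_chrom = 2, lead_pos = 7.2e6, effect_beta = NA, effect_or = 1.2,
    maf = 0.01, year = 2016)

  coloc <- c(coloc, list(
    data.frame(gene = dg[12], trait_term = dtrait, p_value = 1e-9,
               eqtl_p = 1e-7, h4 = 0.5, year = 2014),          # H4 fails
    data.frame(gene = dg[12], trait_term = dtrait, p_value = 1e-6,
               eqtl_p = 1e-7, h4 = 0.95, year = 2014),         # GWAS P fails
    data.frame(gene = dg[12], trait_term = dtrait, p_value = 1e-9,
               eqtl_p = 1e-4, h4 = 0.95, year = 2014)))        # eQTL P fails
  exome <- c(exome, list(
    data.frame(gene = dg[12], trait_term = dtrait, model = "pLoF-burden",
               p_value = 1e-4, year = 2018),                   # P fails
    data.frame(gene = dg[12], trait_term = dtrait, model = "pLoF-SKAT",
               p_value = 1e-5, year = 2018),                   # boundary: dropped
    data.frame(gene = dg[12], trait_term = dtrait, model = "mystery-model",
               p_value = 1e-9, year = 2018)))                  # unknown model

  # --- somatic driver table (oncology branch traits) ---
  onc_groups <- meta$term[meta$role == "trait" & meta$area == "oncology"]
  somatic <- NULL
  if (length(onc_groups)) {
    sg <- sample(genes, min(6, config$n_genes))
    somatic <- do.call(rbind, lapply(seq_along(sg), function(i) {
      n_coh <- sample(2:4, 1)
      roles <- sample(c("oncogene", "tumour_suppressor"), n_coh,
                      replace = TRUE, prob = c(0.6, 0.4))
      if (i == 1) roles <- c("oncogene", "oncogene", "tumour_suppressor")
      if (i == 2) roles <- c("oncogene", "tumour_suppressor")  # tie
      data.frame(gene = sg[i], cohort = paste0("cohort", seq_along(roles)),
                 role = roles,
                 trait_term = sample(onc_groups, 1), year = 2012)
    }))
    for (g in unique(somatic$gene))
      pass$somatic[[length(pass$somatic) + 1L]] <- data.frame(
        gene = g, trait_term = somatic$trait_term[somatic$gene == g][1])
  }

  # --- supplementary-concept remap table; rewrite a few mendelian traits ---
  mend_df <- do.call(rbind, c(mend, list(make.row.names = FALSE)))
  supp_n <- min(3L, nrow(mend_df))
  supp_ids <- sprintf("C%06d", seq_len(supp_n))
  remap <- data.frame(supplementary = supp_ids,
                      main = mend_df$trait_term[seq_len(supp_n)])
  remap <- remap[!is.na(remap$main), , drop = FALSE]

  bind <- function(lst) if (length(lst))
    do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
  pass_lists <- lapply(pass, function(p) {
    df <- bind(p)
    if (is.null(df)) data.frame(gene = character(), trait_term = character())
    else unique(df)
  })
  list(mendelian = mend_df, gwas = bind(gwas_hits), coloc = bind(coloc),
       exome = bind(exome), somatic = somatic, pass_lists = pass_lists,
       remap = remap, intended = intended,
       paired_trait = data.frame(indication_term = inds,
                                 trait_term = unname(paired)))
}

#' Simulate drug-programme phase advancement under known ground truth
#'
#' Each programme is assigned a (gene, indication) pair from the candidate
#' pool and advances through the ordered phase ladder by sequential Bernoulli
#' draws with per-transition probability `baseline_ps[k]` (unsupported pairs)
#' or `min(1, baseline_ps[k] * injected_rs)` (supported pairs). The highest
#' phase reached is recorded; non-launched programmes are flagged active with
#' probability `active_fraction` (after the advancement draws, so active
#' programmes at phase k count as non-successes at k).
#'
#' @param config a [synth_config()].
#' @param truth_support data.frame with `gene`, `indication_term`,
#'   `supported` — the candidate pair pool with support truth.
#' @return data.frame of programmes: `drug_id`, `gene`, `indication_term`,
#'   `highest_phase`, `status`, `year_added`, `supported_truth`.
#' @export
generate_pipeline <- function(config, truth_support) {
  stopifnot(inherits(config, "synth_config"),
            all(c("gene", "indication_term", "supported") %in%
                  names(truth_support)))
  set.seed(config$seed + 3L)
  n <- config$n_drugs
  idx <- sample(nrow(truth_support), n, replace = TRUE)
  sup <- truth_support$supported[idx]
  ps_unsup <- config$baseline_ps
  ps_sup <- pmin(1, config$baseline_ps * config$injected_rs)
  # sequential Bernoulli ladder, vectorized across programmes
  alive <- rep(TRUE, n)
  reached <- rep(1L, n)
  for (k in 1:4) {
    p <- ifelse(sup, ps_sup[k], ps_unsup[k])
    adv <- alive & (stats::runif(n) < p)
    reached[adv] <- k + 1L
    alive <- adv
  }
  launched <- reached == 5L
  active <- !launched & stats::runif(n) < config$active_fraction
  data.frame(drug_id = sprintf("DRUG%05d", seq_len(n)),
             gene = truth_support$gene[idx],
             indication_term = truth_support$indication_term[idx],
             highest_phase = phase_levels[reached],
             status = ifelse(active, "active", "historical"),
             year_added = sample(2000:2022, n, replace = TRUE),
             supported_truth = sup)
}

#' Generate the complete synthetic fixture bundle
#'
#' Runs ontology, association and pipeline generation, realizes ground-truth
#' support by pushing the generator's own pass-list associations through the
#' similarity module at `tau`, simulates programme advancement with the
#' realized flags, and assembles the mapping tables (supplementary-concept
#' remap, therapy-area tree positions, druggability/family gene lists and
#' evidence tiers).
#'
#' @param config a [synth_config()].
#' @param tau similarity threshold used to realize support (default 0.8).
#' @return list of class `fixture_bundle`: `programs`, `raw` (five source
#'   tables), `ontology`, `mappings` (remap, tree_positions, gene_lists,
#'   tiers), `similarity` (calibrated indication x trait table) and `truth`
#'   (config echo, intended and realized support, per-source pass lists,
#'   effective transition probabilities).
#' @export
synth_bundle <- function(config = synth_config(), tau = 0.8) {
  onto <- generate_ontology(config)
  assoc <- generate_associations(config, onto)

  # realized support: the generator's pass-list associations through the
  # similarity module (this is the truth the success simulation uses)
  pl <- assoc$pass_lists
  passing <- do.call(rbind, lapply(names(pl), function(s) {
    if (!nrow(pl[[s]])) return(NULL)
    cbind(pl[[s]], source = s)
  }))
  passing <- passing[!startsWith(passing$trait_term, "C"), , drop = FALSE]
  passing$year <- NA_integer_
  inds <- assoc$paired_trait$indication_term
  sim <- combined_similarity(onto, inds, unique(passing$trait_term))
  realized <- assign_support(assoc$intended, passing, sim, tau = tau)
  ikey <- paste(assoc$intended$gene, assoc$intended$indication_term)
  rkey <- paste(realized$gene, realized$indication_term)
  realized$in_pipeline <- if ("in_pipeline" %in% names(assoc$intended))
    assoc$intended$in_pipeline[match(rkey, ikey)] else TRUE
  truth_support <- realized[realized$in_pipeline,
                            c("gene", "indication_term", "supported")]

  programs <- generate_pipeline(config, truth_support)

  set.seed(config$seed + 4L)
  meta <- onto$meta
  tree_positions <- data.frame(term = meta$term[meta$role == "indication"],
                               area = meta$area[meta$role == "indication"])
  genes <- gene_id(seq_len(config$n_genes))
  fam_draw <- sample(c("kinase", "GPCR", "ion_channel", "nuclear_receptor",
                       "enzyme", "other"), config$n_genes, replace = TRUE,
                     prob = c(0.12, 0.12, 0.08, 0.05, 0.25, 0.38))
  gene_lists <- split(genes, fam_draw)
  gene_lists$other <- NULL
  # overlap to exercise the kinase-priority rule
  if (length(gene_lists$kinase))
    gene_lists$enzyme <- unique(c(gene_lists$enzyme, gene_lists$kinase[1]))
  tract <- data.frame(gene = genes,
                      antibody = stats::runif(config$n_genes) < 0.4,
                      small_molecule = stats::runif(config$n_genes) < 0.5)
  tiers <- list(mendelian = unique(pl$mendelian$gene),
                gwas = unique(pl$gwas$gene))

  truth <- list(config = unclass(config), tau = tau,
                intended = assoc$intended,
                realized = realized,
                pass_lists = pl,
                paired_trait = assoc$paired_trait,
                effective_ps_supported =
                  pmin(1, config$baseline_ps * config$injected_rs),
                baseline_ps = config$baseline_ps,
                injected_rs = config$injected_rs)
  structure(list(programs = programs,
                 raw = assoc[c("mendelian", "gwas", "coloc", "exome",
                               "somatic")],
                 ontology = onto,
                 mappings = list(remap = assoc$remap,
                                 tree_positions = tree_positions,
                                 gene_lists = gene_lists,
                                 tractability = tract, tiers = tiers),
                 similarity = sim, truth = truth),
            class = "fixture_bundle")
}

#' Write / read a fixture bundle as delimited text
#'
#' One tab-separated file per table (header row, empty fields for missing
#' values), the ontology as a child/parent/count edge list, and the truth
#' record as JSON.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @rdname bundle_io
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, paste0(name, ".tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  w(bundle$programs, "programs")
  for (s in names(bundle$raw)) if (!is.null(bundle$raw[[s]]))
    w(bundle$raw[[s]], s)
  write_ontology(bundle$ontology, file.path(dir, "ontology.tsv"))
  w(bundle$ontology$meta, "ontology_meta")
  w(bundle$mappings$remap, "remap")
  w(bundle$mappings$tree_positions, "tree_positions")
  gl <- do.call(rbind, lapply(names(bundle$mappings$gene_lists), function(nm)
    data.frame(list = nm, gene = bundle$mappings$gene_lists[[nm]])))
  w(gl, "gene_lists")
  w(bundle$mappings$tractability, "tractability")
  tl <- do.call(rbind, lapply(names(bundle$mappings$tiers), function(nm)
    data.frame(tier = nm, gene = bundle$mappings$tiers[[nm]])))
  w(tl, "tiers")
  jsonlite::write_json(bundle$truth[c("config", "tau", "baseline_ps",
                                      "injected_rs",
                                      "effective_ps_supported")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  w(bundle$truth$realized, "truth_support")
  invisible(dir)
}

#' @param dir directory written by [write_bundle()].
#' @rdname bundle_io
#' @export
read_bundle <- function(dir) {
  r <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) return(NULL)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
  }
  gl <- r("gene_lists")
  tl <- r("tiers")
  list(programs = r("programs"),
       raw = list(mendelian = r("mendelian"), gwas = r("gwas"),
                  coloc = r("coloc"), exome = r("exome"),
                  somatic = r("somatic")),
       ontology = read_ontology(file.path(dir, "ontology.tsv")),
       mappings = list(
         remap = r("remap"), tree_positions = r("tree_positions"),
         gene_lists = if (!is.null(gl)) split(gl$gene, gl$list),
         tractability = r("tractability"),
         tiers = if (!is.null(tl)) split(tl$gene, tl$tier)),
       truth = c(jsonlite::read_json(file.path(dir, "truth.json"),
                                     simplifyVector = TRUE),
                 list(realized = r("truth_support"))))
}
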