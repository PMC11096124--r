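#' Size of the gene-by-indication possibility space
#'
#' @param genes,indications character vectors (deduplicated internally).
#' @return number of possible G-I pairs, `length(genes) * length(indications)`.
#' @export
universe_size <- function(genes, indications) {
  length(unique(genes)) * length(unique(indications))
}

#' Enumerate the gene-by-indication universe
#'
#' Builds one cell per (gene, indication) pair, marks genetic support (from
#' the support assignments) and clinical pursuit (any programme for the pair
#' with highest phase at or beyond phase I), and summarizes the counts.
#'
#' @param genes character vector of the gene universe.
#' @param indications character vector of the indication universe.
#' @param assignments output of [assign_support()] (pairs absent from it are
#'   unsupported).
#' @param programs optional programme table with `gene`, `indication_term`,
#'   `highest_phase`; when `NULL` all cells are unpursued.
#' @return data.frame of cells (`gene`, `indication_term`, `supported`,
#'   `pursued`) with a `summary` attribute (total, supported count/fraction,
#'   pursued count, pursued-and-supported count).
#' @export
enumerate_universe <- function(genes, indications, assignments,
                               programs = NULL) {
  genes <- unique(genes); indications <- unique(indications)
  if (!length(genes) || !length(indications))
    stop("invalid input: gene and indication lists must be non-empty")
  cells <- expand.grid(gene = genes, indication_term = indications,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  key <- function(g, i) paste(g, i, sep = "\r")
  sup_keys <- key(assignments$gene[assignments$supported],
                  assignments$indication_term[assignments$supported])
  cells$supported <- key(cells$gene, cells$indication_term) %in% sup_keys
  cells$pursued <- FALSE
  if (!is.null(programs) && nrow(programs)) {
    clinical <- programs[phase_rank(programs$highest_phase) >=
                           phase_rank("I"), , drop = FALSE]
    cells$pursued <- key(cells$gene, cells$indication_term) %in%
      key(clinical$gene, clinical$indication_term)
  }
  attr(cells, "summary") <- list(
    total = nrow(cells),
    supported = sum(cells$supported),
    supported_fraction = mean(cells$supported),
    pursued = sum(cells$pursued),
    pursued_and_supported = sum(cells$pursued & cells$supported))
  cells
}

#' Utilization fractions and enrichment of pursuit among supported pairs
#'
#' Reports the fraction of supported cells pursued, the fraction of pursued
#' cells supported, the sample (cross-product) odds ratio of the 2x2
#' pursued-by-supported table, and the two-sided p-value from
#' [stats::fisher.test()]. A zero margin yields a degenerate flag; when the
#' supported and pursued sets coincide exactly the odds ratio is infinite.
#'
#' @param universe output of [enumerate_universe()].
#' @return list with `pursued_given_supported`, `supported_given_pursued`,
#'   `odds_ratio`, `p_value`, `table`, `degenerate`.
#' @export
utilization_stats <- function(universe) {
  a <- sum(universe$pursued & universe$supported)
  b <- sum(!universe$pursued & universe$supported)
  c_ <- sum(universe$pursued & !universe$supported)
  d <- sum(!universe$pursued & !universe$supported)
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(pursued = c("yes", "no"),
                                supported = c("yes", "no")))
  degenerate <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
  or <- if (b * c_ == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c_)
  p <- if (degenerate) NA_real_ else stats::fisher.test(tab)$p.value
  list(pursued_given_supported = if ((a + b) > 0) a / (a + b) else NA_real_,
       supported_given_pursued = if ((a + c_) > 0) a / (a + c_) else NA_real_,
       odds_ratio = or, p_value = p, table = tab, degenerate = degenerate)
}

#' Restrict supported cells to each gene-trait's most similar indication
#'
#' For each supported gene, only the indication(s) with maximal combined
#' similarity to the gene's best trait are retained (exact ties are all
#' retained and logged in the `ties` attribute). Optionally drops genes whose
#' best trait has more than `max_hits` GWAS loci.
#'
#' @param universe output of [enumerate_universe()].
#' @param assignments output of [assign_support()].
#' @param associations unified evidence table (needed when `max_hits` is set).
#' @param max_hits optional cap on the best trait's GWAS locus count.
#' @return the universe with supported cells not at the argmax demoted to
#'   unsupported; attribute `ties` lists genes with tied argmax indications.
#' @export
restrict_most_similar <- function(universe, assignments, associations = NULL,
                                  max_hits = NULL) {
  sup <- assignments[assignments$supported, , drop = FALSE]
  keep <- character(0); ties <- character(0)
  drop_genes <- character(0)
  if (!is.null(max_hits)) {
    stopifnot(!is.null(associations))
    lc <- gwas_locus_counts(associations[associations$source == "gwas", ,
                                         drop = FALSE])
    busy <- lc$trait_term[lc$n_loci > max_hits]
    drop_genes <- unique(sup$gene[sup$best_trait %in% busy])
  }
  for (g in setdiff(unique(sup$gene), drop_genes)) {
    rows <- sup[sup$gene == g, , drop = FALSE]
    best <- max(rows$best_similarity)
    at <- rows$indication_term[rows$best_similarity == best]
    if (length(at) > 1) ties <- c(ties, g)
    keep <- c(keep, paste(g, at, sep = "\r"))
  }
  out <- universe
  cellkey <- paste(out$gene, out$indication_term, sep = "\r")
  out$supported <- out$supported & cellkey %in% keep
  attr(out, "summary") <- list(
    total = nrow(out), supported = sum(out$supported),
    supported_fraction = mean(out$supported), pursued = sum(out$pursued),
    pursued_and_supported = sum(out$pursued & out$supported))
  attr(out, "ties") <- unique(ties)
  out
}

#' Assign genes to non-overlapping druggable family lists
#'
#' Genes present in the kinase list and also in the enzyme, ion-channel or
#' nuclear-receptor lists are considered kinases only; remaining overlaps are
#' left as supplied; genes in no list fall into `"other"`.
#'
#' @param genes character vector.
#' @param lists named list of character vectors (e.g. `kinase`, `GPCR`,
#'   `ion_channel`, `nuclear_receptor`, `enzyme`).
#' @return named character vector gene -> family label.
#' @export
assign_gene_lists <- function(genes, lists) {
  fam <- stats::setNames(rep("other", length(genes)), genes)
  kin <- lists[["kinase"]]
  for (nm in names(lists)) {
    members <- intersect(lists[[nm]], genes)
    if (nm %in% c("enzyme", "ion_channel", "nuclear_receptor") &&
        !is.null(kin))
      members <- setdiff(members, kin)
    fam[members[fam[members] == "other"]] <- nm
  }
  if (!is.null(kin)) fam[intersect(kin, genes)] <- "kinase"
  fam
}

#' Cross-tabulated pursuit fractions of supported pairs
#'
#' For each (therapy area x gene list) cell: the fraction of genetically
#' supported G-I pairs (or genes, with `group_by = "gene"`) developed to at
#' least phase I. Gene-level grouping counts a gene once in the numerator if
#' at least one of its supported indications was pursued, and once in the
#' denominator if it has any supported indication in the area. Empty
#' denominators give `NA`, not zero.
#'
#' @param universe output of [enumerate_universe()] (supported/pursued flags).
#' @param areas named list indication term -> character vector of areas (from
#'   [therapy_areas()]).
#' @param families named character vector gene -> list label (from
#'   [assign_gene_lists()]).
#' @param group_by `"cell"` (G-I pairs) or `"gene"`.
#' @return list with `fraction` (area x list matrix), `numerator`,
#'   `denominator`, and `long` (tidy data.frame).
#' @export
crosstab_utilization <- function(universe, areas, families,
                                 group_by = c("cell", "gene")) {
  group_by <- match.arg(group_by)
  sup <- universe[universe$supported, , drop = FALSE]
  if (!all(sup$gene %in% names(families)))
    stop("unknown list label: genes missing from `families`: ",
         paste(setdiff(sup$gene, names(families)), collapse = ", "))
  area_of <- function(ind) areas[[ind]] %||% "other"
  rows <- do.call(rbind, lapply(seq_len(nrow(sup)), function(i) {
    data.frame(area = area_of(sup$indication_term[i]),
               family = unname(families[sup$gene[i]]),
               gene = sup$gene[i], pursued = sup$pursued[i])
  }))
  if (is.null(rows))
    return(list(fraction = matrix(numeric(0), 0, 0),
                numerator = NULL, denominator = NULL,
                long = data.frame()))
  all_areas <- sort(unique(rows$area))
  all_fams <- sort(unique(rows$family))
  num <- den <- matrix(0L, length(all_areas), length(all_fams),
                       dimnames = list(all_areas, all_fams))
  for (a in all_areas) for (f in all_fams) {
    r <- rows[rows$area == a & rows$family == f, , drop = FALSE]
    if (group_by == "gene") {
      den[a, f] <- length(unique(r$gene))
      num[a, f] <- length(unique(r$gene[r$pursued]))
    } else {
      den[a, f] <- nrow(r)
      num[a, f] <- sum(r$pursued)
    }
  }
  frac <- ifelse(den > 0, num / den, NA_real_)
  long <- do.call(rbind, lapply(all_areas, function(a)
    data.frame(area = a, family = all_fams, numerator = num[a, ],
               denominator = den[a, ], fraction = frac[a, ],
               row.names = NULL)))
  list(fraction = frac, numerator = num, denominator = den, long = long)
}

#' Evidence-tier yield of launched drug targets
#'
#' Per drug, one target is selected by earliest-evidence tier priority; per
#' target, its highest phase reached; per phase, the number of unique
#' targets; per tier, the yield = launched targets in the tier divided by the
#' tier size (after earliest-tier deduplication of the input gene sets).
#'
#' @param programs data.frame with `drug_id`, `gene`, `highest_phase`.
#' @param tiers ordered named list of gene vectors, earliest evidence first;
#'   genes present in several tiers count only in the earliest. A final
#'   implicit `"none"` tier absorbs unlisted genes.
#' @return list with `target_phase` (per selected target), `phase_counts`,
#'   and `yield` data.frame (tier, size, launched, yield).
#' @export
yield_analysis <- function(programs, tiers) {
  if (!nrow(programs))
    return(list(target_phase = data.frame(), phase_counts = integer(0),
                yield = data.frame()))
  # earliest-tier deduplication of the tier gene sets
  seen <- character(0)
  tiers <- lapply(tiers, function(g) {
    g <- setdiff(unique(g), seen); seen <<- c(seen, g); g
  })
  tier_of <- function(gene) {
    for (nm in names(tiers)) if (gene %in% tiers[[nm]]) return(nm)
    "none"
  }
  tier_rank <- stats::setNames(seq_along(tiers), names(tiers))
  # per drug: keep the target with the earliest genetic support
  sel <- lapply(split(programs, programs$drug_id), function(p) {
    tr <- vapply(p$gene, tier_of, character(1))
    rk <- tier_rank[tr]
    rk[is.na(rk)] <- length(tiers) + 1L
    p[which.min(rk), c("gene", "highest_phase"), drop = FALSE]
  })
  sel <- do.call(rbind, c(sel, list(make.row.names = FALSE)))
  # per target: highest phase reached
  tp <- vapply(split(sel$highest_phase, sel$gene),
               function(ph) phase_levels[max(phase_rank(ph))], character(1))
  target_phase <- data.frame(gene = names(tp), highest_phase = unname(tp))
  target_phase$tier <- vapply(target_phase$gene, tier_of, character(1))
  phase_counts <- table(factor(target_phase$highest_phase,
                               levels = phase_levels))
  launched <- target_phase$gene[target_phase$highest_phase == "launched"]
  yield <- do.call(rbind, lapply(names(tiers), function(nm) {
    size <- length(tiers[[nm]])
    nl <- length(intersect(launched, tiers[[nm]]))
    data.frame(tier = nm, size = size, launched = nl,
               yield = if (size > 0) nl / size else NA_real_)
  }))
  list(target_phase = target_phase, phase_counts = phase_counts,
       yield = yield)
}
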