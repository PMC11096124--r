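#' Assign genetic support to target-indication pairs
#'
#' A T-I pair possesses genetic support when the target gene has a (filtered)
#' association to a trait whose combined similarity to the indication is at
#' least `tau` (inclusive; default 0.8). One assignment row is produced per
#' distinct (gene, indication). `sources` lists every evidence source
#' contributing a qualifying association; `first_year` is the earliest year
#' among them.
#'
#' @param ti_pairs data.frame with `gene`, `indication_term` (extra columns
#'   ignored; duplicates collapsed).
#' @param associations unified evidence table (see [assemble_evidence()]).
#' @param similarity calibrated similarity table with `term_a` (indication),
#'   `term_b` (trait), `combined`.
#' @param tau similarity threshold in `[0, 1]`, inclusive (default 0.8).
#' @return data.frame with columns `gene`, `indication_term`, `supported`,
#'   `best_similarity`, `best_trait`, `sources` (comma-joined), `first_year`.
#' @export
assign_support <- function(ti_pairs, associations, similarity, tau = 0.8) {
  if (tau < 0 || tau > 1) stop("invalid config: tau must be in [0, 1]")
  pairs <- unique(ti_pairs[, c("gene", "indication_term")])
  simkey <- paste(similarity$term_a, similarity$term_b, sep = "\r")
  simval <- stats::setNames(similarity$combined, simkey)
  by_gene <- split(seq_len(nrow(associations)), associations$gene)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- pairs$gene[i]; ind <- pairs$indication_term[i]
    base <- data.frame(gene = g, indication_term = ind, supported = FALSE,
                       best_similarity = 0, best_trait = NA_character_,
                       sources = "", first_year = NA_integer_)
    ai <- by_gene[[g]]
    if (is.null(ai)) return(base)
    a <- associations[ai, , drop = FALSE]
    sims <- unname(simval[paste(ind, a$trait_term, sep = "\r")])
    sims[is.na(sims)] <- 0
    best <- max(sims)
    base$best_similarity <- best
    if (best > 0) base$best_trait <- a$trait_term[which.max(sims)]
    if (best >= tau) {
      qual <- a[sims >= tau, , drop = FALSE]
      base$supported <- TRUE
      base$sources <- paste(sort(unique(qual$source)), collapse = ",")
      yrs <- suppressWarnings(as.integer(qual$year))
      if (any(!is.na(yrs))) base$first_year <- min(yrs, na.rm = TRUE)
    }
    base
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

quartile_bin <- function(x) {
  # quartiles over the supplied values; boundary ties go to the lower bin
  br <- unique(stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1),
                               na.rm = TRUE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE, right = TRUE))
}

#' Binned covariates for GWAS-supported pairs
#'
#' For each GWAS-supported (gene, indication) pair, computes the binned
#' variables used in sensitivity analyses of relative success:
#' \itemize{
#'   \item `first_gwas_year`: year the pair first acquired GWAS support,
#'     excluding replications (only the earliest association per gene-trait
#'     counts) and set to `NA` for pairs also supported by Mendelian evidence;
#'   \item `trait_gene_count`: number of genes with a (filtered) GWAS
#'     association to the pair's best trait;
#'   \item `beta_quartile`: quartile of |beta| (quantitative traits);
#'   \item `or_quartile`: quartile of the standardized odds ratio
#'     `max(OR, 1/OR)` (case/control traits);
#'   \item `maf_bin`: order of magnitude of minor allele frequency,
#'     `floor(log10(MAF))`.
#' }
#' Quartiles are computed across the supported pairs present; unsupported
#' pairs carry `NA` throughout.
#'
#' @param assignments output of [assign_support()].
#' @param associations unified evidence table.
#' @param tau similarity threshold used for qualification (default 0.8).
#' @param similarity calibrated similarity table (needed to identify each
#'   pair's qualifying GWAS associations).
#' @return `assignments` with the covariate columns appended.
#' @export
bin_covariates <- function(assignments, associations, similarity, tau = 0.8) {
  gw <- associations[associations$source == "gwas", , drop = FALSE]
  # replications excluded: earliest association per (gene, trait)
  gw <- gw[order(gw$gene, gw$trait_term, gw$year), , drop = FALSE]
  first_gw <- gw[!duplicated(gw[, c("gene", "trait_term")]), , drop = FALSE]

  simkey <- paste(similarity$term_a, similarity$term_b, sep = "\r")
  simval <- stats::setNames(similarity$combined, simkey)

  n <- nrow(assignments)
  out <- assignments
  out$first_gwas_year <- NA_integer_
  out$trait_gene_count <- NA_integer_
  out$beta_abs <- NA_real_
  out$or_std <- NA_real_
  out$maf_bin <- NA_integer_
  gene_count_by_trait <- tapply(gw$gene, gw$trait_term,
                                function(g) length(unique(g)))

  for (i in seq_len(n)) {
    if (!isTRUE(out$supported[i])) next
    ind <- out$indication_term[i]; g <- out$gene[i]
    mine <- gw[gw$gene == g, , drop = FALSE]
    if (!nrow(mine)) next
    sims <- unname(simval[paste(ind, mine$trait_term, sep = "\r")])
    sims[is.na(sims)] <- 0
    qual <- mine[sims >= tau, , drop = FALSE]
    if (!nrow(qual)) next                      # supported by other sources only
    mendelian_too <- grepl("mendelian", out$sources[i], fixed = TRUE)
    if (!mendelian_too) {
      fmine <- first_gw[first_gw$gene == g, , drop = FALSE]
      fsims <- unname(simval[paste(ind, fmine$trait_term, sep = "\r")])
      fsims[is.na(fsims)] <- 0
      fq <- fmine[fsims >= tau, , drop = FALSE]
      yrs <- suppressWarnings(as.integer(fq$year))
      if (any(!is.na(yrs))) out$first_gwas_year[i] <- min(yrs, na.rm = TRUE)
    }
    bt <- out$best_trait[i]
    if (!is.na(bt) && bt %in% names(gene_count_by_trait))
      out$trait_gene_count[i] <- as.integer(gene_count_by_trait[[bt]])
    b <- qual$effect_beta[!is.na(qual$effect_beta)]
    if (length(b)) out$beta_abs[i] <- max(abs(b))
    o <- qual$effect_or[!is.na(qual$effect_or)]
    if (length(o)) out$or_std[i] <- max(pmax(o, 1 / o))
    m <- qual$maf[!is.na(qual$maf)]
    if (length(m)) out$maf_bin[i] <- as.integer(floor(log10(min(m))))
  }
  out$beta_quartile <- NA_integer_
  out$or_quartile <- NA_integer_
  hb <- !is.na(out$beta_abs)
  if (any(hb)) out$beta_quartile[hb] <- quartile_bin(out$beta_abs[hb])
  ho <- !is.na(out$or_std)
  if (any(ho)) out$or_quartile[ho] <- quartile_bin(out$or_std[ho])
  out
}

#' Standardize an odds ratio to be >= 1
#'
#' Case/control effect sizes are compared on the scale `max(OR, 1/OR)`.
#' @param or positive odds ratio(s).
#' @export
standardize_or <- function(or) {
  stopifnot(all(or > 0))
  pmax(or, 1 / or)
}

#' Order-of-magnitude bin for minor allele frequency
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @return integer `floor(log10(maf))`.
#' @export
maf_bin <- function(maf) {
  stopifnot(all(maf > 0))
  as.integer(floor(log10(maf)))
}
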