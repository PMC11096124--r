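#' Construct a rooted disease-ontology DAG with annotation counts
#'
#' Builds the ontology object used for information-content (IC) similarity.
#' The graph is directed child -> parent, must be acyclic, and every term must
#' reach a single root. Annotation counts may be given per term (intrinsic,
#' the default interpretation) in which case the cumulative count of a term is
#' the sum of intrinsic counts over the term and all of its descendants, or
#' already-cumulative via `cumulative = TRUE`.
#'
#' Information content is `IC(t) = -ln(cumcount(t) / cumcount(root))` (nats),
#' so `IC(root) = 0` and IC is non-decreasing from root to leaves.
#'
#' @param edges data.frame with columns `child`, `parent` (term IDs).
#' @param counts named numeric vector of non-negative annotation counts; names
#'   must cover every term. Terms appearing only as parents may be omitted and
#'   default to an intrinsic count of 0.
#' @param cumulative logical; if `TRUE`, `counts` are taken as cumulative.
#' @return An object of class `ontology` with elements `terms`, `root`,
#'   `edges`, `counts` (intrinsic, or NA if cumulative supplied), `cumcount`,
#'   `ic`, and `ancestors` (list of ancestor sets, each including the term
#'   itself).
#' @export
ontology <- function(edges, counts, cumulative = FALSE) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  terms <- unique(c(edges$child, edges$parent))
  if (anyNA(terms)) stop("ontology terms must not be NA")

  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) stop("ontology edges contain a cycle")
  roots <- terms[igraph::degree(g, mode = "out") == 0]
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  root <- roots

  # ancestors of t = everything reachable along child->parent, incl. t
  anc <- lapply(igraph::ego(g, order = length(terms), mode = "out"),
                function(v) v$name)
  names(anc) <- terms
  if (!all(vapply(anc, function(a) root %in% a, logical(1))))
    stop("every term must reach the root")

  if (is.null(names(counts)))
    stop("counts must be a named vector of per-term annotation counts")
  cnt <- stats::setNames(rep(0, length(terms)), terms)
  known <- intersect(names(counts), terms)
  cnt[known] <- as.numeric(counts[known])
  if (any(cnt < 0)) stop("annotation counts must be non-negative")

  if (cumulative) {
    cum <- cnt
  } else {
    # descendants of t (incl. t) = vertices that reach t along child->parent
    desc <- igraph::ego(g, order = length(terms), mode = "in")
    cum <- vapply(desc, function(v) sum(cnt[v$name]), numeric(1))
    names(cum) <- terms
  }
  if (cum[root] <= 0) stop("root cumulative annotation count must be positive")
  bad <- names(cum)[cum <= 0]
  ic <- ifelse(cum > 0, -log(cum / cum[root]), NA_real_)
  names(ic) <- terms

  structure(list(terms = terms, root = root, edges = edges,
                 counts = if (cumulative) NULL else cnt,
                 cumcount = cum, ic = ic, ancestors = anc,
                 undefined_ic = bad),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology DAG: ", length(x$terms), " terms, root '", x$root,
      "', root cumulative count ", x$cumcount[x$root], "\n", sep = "")
  invisible(x)
}

#' Read / write an ontology edge list
#'
#' Tab-separated file with header columns `child_id`, `parent_id`,
#' `annotation_count` (intrinsic count of the child term; the root's own
#' count, if any, is carried on a `root<TAB>root` self-marker-free line and
#' defaults to 0).
#'
#' @param path file path.
#' @rdname ontology_io
#' @export
read_ontology <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  stopifnot(all(c("child_id", "parent_id", "annotation_count") %in% names(df)))
  counts <- stats::setNames(df$annotation_count, df$child_id)
  edges <- df[!is.na(df$parent_id), , drop = FALSE]
  ontology(data.frame(child = edges$child_id, parent = edges$parent_id),
           counts)
}

#' @param onto an `ontology` object.
#' @rdname ontology_io
#' @export
write_ontology <- function(onto, path) {
  df <- data.frame(child_id = onto$edges$child, parent_id = onto$edges$parent,
                   annotation_count = unname(onto$counts[onto$edges$child]))
  # the root is never a child; carry its intrinsic count on a parentless row
  df <- rbind(df, data.frame(child_id = onto$root, parent_id = "",
                             annotation_count = unname(onto$counts[onto$root])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_terms <- function(onto, terms) {
  missing <- setdiff(terms, onto$terms)
  if (length(missing))
    stop("term(s) not in ontology: ", paste(missing, collapse = ", "))
}

#' Information content of ontology terms
#'
#' `IC(t) = -ln(cumcount(t)/cumcount(root))`, in nats. The root has IC 0.
#'
#' @param onto an `ontology` object.
#' @param terms character vector of term IDs.
#' @return Named numeric vector of IC values.
#' @export
information_content <- function(onto, terms) {
  check_terms(onto, terms)
  if (any(terms %in% onto$undefined_ic))
    stop("IC undefined for zero cumulative count: ",
         paste(intersect(terms, onto$undefined_ic), collapse = ", "))
  onto$ic[terms]
}

#' Ancestors of a term (including the term itself)
#' @inheritParams information_content
#' @param term a single term ID.
#' @export
term_ancestors <- function(onto, term) {
  check_terms(onto, term)
  onto$ancestors[[term]]
}

#' Resnik and Lin similarity for one term pair
#'
#' Resnik similarity is the IC of the most informative common ancestor (MICA);
#' since the root is a common ancestor of every pair it is always >= 0. Lin
#' similarity is `2 * resnik / (IC(a) + IC(b))`, in `[0, 1]`. When both terms
#' are the root (IC sum 0) Lin is 1 for identical terms and 0 otherwise. Any
#' undefined/sentinel similarity (-1) is mapped to 0.
#'
#' @inheritParams information_content
#' @param a,b term IDs.
#' @return list with `resnik_raw` and `lin`.
#' @export
pairwise_similarity <- function(onto, a, b) {
  check_terms(onto, c(a, b))
  common <- intersect(onto$ancestors[[a]], onto$ancestors[[b]])
  resnik <- max(onto$ic[common], 0)
  denom <- onto$ic[[a]] + onto$ic[[b]]
  lin <- if (denom == 0) as.numeric(a == b) else 2 * resnik / denom
  if (is.na(lin) || lin < 0) lin <- 0        # sentinel "-1"/undefined -> 0
  if (resnik < 0) resnik <- 0
  list(resnik_raw = unname(resnik), lin = unname(lin))
}

#' All-pairs similarity table between two term sets
#'
#' @inheritParams information_content
#' @param terms_a,terms_b character vectors (e.g. indication terms and
#'   genetically associated trait terms).
#' @return data.frame with columns `term_a`, `term_b`, `resnik_raw`, `lin`,
#'   one row per pair of the cross product.
#' @export
similarity_table <- function(onto, terms_a, terms_b) {
  terms_a <- unique(terms_a); terms_b <- unique(terms_b)
  check_terms(onto, c(terms_a, terms_b))
  grid <- expand.grid(term_a = terms_a, term_b = terms_b,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sims <- mapply(function(a, b) {
    s <- pairwise_similarity(onto, a, b)
    c(s$resnik_raw, s$lin)
  }, grid$term_a, grid$term_b)
  grid$resnik_raw <- sims[1, ]
  grid$lin <- sims[2, ]
  grid
}

#' Calibrate Resnik against Lin and combine into one similarity score
#'
#' The two scores live on different scales: Lin is already in `[0, 1]` while
#' raw Resnik is in IC units. The raw Resnik scores are rescaled by a single
#' multiplier `m = 1/slope`, where `slope` is the least-squares slope through
#' the origin of raw Resnik on Lin across all supplied pairs, so that the
#' origin-anchored regression of rescaled Resnik on Lin has slope exactly 1.
#' Rescaled values are then clipped to `[0, 1]` (clipping affects only values
#' above 1 and is applied after the slope condition is set). The combined
#' score is the mean of Lin and adjusted Resnik.
#'
#' @param sim data.frame from [similarity_table()].
#' @param clip logical, clip adjusted Resnik to `[0, 1]` (default `TRUE`).
#' @return `sim` with added columns `resnik_adjusted`, `combined`; the
#'   multiplier is attached as attribute `"multiplier"`.
#' @export
calibrate_similarity <- function(sim, clip = TRUE) {
  stopifnot(all(c("resnik_raw", "lin") %in% names(sim)))
  if (nrow(sim) < 2 ||
      (length(unique(sim$lin)) < 2 && length(unique(sim$resnik_raw)) < 2))
    stop("calibration failure: need >= 2 non-identical (lin, resnik) records")
  ss <- sum(sim$lin^2)
  sxy <- sum(sim$lin * sim$resnik_raw)
  if (ss == 0 || sxy == 0)
    stop("calibration failure: degenerate origin-anchored regression ",
         "(all Lin or all Resnik zero)")
  m <- ss / sxy                        # 1 / slope of raw Resnik on Lin
  adj <- sim$resnik_raw * m
  if (clip) adj <- pmin(1, pmax(0, adj))
  sim$resnik_adjusted <- adj
  sim$combined <- (sim$lin + sim$resnik_adjusted) / 2
  attr(sim, "multiplier") <- m
  sim
}

#' Combined indication-trait similarity in one call
#'
#' Convenience wrapper: all-pairs Resnik/Lin then calibration.
#' @inheritParams similarity_table
#' @inheritParams calibrate_similarity
#' @export
combined_similarity <- function(onto, terms_a, terms_b, clip = TRUE) {
  calibrate_similarity(similarity_table(onto, terms_a, terms_b), clip = clip)
}

#' Remap supplementary-concept term IDs to preferred main headings
#'
#' IDs beginning in "C" (supplementary concept records) are looked up in the
#' remap table; IDs beginning in "D" (main headings) pass through unchanged.
#' Supplementary IDs absent from the table are dropped with a warning and
#' recorded in the `"dropped"` attribute.
#'
#' @param terms character vector of term IDs.
#' @param remap data.frame with columns `supplementary`, `main`.
#' @return character vector of main-heading IDs (possibly shorter than the
#'   input), with attribute `dropped` listing unmapped supplementary IDs.
#' @export
remap_to_main_headings <- function(terms, remap) {
  stopifnot(all(c("supplementary", "main") %in% names(remap)))
  lut <- stats::setNames(as.character(remap$main), remap$supplementary)
  is_supp <- startsWith(terms, "C")
  out <- terms
  out[is_supp] <- lut[terms[is_supp]]
  dropped <- terms[is_supp & is.na(out)]
  if (length(dropped))
    warning("dropping ", length(dropped),
            " supplementary term(s) with no main-heading mapping: ",
            paste(dropped, collapse = ", "))
  res <- out[!is.na(out)]
  attr(res, "dropped") <- dropped
  res
}
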