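# Shared fixtures and independent oracles, built in code.

# 5-term toy DAG: root(cum 100) -> A(50), B(50); A -> A1(10), A2(40)
toy_dag <- function() {
  edges <- data.frame(child = c("A", "B", "A1", "A2"),
                      parent = c("root", "root", "A", "A"))
  counts <- c(root = 100, A = 50, B = 50, A1 = 10, A2 = 40)
  ontology(edges, counts, cumulative = TRUE)
}

# random DAG on n terms: term 1 is the root; each later term gets 1-2
# parents among earlier terms; every term has a positive intrinsic count
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n))
  edges <- do.call(rbind, lapply(2:n, function(i) {
    k <- sample(1:min(2, i - 1), 1)
    data.frame(child = ids[i], parent = ids[sample(i - 1, k)])
  }))
  counts <- stats::setNames(sample(1:3, n, replace = TRUE), ids)
  ontology(edges, counts)
}

# --- independent oracles (plain loops over the edge list, no igraph) -------

oracle_ancestors <- function(edges, term) {
  anc <- term
  frontier <- term
  repeat {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, anc)
    if (!length(nxt)) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  anc
}

oracle_descendants <- function(edges, term) {
  dec <- term
  frontier <- term
  repeat {
    nxt <- unique(edges$child[edges$parent %in% frontier])
    nxt <- setdiff(nxt, dec)
    if (!length(nxt)) break
    dec <- c(dec, nxt)
    frontier <- nxt
  }
  dec
}

# exhaustive IC / MICA / Lin from intrinsic counts
oracle_similarity <- function(edges, counts, a, b) {
  terms <- unique(c(edges$child, edges$parent))
  root <- setdiff(terms, edges$child)
  cum <- vapply(terms, function(t)
    sum(counts[oracle_descendants(edges, t)]), numeric(1))
  names(cum) <- terms
  ic <- -log(cum / cum[root])
  common <- intersect(oracle_ancestors(edges, a), oracle_ancestors(edges, b))
  resnik <- max(c(ic[common], 0))
  denom <- ic[[a]] + ic[[b]]
  lin <- if (denom == 0) as.numeric(a == b) else 2 * resnik / denom
  list(resnik_raw = unname(resnik), lin = unname(lin), ic = ic)
}

prank <- function(p) match(p, phase_levels)

# tiny bundle for fast end-to-end tests
small_bundle <- function(seed = 11, ...) {
  synth_bundle(synth_config(n_genes = 40, n_indications = 12, n_drugs = 150,
                            seed = seed, ...))
}
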