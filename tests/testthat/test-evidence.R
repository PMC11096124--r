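mend_record <- function(label, code = 3, gene = "G1", pid = "P1",
                        trait = "D000002") {
  data.frame(gene = gene, phenotype_label = label, mapping_code = code,
             phenotype_id = pid, gene_id = paste0("GM", gene),
             trait_term = trait, year = 2010)
}

test_that("Mendelian label rules retain and drop as specified", {
  cases <- list(
    list("Leukemia, acute myeloid, somatic", FALSE),
    list("{Colorectal cancer, susceptibility to}", TRUE),
    list("?Cataract 12", FALSE),
    list("[Blood group, Lewis]", FALSE),
    list("Warfarin response", FALSE),
    list("Diabetes, susceptibility to", FALSE),
    list("{Hypertension, essential}", FALSE),
    list("{Breast-ovarian cancer, somatic}", FALSE),  # cancer but somatic
    list("Plain Mendelian disorder", TRUE))
  for (i in seq_along(cases)) {
    rec <- mend_record(cases[[i]][[1]], pid = paste0("P", i),
                       gene = paste0("G", i))
    out <- filter_mendelian(rec)
    expect_equal(nrow(out), as.integer(cases[[i]][[2]]),
                 info = cases[[i]][[1]])
  }
})

test_that("Mendelian filter enforces mapping code, presence and dedupe", {
  recs <- rbind(
    mend_record("Disorder one", code = 2, pid = "Pa"),
    mend_record("Disorder two", code = 3, pid = "Pb"),
    mend_record("Disorder two", code = 3, pid = "Pb"),      # exact dup
    mend_record("Disorder three", code = 3, pid = NA),      # missing id
    mend_record("Disorder four", code = 3, pid = "Pd", trait = NA))
  out <- filter_mendelian(recs)
  expect_equal(nrow(out), 1L)
  log <- attr(out, "drop_log")
  expect_equal(sum(log$n), nrow(recs) - nrow(out))
})

test_that("L2G shares normalize to 1 per hit and validate inputs", {
  sc <- data.frame(hit_id = c("h1", "h1", "h1", "h2"),
                   gene = c("A", "B", "C", "A"),
                   l2g_score = c(0.6, 0.3, 0.1, 0.2))
  sh <- l2g_shares(sc)
  expect_equal(sh$l2g_share, c(0.6, 0.3, 0.1, 1.0), tolerance = 1e-12)
  even <- l2g_shares(data.frame(hit_id = "h", gene = c("A", "B"),
                                l2g_score = c(0.4, 0.4)))
  expect_equal(even$l2g_share, c(0.5, 0.5))
  expect_error(l2g_shares(data.frame(hit_id = "h", gene = "A",
                                     l2g_score = 0)), "undefined L2G share")
})

test_that("GWAS filter applies strict P and inclusive share thresholds", {
  hits <- data.frame(gene = c("A", "B", "C", "D"),
                     trait_term = "T",
                     p_value = c(4e-8, 5e-8, 1e-9, 1e-9),
                     l2g_share = c(0.9, 0.9, 0.5, 0.49),
                     lead_chrom = 1, lead_pos = 1e6, year = 2015)
  out <- filter_gwas(hits)
  expect_setequal(out$gene, c("A", "C"))     # boundary P dropped, share 0.5 kept
  expect_error(filter_gwas(hits, share_min = 1.5), "invalid config")
  # sweep monotonicity
  ns <- vapply(seq(0.1, 1, by = 0.05),
               function(s) nrow(filter_gwas(hits, share_min = s)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("colocalization filter needs all three thresholds", {
  rec <- function(p, e, h) data.frame(gene = "A", trait_term = "T",
                                      p_value = p, eqtl_p = e, h4 = h)
  expect_equal(nrow(filter_coloc(rec(5e-9, 1e-6, 0.95))), 1L)
  expect_equal(nrow(filter_coloc(rec(5e-9, 1e-6, 0.89))), 0L)
  expect_equal(nrow(filter_coloc(rec(5e-9, 1e-6, 0.9))), 1L)   # inclusive H4
  expect_equal(nrow(filter_coloc(rec(5e-8, 1e-6, 0.95))), 0L)  # strict P
  expect_equal(nrow(filter_coloc(rec(5e-9, 1e-5, 0.95))), 0L)  # strict eQTL P
})

test_that("exome filter keeps any significant model, dedupes, rejects unknowns", {
  recs <- data.frame(gene = c("A", "A", "A", "B", "C"),
                     trait_term = "T",
                     model = c("pLoF-burden", "pLoF-SKAT",
                               "missenseLC-burden", "pLoF-burden", "oddball"),
                     p_value = c(5e-7, 1e-8, 1e-6, 1e-5, 1e-9))
  out <- filter_exome(recs)
  expect_equal(nrow(out[out$gene == "A", ]), 1L)   # 3 models -> 1 association
  expect_false("B" %in% out$gene)                  # boundary 1e-5 dropped
  expect_false("C" %in% out$gene)                  # unknown model rejected
  log <- attr(out, "drop_log")
  expect_equal(log$n[log$rule == "unknown_model_label"], 1)
})

test_that("somatic roles are modal with ties flagged ambiguous", {
  recs <- data.frame(
    gene = c(rep("A", 4), "B", rep("C", 4)),
    cohort = paste0("c", 1:9),
    role = c("oncogene", "oncogene", "oncogene", "tumour_suppressor",
             "tumour_suppressor",
             "oncogene", "oncogene", "tumour_suppressor",
             "tumour_suppressor"))
  roles <- somatic_roles(recs)
  expect_equal(roles$role[roles$gene == "A"], "oncogene")
  expect_equal(roles$role[roles$gene == "B"], "tumour_suppressor")
  expect_equal(roles$role[roles$gene == "C"], "ambiguous")
})

test_that("megabase binning of lead variants counts independent loci", {
  gw <- function(pos, chrom = "1") data.frame(
    gene = "A", trait_term = "T", source = "gwas", lead_chrom = chrom,
    lead_pos = pos)
  # 1.2 Mb and 1.4 Mb both round to bin 1: one locus
  two_same <- rbind(gw(1.2e6), gw(1.4e6))
  expect_equal(gwas_locus_counts(two_same)$n_loci, 1L)
  # 0.4, 1.6, 3.4 Mb -> bins 0, 2, 3: three loci
  three <- rbind(gw(4e5), gw(1.6e6), gw(3.4e6))
  expect_equal(gwas_locus_counts(three)$n_loci, 3L)
  # same bin on different chromosomes counts separately
  cross <- rbind(gw(1.2e6, "1"), gw(1.2e6, "2"))
  expect_equal(gwas_locus_counts(cross)$n_loci, 2L)
})

test_that("genetic insight needs a similar Mendelian trait or a 3-locus GWAS trait", {
  sim <- data.frame(term_a = rep(c("I1", "I2", "I3"), each = 2),
                    term_b = rep(c("Tm", "Tg"), 3),
                    combined = c(0.85, 0.1, 0.1, 0.9, 0.3, 0.3))
  assoc <- rbind(
    data.frame(gene = "G1", trait_term = "Tm", source = "mendelian",
               lead_chrom = NA, lead_pos = NA),
    data.frame(gene = paste0("G", 2:4), trait_term = "Tg", source = "gwas",
               lead_chrom = "1", lead_pos = c(4e5, 1.6e6, 3.4e6)))
  fl <- genetic_insight(c("I1", "I2", "I3"), assoc, sim)
  expect_true(fl$insight[fl$indication_term == "I1"])   # Mendelian clause
  expect_true(fl$insight[fl$indication_term == "I2"])   # 3-locus GWAS clause
  expect_false(fl$insight[fl$indication_term == "I3"])  # nothing similar
  # two leads in the same megabase bin are one locus: clause fails
  assoc2 <- assoc[assoc$source == "gwas", ][1:2, ]
  assoc2$lead_pos <- c(1.2e6, 1.4e6)
  fl2 <- genetic_insight("I2", assoc2, sim)
  expect_false(fl2$insight)
  expect_error(genetic_insight("missing", assoc, sim), "missing similarity")
})

test_that("drop-log counters sum to input minus output for every filter", {
  b <- small_bundle(seed = 5)
  for (s in c("mendelian", "gwas", "coloc", "exome")) {
    raw <- b$raw[[s]]
    out <- switch(s,
                  mendelian = filter_mendelian(raw),
                  gwas = filter_gwas(l2g_shares(raw)),
                  coloc = filter_coloc(raw),
                  exome = filter_exome(raw))
    log <- attr(out, "drop_log")
    expect_equal(sum(log$n), nrow(raw) - nrow(out), info = s)
  }
})
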