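test_that("top-variant selection ranks by contribution with stable ties", {
  m <- matrix(c(0.4, 0.3, 0.1, 0.1, 0.1), 5, 1,
              dimnames = list(c("v5", "v1", "v2", "v3", "v4"), "PC1"))
  tab <- degas:::new_score_table(m, "variant", "contribution")
  sel <- select_top_variants(tab, 1, 3)
  expect_equal(sel$variant_id, c("v5", "v1", "v2"))

  flat <- degas:::new_score_table(
    matrix(0.2, 5, 1, dimnames = list(paste0("v", 5:1), "PC1")),
    "variant", "contribution")
  expect_equal(select_top_variants(flat, 1, 2)$variant_id, c("v1", "v2"))
})

test_that("variant BED export is 0-based half-open single-base", {
  vars <- make_variants(make_variant("v1", chrom = "3", pos = 101L))
  sel <- data.table::data.table(variant_id = "v1", score = 0.5)
  bed <- variant_bed(sel, vars)
  expect_equal(bed$start, 100L)
  expect_equal(bed$end, 101L)
  expect_error(variant_bed(data.table::data.table(variant_id = "vX",
                                                  score = 1), vars),
               "missing from the annotation")
})

test_that("regulatory domains follow the basal-plus-extension rule", {
  # lone gene: basal [tss-5000, tss+1000), extended 1 Mb both ways
  tss <- data.frame(gene = "G1", chrom = "1", tss = 2e6, strand = "+")
  dom <- build_regulatory_domains(tss, chrom_sizes = c("1" = 1e7))
  expect_equal(dom$start, 1e6)
  expect_equal(dom$end, 3e6)

  # two adjacent genes: extensions stop at the neighbor's basal edge
  tss2 <- data.frame(gene = c("A", "B"), chrom = "1",
                     tss = c(2e6, 2.5e6), strand = "+")
  dom2 <- build_regulatory_domains(tss2, chrom_sizes = c("1" = 1e7))
  # A basal [1995000, 2001000); B basal [2495000, 2501000)
  expect_equal(dom2[dom2$gene == "A", ]$end, 2495000)   # stops at B's basal start
  expect_equal(dom2[dom2$gene == "B", ]$start, 2001000) # stops at A's basal end
  expect_equal(dom2[dom2$gene == "A", ]$start, 1e6)
  expect_equal(dom2[dom2$gene == "B", ]$end, 3.5e6)

  # minus strand flips the basal window
  tss3 <- data.frame(gene = "M", chrom = "1", tss = 2e6, strand = "-")
  basal_only <- build_regulatory_domains(tss3, extension = 0,
                                         chrom_sizes = c("1" = 1e7))
  expect_equal(basal_only$start, 2e6 - 1000)
  expect_equal(basal_only$end, 2e6 + 5000)

  # clipping at the chromosome start
  tss4 <- data.frame(gene = "E", chrom = "1", tss = 3000, strand = "+")
  dom4 <- build_regulatory_domains(tss4, chrom_sizes = c("1" = 1e7))
  expect_equal(dom4$start, 0)

  dup <- data.frame(gene = c("X", "X"), chrom = "1", tss = c(1e6, 2e6),
                    strand = "+")
  expect_error(build_regulatory_domains(dup), "duplicate gene")
})

test_that("binomial enrichment matches the exact tail sum and edge cases", {
  genome <- 1000
  # one gene whose domain covers [0, 100): pi = 0.1
  domains <- data.table::data.table(gene = "G", chrom = "1",
                                    start = 0, end = 100)
  # 10 single-base regions, 5 inside the domain
  pos <- c(10, 20, 30, 40, 50, 500, 600, 700, 800, 900)
  regions <- data.table::data.table(chrom = "1", start = pos, end = pos + 1)
  terms <- data.table::data.table(term_id = "T", gene = "G")
  res <- binomial_region_enrichment(regions, domains, terms, genome)
  expect_equal(res$n_hits, 5L)
  expect_equal(res$fold, 5 / (10 * 0.1))
  expect_equal(res$p_value, exact_binomial_tail(5, 10, 0.1),
               tolerance = 1e-14)

  # term covering the whole genome: fold 1, p 1
  whole <- data.table::data.table(gene = "W", chrom = "1",
                                  start = 0, end = genome)
  res_w <- binomial_region_enrichment(
    regions, whole, data.table::data.table(term_id = "TW", gene = "W"), genome)
  expect_equal(res_w$fold, 1)
  expect_equal(res_w$p_value, 1)

  # no hits: fold 0, p 1
  far <- data.table::data.table(chrom = "1", start = 990, end = 991)
  res_0 <- binomial_region_enrichment(far, domains, terms, genome)
  expect_equal(res_0$fold, 0)
  expect_equal(res_0$p_value, 1)

  # term whose gene has no domain: zero coverage, no hits
  res_na <- binomial_region_enrichment(
    regions, domains, data.table::data.table(term_id = "TX", gene = "NOPE"),
    genome)
  expect_equal(res_na$n_hits, 0L)
  expect_equal(res_na$fold, 0)
})

test_that("domain union coverage is order-invariant and bounded by the genome", {
  set.seed(31)
  doms <- data.table::data.table(
    gene = paste0("g", 1:8), chrom = "1",
    start = sample(0:900, 8), end = 0)
  doms$end <- doms$start + sample(50:400, 8, replace = TRUE)
  doms$end <- pmin(doms$end, 1000)
  terms <- data.table::data.table(term_id = "T", gene = doms$gene)
  regions <- data.table::data.table(chrom = "1", start = 0, end = 1)
  a <- binomial_region_enrichment(regions, doms, terms, 1000)
  b <- binomial_region_enrichment(regions, doms[sample(8)], terms, 1000)
  expect_equal(a$coverage_bp, b$coverage_bp)
  expect_lte(a$coverage_bp, 1000)
})

test_that("significance filters separate table and plot modes", {
  res <- data.table::data.table(
    component = 1L,
    term_id = c("a", "b", "c"),
    n_hits = 1L, n_regions = 1L, coverage_bp = 1,
    fold = c(1.5, 1.0, 3.0),
    p_value = c(1e-6, 1e-5, 1e-8)
  )
  tab <- filter_significant(res, "table")
  expect_setequal(tab$term_id, c("a", "c"))
  plot <- filter_significant(res, "plot")
  expect_equal(plot$term_id, "c")
})

test_that("Jaccard similarity satisfies the set identities", {
  terms <- data.table::data.table(
    term_id = c("t1", "t1", "t1", "t2", "t2", "t2", "t3", "t4"),
    gene = c("a", "b", "c", "b", "c", "d", "x", "y")
  )
  expect_equal(jaccard_similarity("t1", "t1", terms), 1)
  expect_equal(jaccard_similarity("t1", "t2", terms), 0.5)
  expect_equal(jaccard_similarity("t1", "t2", terms),
               jaccard_similarity("t2", "t1", terms))
  expect_equal(jaccard_similarity("t3", "t4", terms), 0)
  expect_error(jaccard_similarity("t1", "zz", terms), "unresolvable")
  empty <- data.table::data.table(term_id = c("e1", "e2"),
                                  gene = c(NA, NA))[0]
  expect_warning(
    val <- jaccard_similarity(character(), character(), terms), "empty")
  expect_equal(val, 0)
})

test_that("specificity profile reports the median pairwise similarity", {
  terms <- data.table::data.table(
    term_id = c(rep("tA", 4), rep("tB", 4), rep("tC", 3)),
    gene = c("g1", "g2", "g3", "g4",
             "g1", "g2", "g5", "g7",
             "g1", "g2", "g5")
  )
  # hand-computed: J(A,B) = 2/6, J(A,C) = 2/5, J(B,C) = 3/4 -> median 0.4
  results <- data.table::data.table(
    component = 1:3, term_id = c("tA", "tB", "tC"),
    n_hits = 1L, n_regions = 1L, coverage_bp = 1, fold = 5, p_value = 1e-9
  )
  prof <- component_specificity_profile(results, terms)
  expect_equal(prof[prof$k == 3, ]$median_jaccard, 0.4)
  expect_equal(prof[prof$k == 2, ]$median_jaccard, 1 / 3)

  # identical components -> similarity 1
  res2 <- data.table::data.table(
    component = 1:2, term_id = "tA",
    n_hits = 1L, n_regions = 1L, coverage_bp = 1, fold = 5, p_value = 1e-9)
  expect_equal(component_specificity_profile(res2, terms)$median_jaccard, 1)

  # components with disjoint gene sets -> similarity 0
  res3 <- data.table::data.table(
    component = 1:2, term_id = c("t3", "t4"),
    n_hits = 1L, n_regions = 1L, coverage_bp = 1, fold = 5, p_value = 1e-9)
  terms2 <- data.table::data.table(term_id = c("t3", "t4"), gene = c("x", "y"))
  expect_equal(component_specificity_profile(res3, terms2)$median_jaccard, 0)

  # components without any enriched term are skipped with a message
  expect_message(
    prof4 <- component_specificity_profile(results, terms, components = 1:4),
    "skipping")
  expect_equal(max(prof4$k), 3L)
})
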