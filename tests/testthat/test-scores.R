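# orthonormal 2-column test factors
u_fix <- cbind(c(0.6, 0.8, 0), c(0.8, -0.6, 0))
v_fix <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))

test_that("factor scores are U S and V S with column norms equal to S", {
  d <- manual_decomposition(u_fix, c(10, 2), v_fix)
  f <- factor_scores(d)
  expect_equal(unname(f$phenotype), unname(u_fix %*% diag(c(10, 2))))
  expect_equal(sqrt(colSums(f$phenotype^2)), c(10, 2), tolerance = 1e-8)
  expect_equal(sqrt(colSums(f$variant^2)), c(10, 2), tolerance = 1e-8)

  # factor scores equal projections of the data onto the singular axes
  set.seed(4)
  w <- matrix(rnorm(6 * 10), 6, 10)
  dd <- truncated_svd(w, 6)
  ff <- factor_scores(dd)
  expect_equal(unname(ff$phenotype), unname(w %*% dd$V), tolerance = 1e-8)
})

test_that("contribution scores are squared singular vectors summing to one", {
  d <- manual_decomposition(u_fix, c(10, 2), v_fix)
  pc <- contribution_scores(d, "phenotype")
  expect_equal(unname(unclass(pc)[, 1]), c(0.36, 0.64, 0))
  expect_equal(colSums(unclass(pc)), c(PC1 = 1, PC2 = 1))
  vc <- contribution_scores(d, "variant")
  expect_equal(unname(unclass(vc)[, 1]), c(1, 0, 0, 0))
  # sign flips leave contributions unchanged
  d_flip <- manual_decomposition(-u_fix, c(10, 2), -v_fix)
  expect_equal(unclass(contribution_scores(d_flip, "phenotype")),
               unclass(pc), ignore_attr = TRUE)
})

test_that("gene groups partition variants by exact annotation set", {
  vars <- make_variants(
    make_variant("v1", consequence = "coding_nonptv", genes = "GENE_A"),
    make_variant("v2", consequence = "coding_nonptv", genes = "GENE_A"),
    make_variant("v3", consequence = "coding_nonptv", genes = "GENE_B,GENE_A"),
    make_variant("v4", consequence = "noncoding", genes = "")
  )
  g <- build_gene_groups(vars)
  expect_equal(g$group_key[g$variant_id %in% c("v1", "v2")],
               c("GENE_A", "GENE_A"))
  expect_equal(g$group_key[g$variant_id == "v3"], "GENE_A,GENE_B")
  expect_equal(g$group_key[g$variant_id == "v4"], "v4")
})

test_that("gene contributions add variant scores and conserve mass", {
  # v1,v2 in GENE_A with contributions 0.1 and 0.2 in component 1
  v <- cbind(c(sqrt(0.1), sqrt(0.2), sqrt(0.3), sqrt(0.4)))
  u <- cbind(c(1, 0, 0, 0))
  d <- manual_decomposition(u, 5, v)
  rownames(d$V) <- c("v1", "v2", "v3", "v4")
  vars <- make_variants(
    make_variant("v1", genes = "GENE_A", consequence = "coding_nonptv"),
    make_variant("v2", genes = "GENE_A", consequence = "coding_nonptv"),
    make_variant("v3", genes = "GENE_B", consequence = "coding_nonptv"),
    make_variant("v4", genes = "", consequence = "noncoding")
  )
  groups <- build_gene_groups(vars)
  gc <- gene_contribution(d, groups)
  expect_equal(unclass(gc)["GENE_A", 1], 0.3, tolerance = 1e-12)
  expect_equal(unclass(gc)["v4", 1], 0.4, tolerance = 1e-12)
  expect_equal(sum(unclass(gc)[, 1]), 1, tolerance = 1e-12)

  bad <- groups[-1]
  expect_error(gene_contribution(d, bad), "partition")
})

test_that("squared cosine rows normalize factor scores across components", {
  u <- diag(2)
  d <- manual_decomposition(u, c(3, 4), diag(2))
  # entity with factor scores (3, 4) across two components
  f <- structure(list(phenotype = matrix(c(3, 0, 4, 0), 2, 2,
                                         dimnames = list(c("e1", "e2"), NULL)),
                      variant = matrix(c(3, 0, 4, 0), 2, 2,
                                       dimnames = list(c("x1", "x2"), NULL))),
                 class = "degas_factor_scores")
  cs <- squared_cosine(f, "phenotype")
  expect_equal(unname(unclass(cs)["e1", ]), c(9, 16) / 25)
  expect_equal(rowSums(unclass(cs)), c(e1 = 1))
  expect_equal(attr(cs, "dropped"), "e2")

  # one-hot loading
  f1 <- structure(list(phenotype = matrix(c(0, 5), 1, 2,
                                          dimnames = list("solo", NULL))),
                  class = "degas_factor_scores")
  expect_equal(unname(unclass(squared_cosine(f1, "phenotype"))[1, ]), c(0, 1))
})

test_that("driver rankings are deterministic with lexicographic ties", {
  m <- matrix(c(0.5, 0.3, 0.2), 3, 1,
              dimnames = list(c("b", "a", "c"), "PC1"))
  tab <- degas:::new_score_table(m, "phenotype", "contribution")
  top <- top_drivers(tab, 1, 2)
  expect_equal(top$entity, c("b", "a"))
  expect_equal(top$score, c(0.5, 0.3))

  tied <- degas:::new_score_table(
    matrix(c(0.25, 0.25, 0.5), 3, 1,
           dimnames = list(c("zeta", "alpha", "mid"), "PC1")),
    "phenotype", "contribution")
  expect_equal(top_drivers(tied, 1, 3)$entity, c("mid", "alpha", "zeta"))
  expect_equal(nrow(top_drivers(tied, 1, 99)), 3L)
})

test_that("key components rank squared cosines with cumulative shares", {
  row <- c(0.47, 0.18, 0.04, 0.31)
  m <- matrix(row, 1, 4, dimnames = list("bmi", paste0("PC", 1:4)))
  tab <- degas:::new_score_table(m, "phenotype", "squared_cosine")
  kc <- key_components(tab, "bmi", 3)
  expect_equal(kc$component, c(1, 4, 2))
  expect_equal(kc$cumulative[3], 0.47 + 0.31 + 0.18)
  full <- key_components(tab, "bmi", 4)
  expect_equal(full$cumulative[4], 1)
  expect_error(key_components(tab, "nope", 3), "unknown entity")
})

test_that("group aggregation preserves column mass", {
  m <- matrix(c(0.3, 0.25, 0.45), 3, 1,
              dimnames = list(c("p1", "p2", "p3"), "PC1"))
  tab <- degas:::new_score_table(m, "phenotype", "contribution")
  g <- group_contribution(tab, c(p1 = "fat", p2 = "fat"))
  expect_equal(unclass(g)["fat", 1], 0.55)
  expect_equal(unclass(g)["other", 1], 0.45)
  expect_equal(sum(unclass(g)[, 1]), 1)

  all_one <- group_contribution(tab, c(p1 = "g", p2 = "g", p3 = "g"))
  expect_equal(unname(unclass(all_one)[, 1]), 1)
})

test_that("stacked bars collapse segments below the display threshold", {
  m <- matrix(c(0.6, 0.396, 0.004), 3, 1,
              dimnames = list(c("big", "mid", "tiny"), "PC1"))
  tab <- degas:::new_score_table(m, "phenotype", "contribution")
  bars <- stacked_bar_frame(tab, threshold = 0.005)
  expect_setequal(bars$entity, c("big", "mid", "others"))
  expect_equal(bars$score[bars$entity == "others"], 0.004)
  expect_equal(sum(bars$score), 1)
})

test_that("biplot inner products encode projected association sign", {
  u <- cbind(c(1, 0), c(0, 1))
  v <- cbind(c(0.6, -0.6, 0), c(0.8, -0.8, 0))
  # make V orthonormal-ish for the fixture: columns normalized
  v <- sweep(v, 2, sqrt(colSums(v^2)), `/`)
  d <- manual_decomposition(u, c(2, 1), v)
  rownames(d$U) <- c("pheA", "pheB")
  rownames(d$V) <- c("varPos", "varNeg", "varZero")
  bp <- biplot_frame(d, selected_phenotypes = "pheA", cx = 1, cy = 2)
  arrow <- bp[bp$kind == "arrow" & bp$id == "pheA", c("x", "y")]
  vpos <- bp[bp$kind == "variant_point" & bp$id == "varPos", c("x", "y")]
  vneg <- bp[bp$kind == "variant_point" & bp$id == "varNeg", c("x", "y")]
  vzero <- bp[bp$kind == "variant_point" & bp$id == "varZero", c("x", "y")]
  ip <- function(a, b) sum(unlist(a) * unlist(b))
  expect_gt(ip(vpos, arrow), 0)
  expect_lt(ip(vneg, arrow), 0)
  expect_equal(ip(vzero, arrow), 0)
  expect_error(biplot_frame(d, cx = 1, cy = 1), "distinct")
})

test_that("squared cosine and contribution scores need not invert each other", {
  # phenotype p1's top component is PC1, yet PC1's top driver is p2
  u <- cbind(c(0.6, 0.8), c(0.8, -0.6))
  d <- manual_decomposition(u, c(10, 1), diag(2))
  rownames(d$U) <- c("p1", "p2")
  cs <- squared_cosine(factor_scores(d), "phenotype")
  expect_equal(key_components(cs, "p1", 1)$component, 1)
  top <- top_drivers(contribution_scores(d, "phenotype"), 1, 1)
  expect_equal(top$entity, "p2")
})
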