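# Shared fixture builders. Everything is generated in code; no data files.

# minimal association record table
make_records <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(
      phenotype_id = r[["phenotype_id"]],
      variant_id = r[["variant_id"]],
      estimate = as.numeric(r[["estimate"]]),
      se = as.numeric(r[["se"]]),
      p_value = as.numeric(r[["p_value"]]),
      kind = if (is.null(r[["kind"]])) "quantitative" else r[["kind"]]
    )
  }))
}

# variant annotation row with passing QC defaults, overridable
make_variant <- function(variant_id, chrom = "7", pos = 1000000L,
                         consequence = "noncoding", genes = "",
                         maf = 0.1, missingness = 0.001, hwe_p = 0.5,
                         ld_pruned_in = TRUE) {
  data.table::data.table(
    variant_id = variant_id, chrom = chrom, pos = as.integer(pos),
    consequence = consequence, genes = genes, maf = maf,
    missingness = missingness, hwe_p = hwe_p, ld_pruned_in = ld_pruned_in
  )
}

make_variants <- function(...) data.table::rbindlist(list(...))

# a hand-built decomposition object (bypasses truncated_svd) for score tests
manual_decomposition <- function(U, S, V, total_variance = sum(S^2)) {
  if (is.null(rownames(U))) rownames(U) <- sprintf("phe%02d", seq_len(nrow(U)))
  if (is.null(rownames(V))) rownames(V) <- sprintf("var%02d", seq_len(nrow(V)))
  colnames(U) <- colnames(V) <- paste0("PC", seq_along(S))
  structure(list(U = U, S = S, V = V, K = length(S),
                 total_variance = total_variance),
            class = "degas_decomposition")
}

# write a PLINK2-style association table and return its path
write_assoc_table <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# independent spectral-norm oracle: power iteration on t(W) %*% W
power_iteration_norm <- function(w, iters = 500) {
  set.seed(42)
  v <- rnorm(ncol(w))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    v <- crossprod(w, w %*% v)
    v <- v / sqrt(sum(v^2))
  }
  sqrt(sum((w %*% v)^2))
}

# exact binomial upper-tail oracle via log-space term summation
exact_binomial_tail <- function(hits, n, p) {
  if (hits <= 0) return(1)
  x <- hits:n
  sum(exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)))
}

# genes hosting the most of the selected variants, for planting ontology terms
top_host_genes <- function(selected, variants, n_genes = 3L) {
  idx <- match(selected$variant_id, variants$variant_id)
  genes <- unlist(strsplit(variants$genes[idx], ",", fixed = TRUE))
  genes <- genes[nzchar(genes)]
  counts <- sort(table(genes), decreasing = TRUE)
  head(names(counts), n_genes)
}
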