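#' Chromosome sizes used by the synthetic genome
#'
#' A simplified autosomal karyotype: chromosomes "1".."22", each 250 Mb.
#' All synthetic positions, TSS coordinates, and enrichment genome sizes
#' refer to this coordinate system.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
synthetic_chrom_sizes <- function() {
  setNames(rep(2.5e8, 22L), as.character(1:22))
}

random_orthonormal <- function(n, k) {
  if (k == 0L) return(matrix(numeric(0), n, 0L))
  qr.Q(qr(matrix(rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

#' Simulate association tables with planted low-rank latent structure
#'
#' Draws orthonormal factors `U0` (phenotypes x k0) and `V0`
#' (variants x k0), plants the signal `W0 = U0 diag(S0) t(V0)` with
#' `S0 = s_profile * sqrt(n_variants)`, and adds i.i.d. Gaussian noise of
#' standard deviation `noise_sd` to every Z-score. Scaling the singular
#' values by `sqrt(n_variants)` keeps each component's per-entry Z-score
#' magnitude (and hence the signal-to-noise ratio against per-entry noise)
#' independent of the variant count. Z-scores are then converted back to
#' association records: the standard error is drawn uniformly below the
#' value-filter cap for the phenotype's kind, the estimate is `z * se`, and
#' the p-value is the two-sided normal tail of `z`. A random
#' `(1 - sparsity)` fraction of entries is masked to emulate the
#' significance-based selection of associations.
#'
#' @param n_phenotypes,n_variants Matrix dimensions.
#' @param k0 Planted rank (0 for pure noise).
#' @param s_profile Decreasing positive vector of length `k0`: planted
#'   singular values in units of `sqrt(n_variants)`.
#' @param noise_sd Standard deviation of the additive Z-score noise.
#' @param sparsity Fraction of entries emitted as records, in `(0, 1]`.
#' @param binary_fraction Fraction of phenotypes labelled binary.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return A list with `associations` (record `data.table` with `kind`),
#'   `phenotypes` (metadata table), and `truth` (a `degas_truth` with
#'   `U_true`, `S_true`, `V_true`, `noise_sd`, `sparsity`, `seed`).
#' @export
simulate_latent_model <- function(n_phenotypes = 200L, n_variants = 500L,
                                  k0 = 3L, s_profile = c(10, 5, 1),
                                  noise_sd = 0.1, sparsity = 1,
                                  binary_fraction = 0.5, seed = 1L) {
  if (k0 > min(n_phenotypes, n_variants)) {
    stop("k0 must not exceed min(n_phenotypes, n_variants)", call. = FALSE)
  }
  if (length(s_profile) != k0) {
    stop("s_profile must have length k0", call. = FALSE)
  }
  if (k0 > 0 && (any(s_profile <= 0) || is.unsorted(rev(s_profile)))) {
    stop("s_profile must be positive and nonincreasing", call. = FALSE)
  }
  if (sparsity <= 0 || sparsity > 1) {
    stop("sparsity must be in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  phenotype_ids <- sprintf("phe%04d", seq_len(n_phenotypes))
  variant_ids <- sprintf("var%05d", seq_len(n_variants))
  u0 <- random_orthonormal(n_phenotypes, k0)
  v0 <- random_orthonormal(n_variants, k0)
  s0 <- s_profile * sqrt(n_variants)
  w <- matrix(rnorm(n_phenotypes * n_variants, sd = noise_sd),
              n_phenotypes, n_variants)
  if (k0 > 0) w <- w + u0 %*% diag(s0, k0) %*% t(v0)

  kind <- sample(c("binary", "quantitative"), n_phenotypes, replace = TRUE,
                 prob = c(binary_fraction, 1 - binary_fraction))
  keep <- matrix(runif(n_phenotypes * n_variants) <= sparsity,
                 n_phenotypes, n_variants)
  idx <- which(keep, arr.ind = TRUE)
  z <- w[idx]
  se_cap <- ifelse(kind[idx[, 1L]] == "quantitative", 0.08, 0.2)
  se <- runif(nrow(idx), 0.01, se_cap - 1e-6)
  associations <- data.table(
    phenotype_id = phenotype_ids[idx[, 1L]],
    variant_id = variant_ids[idx[, 2L]],
    estimate = z * se,
    se = se,
    p_value = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
    kind = kind[idx[, 1L]]
  )
  associations <- associations[order(phenotype_id, variant_id)]
  phenotypes <- data.table(
    phenotype_id = phenotype_ids,
    kind = kind,
    n_effective = sample(500:50000, n_phenotypes, replace = TRUE),
    group = sprintf("group%02d", sample(1:8, n_phenotypes, replace = TRUE))
  )
  rownames(u0) <- phenotype_ids
  rownames(v0) <- variant_ids
  truth <- structure(
    list(U_true = u0, S_true = s0, V_true = v0, k0 = as.integer(k0),
         noise_sd = noise_sd, sparsity = sparsity, seed = as.integer(seed),
         phenotype_ids = phenotype_ids, variant_ids = variant_ids),
    class = "degas_truth"
  )
  list(associations = associations, phenotypes = phenotypes, truth = truth)
}

#' Simulate variant annotations, QC fields, and a gene TSS table
#'
#' Plants disjoint blocks of variants that each violate exactly one QC rule
#' (MHC position, missingness, MAF, Hardy-Weinberg, LD-prune flag) so that
#' every filter's removal count is known exactly, then assigns consequence
#' classes (PTV / other coding / non-coding) and gene annotations. Coding
#' variants are placed within 500 bp of their host gene's TSS so that
#' region enrichment over regulatory domains can recover planted gene sets;
#' non-coding variants are placed uniformly. A `shared_gene_fraction` of
#' coding variants is annotated to two adjacent genes to exercise
#' intersection gene groups.
#'
#' @param n_variants Number of variants (must match the latent model).
#' @param gene_count Number of genes in the TSS table.
#' @param ptv_fraction,coding_fraction Fractions of variants that are PTVs
#'   and non-PTV coding, respectively.
#' @param shared_gene_fraction Fraction of coding variants annotated to two
#'   genes.
#' @param mhc_fraction Fraction of variants planted inside the MHC window.
#' @param qc_fail_fraction Fraction planted to fail each of the four
#'   non-positional QC rules (missingness, MAF, HWE, LD flag).
#' @param seed Integer seed.
#' @return A list with `variants` (annotation table), `tss` (gene TSS
#'   table), and `counts` (planted counts per class, the truth sidecar for
#'   filter tests).
#' @export
simulate_annotations <- function(n_variants = 500L, gene_count = 40L,
                                 ptv_fraction = 0.1, coding_fraction = 0.2,
                                 shared_gene_fraction = 0.1,
                                 mhc_fraction = 0.05,
                                 qc_fail_fraction = 0.02, seed = 1L) {
  fr <- c(mhc_fraction, rep(qc_fail_fraction, 4L))
  if (any(fr < 0) || sum(fr) > 1) {
    stop("planted failure fractions must be nonnegative and sum to <= 1",
         call. = FALSE)
  }
  if (ptv_fraction < 0 || coding_fraction < 0 ||
      ptv_fraction + coding_fraction > 1) {
    stop("consequence fractions must be nonnegative with sum <= 1",
         call. = FALSE)
  }
  set.seed(seed + 1L)
  sizes <- synthetic_chrom_sizes()
  variant_ids <- sprintf("var%05d", seq_len(n_variants))
  mhc <- mhc_region()

  # genes live away from chromosome 6 so regulatory domains never touch the
  # MHC exclusion window
  gene_ids <- sprintf("GENE%03d", seq_len(gene_count))
  gene_chrom <- sample(setdiff(names(sizes), "6"), gene_count, replace = TRUE)
  gene_tss <- round(runif(gene_count, 5e6, 2.4e8))
  gene_strand <- sample(c("+", "-"), gene_count, replace = TRUE)
  tss <- data.table(gene = gene_ids, chrom = gene_chrom, tss = gene_tss,
                    strand = gene_strand)

  n_mhc <- round(mhc_fraction * n_variants)
  n_fail <- rep(round(qc_fail_fraction * n_variants), 4L)
  fail_labels <- c("missingness", "maf", "hwe", "ld")
  block <- rep("pass", n_variants)
  pos0 <- 1L
  take <- function(n) {
    idx <- seq.int(pos0, length.out = n)
    pos0 <<- pos0 + n
    idx
  }
  mhc_idx <- take(n_mhc)
  fail_idx <- lapply(n_fail, take)
  block[mhc_idx] <- "mhc"
  for (i in seq_along(fail_labels)) block[fail_idx[[i]]] <- fail_labels[[i]]

  n_ptv <- round(ptv_fraction * n_variants)
  n_coding <- round(coding_fraction * n_variants)
  consequence <- rep("noncoding", n_variants)
  # consequence classes are assigned independently of the QC blocks, cycling
  # from the start so every filter branch sees every class
  consequence[seq_len(min(n_ptv, n_variants))] <- "ptv"
  if (n_coding > 0 && n_ptv < n_variants) {
    consequence[seq.int(n_ptv + 1L, min(n_ptv + n_coding, n_variants))] <-
      "coding_nonptv"
  }

  coding <- consequence != "noncoding"
  host <- rep(NA_integer_, n_variants)
  host[coding] <- sample(gene_count, sum(coding), replace = TRUE)
  genes <- rep("", n_variants)
  chrom <- character(n_variants)
  pos <- integer(n_variants)
  shared <- coding & runif(n_variants) < shared_gene_fraction
  for (i in which(coding)) {
    g <- host[[i]]
    if (shared[[i]]) {
      g2 <- if (g == gene_count) g - 1L else g + 1L
      genes[[i]] <- paste(sort(c(gene_ids[g], gene_ids[g2])), collapse = ",")
    } else {
      genes[[i]] <- gene_ids[g]
    }
    chrom[[i]] <- gene_chrom[[g]]
    pos[[i]] <- as.integer(gene_tss[[g]] + sample(-500:500, 1L))
  }
  nc <- which(!coding)
  chrom[nc] <- sample(setdiff(names(sizes), "6"), length(nc), replace = TRUE)
  pos[nc] <- as.integer(round(runif(length(nc), 1e6, 2.4e8)))
  # planted MHC block overrides position regardless of consequence
  chrom[mhc_idx] <- "6"
  pos[mhc_idx] <- as.integer(round(runif(n_mhc, mhc$start, mhc$end)))

  maf <- runif(n_variants, 0.01, 0.5)
  missingness <- runif(n_variants, 0, 0.009)
  hwe_p <- runif(n_variants, 0.001, 1)
  ld_pruned_in <- rep(TRUE, n_variants)
  missingness[fail_idx[[1L]]] <- runif(n_fail[[1L]], 0.011, 0.05)
  maf[fail_idx[[2L]]] <- runif(n_fail[[2L]], 1e-6, 9e-5)
  hwe_p[fail_idx[[3L]]] <- runif(n_fail[[3L]], 1e-12, 9e-8)
  ld_pruned_in[fail_idx[[4L]]] <- FALSE

  variants <- data.table(
    variant_id = variant_ids, chrom = chrom, pos = pos,
    consequence = consequence, genes = genes, maf = maf,
    missingness = missingness, hwe_p = hwe_p, ld_pruned_in = ld_pruned_in
  )
  counts <- list(
    mhc = n_mhc,
    missingness = n_fail[[1L]], maf = n_fail[[2L]], hwe = n_fail[[3L]],
    ld = n_fail[[4L]],
    ptv = n_ptv, coding_nonptv = n_coding,
    noncoding = n_variants - n_ptv - n_coding,
    shared_gene = sum(shared)
  )
  list(variants = variants, tss = tss, counts = counts)
}

#' Simulate a flat gene-ontology annotation table
#'
#' Background terms receive random gene sets. Optionally one planted term
#' receives a gene set drawn (at the given concentration) from a supplied
#' list of genes - typically the genes hosting the top-contributing
#' variants of a component - so that enrichment recovery can be tested.
#' When a term is planted, background terms sample from the non-planted gene
#' pool: the planted signal is then identifiable, rather than leaking into
#' background terms that would otherwise pick up the same genes by chance.
#'
#' @param genes Character vector of all gene symbols.
#' @param n_terms Number of background terms.
#' @param genes_per_term Genes per background term.
#' @param planted_genes Optional genes for the planted term.
#' @param concentration Fraction of the planted term's genes taken from
#'   `planted_genes` (the rest are random background genes).
#' @param planted_term_id Identifier of the planted term.
#' @param seed Integer seed.
#' @return A `data.table` with columns `term_id`, `gene`.
#' @export
simulate_ontology <- function(genes, n_terms = 30L, genes_per_term = 4L,
                              planted_genes = NULL, concentration = 1,
                              planted_term_id = "TERM_PLANTED", seed = 1L) {
  set.seed(seed + 2L)
  background_pool <- setdiff(genes, planted_genes)
  if (length(background_pool) < genes_per_term) background_pool <- genes
  out <- lapply(seq_len(n_terms), function(t) {
    data.table(term_id = sprintf("TERM%03d", t),
               gene = sample(background_pool,
                             min(genes_per_term, length(background_pool))))
  })
  if (!is.null(planted_genes)) {
    missing <- setdiff(planted_genes, genes)
    if (length(missing)) {
      stop("planted gene(s) not in the gene universe: ",
           paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
    }
    n_keep <- round(concentration * length(planted_genes))
    chosen <- if (n_keep > 0) sample(planted_genes, n_keep) else character()
    n_fill <- length(planted_genes) - n_keep
    fill <- if (n_fill > 0) {
      sample(background_pool, min(n_fill, length(background_pool)))
    } else character()
    out <- c(out, list(data.table(term_id = planted_term_id,
                                  gene = c(chosen, fill))))
  }
  res <- data.table::rbindlist(out)
  unique(res)[order(term_id, gene)]
}

#' Match recovered components to planted components
#'
#' Greedily pairs each recovered variant singular vector, in component
#' order, with the unmatched planted component of largest absolute cosine,
#' and reports the per-pair |cosine|. Values near 1 mean the planted
#' subspace directions were recovered.
#'
#' @param d A `degas_decomposition` on the same variant axis as `truth`.
#' @param truth A `degas_truth` from [simulate_latent_model()].
#' @return A `data.table` with columns `component`, `matched_component`,
#'   `cosine`; the mean |cosine| is attached as attribute `mean_cosine`.
#' @export
recovery_score <- function(d, truth) {
  stopifnot(inherits(d, "degas_decomposition"), inherits(truth, "degas_truth"))
  if (!identical(rownames(d$V), truth$variant_ids)) {
    stop("decomposition and truth do not share the variant axis", call. = FALSE)
  }
  k0 <- truth$k0
  if (k0 == 0L) {
    out <- data.table(component = integer(), matched_component = integer(),
                      cosine = numeric())
    attr(out, "mean_cosine") <- NA_real_
    return(out)
  }
  k <- min(d$K, k0)
  cmat <- abs(crossprod(d$V[, seq_len(k), drop = FALSE], truth$V_true))
  used <- rep(FALSE, k0)
  comp <- integer(k); match_to <- integer(k); cosv <- numeric(k)
  for (i in seq_len(k)) {
    row <- cmat[i, ]
    row[used] <- -Inf
    j <- which.max(row)
    comp[i] <- i; match_to[i] <- j; cosv[i] <- cmat[i, j]
    used[j] <- TRUE
  }
  out <- data.table(component = comp, matched_component = match_to,
                    cosine = cosv)
  attr(out, "mean_cosine") <- mean(cosv)
  out
}

#' Write a synthetic dataset in the ingestion formats
#'
#' Emits one per-phenotype association table under `sumstats/` (PLINK2
#' `.glm`-style columns `ID`, `CHROM`, `POS`, `BETA` or `OR`, `SE`, `P`),
#' plus `variants.tsv`, `phenotypes.tsv`, `tss.tsv`, and a `truth.json`
#' sidecar with the planted factors.
#'
#' @param sim Output of [simulate_latent_model()].
#' @param annotations Output of [simulate_annotations()] on the same
#'   variants.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, annotations, dir) {
  dir.create(file.path(dir, "sumstats"), recursive = TRUE, showWarnings = FALSE)
  variants <- annotations$variants
  for (pid in sim$phenotypes$phenotype_id) {
    rec <- sim$associations[phenotype_id == pid]
    kind <- sim$phenotypes$kind[sim$phenotypes$phenotype_id == pid]
    idx <- match(rec$variant_id, variants$variant_id)
    tab <- data.table(
      ID = rec$variant_id,
      CHROM = variants$chrom[idx],
      POS = variants$pos[idx],
      SE = fmt_full(rec$se),
      P = fmt_full(rec$p_value)
    )
    if (kind == "binary") {
      tab[, `:=`(OR = fmt_full(exp(rec$estimate)))]
    } else {
      tab[, `:=`(BETA = fmt_full(rec$estimate))]
    }
    fwrite(tab, file.path(dir, "sumstats", paste0(pid, ".glm.tsv")),
           sep = "\t")
  }
  fwrite(sim$phenotypes, file.path(dir, "phenotypes.tsv"), sep = "\t")
  fwrite(variants, file.path(dir, "variants.tsv"), sep = "\t")
  fwrite(annotations$tss, file.path(dir, "tss.tsv"), sep = "\t")
  truth <- sim$truth
  jsonlite::write_json(
    list(k0 = truth$k0, S_true = truth$S_true, noise_sd = truth$noise_sd,
         sparsity = truth$sparsity, seed = truth$seed,
         phenotype_ids = truth$phenotype_ids,
         variant_ids = truth$variant_ids,
         U_true = truth$U_true, V_true = truth$V_true,
         counts = annotations$counts),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor"
  )
  invisible(dir)
}

#' Read the planted-truth sidecar written by [write_synthetic_dataset()]
#'
#' @param path Path to `truth.json`.
#' @return A `degas_truth`.
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, n) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = n, byrow = TRUE)
  }
  u <- as_mat(raw$U_true, length(raw$phenotype_ids))
  v <- as_mat(raw$V_true, length(raw$variant_ids))
  rownames(u) <- raw$phenotype_ids
  rownames(v) <- raw$variant_ids
  structure(
    list(U_true = u, S_true = raw$S_true, V_true = v,
         k0 = as.integer(raw$k0), noise_sd = raw$noise_sd,
         sparsity = raw$sparsity, seed = as.integer(raw$seed),
         phenotype_ids = raw$phenotype_ids, variant_ids = raw$variant_ids),
    class = "degas_truth"
  )
}
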