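#' Select the top-contributing variants of a component
#'
#' Ranks variants by contribution score within one component (ties broken
#' lexicographically by variant identifier) and keeps the top `n`; the
#' default of 5000 is the setting used for region-enrichment input.
#'
#' @param tab A variant contribution `degas_score_table`.
#' @param component Component index.
#' @param n Number of variants to keep (default 5000).
#' @return A `data.table` with columns `variant_id` and `score`, descending.
#' @export
select_top_variants <- function(tab, component, n = 5000L) {
  stopifnot(inherits(tab, "degas_score_table"), n >= 1L)
  top <- top_drivers(tab, component, n = n)
  setnames(top, "entity", "variant_id")
  top
}

#' BED intervals for selected variants
#'
#' Converts selected variants to single-base BED intervals (0-based
#' half-open, so a variant at 1-based position `p` becomes `[p-1, p)`) with
#' the contribution score in the score column.
#'
#' @param selected Output of [select_top_variants()].
#' @param variants Variant annotation table with `variant_id`, `chrom`, `pos`
#'   (1-based).
#' @return A `data.table` with BED columns `chrom`, `start`, `end`, `name`,
#'   `score`.
#' @export
variant_bed <- function(selected, variants) {
  variants <- as.data.table(variants)
  idx <- match(selected$variant_id, variants$variant_id)
  if (anyNA(idx)) {
    stop("selected variant(s) missing from the annotation table: ",
         paste(utils::head(selected$variant_id[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  }
  data.table(
    chrom = variants$chrom[idx],
    start = variants$pos[idx] - 1L,
    end = variants$pos[idx],
    name = selected$variant_id,
    score = selected$score
  )
}

#' Write a BED file
#'
#' @param bed A `data.table` from [variant_bed()] (or any BED-like frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Gene regulatory domains (basal plus extension)
#'
#' Assigns each gene a regulatory domain following the basal-plus-extension
#' rule used by region-based enrichment tools: a strand-oriented basal
#' window of `basal_upstream` bp upstream and `basal_downstream` bp
#' downstream of the TSS (defaults 5 kb / 1 kb), extended in both directions
#' up to `extension` bp (default 1 Mb) from the TSS but stopping at the
#' nearest neighboring gene's basal domain, and never shrinking below the
#' gene's own basal window. Domains are clipped to `[0, chromosome size]`.
#'
#' @param tss Table with columns `gene`, `chrom`, `tss` (coordinate in the
#'   same 0-based system as BED starts), `strand` (`"+"` or `"-"`).
#' @param basal_upstream,basal_downstream,extension Rule parameters in bp.
#' @param chrom_sizes Optional named vector (or two-column
#'   `chrom`/`size` frame) of chromosome lengths used for clipping.
#' @return A `data.table` with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
build_regulatory_domains <- function(tss,
                                     basal_upstream = 5000L,
                                     basal_downstream = 1000L,
                                     extension = 1e6,
                                     chrom_sizes = NULL) {
  tss <- as.data.table(tss)
  required <- c("gene", "chrom", "tss", "strand")
  missing <- setdiff(required, names(tss))
  if (length(missing)) {
    stop("TSS table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tss$gene)) {
    stop("duplicate gene symbol in TSS table: ",
         tss$gene[duplicated(tss$gene)][1L], call. = FALSE)
  }
  sizes <- NULL
  if (!is.null(chrom_sizes)) {
    if (is.data.frame(chrom_sizes)) {
      sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
    } else {
      sizes <- chrom_sizes
    }
  }
  plus <- tss$strand == "+"
  basal_start <- ifelse(plus, tss$tss - basal_upstream, tss$tss - basal_downstream)
  basal_end <- ifelse(plus, tss$tss + basal_downstream, tss$tss + basal_upstream)
  out <- data.table(gene = tss$gene, chrom = as.character(tss$chrom),
                    tss = tss$tss, basal_start = basal_start,
                    basal_end = basal_end)
  res <- out[, {
    ord <- order(tss)
    bs <- basal_start[ord]; be <- basal_end[ord]; t0 <- tss[ord]
    n <- .N
    start <- numeric(n); end <- numeric(n)
    lim <- if (!is.null(sizes) && .BY[[1L]] %in% names(sizes)) {
      as.numeric(sizes[[.BY[[1L]]]])
    } else Inf
    for (i in seq_len(n)) {
      left_neighbor <- if (i > 1L) max(be[seq_len(i - 1L)]) else -Inf
      right_neighbor <- if (i < n) min(bs[(i + 1L):n]) else Inf
      start[i] <- min(bs[i], max(t0[i] - extension, left_neighbor, 0))
      end[i] <- max(be[i], min(t0[i] + extension, right_neighbor, lim))
      start[i] <- max(start[i], 0)
      end[i] <- min(end[i], lim)
    }
    list(gene = gene[ord], start = start, end = end)
  }, by = "chrom"]
  res <- res[, list(gene, chrom, start, end)]
  if (any(res$start >= res$end)) {
    stop("degenerate regulatory domain (start >= end); check TSS coordinates",
         call. = FALSE)
  }
  res[order(gene)]
}

domains_to_granges <- function(domains, seqlevels = unique(domains$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(domains$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = domains$start + 1L, end = domains$end)
  )
}

#' Binomial region enrichment over regulatory domains
#'
#' For each ontology term: take the union of the regulatory domains of the
#' term's genes, let `pi` be the fraction of the genome it covers, count the
#' query regions overlapping it, and test the count against
#' `Binomial(n_regions, pi)` with the upper-tail p-value
#' `Pr[X >= hits]`. Fold enrichment is `hits / (n_regions * pi)`.
#'
#' @param regions Query regions as a BED-like frame (`chrom`, `start`, `end`,
#'   0-based half-open), typically single-base variant intervals from
#'   [variant_bed()].
#' @param domains Regulatory domains from [build_regulatory_domains()].
#' @param terms Ontology annotation: a frame with columns `term_id`, `gene`.
#' @param genome_size Total genome length in bp on the shared coordinate
#'   system.
#' @param component Optional component label stored in the result.
#' @return A `data.table` with columns `component`, `term_id`, `n_hits`,
#'   `n_regions`, `coverage_bp`, `fold`, `p_value`.
#' @export
binomial_region_enrichment <- function(regions, domains, terms, genome_size,
                                       component = NA_integer_) {
  regions <- as.data.table(regions)
  terms <- as.data.table(terms)
  domains <- as.data.table(domains)
  if (nrow(terms) == 0L) {
    return(data.table(component = integer(), term_id = character(),
                      n_hits = integer(), n_regions = integer(),
                      coverage_bp = numeric(), fold = numeric(),
                      p_value = numeric()))
  }
  seqlev <- sort(unique(c(regions$chrom, domains$chrom)))
  region_gr <- GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = seqlev),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  n_regions <- length(region_gr)
  term_ids <- sort(unique(terms$term_id))
  out <- lapply(term_ids, function(tid) {
    genes <- unique(terms$gene[terms$term_id == tid])
    dom <- domains[domains$gene %in% genes]
    if (nrow(dom) == 0L) {
      coverage <- 0
      hits <- 0L
    } else {
      red <- GenomicRanges::reduce(domains_to_granges(dom, seqlevels = seqlev))
      coverage <- sum(as.numeric(GenomicRanges::width(red)))
      hits <- sum(IRanges::overlapsAny(region_gr, red))
    }
    pi_term <- coverage / genome_size
    if (pi_term == 0 && hits > 0) {
      stop("term '", tid, "' has zero domain coverage but ", hits,
           " overlapping regions: inconsistent coordinates", call. = FALSE)
    }
    fold <- if (hits == 0L) 0 else hits / (n_regions * pi_term)
    p <- if (hits == 0L) 1 else stats::pbinom(hits - 1L, n_regions, pi_term,
                                              lower.tail = FALSE)
    data.table(component = component, term_id = tid, n_hits = as.integer(hits),
               n_regions = n_regions, coverage_bp = coverage, fold = fold,
               p_value = p)
  })
  data.table::rbindlist(out)
}

#' Significance filters for enrichment results
#'
#' `table` mode applies the Bonferroni-corrected threshold `p < 5e-6`;
#' `plot` mode applies the stricter display filter `p < 5e-7` and
#' `fold >= 2`.
#'
#' @param results Enrichment results from [binomial_region_enrichment()].
#' @param mode `"table"` or `"plot"`.
#' @param max_p_table,max_p_plot,min_fold Threshold overrides.
#' @return The filtered results.
#' @export
filter_significant <- function(results, mode = c("table", "plot"),
                               max_p_table = 5e-6, max_p_plot = 5e-7,
                               min_fold = 2) {
  mode <- match.arg(mode)
  results <- as.data.table(results)
  if (mode == "table") {
    results[p_value < max_p_table]
  } else {
    results[p_value < max_p_plot & fold >= min_fold]
  }
}

term_gene_union <- function(term_set, terms) {
  terms <- as.data.table(terms)
  unknown <- setdiff(term_set, terms$term_id)
  if (length(unknown)) {
    stop("unresolvable term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unique(terms$gene[terms$term_id %in% term_set])
}

#' Jaccard similarity between the gene sets of two term sets
#'
#' Each term set is first expanded to the union of its terms' annotated
#' genes; the similarity is `|A n B| / |A u B|`, between 0 (disjoint) and 1
#' (identical). If both unions are empty the similarity is defined as 0
#' with a warning.
#'
#' @param term_set_a,term_set_b Character vectors of term identifiers.
#' @param terms Ontology annotation frame (`term_id`, `gene`).
#' @return A single numeric value in `[0, 1]`.
#' @export
jaccard_similarity <- function(term_set_a, term_set_b, terms) {
  a <- term_gene_union(term_set_a, terms)
  b <- term_gene_union(term_set_b, terms)
  u <- union(a, b)
  if (length(u) == 0L) {
    warning("both term sets have empty gene unions; similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  length(intersect(a, b)) / length(u)
}

#' Specificity profile of per-component enrichments
#'
#' For each component, takes its top `top_terms` enriched terms sorted by
#' binomial fold (ties broken by term identifier), then for each `k`
#' computes all pairwise Jaccard similarities among the first `k`
#' components' term-set gene unions and reports the median. A small median
#' indicates that components capture distinct biology. Components with no
#' enriched term are skipped with a message.
#'
#' @param results Combined enrichment results across components.
#' @param terms Ontology annotation frame (`term_id`, `gene`).
#' @param top_terms Number of top-fold terms per component (default 5).
#' @param k_values Values of `k` to profile; defaults to `2:n_components`.
#' @param components Full set of component labels considered; components in
#'   this set with no enriched term are skipped with a message. Defaults to
#'   the components present in `results`.
#' @return A `data.table` with columns `k`, `n_pairs`, `median_jaccard`.
#' @export
component_specificity_profile <- function(results, terms, top_terms = 5L,
                                          k_values = NULL,
                                          components = NULL) {
  results <- as.data.table(results)
  comps <- if (is.null(components)) sort(unique(results$component)) else
    sort(components)
  top_sets <- list()
  for (k in comps) {
    sub <- results[component == k]
    sub <- sub[order(-fold, term_id)]
    if (nrow(sub) == 0L) next
    top_sets[[as.character(k)]] <-
      sub$term_id[seq_len(min(top_terms, nrow(sub)))]
  }
  skipped <- setdiff(as.character(comps), names(top_sets))
  if (length(skipped)) {
    message("skipping component(s) with no enriched term: ",
            paste(skipped, collapse = ", "))
  }
  n_comp <- length(top_sets)
  if (n_comp < 2L) {
    return(data.table(k = integer(), n_pairs = integer(),
                      median_jaccard = numeric()))
  }
  if (is.null(k_values)) k_values <- 2:n_comp
  k_values <- k_values[k_values >= 2L & k_values <= n_comp]
  # precompute pairwise similarities among all available components
  sims <- matrix(NA_real_, n_comp, n_comp)
  for (a in seq_len(n_comp - 1L)) {
    for (b in (a + 1L):n_comp) {
      sims[a, b] <- jaccard_similarity(top_sets[[a]], top_sets[[b]], terms)
    }
  }
  out <- lapply(k_values, function(k) {
    vals <- sims[seq_len(k), seq_len(k)]
    vals <- vals[upper.tri(vals)]
    data.table(k = k, n_pairs = length(vals), median_jaccard = median(vals))
  })
  data.table::rbindlist(out)
}
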