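#' Factor scores (principal-component coordinates)
#'
#' Phenotype factor scores `F_p = U diag(S)` and variant factor scores
#' `F_v = V diag(S)`. These are the principal components of the two axes:
#' column `k` of each has Euclidean norm `S[k]`.
#'
#' @param d A `degas_decomposition`.
#' @return An object of class `degas_factor_scores`: list with matrices
#'   `phenotype` (N x K) and `variant` (M x K).
#' @export
factor_scores <- function(d) {
  stopifnot(inherits(d, "degas_decomposition"))
  structure(
    list(phenotype = d$U %*% diag(d$S, d$K),
         variant = d$V %*% diag(d$S, d$K)),
    class = "degas_factor_scores"
  )
}

new_score_table <- function(values, axis, score_kind) {
  structure(values, class = c("degas_score_table", "matrix", "array"),
            axis = axis, score_kind = score_kind)
}

#' @export
print.degas_score_table <- function(x, ...) {
  cat(sprintf("degas %s scores (%s axis): %d entities x %d components\n",
              attr(x, "score_kind"), attr(x, "axis"), nrow(x), ncol(x)))
  invisible(x)
}

#' Contribution scores of phenotypes or variants to each component
#'
#' The contribution of entity `i` to component `k` is the squared singular
#' vector entry (`U[i,k]^2` on the phenotype axis, `V[j,k]^2` on the variant
#' axis). Orthonormality of `U` and `V` guarantees that each component
#' column sums to one, so a contribution reads directly as the share of a
#' component attributable to one entity.
#'
#' @param d A `degas_decomposition`.
#' @param axis `"phenotype"` or `"variant"`.
#' @return A `degas_score_table` (entities x components).
#' @export
contribution_scores <- function(d, axis = c("phenotype", "variant")) {
  axis <- match.arg(axis)
  stopifnot(inherits(d, "degas_decomposition"))
  m <- if (axis == "phenotype") d$U else d$V
  new_score_table(m^2, axis = axis, score_kind = "contribution")
}

#' Partition matrix variants into gene-contribution groups
#'
#' Variants sharing exactly the same non-empty gene annotation set fall into
#' one group keyed by that set (multi-gene annotations form intersection
#' groups such as `"GENE_A,GENE_B"`, distinct from either single gene);
#' every unannotated non-coding variant forms its own singleton group keyed
#' by its variant identifier. The groups partition the variant axis, which
#' is what makes gene contribution scores sum to one per component.
#'
#' @param variants Variant annotation table with `variant_id` and `genes`
#'   (comma-separated symbols, empty string for none) covering every matrix
#'   variant.
#' @return A `data.table` with columns `variant_id` and `group_key`, class
#'   `degas_gene_groups`.
#' @export
build_gene_groups <- function(variants) {
  variants <- as.data.table(variants)
  key <- vapply(strsplit(variants$genes, ",", fixed = TRUE), function(g) {
    g <- sort(unique(g[nzchar(g)]))
    paste(g, collapse = ",")
  }, character(1L))
  key <- ifelse(nzchar(key), key, variants$variant_id)
  out <- data.table(variant_id = variants$variant_id, group_key = key)
  class(out) <- c("degas_gene_groups", class(out))
  out
}

#' Gene-level contribution scores
#'
#' Sums variant contribution scores over each gene group from
#' [build_gene_groups()]. Because the groups partition the variant axis,
#' each component column still sums to one.
#'
#' @param d A `degas_decomposition`.
#' @param groups Gene groups covering exactly the matrix variant axis.
#' @return A `degas_score_table` on the `gene` axis.
#' @export
gene_contribution <- function(d, groups) {
  vc <- contribution_scores(d, axis = "variant")
  groups <- as.data.table(groups)
  ids <- rownames(vc)
  if (anyDuplicated(groups$variant_id) ||
      !setequal(groups$variant_id, ids) ||
      nrow(groups) != length(ids)) {
    stop("gene groups must partition the variant axis: every matrix variant ",
         "in exactly one group", call. = FALSE)
  }
  key <- groups$group_key[match(ids, groups$variant_id)]
  agg <- rowsum(unclass(vc), group = key, reorder = TRUE)
  new_score_table(agg, axis = "gene", score_kind = "contribution")
}

#' Squared cosine scores: component relevance for one entity
#'
#' The squared cosine of entity `i` on component `k` is its squared factor
#' score normalized across the `K` computed components:
#' `F[i,k]^2 / sum_k' F[i,k']^2`. Each entity row sums to one, so the score
#' reads as the share of an entity's (truncated-space) association signal
#' carried by one component. Entities whose factor scores are all zero have
#' no defined direction; their rows are dropped and recorded in the
#' `dropped` attribute instead of propagating NaN.
#'
#' @param f A `degas_factor_scores`.
#' @param axis `"phenotype"` or `"variant"`.
#' @return A `degas_score_table` with rows summing to one.
#' @export
squared_cosine <- function(f, axis = c("phenotype", "variant")) {
  axis <- match.arg(axis)
  stopifnot(inherits(f, "degas_factor_scores"))
  m <- f[[axis]]^2
  denom <- rowSums(m)
  zero <- denom == 0
  out <- new_score_table(m[!zero, , drop = FALSE] / denom[!zero],
                         axis = axis, score_kind = "squared_cosine")
  attr(out, "dropped") <- rownames(m)[zero]
  out
}

#' Top driving entities of a component
#'
#' Ranks entities by score within one component, descending, with ties
#' broken lexicographically by entity identifier for deterministic reports.
#'
#' @param tab A `degas_score_table` (typically contributions).
#' @param component Component index.
#' @param n Number of entities to return (default 20, truncated to the
#'   entity count).
#' @return A `data.table` with columns `entity` and `score`.
#' @export
top_drivers <- function(tab, component, n = 20L) {
  stopifnot(inherits(tab, "degas_score_table"))
  if (component < 1L || component > ncol(tab)) {
    stop("component must be between 1 and ", ncol(tab), call. = FALSE)
  }
  scores <- unclass(tab)[, component]
  ord <- order(-scores, rownames(tab))
  ord <- ord[seq_len(min(n, length(ord)))]
  data.table(entity = rownames(tab)[ord], score = unname(scores[ord]))
}

#' Key components for one entity
#'
#' Ranks components by squared cosine score for a given entity and reports
#' the cumulative share, e.g. "the top three components explain 69% of this
#' phenotype's associations".
#'
#' @param tab A squared-cosine `degas_score_table`.
#' @param entity Entity identifier (row name).
#' @param n Number of components to report.
#' @return A `data.table` with columns `component`, `score`, `cumulative`.
#' @export
key_components <- function(tab, entity, n = 3L) {
  stopifnot(inherits(tab, "degas_score_table"))
  if (!entity %in% rownames(tab)) {
    stop("unknown entity '", entity, "'", call. = FALSE)
  }
  scores <- unclass(tab)[entity, ]
  ord <- order(-scores, seq_along(scores))
  ord <- ord[seq_len(min(n, length(ord)))]
  data.table(component = ord, score = unname(scores[ord]),
             cumulative = cumsum(unname(scores[ord])))
}

#' Aggregate phenotype contributions into phenotype groups
#'
#' Sums phenotype contribution scores over user-supplied group labels
#' (e.g. "fat", "fat-free") for stacked-bar summaries. Phenotypes without a
#' label fall into `"other"`. Columns still sum to one.
#'
#' @param tab A phenotype contribution `degas_score_table`.
#' @param groups Named character vector mapping `phenotype_id` to group
#'   label.
#' @return A `degas_score_table` on the `phenotype_group` axis.
#' @export
group_contribution <- function(tab, groups) {
  stopifnot(inherits(tab, "degas_score_table"))
  labels <- groups[rownames(tab)]
  labels[is.na(labels)] <- "other"
  agg <- rowsum(unclass(tab), group = labels, reorder = TRUE)
  new_score_table(agg, axis = "phenotype_group",
                  score_kind = attr(tab, "score_kind"))
}

#' Long-format stacked-bar data with small segments collapsed
#'
#' For each component, entities whose score reaches `threshold` appear as
#' their own segment; the remainder is aggregated as `other_label`. The
#' default thresholds used for display are 0.005 on the phenotype axis and
#' 0.0005 on the gene axis.
#'
#' @param tab A contribution `degas_score_table`.
#' @param threshold Minimum score for an entity to keep its own segment.
#' @param other_label Label of the aggregated remainder.
#' @return A `data.table` with columns `component`, `entity`, `score`.
#' @export
stacked_bar_frame <- function(tab, threshold = 0.005, other_label = "others") {
  stopifnot(inherits(tab, "degas_score_table"))
  vals <- unclass(tab)
  out <- lapply(seq_len(ncol(vals)), function(k) {
    s <- vals[, k]
    keep <- s >= threshold
    seg <- data.table(component = k, entity = rownames(vals)[keep],
                      score = unname(s[keep]))
    seg <- seg[order(-score, entity)]
    rest <- sum(s[!keep])
    if (rest > 0 || !any(keep)) {
      seg <- rbind(seg, data.table(component = k, entity = other_label,
                                   score = rest))
    }
    seg
  })
  data.table::rbindlist(out)
}

#' Biplot data frame for a pair of components
#'
#' Builds the plotting table for the scatter-plus-arrows display: phenotype
#' points at their factor scores `F_p`, variant points at `F_v`, and arrows
#' at the singular-vector coordinates `U` for a selected set of phenotypes
#' (drawn on sub-axes). The inner product of a variant point with a
#' phenotype arrow equals the projection of that pair's association onto the
#' two displayed components: same direction means a positive projected
#' association, opposite direction negative, orthogonal or zero-length
#' vectors mean no projected association.
#'
#' @param d A `degas_decomposition`.
#' @param selected_phenotypes Phenotype identifiers to annotate as arrows.
#' @param cx,cy Distinct component indices for the x and y axes.
#' @return A `data.table` with columns `kind` (`phenotype_point`,
#'   `variant_point`, `arrow`), `id`, `x`, `y`.
#' @export
biplot_frame <- function(d, selected_phenotypes = character(), cx = 1L, cy = 2L) {
  stopifnot(inherits(d, "degas_decomposition"))
  if (cx == cy) stop("cx and cy must be distinct components", call. = FALSE)
  if (max(cx, cy) > d$K) stop("component index exceeds K", call. = FALSE)
  missing <- setdiff(selected_phenotypes, rownames(d$U))
  if (length(missing)) {
    stop("selected phenotype(s) not in the decomposition: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  f <- factor_scores(d)
  rbind(
    data.table(kind = "phenotype_point", id = rownames(d$U),
               x = f$phenotype[, cx], y = f$phenotype[, cy]),
    data.table(kind = "variant_point", id = rownames(d$V),
               x = f$variant[, cx], y = f$variant[, cy]),
    if (length(selected_phenotypes)) {
      data.table(kind = "arrow", id = selected_phenotypes,
                 x = d$U[selected_phenotypes, cx],
                 y = d$U[selected_phenotypes, cy])
    }
  )
}
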