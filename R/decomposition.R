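#' Truncated singular value decomposition of the association matrix
#'
#' Computes the leading `k` singular triplets of `W` (N phenotypes x M
#' variants) so that `W ~ U diag(S) t(V)` with orthonormal `U`, `V` and
#' nonincreasing positive `S`. The factorization works through the symmetric
#' eigendecomposition of the Gram matrix on the smaller of the two axes,
#' which is exact, deterministic, and cheap whenever one axis (here the
#' phenome) is only a few thousand entries long. Component signs are
#' canonicalized so that the largest-magnitude entry of each phenotype
#' singular vector is positive, with the flip mirrored in `V`; the product
#' `U S V'` is unchanged.
#'
#' @param w A `degas_zmatrix` or plain numeric matrix.
#' @param k Number of components, `1 <= k <= min(N, M)`.
#' @return An object of class `degas_decomposition`: list with `U`, `S`
#'   (vector of singular values), `V`, `K`, and `total_variance`
#'   (squared Frobenius norm of the input).
#' @export
truncated_svd <- function(w, k) {
  vals <- if (inherits(w, "degas_zmatrix")) w$values else w
  stopifnot(is.matrix(vals), is.numeric(vals))
  n <- nrow(vals); m <- ncol(vals)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > min(n, m)) {
    stop("k must satisfy 1 <= k <= min(N, M) = ", min(n, m), call. = FALSE)
  }
  k <- as.integer(k)
  if (n <= m) {
    e <- eigen(tcrossprod(vals), symmetric = TRUE)
    s <- sqrt(pmax(e$values[seq_len(k)], 0))
    if (any(s <= sqrt(.Machine$double.eps) * max(s, 1))) {
      stop("requested k = ", k, " exceeds the numerical rank of the matrix",
           call. = FALSE)
    }
    u <- e$vectors[, seq_len(k), drop = FALSE]
    v <- crossprod(vals, u) %*% diag(1 / s, k)
  } else {
    e <- eigen(crossprod(vals), symmetric = TRUE)
    s <- sqrt(pmax(e$values[seq_len(k)], 0))
    if (any(s <= sqrt(.Machine$double.eps) * max(s, 1))) {
      stop("requested k = ", k, " exceeds the numerical rank of the matrix",
           call. = FALSE)
    }
    v <- e$vectors[, seq_len(k), drop = FALSE]
    u <- (vals %*% v) %*% diag(1 / s, k)
  }
  flip <- canonical_signs(u)
  u <- sweep(u, 2L, flip, `*`)
  v <- sweep(v, 2L, flip, `*`)
  rownames(u) <- rownames(vals)
  rownames(v) <- colnames(vals)
  colnames(u) <- colnames(v) <- paste0("PC", seq_len(k))
  structure(
    list(U = u, S = s, V = v, K = k, total_variance = sum(vals^2)),
    class = "degas_decomposition"
  )
}

# sign convention: the largest-magnitude entry of each U column is positive;
# ties (exactly equal magnitudes) resolve to the earliest row
canonical_signs <- function(u) {
  apply(u, 2L, function(col) {
    pivot <- which.max(abs(col))
    if (col[pivot] < 0) -1 else 1
  })
}

#' @export
print.degas_decomposition <- function(x, ...) {
  cat(sprintf("degas decomposition: %d x %d, K = %d, leading s = %.4g\n",
              nrow(x$U), nrow(x$V), x$K, x$S[[1L]]))
  invisible(x)
}

#' Variance explained by each latent component
#'
#' Fraction of the total variance of `W` captured by component `k`:
#' `S[k]^2 / VarTot(W)` where `VarTot` is the squared Frobenius norm of the
#' input matrix.
#'
#' @param d A `degas_decomposition`.
#' @return Length-`K` numeric vector of fractions (nonincreasing, sum <= 1).
#' @export
variance_explained <- function(d) {
  stopifnot(inherits(d, "degas_decomposition"))
  if (!is.finite(d$total_variance) || d$total_variance <= 0) {
    stop("total variance of the input matrix must be positive", call. = FALSE)
  }
  d$S^2 / d$total_variance
}

#' Null expectation for per-component variance explained
#'
#' The reference value against which observed variance-explained fractions
#' are compared when choosing the number of components. The default
#' `"squared-rank"` model returns `1 / Rank(W)^2`; the `"uniform"` model
#' returns `1 / Rank(W)`, the expectation when variance-explained fractions
#' are spread uniformly across the full rank. Both are exposed because the
#' two references differ by a factor of `Rank(W)` and the choice materially
#' changes how conservative the component-count selection is (see the
#' methods vignette).
#'
#' @param rank Rank of the full matrix (the phenotype count in practice).
#' @param model `"squared-rank"` (default) or `"uniform"`.
#' @return A single numeric value.
#' @export
null_expected_variance <- function(rank, model = c("squared-rank", "uniform")) {
  model <- match.arg(model)
  if (!is.numeric(rank) || length(rank) != 1L || rank < 1) {
    stop("rank must be a single integer >= 1", call. = FALSE)
  }
  if (model == "squared-rank") 1 / rank^2 else 1 / rank
}

#' Choose the number of informative components
#'
#' Returns the largest `k` (capped at `k_max`, default 100) whose
#' variance-explained fraction exceeds the null expectation from
#' [null_expected_variance()]. Because the fractions are nonincreasing this
#' is the count of informative components.
#'
#' @param d A `degas_decomposition` with at least `k_max` components (or as
#'   many as the matrix admits).
#' @param rank Full rank of the input matrix.
#' @param k_max Cap on the returned count; default 100.
#' @param model Null model, passed to [null_expected_variance()].
#' @return An integer in `[0, k_max]`.
#' @export
select_component_count <- function(d, rank, k_max = 100L,
                                   model = c("squared-rank", "uniform")) {
  model <- match.arg(model)
  ve <- variance_explained(d)
  above <- which(ve > null_expected_variance(rank, model))
  if (length(above) == 0L) return(0L)
  min(as.integer(k_max), max(above))
}

#' Scree table for a decomposition
#'
#' @param d A `degas_decomposition`.
#' @param rank Optional full rank for the null-expectation column.
#' @param model Null model, passed to [null_expected_variance()].
#' @return A `data.table` with columns `component`, `singular_value`,
#'   `variance_explained`, `cumulative`, and (when `rank` is given)
#'   `null_expected`.
#' @export
scree_table <- function(d, rank = NULL, model = c("squared-rank", "uniform")) {
  model <- match.arg(model)
  ve <- variance_explained(d)
  out <- data.table(
    component = seq_len(d$K),
    singular_value = d$S,
    variance_explained = ve,
    cumulative = cumsum(ve)
  )
  if (!is.null(rank)) {
    out[, `:=`(null_expected = null_expected_variance(rank, model))]
  }
  out[]
}

#' Decompose an individual-by-phenotype measurement matrix
#'
#' Prepares a raw phenotype matrix (individuals in rows, phenotypes in
#' columns, `NA` for missing measurements) by per-column median imputation
#' followed by Z-score standardization (zero mean, unit population
#' variance), then applies [truncated_svd()]. Individual scores are the left
#' factor scores `U diag(S)`.
#'
#' @param p Numeric matrix of raw phenotype measurements.
#' @param k Number of components.
#' @return A list with `decomposition` (a `degas_decomposition`),
#'   `individual_scores`, and `prepared` (the imputed, standardized matrix).
#' @export
decompose_phenotype_matrix <- function(p, k) {
  stopifnot(is.matrix(p), is.numeric(p))
  if (is.null(colnames(p))) colnames(p) <- paste0("phe", seq_len(ncol(p)))
  if (is.null(rownames(p))) rownames(p) <- paste0("ind", seq_len(nrow(p)))
  for (j in seq_len(ncol(p))) {
    col <- p[, j]
    if (all(is.na(col))) {
      stop("phenotype column '", colnames(p)[j], "' has no observed values",
           call. = FALSE)
    }
    col[is.na(col)] <- median(col, na.rm = TRUE)
    p[, j] <- col
  }
  mu <- colMeans(p)
  p <- sweep(p, 2L, mu)
  v <- colMeans(p^2)
  if (any(v < 1e-12)) {
    stop("phenotype column '", colnames(p)[which(v < 1e-12)[1L]],
         "' is constant after imputation", call. = FALSE)
  }
  p <- sweep(p, 2L, sqrt(v), `/`)
  d <- truncated_svd(p, k)
  list(decomposition = d,
       individual_scores = d$U %*% diag(d$S, d$K),
       prepared = p)
}
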