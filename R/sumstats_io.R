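#' @importFrom data.table data.table as.data.table fread fwrite setnames := .N .SD
#' @importFrom stats median pnorm rnorm runif setNames
NULL

# quiet R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  "phenotype_id", "variant_id", "estimate", "se", "p_value", "kind",
  "chrom", "pos", "consequence", "genes", "maf", "missingness", "hwe_p",
  "ld_pruned_in", "n_effective", "group_key", "score", "fold", "term_id",
  "component", "gene", "tss", "strand", "value", "n_hits", "n_regions",
  "..keep"
))

#' MHC region excluded from association matrices
#'
#' The major histocompatibility complex interval on chromosome 6
#' (GRCh37, 1-based inclusive) that is removed from every dataset because of
#' its extreme linkage disequilibrium.
#'
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
mhc_region <- function() {
  list(chrom = "6", start = 25477797L, end = 36448354L)
}

#' Read a per-phenotype GWAS association table
#'
#' Parses a tab-separated association table in the PLINK2 `.glm` dialect:
#' a header row with columns `ID`, `P`, a standard-error column (`SE` or
#' `LOG(OR)_SE`), and exactly one effect column (`BETA` for quantitative
#' traits or `OR` for binary traits). `OR` values are log-transformed so the
#' `estimate` field always holds a beta or log odds ratio. Rows whose
#' statistics are missing or non-numeric are dropped with a warning that
#' reports the count. Gzipped files are read transparently.
#'
#' @param path Path to the association table.
#' @param phenotype_id Identifier attached to every parsed record.
#' @param kind Either `"quantitative"` or `"binary"`; recorded on each record
#'   and used later by the value filter.
#' @return A `data.table` of association records with columns
#'   `phenotype_id`, `variant_id`, `estimate`, `se`, `p_value`, `kind`.
#' @export
read_association_table <- function(path, phenotype_id,
                                   kind = c("quantitative", "binary")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("association table not found: ", path, call. = FALSE)
  }
  tab <- fread(path, sep = "\t", header = TRUE)
  cols <- names(tab)
  if (!"ID" %in% cols) stop("mandatory column 'ID' missing in ", path, call. = FALSE)
  if (!"P" %in% cols) stop("mandatory column 'P' missing in ", path, call. = FALSE)
  se_col <- intersect(c("SE", "LOG(OR)_SE"), cols)
  if (length(se_col) == 0L) {
    stop("mandatory column 'SE' (or 'LOG(OR)_SE') missing in ", path, call. = FALSE)
  }
  se_col <- se_col[[1L]]
  eff_col <- intersect(c("BETA", "OR"), cols)
  if (length(eff_col) == 0L) {
    stop("mandatory column 'BETA' or 'OR' missing in ", path, call. = FALSE)
  }
  if (length(eff_col) > 1L) {
    stop("ambiguous effect columns in ", path,
         ": exactly one of 'BETA' or 'OR' must be present", call. = FALSE)
  }
  eff_col <- eff_col[[1L]]

  num <- function(x) suppressWarnings(as.numeric(x))
  est <- num(tab[[eff_col]])
  if (eff_col == "OR") est <- log(est)
  se <- num(tab[[se_col]])
  p <- num(tab[["P"]])
  keep <- is.finite(est) & is.finite(se) & is.finite(p)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with missing or non-numeric statistics ",
            "dropped from ", path, call. = FALSE)
  }
  data.table(
    phenotype_id = phenotype_id,
    variant_id = as.character(tab[["ID"]])[keep],
    estimate = est[keep],
    se = se[keep],
    p_value = p[keep],
    kind = kind
  )
}

#' Read a variant annotation table
#'
#' Expects tab-separated columns `variant_id`, `chrom`, `pos`, `consequence`
#' (`ptv`, `coding_nonptv`, or `noncoding`), `genes` (comma-separated gene
#' symbols, empty for unannotated non-coding variants), `maf`, `missingness`,
#' `hwe_p`, and `ld_pruned_in` (logical).
#'
#' @param path Path to the annotation TSV (optionally gzipped).
#' @return A `data.table` with the columns above.
#' @export
read_variant_table <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE,
               colClasses = list(character = c("variant_id", "chrom", "genes")))
  required <- c("variant_id", "chrom", "pos", "consequence", "genes",
                "maf", "missingness", "hwe_p", "ld_pruned_in")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("variant table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab[, genes := ifelse(is.na(genes), "", genes)]
  tab[]
}

#' Read a phenotype metadata table
#'
#' Expects tab-separated columns `phenotype_id`, `kind` (`binary` or
#' `quantitative`), `n_effective` (case count for binary phenotypes,
#' non-missing count for quantitative ones), and `group`.
#'
#' @param path Path to the metadata TSV.
#' @return A `data.table`.
#' @export
read_phenotype_table <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE,
               colClasses = list(character = c("phenotype_id", "kind", "group")))
  required <- c("phenotype_id", "kind", "n_effective", "group")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("phenotype table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab[]
}

#' Collapse repeated phenotype measurements to one value per individual
#'
#' Biobank phenotypes are often measured at several assessment instances.
#' For a binary phenotype an individual is a case if they are a case at any
#' instance; for a quantitative phenotype the median of the non-missing
#' instance values is used.
#'
#' @param long A data frame with columns `individual_id`, `instance`, `value`.
#'   Missing values are `NA`; binary values are 0/1.
#' @param kind `"binary"` or `"quantitative"`.
#' @return A `data.table` with columns `individual_id`, `value` (one row per
#'   individual with at least one non-missing instance).
#' @export
collapse_phenotype_instances <- function(long, kind = c("binary", "quantitative")) {
  kind <- match.arg(kind)
  long <- as.data.table(long)
  required <- c("individual_id", "instance", "value")
  missing <- setdiff(required, names(long))
  if (length(missing)) {
    stop("long-format table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  obs <- long[!is.na(value)]
  if (kind == "binary") {
    out <- obs[, list(value = as.numeric(any(value != 0))), by = "individual_id"]
  } else {
    out <- obs[, list(value = median(value)), by = "individual_id"]
  }
  out[order(individual_id)]
}

#' Phenotype inclusion filter
#'
#' Keeps phenotypes with at least `min_n` cases (binary) or non-missing
#' measurements (quantitative).
#'
#' @param phenotypes Phenotype metadata table (see [read_phenotype_table()]).
#' @param min_n Minimum effective sample size; default 100.
#' @return Character vector of retained `phenotype_id`s.
#' @export
filter_phenotypes <- function(phenotypes, min_n = 100L) {
  phenotypes <- as.data.table(phenotypes)
  phenotypes[n_effective >= min_n, phenotype_id]
}

#' Variant quality-control filter
#'
#' Retains variants with missingness below 1%, minor-allele frequency above
#' 0.01%, membership in the LD-pruned set, Hardy-Weinberg disequilibrium
#' p-value above 1e-7, and position outside the MHC region
#' (chr6:25477797-36448354, 1-based inclusive). Thresholds are exposed as
#' arguments; the defaults are the canonical settings.
#'
#' @param variants Variant annotation table (see [read_variant_table()]).
#' @param max_missingness,min_maf,min_hwe_p QC thresholds.
#' @param mhc MHC interval as returned by [mhc_region()], or `NULL` to skip
#'   the exclusion.
#' @return Character vector of retained `variant_id`s, in input order.
#' @export
filter_variants_qc <- function(variants,
                               max_missingness = 0.01,
                               min_maf = 1e-4,
                               min_hwe_p = 1e-7,
                               mhc = mhc_region()) {
  variants <- as.data.table(variants)
  qc_fields <- c("maf", "missingness", "hwe_p", "ld_pruned_in", "chrom", "pos")
  for (f in qc_fields) {
    bad <- which(is.na(variants[[f]]))
    if (length(bad)) {
      stop("variant ", variants$variant_id[bad[1L]],
           " has missing QC field '", f, "'", call. = FALSE)
    }
  }
  keep <- variants$missingness < max_missingness &
    variants$maf > min_maf &
    variants$ld_pruned_in &
    variants$hwe_p > min_hwe_p
  if (!is.null(mhc)) {
    in_mhc <- variants$chrom == mhc$chrom &
      variants$pos >= mhc$start & variants$pos <= mhc$end
    keep <- keep & !in_mhc
  }
  variants$variant_id[keep]
}

#' Subset variants by predicted consequence
#'
#' The three analysis datasets: `all` keeps every variant; `coding` keeps
#' protein-truncating plus other coding consequences (missense, splice
#' region, loss of start/stop, ...); `ptv` keeps protein-truncating variants
#' only (stop gain, frameshift, splice acceptor/donor).
#'
#' @param variant_ids Variant identifiers to subset (e.g. the QC survivors).
#' @param variants Variant annotation table with `consequence`.
#' @param dataset One of `"all"`, `"coding"`, `"ptv"`.
#' @return Character vector of retained `variant_id`s.
#' @export
subset_by_consequence <- function(variant_ids, variants,
                                  dataset = c("all", "coding", "ptv")) {
  dataset <- match.arg(dataset)
  if (dataset == "all") return(variant_ids)
  variants <- as.data.table(variants)
  cons <- setNames(variants$consequence, variants$variant_id)[variant_ids]
  wanted <- if (dataset == "coding") c("ptv", "coding_nonptv") else "ptv"
  variant_ids[cons %in% wanted]
}

#' Value-based association filter
#'
#' Keeps associations with p-value below 0.001 and standard error of the
#' beta (quantitative phenotypes) below 0.08 or of the log odds ratio
#' (binary phenotypes) below 0.2, so that the matrix only carries confident
#' estimates.
#'
#' @param records Association records carrying a `kind` column
#'   (see [read_association_table()]).
#' @param max_p,max_se_quantitative,max_se_binary Filter thresholds.
#' @return The surviving records (possibly zero rows).
#' @export
apply_value_filter <- function(records,
                               max_p = 0.001,
                               max_se_quantitative = 0.08,
                               max_se_binary = 0.2) {
  records <- as.data.table(records)
  if (!"kind" %in% names(records)) {
    stop("records must carry a 'kind' column (binary/quantitative)", call. = FALSE)
  }
  se_cap <- ifelse(records$kind == "quantitative",
                   max_se_quantitative, max_se_binary)
  records[records$p_value < max_p & records$se < se_cap]
}

#' Construct a labelled Z-score matrix
#'
#' @param values Numeric matrix with phenotype row names and variant column
#'   names.
#' @param standardized Whether rows have already been standardized.
#' @return An object of class `degas_zmatrix`.
#' @export
zmatrix <- function(values, standardized = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("zmatrix values must carry phenotype row names and variant column names",
         call. = FALSE)
  }
  structure(
    list(values = values,
         phenotype_ids = rownames(values),
         variant_ids = colnames(values),
         standardized = isTRUE(standardized)),
    class = "degas_zmatrix"
  )
}

#' @export
print.degas_zmatrix <- function(x, ...) {
  cat(sprintf("degas Z-score matrix: %d phenotypes x %d variants (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "unstandardized"))
  invisible(x)
}

#' @export
dim.degas_zmatrix <- function(x) dim(x$values)

#' Assemble the phenotype-by-variant Z-score matrix
#'
#' Each surviving association contributes the Wald Z-score `estimate/se` at
#' its (phenotype, variant) cell; cells with no surviving association are
#' zero. Phenotypes and variants with no surviving association at all are
#' dropped from the axes, which is why consequence-restricted datasets end
#' up with fewer phenotypes.
#'
#' @param records Filtered association records.
#' @param phenotype_ids,variant_ids Optional retained axis identifiers;
#'   records outside them are an error. Defaults to the sorted identifiers
#'   observed in `records`.
#' @return An unstandardized `degas_zmatrix`.
#' @export
build_zscore_matrix <- function(records, phenotype_ids = NULL, variant_ids = NULL) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) stop("no association records survive the filters", call. = FALSE)
  if (any(records$se <= 0)) {
    stop("standard errors must be positive to form Z-scores", call. = FALSE)
  }
  if (anyDuplicated(records[, c("phenotype_id", "variant_id")])) {
    dup <- records[duplicated(records[, c("phenotype_id", "variant_id")])][1L]
    stop("duplicate association for phenotype '", dup$phenotype_id,
         "' and variant '", dup$variant_id, "': matrix entry is ambiguous",
         call. = FALSE)
  }
  if (is.null(phenotype_ids)) phenotype_ids <- sort(unique(records$phenotype_id))
  if (is.null(variant_ids)) variant_ids <- sort(unique(records$variant_id))
  if (!all(records$phenotype_id %in% phenotype_ids)) {
    stop("records reference phenotypes outside the retained list", call. = FALSE)
  }
  if (!all(records$variant_id %in% variant_ids)) {
    stop("records reference variants outside the retained list", call. = FALSE)
  }
  # drop axis entries with no surviving record (mirrors the smaller
  # coding/PTV matrices)
  phenotype_ids <- phenotype_ids[phenotype_ids %in% unique(records$phenotype_id)]
  variant_ids <- variant_ids[variant_ids %in% unique(records$variant_id)]
  w <- matrix(0, length(phenotype_ids), length(variant_ids),
              dimnames = list(phenotype_ids, variant_ids))
  i <- match(records$phenotype_id, phenotype_ids)
  j <- match(records$variant_id, variant_ids)
  w[cbind(i, j)] <- records$estimate / records$se
  zmatrix(w, standardized = FALSE)
}

#' Standardize phenotype rows to zero mean and unit variance
#'
#' Each phenotype row is centered and scaled to unit population variance
#' (division by `M`, the number of variants). Rows with zero variance carry
#' no direction and are dropped with a warning.
#'
#' @param z An unstandardized `degas_zmatrix`.
#' @param tol Variance below which a row counts as constant.
#' @return A standardized `degas_zmatrix` (possibly with fewer rows).
#' @export
standardize_phenotype_rows <- function(z, tol = 1e-12) {
  stopifnot(inherits(z, "degas_zmatrix"))
  if (z$standardized) stop("matrix is already standardized", call. = FALSE)
  w <- z$values
  mu <- rowMeans(w)
  w <- w - mu
  v <- rowMeans(w^2)
  constant <- v < tol
  if (any(constant)) {
    warning("dropping ", sum(constant),
            " constant phenotype row(s) with undefined standardization: ",
            paste(utils::head(rownames(w)[constant], 5L), collapse = ", "),
            call. = FALSE)
    w <- w[!constant, , drop = FALSE]
    v <- v[!constant]
  }
  if (nrow(w) == 0L) stop("no phenotype rows left after standardization", call. = FALSE)
  w <- w / sqrt(v)
  zmatrix(w, standardized = TRUE)
}

#' Apply the full ingestion pipeline for one dataset
#'
#' Composes the phenotype filter, variant QC filter, consequence subset and
#' value filter, assembles the Z-score matrix, and standardizes it. The
#' filters commute, so the order used here is a convenience, not a
#' requirement. A per-stage report of removed counts is returned alongside
#' the matrix.
#'
#' @param associations Association records (rbind of
#'   [read_association_table()] outputs).
#' @param variants Variant annotation table.
#' @param phenotypes Phenotype metadata table.
#' @param dataset `"all"`, `"coding"`, or `"ptv"`.
#' @param min_n,max_missingness,min_maf,min_hwe_p,mhc,max_p,max_se_quantitative,max_se_binary
#'   Filter thresholds, passed through to the individual filters.
#' @param standardize Whether to standardize rows (default `TRUE`).
#' @return A list with `z` (the `degas_zmatrix`) and `report`
#'   (a `data.table` of per-stage retained counts).
#' @export
assemble_zscore_matrix <- function(associations, variants, phenotypes,
                                   dataset = c("all", "coding", "ptv"),
                                   min_n = 100L,
                                   max_missingness = 0.01, min_maf = 1e-4,
                                   min_hwe_p = 1e-7, mhc = mhc_region(),
                                   max_p = 0.001, max_se_quantitative = 0.08,
                                   max_se_binary = 0.2,
                                   standardize = TRUE) {
  dataset <- match.arg(dataset)
  associations <- as.data.table(associations)
  n0 <- nrow(associations)

  keep_phe <- filter_phenotypes(phenotypes, min_n = min_n)
  keep_var <- filter_variants_qc(variants, max_missingness = max_missingness,
                                 min_maf = min_maf, min_hwe_p = min_hwe_p,
                                 mhc = mhc)
  keep_var <- subset_by_consequence(keep_var, variants, dataset = dataset)
  if (length(keep_var) == 0L) {
    stop("empty variant axis: no variant survives QC for dataset '",
         dataset, "'", call. = FALSE)
  }
  rec <- associations[phenotype_id %in% keep_phe & variant_id %in% keep_var]
  n_axes <- nrow(rec)
  rec <- apply_value_filter(rec, max_p = max_p,
                            max_se_quantitative = max_se_quantitative,
                            max_se_binary = max_se_binary)
  n_value <- nrow(rec)
  z <- build_zscore_matrix(rec, phenotype_ids = keep_phe, variant_ids = keep_var)
  if (standardize) z <- standardize_phenotype_rows(z)
  report <- data.table(
    stage = c("input", "phenotype+variant filters", "value filter",
              "matrix (after axis drop)"),
    records = c(n0, n_axes, n_value, sum(z$values != 0)),
    phenotypes = c(NA_integer_, NA_integer_, NA_integer_, nrow(z$values)),
    variants = c(NA_integer_, NA_integer_, NA_integer_, ncol(z$values))
  )
  list(z = z, report = report)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Serialize a Z-score matrix to disk
#'
#' Writes three files: `<prefix>_values.tsv` (dense matrix, full `%.17g`
#' precision so the round trip is bit-exact), `<prefix>_phenotypes.txt`, and
#' `<prefix>_variants.txt`.
#'
#' @param z A `degas_zmatrix`.
#' @param prefix File path prefix.
#' @return `prefix`, invisibly.
#' @export
write_zmatrix <- function(z, prefix) {
  stopifnot(inherits(z, "degas_zmatrix"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  vals <- apply(z$values, 2L, fmt_full)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(z$values))
  lines <- apply(vals, 1L, paste, collapse = "\t")
  writeLines(c(if (z$standardized) "#standardized" else "#unstandardized", lines),
             paste0(prefix, "_values.tsv"))
  writeLines(z$phenotype_ids, paste0(prefix, "_phenotypes.txt"))
  writeLines(z$variant_ids, paste0(prefix, "_variants.txt"))
  invisible(prefix)
}

#' Read a Z-score matrix written by [write_zmatrix()]
#'
#' @param prefix File path prefix used at write time.
#' @return A `degas_zmatrix`.
#' @export
read_zmatrix <- function(prefix) {
  lines <- readLines(paste0(prefix, "_values.tsv"))
  standardized <- identical(lines[[1L]], "#standardized")
  vals <- do.call(rbind, lapply(lines[-1L], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])
  }))
  rownames(vals) <- readLines(paste0(prefix, "_phenotypes.txt"))
  colnames(vals) <- readLines(paste0(prefix, "_variants.txt"))
  zmatrix(vals, standardized = standardized)
}
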