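#' Run configuration for the decomposition pipeline
#'
#' Collects every tunable of a run with the canonical defaults: K = 100
#' components, value filter p < 0.001 with SE caps 0.08 (quantitative) and
#' 0.2 (binary), variant QC thresholds (missingness < 1%, MAF > 0.01%,
#' HWE p > 1e-7, LD-pruned set, MHC excluded), phenotype inclusion at
#' n >= 100, and the display thresholds for stacked bars. The resolved
#' configuration is serialized as JSON next to every run's outputs, and its
#' hash is stamped into every output header so runs are traceable.
#'
#' @param input_dir Directory in the layout written by
#'   [write_synthetic_dataset()] (`sumstats/`, `phenotypes.tsv`,
#'   `variants.tsv`, `tss.tsv`, optionally `ontology.tsv`).
#' @param out_dir Output directory.
#' @param dataset `"all"`, `"coding"`, or `"ptv"`.
#' @param k Number of components to compute (capped at the matrix rank).
#' @param k_max Cap used by [select_component_count()].
#' @param min_n,max_missingness,min_maf,min_hwe_p Inclusion/QC thresholds.
#' @param max_p,max_se_quantitative,max_se_binary Value-filter thresholds.
#' @param display_threshold_phenotype,display_threshold_gene Stacked-bar
#'   display thresholds.
#' @param top_n_variants Variants per component exported for enrichment
#'   (default 5000).
#' @param top_terms Terms per component in the specificity profile.
#' @param null_model Null model for component-count selection.
#' @param seed Seed recorded with the run.
#' @return An object of class `degas_config`.
#' @export
degas_config <- function(input_dir, out_dir,
                         dataset = c("all", "coding", "ptv"),
                         k = 100L, k_max = 100L,
                         min_n = 100L,
                         max_missingness = 0.01, min_maf = 1e-4,
                         min_hwe_p = 1e-7,
                         max_p = 0.001, max_se_quantitative = 0.08,
                         max_se_binary = 0.2,
                         display_threshold_phenotype = 0.005,
                         display_threshold_gene = 0.0005,
                         top_n_variants = 5000L,
                         top_terms = 5L,
                         null_model = c("squared-rank", "uniform"),
                         seed = 1L) {
  cfg <- list(
    input_dir = input_dir, out_dir = out_dir,
    dataset = match.arg(dataset),
    k = as.integer(k), k_max = as.integer(k_max),
    min_n = as.integer(min_n),
    max_missingness = max_missingness, min_maf = min_maf,
    min_hwe_p = min_hwe_p,
    max_p = max_p, max_se_quantitative = max_se_quantitative,
    max_se_binary = max_se_binary,
    display_threshold_phenotype = display_threshold_phenotype,
    display_threshold_gene = display_threshold_gene,
    top_n_variants = as.integer(top_n_variants),
    top_terms = as.integer(top_terms),
    null_model = match.arg(null_model),
    seed = as.integer(seed)
  )
  structure(cfg, class = "degas_config")
}

# polynomial rolling hash of the serialized config; a short stable
# fingerprint for output headers, not a cryptographic hash. Paths are
# excluded so that the same analysis run into a different directory is
# stamped identically.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$input_dir <- NULL
  cfg$out_dir <- NULL
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

degas_version <- function() {
  as.character(utils::packageVersion("degas"))
}

write_stamped_tsv <- function(dt, path, hash) {
  writeLines(sprintf("#degas %s config=%s", degas_version(), hash), path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written with a `#degas` header stamp
#'
#' @param path File path.
#' @return A `data.table` (the header comment is skipped).
#' @export
read_stamped_tsv <- function(path) {
  fread(path, sep = "\t", header = TRUE, skip = 1L)
}

read_input_bundle <- function(config) {
  phenotypes <- read_phenotype_table(file.path(config$input_dir, "phenotypes.tsv"))
  variants <- read_variant_table(file.path(config$input_dir, "variants.tsv"))
  files <- list.files(file.path(config$input_dir, "sumstats"),
                      pattern = "\\.glm\\.tsv(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no association tables found under ",
         file.path(config$input_dir, "sumstats"), call. = FALSE)
  }
  assoc <- lapply(files, function(f) {
    pid <- sub("\\.glm\\.tsv(\\.gz)?$", "", basename(f))
    kind <- phenotypes$kind[match(pid, phenotypes$phenotype_id)]
    if (is.na(kind)) {
      stop("association table ", basename(f),
           " has no phenotype metadata entry", call. = FALSE)
    }
    read_association_table(f, phenotype_id = pid, kind = kind)
  })
  list(associations = data.table::rbindlist(assoc),
       phenotypes = phenotypes, variants = variants)
}

mat_to_dt <- function(m, id_col) {
  dt <- data.table(id = rownames(m))
  setnames(dt, "id", id_col)
  cbind(dt, as.data.table(unclass(m)))
}

#' Run ingestion, decomposition, and scoring end to end
#'
#' Reads the input bundle, applies the phenotype/variant/value filters,
#' assembles and standardizes the Z-score matrix, computes the truncated
#' SVD and the full scoring system, and writes every artifact to
#' `config$out_dir`: `U.tsv`, `S.tsv`, `V.tsv`, `scree.tsv`, the four
#' contribution tables, the two squared-cosine tables, `top_drivers.json`,
#' `filter_report.tsv`, `stacked_phenotype.tsv`, `stacked_gene.tsv`, and
#' the resolved `config.json`. Every table carries a header stamp with the
#' package version and config hash.
#'
#' @param config A `degas_config`.
#' @return Invisibly, a list with the in-memory objects (`z`,
#'   `decomposition`, score tables, `report`).
#' @export
run_decompose <- function(config) {
  stopifnot(inherits(config, "degas_config"))
  hash <- config_hash(config)
  stage <- "ingest"
  result <- tryCatch({
    inputs <- read_input_bundle(config)
    stage <- "filter+matrix"
    asm <- assemble_zscore_matrix(
      inputs$associations, inputs$variants, inputs$phenotypes,
      dataset = config$dataset, min_n = config$min_n,
      max_missingness = config$max_missingness, min_maf = config$min_maf,
      min_hwe_p = config$min_hwe_p, max_p = config$max_p,
      max_se_quantitative = config$max_se_quantitative,
      max_se_binary = config$max_se_binary
    )
    stage <- "tsvd"
    d <- truncated_svd(asm$z, min(config$k, nrow(asm$z$values),
                                  ncol(asm$z$values)))
    stage <- "scores"
    f <- factor_scores(d)
    phe_contrib <- contribution_scores(d, "phenotype")
    var_contrib <- contribution_scores(d, "variant")
    groups <- build_gene_groups(
      inputs$variants[match(rownames(d$V), inputs$variants$variant_id)])
    gene_contrib <- gene_contribution(d, groups)
    group_map <- setNames(inputs$phenotypes$group,
                          inputs$phenotypes$phenotype_id)
    grp_contrib <- group_contribution(phe_contrib, group_map)
    cos2_phe <- squared_cosine(f, "phenotype")
    cos2_var <- squared_cosine(f, "variant")
    list(inputs = inputs, asm = asm, d = d, f = f,
         phe_contrib = phe_contrib, var_contrib = var_contrib,
         gene_contrib = gene_contrib, grp_contrib = grp_contrib,
         cos2_phe = cos2_phe, cos2_var = cos2_var, groups = groups)
  }, error = function(e) {
    stop("run_decompose failed at stage '", stage, "' (config ", hash, "): ",
         conditionMessage(e), call. = FALSE)
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  d <- result$d
  jsonlite::write_json(unclass(config), out("config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_stamped_tsv(mat_to_dt(d$U, "phenotype_id"), out("U.tsv"), hash)
  write_stamped_tsv(data.table(component = seq_len(d$K), singular_value = d$S),
                    out("S.tsv"), hash)
  write_stamped_tsv(mat_to_dt(d$V, "variant_id"), out("V.tsv"), hash)
  write_stamped_tsv(scree_table(d, rank = nrow(d$U), model = config$null_model),
                    out("scree.tsv"), hash)
  write_stamped_tsv(mat_to_dt(result$phe_contrib, "phenotype_id"),
                    out("contribution_phenotype.tsv"), hash)
  write_stamped_tsv(mat_to_dt(result$var_contrib, "variant_id"),
                    out("contribution_variant.tsv"), hash)
  write_stamped_tsv(mat_to_dt(result$gene_contrib, "gene_group"),
                    out("contribution_gene.tsv"), hash)
  write_stamped_tsv(mat_to_dt(result$grp_contrib, "phenotype_group"),
                    out("contribution_phenotype_group.tsv"), hash)
  write_stamped_tsv(mat_to_dt(result$cos2_phe, "phenotype_id"),
                    out("cos2_phenotype.tsv"), hash)
  write_stamped_tsv(mat_to_dt(result$cos2_var, "variant_id"),
                    out("cos2_variant.tsv"), hash)
  write_stamped_tsv(result$asm$report, out("filter_report.tsv"), hash)
  write_stamped_tsv(
    stacked_bar_frame(result$phe_contrib,
                      threshold = config$display_threshold_phenotype),
    out("stacked_phenotype.tsv"), hash)
  write_stamped_tsv(
    stacked_bar_frame(result$gene_contrib,
                      threshold = config$display_threshold_gene),
    out("stacked_gene.tsv"), hash)
  drivers <- lapply(seq_len(min(5L, d$K)), function(k) {
    list(component = k,
         phenotypes = top_drivers(result$phe_contrib, k, 10L),
         genes = top_drivers(result$gene_contrib, k, 10L))
  })
  jsonlite::write_json(drivers, out("top_drivers.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(result)
}

#' Run region enrichment and specificity profiling
#'
#' Consumes a decomposition (in memory from [run_decompose()], or re-read
#' from `config$out_dir`), exports the top-contributing variants of each
#' component as BED, runs the binomial regulatory-domain enrichment against
#' the ontology, applies the table and plot significance filters, and
#' computes the Jaccard specificity profile. Outputs land in
#' `config$out_dir`: `bed/component_<k>.bed`, `enrichment.tsv`,
#' `enrichment_table.tsv`, `enrichment_plot.tsv`, `specificity.tsv`.
#'
#' @param config A `degas_config`; `input_dir` must contain `tss.tsv` and
#'   `ontology.tsv`.
#' @param decomposition Optional result of [run_decompose()]; when `NULL`,
#'   the variant contribution table and variant annotations are re-read
#'   from disk.
#' @param n_components Number of leading components to enrich (default:
#'   all computed).
#' @return Invisibly, a list with `enrichment`, `table_hits`, `plot_hits`,
#'   `specificity`.
#' @export
run_enrich <- function(config, decomposition = NULL, n_components = NULL) {
  stopifnot(inherits(config, "degas_config"))
  hash <- config_hash(config)
  ontology_path <- file.path(config$input_dir, "ontology.tsv")
  tss_path <- file.path(config$input_dir, "tss.tsv")
  if (!file.exists(tss_path)) {
    stop("missing ", tss_path, "; run_enrich needs the gene TSS table",
         call. = FALSE)
  }
  if (is.null(decomposition)) {
    vc_path <- file.path(config$out_dir, "contribution_variant.tsv")
    if (!file.exists(vc_path)) {
      stop("missing ", vc_path, "; run run_decompose first", call. = FALSE)
    }
    vc_dt <- read_stamped_tsv(vc_path)
    m <- as.matrix(vc_dt[, -1L])
    rownames(m) <- vc_dt[[1L]]
    var_contrib <- new_score_table(m, axis = "variant",
                                   score_kind = "contribution")
    variants <- read_variant_table(file.path(config$input_dir, "variants.tsv"))
  } else {
    var_contrib <- decomposition$var_contrib
    variants <- decomposition$inputs$variants
  }
  tss <- fread(tss_path, sep = "\t", header = TRUE,
               colClasses = list(character = c("gene", "chrom", "strand")))
  terms <- if (file.exists(ontology_path)) {
    fread(ontology_path, sep = "\t", header = TRUE,
          colClasses = list(character = c("term_id", "gene")))
  } else {
    data.table(term_id = character(), gene = character())
  }
  if (nrow(terms) == 0L) {
    warning("empty ontology: enrichment results will be empty", call. = FALSE)
  }
  sizes <- synthetic_chrom_sizes()
  sizes_path <- file.path(config$input_dir, "chrom.sizes")
  if (file.exists(sizes_path)) {
    sz <- fread(sizes_path, header = FALSE, col.names = c("chrom", "size"),
                colClasses = list(character = 1L))
    sizes <- setNames(sz$size, sz$chrom)
  }
  genome_size <- sum(as.numeric(sizes))
  domains <- build_regulatory_domains(tss, chrom_sizes = sizes)

  dir.create(file.path(config$out_dir, "bed"), recursive = TRUE,
             showWarnings = FALSE)
  if (is.null(n_components)) n_components <- ncol(var_contrib)
  n_components <- min(n_components, ncol(var_contrib))
  all_results <- lapply(seq_len(n_components), function(k) {
    sel <- select_top_variants(var_contrib, k, n = config$top_n_variants)
    bed <- variant_bed(sel, variants)
    write_bed(bed, file.path(config$out_dir, "bed",
                             sprintf("component_%03d.bed", k)))
    binomial_region_enrichment(bed, domains, terms, genome_size,
                               component = k)
  })
  enrichment <- data.table::rbindlist(all_results)
  table_hits <- filter_significant(enrichment, "table")
  plot_hits <- filter_significant(enrichment, "plot")
  specificity <- suppressMessages(component_specificity_profile(
    table_hits, terms, top_terms = config$top_terms,
    components = seq_len(n_components)))
  write_stamped_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"),
                    hash)
  write_stamped_tsv(table_hits,
                    file.path(config$out_dir, "enrichment_table.tsv"), hash)
  write_stamped_tsv(plot_hits,
                    file.path(config$out_dir, "enrichment_plot.tsv"), hash)
  write_stamped_tsv(specificity,
                    file.path(config$out_dir, "specificity.tsv"), hash)
  invisible(list(enrichment = enrichment, table_hits = table_hits,
                 plot_hits = plot_hits, specificity = specificity))
}
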