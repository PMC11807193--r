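# End-to-end orchestration: read -> rebin -> impute -> classify ->
# subpopulations -> RT outputs, with a JSON run manifest. Each stage is a
# thin call into the standalone module functions; no state is shared
# between stages beyond the returned objects and the files written.

#' Default pipeline configuration
#'
#' All thresholds carry their published defaults: master seed 18671107,
#' 100 kb bins, k = 5 imputation neighbours, 30,000-read barcode floor,
#' epsilon clamp \[1.25, 2\], 98.5% merge identity, minimum subpopulation
#' size 10, 1000 permutations.
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    input = NULL, layout = "bed", chrom_sizes = NULL, bin_size = 1e5,
    rebin = FALSE, model = NULL, out_dir = NULL,
    seed = DEFAULT_SEED, k = 5, min_reads = 30000,
    epsilon_bounds = c(1.25, 2), merge_identity = 0.985,
    min_subpop_cells = 10, min_samples_frac = 0.10, n_perm = 1000,
    min_s_cells_rt = 30, rt = TRUE)
  override <- list(...)
  if (length(override) == 1 && is.list(override[[1]]) && is.null(names(override))) {
    override <- override[[1]]
  }
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return configuration list with defaults filled in.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Stages: load copy numbers (unless a matrix is passed directly),
#' optionally re-bin to fixed windows, drop empty bins, impute missing
#' values, classify replication states, discover subpopulations and match
#' replicating cells, and (optionally) emit per-subpopulation pseudo-bulk
#' RT profiles. Results are returned and, when `out_dir` is set, written
#' alongside a JSON manifest of seeds, thresholds and per-stage counts.
#'
#' @param config list from [pipeline_config()] / [read_config()].
#' @param matrix optional in-memory copy-number matrix overriding
#'   `config$input`.
#' @param model optional `mnm_model` overriding `config$model` (which is a
#'   path for [load_model()]).
#' @return list with `matrix` (imputed), `phases`, `assignment`,
#'   `rt_profiles`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), matrix = NULL, model = NULL) {
  cfg <- pipeline_config(config)
  manifest <- list(seed = cfg$seed, thresholds = cfg[c(
    "bin_size", "k", "min_reads", "merge_identity", "min_subpop_cells",
    "min_samples_frac", "n_perm", "min_s_cells_rt")], stages = list())
  stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  m <- matrix
  if (is.null(m)) {
    if (is.null(cfg$input)) stop("stage 'load': no input matrix or file given")
    m <- read_cn(cfg$input, layout = cfg$layout)
  }
  stage("load", n_cells = nrow(m), n_bins = ncol(m),
        missing = sum(is.na(m)))

  if (isTRUE(cfg$rebin)) {
    if (is.null(cfg$chrom_sizes)) stop("stage 'rebin': chrom_sizes required")
    m <- rebin(m, bin_size = cfg$bin_size, chrom_sizes = cfg$chrom_sizes)
    stage("rebin", n_bins = ncol(m), bin_size = cfg$bin_size)
  }

  dropped <- drop_empty_bins(m)
  m <- dropped$matrix
  stage("drop_empty_bins", removed = nrow(dropped$removed))

  imp <- knn_impute(m, k = cfg$k)
  m_imp <- imp$matrix
  stage("impute", imputed = nrow(imp$imputed), skipped = nrow(imp$skipped))
  if (nrow(imp$skipped) > 0) {
    keep <- setdiff(seq_len(ncol(m_imp)), unique(imp$skipped$col))
    m_imp <- m_imp[, keep, drop = FALSE]
  }

  mdl <- model
  if (is.null(mdl)) {
    if (is.null(cfg$model)) stop("stage 'classify': no model available")
    mdl <- load_model(cfg$model)
  }
  phases <- predict_states(mdl, m_imp)
  stage("classify", n_replicating = sum(phases$replicating),
        n_non_replicating = sum(!phases$replicating))

  assignment <- subpopulations(
    m_imp, phases$replicating, seed = cfg$seed,
    min_samples_frac = cfg$min_samples_frac,
    min_cells = cfg$min_subpop_cells,
    merge_threshold = cfg$merge_identity)
  stage("subpopulations",
        k = length(unique(assignment$labels)),
        epsilon = assignment$epsilon,
        min_samples = assignment$min_samples,
        seed_used = assignment$seed_used,
        votes = as.list(stats::setNames(assignment$votes$k,
                                        assignment$votes$seed)))

  rt_profiles <- NULL
  if (isTRUE(cfg$rt) && any(phases$replicating)) {
    rt_profiles <- list()
    for (k_sub in sort(unique(assignment$labels))) {
      cells_sub <- names(assignment$labels)[assignment$labels == k_sub]
      s_cells <- intersect(cells_sub, phases$cell[phases$replicating])
      g1_cells <- intersect(cells_sub, phases$cell[!phases$replicating])
      if (length(s_cells) < cfg$min_s_cells_rt || length(g1_cells) == 0) next
      baseline <- apply(m_imp[g1_cells, , drop = FALSE], 2, stats::median)
      binr <- binarize_s_cells(m_imp[s_cells, , drop = FALSE], baseline)
      rt_profiles[[as.character(k_sub)]] <- pseudobulk_rt(binr)
    }
    stage("rt", n_profiles = length(rt_profiles))
  }

  out <- list(matrix = m_imp, phases = phases, assignment = assignment,
              rt_profiles = rt_profiles, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

# Write pipeline outputs to a run directory.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cn(result$matrix, file.path(out_dir, "imputed_matrix.tsv"),
           layout = "matrix")
  data.table::fwrite(result$phases, file.path(out_dir, "phases.tsv"), sep = "\t")
  asg <- result$assignment
  data.table::fwrite(
    data.frame(cell_id = names(asg$labels),
               phase = result$phases$phase[match(names(asg$labels),
                                                 result$phases$cell)],
               subpopulation = asg$labels),
    file.path(out_dir, "subpopulations.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(cell_id = rownames(asg$embedding), asg$embedding),
    file.path(out_dir, "embedding_2d.tsv"), sep = "\t")
  if (!is.null(asg$embedding10)) {
    data.table::fwrite(
      data.frame(cell_id = rownames(asg$embedding10), asg$embedding10),
      file.path(out_dir, "embedding_10d.tsv"), sep = "\t")
  }
  med <- asg$medians
  bins <- parse_regions(colnames(med))
  for (k_sub in rownames(med)) {
    data.table::fwrite(
      data.frame(bins, cn = med[k_sub, ]),
      file.path(out_dir, sprintf("subpop_%s_median.bed", k_sub)),
      sep = "\t", col.names = FALSE)
  }
  if (!is.null(result$rt_profiles)) {
    for (k_sub in names(result$rt_profiles)) {
      write_rt_bedgraph(result$rt_profiles[[k_sub]],
                        file.path(out_dir, sprintf("subpop_%s_rt.bedgraph", k_sub)),
                        name = paste0("subpop_", k_sub))
    }
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
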