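# End-to-end orchestration: normalize -> CNR/BTIF -> PAL -> features ->
# screening -> selection/intersection -> signature -> evaluation, with a
# machine-readable run manifest.

#' Run configuration
#'
#' @param counts,controls,clinical,pathways,variants,hla input file paths
#'   (TSV/CSV/JSON as written by [write_cohort()]); `variants` and `hla`
#'   optional.
#' @param alpha BTIF / test significance level.
#' @param min_frac minimum group fraction for threshold optimization.
#' @param auc_cutoff,hr_low,hr_high selection filter settings.
#' @param tmb_cutoff TMB high/low boundary (mutations per megabase).
#' @param capture_mb captured exome size; required when `variants` given.
#' @param subset restrict screening to one histotype (`"all"`,
#'   `"adenocarcinoma"`, `"squamous"`, `"other"`).
#' @param expression_markers gene ids screened as expression biomarkers;
#'   `NULL` selects the 20 highest-variance genes.
#' @param seed integer seed echoed into the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(counts, controls, clinical, pathways,
                       variants = NULL, hla = NULL,
                       alpha = 0.05, min_frac = 0.3, auc_cutoff = 0.62,
                       hr_low = 0.4, hr_high = 2.5, tmb_cutoff = 10,
                       capture_mb = NULL, subset = "all",
                       expression_markers = NULL, seed = 1L) {
  stopifnot(alpha > 0, min_frac > 0, auc_cutoff > 0, hr_low > 0,
            hr_high > 0, tmb_cutoff > 0)
  if (!subset %in% c("all", "adenocarcinoma", "squamous", "other"))
    stop("subset must be one of: all, adenocarcinoma, squamous, other")
  structure(list(counts = counts, controls = controls, clinical = clinical,
                 pathways = pathways, variants = variants, hla = hla,
                 alpha = alpha, min_frac = min_frac,
                 auc_cutoff = auc_cutoff, hr_low = hr_low, hr_high = hr_high,
                 tmb_cutoff = tmb_cutoff, capture_mb = capture_mb,
                 subset = subset, expression_markers = expression_markers,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file whose fields mirror [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, o)
}

#' Run the full pipeline
#'
#' Executes the seven stages (normalize, activity, pal, features, screening,
#' selection, signature) and writes results under `out_dir`: `screen.tsv`
#' (one row per biomarker with selection flags), `pal.tsv`, `scores.tsv`,
#' `model.json` (when a signature could be built) and `manifest.json`
#' (stages, seed, package version, config echo, per-stage notes including
#' every excluded sample and the reason). Reruns with the same inputs and
#' config are byte-identical: nothing in the outputs depends on time or
#' environment.
#'
#' @param config a [run_config()] or path to its JSON form.
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  notes <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  counts <- read_expr_tsv(config$counts, stage = "raw")
  controls_raw <- read_expr_tsv(config$controls, stage = "raw")
  clinical <- as.data.frame(data.table::fread(config$clinical))
  pathways <- read_pathways_json(config$pathways)

  if (config$subset != "all") {
    keep <- clinical$histotype == config$subset
    notes$subset <- sprintf("subset=%s: %d of %d samples retained",
                            config$subset, sum(keep), nrow(clinical))
    clinical <- clinical[keep, , drop = FALSE]
    counts <- expr_matrix(
      as_plain_matrix(counts)[, clinical$sample_id, drop = FALSE], "raw")
  }
  resp <- map_response(clinical$recist)
  excl <- c(
    sprintf("%s: missing RECIST, excluded from response screening",
            clinical$sample_id[is.na(resp)]),
    sprintf("%s: missing PFS, excluded from survival screening",
            clinical$sample_id[is.na(clinical$pfs_months) |
                               is.na(clinical$event)]))
  notes$exclusions <- excl

  # 1: normalization (tumors and controls against their own panels)
  norm <- run_stage("normalize", function() {
    list(tumor = normalize_median_of_ratios(counts),
         control = normalize_median_of_ratios(controls_raw))
  })
  # 2: per-sample activity (CNR/BTIF) feeds the PAL stage
  activity <- run_stage("activity", function() {
    lapply(stats::setNames(colnames(norm$tumor$matrix),
                           colnames(norm$tumor$matrix)), function(s) {
      v <- stats::setNames(as_plain_matrix(norm$tumor$matrix)[, s],
                           rownames(norm$tumor$matrix))
      gene_activity(v, norm$control$matrix, alpha = config$alpha)
    })
  })
  # 3: PAL matrix
  pal <- run_stage("pal", function() {
    ids <- vapply(pathways, function(p) p$id, character(1))
    out <- matrix(NA_real_, length(pathways), length(activity),
                  dimnames = list(ids, names(activity)))
    for (s in names(activity))
      for (i in seq_along(pathways))
        out[i, s] <- suppressMessages(
          compute_pal(pathways[[i]], activity[[s]])$pal)
    out
  })
  # 4: exome-derived features
  feats <- run_stage("features", function() {
    out <- NULL
    if (!is.null(config$variants)) {
      if (is.null(config$capture_mb))
        stop("capture_mb is required when a variant table is supplied")
      variants <- as.data.frame(data.table::fread(config$variants))
      tmb <- compute_tmb(variants, config$capture_mb,
                         samples = clinical$sample_id,
                         cutoff = config$tmb_cutoff)
      muts <- mutation_flags(variants, samples = clinical$sample_id)
      out <- rbind(matrix(tmb$tmb, 1, dimnames = list("tmb", tmb$sample_id)),
                   muts)
    }
    if (!is.null(config$hla)) {
      hla <- as.data.frame(data.table::fread(config$hla))
      hla <- hla[hla$sample_id %in% clinical$sample_id, , drop = FALSE]
      hf <- hla_features(hla)
      out <- if (is.null(out)) hf else
        rbind(out, hf[, colnames(out), drop = FALSE])
    }
    out
  })
  # 5: screening over PALs, expression markers and categorical features
  screen <- run_stage("screening", function() {
    lognorm <- log(as_plain_matrix(norm$tumor$matrix))
    genes <- config$expression_markers
    if (is.null(genes)) {
      v <- apply(lognorm, 1, stats::var)
      genes <- names(sort(v, decreasing = TRUE))[seq_len(min(20, length(v)))]
      genes <- sort(genes)
    }
    markers <- rbind(pal, lognorm[genes, colnames(pal), drop = FALSE])
    if (!is.null(feats))
      markers <- rbind(markers, feats[, colnames(pal), drop = FALSE])
    screen_biomarkers(markers, clinical, min_frac = config$min_frac,
                      hr_low = config$hr_low, hr_high = config$hr_high,
                      alpha = config$alpha, auc_cutoff = config$auc_cutoff)
  })
  # 6: selection filters and their intersection
  sel <- run_stage("selection", function() {
    pfs_ids <- screen$id[screen$selected_pfs]
    resp_ids <- screen$id[screen$selected_response]
    list(pfs = pfs_ids, response = resp_ids,
         both = intersect_biomarkers(pfs_ids, resp_ids))
  })
  # 7: signature construction on the intersected biomarkers
  sig <- run_stage("signature", function() {
    if (length(sel$both) < 2)
      return(list(built = FALSE,
                  reason = sprintf("only %d intersected biomarker(s); >= 2 required",
                                   length(sel$both))))
    lognorm <- log(as_plain_matrix(norm$tumor$matrix))
    cand <- rbind(pal, lognorm[, colnames(pal), drop = FALSE])
    if (!is.null(feats)) cand <- rbind(cand, feats[, colnames(pal), drop = FALSE])
    cand <- cand[sel$both, , drop = FALSE]
    bt <- backward_eliminate(cand, clinical, min_frac = config$min_frac)
    ev <- evaluate_signature(bt$model, cand, clinical)
    list(built = TRUE, model = bt$model, trace = bt$trace, evaluation = ev)
  })

  # outputs
  data.table::fwrite(screen, file.path(out_dir, "screen.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(pathway = rownames(pal), pal),
    file.path(out_dir, "pal.tsv"), sep = "\t")
  if (isTRUE(sig$built)) {
    write_signature_json(sig$model, file.path(out_dir, "model.json"))
    data.table::fwrite(
      data.frame(sample_id = names(sig$evaluation$scores),
                 score = unname(sig$evaluation$scores)),
      file.path(out_dir, "scores.tsv"), sep = "\t")
  }
  manifest <- list(
    package = "immunomark",
    version = as.character(utils::packageVersion("immunomark")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    notes = notes,
    selection = sel,
    signature = if (isTRUE(sig$built))
      list(built = TRUE, components = sig$model$components,
           hr = sig$evaluation$hr, hr_p = sig$evaluation$hr_p,
           auc = sig$evaluation$auc, threshold = sig$model$risk_threshold,
           orientation = sig$model$orientation)
    else list(built = FALSE, reason = sig$reason))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
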