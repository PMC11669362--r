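# Seed-reproducible synthetic cohorts with planted effects: log-normal
# expression with a matched control panel, proportional-hazards PFS with
# uniform censoring, logistic RECIST labels, and binary HLA/mutation
# features with planted odds ratios.

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the reference NSCLC ICI cohort: 61 tumors, ~25%
#' responders, median PFS of 6 months (baseline exponential hazard
#' log(2)/6 per month), and a censoring window of 24 months giving roughly
#' one third censored subjects. Five planted protective genes act on both
#' the PFS hazard (log-HR -1 per SD of log-expression) and the response
#' odds (log-OR +1.5 per SD).
#'
#' @param n_tumor,n_control,n_genes cohort sizes (all > 0).
#' @param informative_genes data.frame with columns `gene`, `hazard_effect`
#'   (log-HR per SD of the latent marker), `response_effect` (log-OR per
#'   SD), `shift` (tumor-vs-control log shift, makes the gene visible to
#'   CNR/BTIF).
#' @param baseline_log_mean_sd length-2 numeric: mean and SD of per-gene
#'   baseline log expression.
#' @param within_sd within-gene biological SD of log expression.
#' @param baseline_hazard baseline event rate per month.
#' @param censor_window censoring uniform on (0, censor_window) months.
#' @param responder_target_fraction target mean response probability.
#' @param cr_fraction fraction of responders labelled CR (rest PR).
#' @param sd_fraction fraction of non-responders labelled SD (rest PD).
#' @param n_pathways,pathway_size_range pathway collection shape.
#' @param categorical_features data.frame with columns `name`, `prevalence`,
#'   `odds_ratio` (odds ratio of feature presence in responders vs
#'   non-responders).
#' @param mutation_rate mean nonsynonymous variants per sample (Poisson).
#' @param capture_mb nominal capture size used by downstream TMB examples.
#' @param seed integer seed; every draw is governed by it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 61,
                       n_control = 10,
                       n_genes = 500,
                       informative_genes = default_informative_genes(),
                       baseline_log_mean_sd = c(4, 1.5),
                       within_sd = 0.5,
                       baseline_hazard = log(2) / 6,
                       censor_window = 24,
                       responder_target_fraction = 15 / 61,
                       cr_fraction = 0.2,
                       sd_fraction = 0.5,
                       n_pathways = 20,
                       pathway_size_range = c(5, 20),
                       categorical_features = default_categorical_features(),
                       mutation_rate = 150,
                       capture_mb = 30,
                       seed = 1L) {
  cfg <- list(n_tumor = n_tumor, n_control = n_control, n_genes = n_genes,
              informative_genes = informative_genes,
              baseline_log_mean_sd = baseline_log_mean_sd,
              within_sd = within_sd,
              baseline_hazard = baseline_hazard,
              censor_window = censor_window,
              responder_target_fraction = responder_target_fraction,
              cr_fraction = cr_fraction, sd_fraction = sd_fraction,
              n_pathways = n_pathways,
              pathway_size_range = as.integer(pathway_size_range),
              categorical_features = categorical_features,
              mutation_rate = mutation_rate, capture_mb = capture_mb,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_informative_genes <- function() {
  data.frame(gene = sprintf("G%04d", 1:5),
             hazard_effect = -1.0,
             response_effect = 1.5,
             shift = 1.0,
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_categorical_features <- function() {
  data.frame(name = c("hla_hom_any", "mut_KRAS", "mut_STK11"),
             prevalence = c(0.15, 0.3, 0.15),
             odds_ratio = c(1, 1, 0.5),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_tumor, cfg$n_control, cfg$n_genes, cfg$n_pathways)
  if (any(counts <= 0)) stop("configuration error: all counts must be > 0")
  if (cfg$censor_window <= 0) stop("configuration error: censor_window must be > 0")
  props <- c(cfg$responder_target_fraction, cfg$cr_fraction, cfg$sd_fraction)
  if (any(props <= 0 | props >= 1))
    stop("configuration error: proportions must be in (0, 1)")
  if (cfg$pathway_size_range[2] > cfg$n_genes)
    stop("configuration error: pathway size range exceeds n_genes")
  if (nrow(cfg$informative_genes) > 0 &&
      !all(cfg$informative_genes$gene %in% sprintf("G%04d", seq_len(cfg$n_genes))))
    stop("configuration error: informative genes outside the gene universe")
  invisible(cfg)
}

gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

#' Simulate a complete cohort
#'
#' Counts are rounded log-normal per gene; tumors carry planted log shifts
#' on informative genes plus a per-tumor latent standard-normal marker z.
#' PFS times are exponential with log-hazard = log(baseline) +
#' sum(hazard_effect * z); censoring is uniform on (0, censor_window) and
#' the event flag is (event time <= censor time). Responder status is drawn
#' from a logistic model on the same latent markers with an intercept
#' calibrated to the target responder fraction, then mapped to CR/PR/SD/PD.
#' Binary categorical features are drawn with planted odds ratios relative
#' to responder status. Two calls with the same config are identical.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort`: list with `expression` (raw
#'   counts), `control_panel`, `clinical`, `pathways`, `interactome`,
#'   `variants`, `hla`, `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr_seed <- set_local_seed(cfg$seed)
  on.exit(withr_seed(), add = TRUE)

  genes <- gene_ids(cfg)
  tumors <- sprintf("T%03d", seq_len(cfg$n_tumor))
  controls <- sprintf("N%03d", seq_len(cfg$n_control))
  info <- cfg$informative_genes
  n_info <- nrow(info)

  mu <- stats::rnorm(cfg$n_genes, cfg$baseline_log_mean_sd[1],
                     cfg$baseline_log_mean_sd[2])
  names(mu) <- genes

  # latent standardized markers driving hazard and response
  z <- matrix(stats::rnorm(n_info * cfg$n_tumor), n_info, cfg$n_tumor,
              dimnames = list(info$gene, tumors))

  log_tumor <- matrix(mu, cfg$n_genes, cfg$n_tumor) +
    matrix(stats::rnorm(cfg$n_genes * cfg$n_tumor, 0, cfg$within_sd),
           cfg$n_genes, cfg$n_tumor)
  dimnames(log_tumor) <- list(genes, tumors)
  if (n_info > 0) {
    ii <- match(info$gene, genes)
    # informative genes: baseline + planted shift + within_sd * z
    log_tumor[ii, ] <- matrix(mu[ii] + info$shift, n_info, cfg$n_tumor) +
      cfg$within_sd * z
  }
  log_ctrl <- matrix(mu, cfg$n_genes, cfg$n_control) +
    matrix(stats::rnorm(cfg$n_genes * cfg$n_control, 0, cfg$within_sd),
           cfg$n_genes, cfg$n_control)
  dimnames(log_ctrl) <- list(genes, controls)

  expr <- expr_matrix(round(exp(log_tumor)), stage = "raw")
  ctrl <- expr_matrix(round(exp(log_ctrl)), stage = "raw")

  # PFS from an exponential proportional-hazards model
  loghaz <- rep(log(cfg$baseline_hazard), cfg$n_tumor)
  if (n_info > 0) loghaz <- loghaz + drop(crossprod(z, info$hazard_effect))
  t_event <- stats::rexp(cfg$n_tumor, rate = exp(loghaz))
  t_cens <- stats::runif(cfg$n_tumor, 0, cfg$censor_window)
  event <- as.integer(t_event <= t_cens)
  pfs <- pmin(t_event, t_cens)

  # responder labels from a logistic model, intercept calibrated to target
  lp_slope <- if (n_info > 0) drop(crossprod(z, info$response_effect)) else
    numeric(cfg$n_tumor)
  a <- stats::uniroot(function(a)
    mean(stats::plogis(a + lp_slope)) - cfg$responder_target_fraction,
    c(-20, 20))$root
  p_resp <- stats::plogis(a + lp_slope)
  responder <- stats::runif(cfg$n_tumor) < p_resp
  recist <- ifelse(responder,
                   ifelse(stats::runif(cfg$n_tumor) < cfg$cr_fraction, "CR", "PR"),
                   ifelse(stats::runif(cfg$n_tumor) < cfg$sd_fraction, "SD", "PD"))

  histotype <- sample(c("adenocarcinoma", "squamous", "other"),
                      cfg$n_tumor, replace = TRUE, prob = c(0.4, 0.44, 0.16))
  anti_pd1 <- stats::rbinom(cfg$n_tumor, 1, 54 / 61)
  clinical <- data.frame(
    sample_id = tumors,
    histotype = histotype,
    recist = recist,
    pfs_months = pfs,
    event = event,
    anti_pd1 = anti_pd1,
    anti_pdl1 = 1L - anti_pd1,
    anti_ctla4 = stats::rbinom(cfg$n_tumor, 1, 11 / 61),
    sex = sample(c("F", "M"), cfg$n_tumor, replace = TRUE, prob = c(20, 41)),
    age = round(stats::runif(cfg$n_tumor, 41, 79)),
    stringsAsFactors = FALSE)

  # categorical features with planted odds ratios vs responder status
  cat_feats <- cfg$categorical_features
  cat_matrix <- NULL
  if (!is.null(cat_feats) && nrow(cat_feats) > 0) {
    cat_matrix <- matrix(0L, nrow(cat_feats), cfg$n_tumor,
                         dimnames = list(cat_feats$name, tumors))
    for (k in seq_len(nrow(cat_feats))) {
      p0 <- cat_feats$prevalence[k]
      p1 <- stats::plogis(stats::qlogis(p0) + log(cat_feats$odds_ratio[k]))
      p <- ifelse(responder, p1, p0)
      cat_matrix[k, ] <- as.integer(stats::runif(cfg$n_tumor) < p)
    }
  }

  # variant table: Poisson nonsynonymous load plus driver-gene rows coupled
  # to the planted mutation features
  n_mut <- stats::rpois(cfg$n_tumor, cfg$mutation_rate)
  variants <- do.call(rbind, lapply(seq_len(cfg$n_tumor), function(i) {
    g <- sample(genes, n_mut[i], replace = TRUE)
    data.frame(sample_id = tumors[i], gene = g,
               effect_class = sample(c("nonsynonymous", "synonymous", "other"),
                                     n_mut[i], replace = TRUE,
                                     prob = c(0.7, 0.25, 0.05)),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cat_matrix)) {
    mut_rows <- grep("^mut_", rownames(cat_matrix), value = TRUE)
    for (mr in mut_rows) {
      carriers <- tumors[cat_matrix[mr, ] == 1L]
      if (length(carriers))
        variants <- rbind(variants, data.frame(
          sample_id = carriers, gene = sub("^mut_", "", mr),
          effect_class = "nonsynonymous", stringsAsFactors = FALSE))
    }
  }
  variants <- variants[order(variants$sample_id, variants$gene), , drop = FALSE]
  rownames(variants) <- NULL

  # HLA table: two calls per locus per sample from a small vocabulary
  loci <- c("A", "B", "C", "DPB1", "DQB1", "DRB1")
  hla <- do.call(rbind, lapply(loci, function(l) {
    vocab <- paste0(l, "-", sprintf("%02d", 1:4))
    data.frame(sample_id = rep(tumors, each = 1),
               locus = l,
               allele1 = sample(vocab, cfg$n_tumor, replace = TRUE),
               allele2 = sample(vocab, cfg$n_tumor, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  hla <- hla[order(hla$sample_id, hla$locus), , drop = FALSE]
  rownames(hla) <- NULL

  pw <- simulate_pathways(cfg, reseed = FALSE)

  truth <- list(informative_genes = info,
                latent_markers = z,
                responder_probability = stats::setNames(p_resp, tumors),
                responder = stats::setNames(responder, tumors),
                categorical_features = cat_feats,
                logistic_intercept = a)

  structure(list(expression = expr, control_panel = ctrl,
                 clinical = clinical, pathways = pw$pathways,
                 interactome = pw$interactome, variants = variants,
                 hla = hla, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(paste0("<sim_cohort> %d tumors x %d genes, %d controls, ",
                     "%d pathways, seed %d\n"),
              ncol(x$expression), nrow(x$expression), ncol(x$control_panel),
              length(x$pathways), x$config$seed))
  invisible(x)
}

#' Simulate a pathway collection and merged interactome
#'
#' Pathway memberships are drawn from the gene universe with consecutive
#' pathways sharing one gene, so the merged interactome is connected on the
#' union of members. Each member is assigned an activator/repressor role
#' from \{-1, -0.5, 0, 0.5, 1\}; edges form a random spanning tree per
#' pathway plus extras, typed from the nine interaction labels.
#'
#' @param config a [sim_config()].
#' @param reseed set the seed from `config$seed` (disabled when called
#'   inside [simulate_cohort()], which manages the seed).
#' @return list with `pathways` (list of [pathway()]) and `interactome`.
#' @export
simulate_pathways <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (reseed) {
    restore <- set_local_seed(cfg$seed + 1L)
    on.exit(restore(), add = TRUE)
  }
  genes <- gene_ids(cfg)
  size_choices <- seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), cfg$n_pathways,
                                   replace = TRUE)]
  pathways <- vector("list", cfg$n_pathways)
  prev_member <- NULL
  for (i in seq_len(cfg$n_pathways)) {
    members <- sample(genes, sizes[i])
    if (!is.null(prev_member) && !prev_member %in% members)
      members[1] <- prev_member # chain overlap keeps the union connected
    prev_member <- members[length(members)]
    roles <- sample(c(-1, -0.5, 0, 0.5, 1), length(members), replace = TRUE,
                    prob = c(0.25, 0.10, 0.05, 0.10, 0.50))
    # spanning tree plus extra edges so each pathway graph is connected
    src <- tgt <- character(0)
    if (length(members) > 1) {
      perm <- sample(members)
      src <- perm[-length(perm)]; tgt <- perm[-1]
      n_extra <- max(0L, round(length(members) / 2))
      if (n_extra > 0) {
        es <- sample(members, n_extra, replace = TRUE)
        et <- sample(members, n_extra, replace = TRUE)
        keep <- es != et
        src <- c(src, es[keep]); tgt <- c(tgt, et[keep])
      }
    }
    edges <- if (length(src)) data.frame(
      source = src,
      type = sample(interaction_types, length(src), replace = TRUE),
      target = tgt, stringsAsFactors = FALSE) else NULL
    pathways[[i]] <- pathway(id = sprintf("PW%03d", i),
                             roles = stats::setNames(roles, members),
                             origin = "curated", edges = edges)
  }
  list(pathways = pathways, interactome = merge_interactome(pathways))
}

# Seed the RNG locally and return a restore function, so simulation never
# perturbs the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the standard exchange formats: counts and control panel as TSV,
#' clinical table as CSV, pathways as JSON and GMT (+roles sidecar),
#' interactome as SIF-like TSV, variants as TSV, HLA table as CSV, and the
#' configuration echo as JSON.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expr_tsv(cohort$expression, file.path(dir, "counts.tsv"))
  write_expr_tsv(cohort$control_panel, file.path(dir, "control_panel.tsv"))
  data.table::fwrite(cohort$clinical, file.path(dir, "clinical.csv"))
  write_pathways_json(cohort$pathways, file.path(dir, "pathways.json"))
  write_pathways_gmt(cohort$pathways, file.path(dir, "pathways.gmt"))
  write_interactome_sif(cohort$interactome, file.path(dir, "interactome.sif"))
  data.table::fwrite(cohort$variants, file.path(dir, "variants.tsv"), sep = "\t")
  data.table::fwrite(cohort$hla, file.path(dir, "hla.csv"))
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
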