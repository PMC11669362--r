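# Exome-derived biomarker features: tumor mutational burden, driver mutation
# flags, HLA presence/homozygosity features, and the published GEP and
# TMB+GEP signature values.

#' Tumor mutational burden per megabase
#'
#' TMB is the count of nonsynonymous variant rows per sample divided by the
#' captured exome size in megabases. "High" status requires TMB strictly
#' exceeding `cutoff` (10 mutations/Mb by convention).
#'
#' @param variants data.frame with columns `sample_id`, `gene`,
#'   `effect_class` (values `nonsynonymous`, `synonymous`, `other`).
#' @param capture_mb captured exome size in megabases; required, no default
#'   is assumed.
#' @param samples optional sample ids to report (zero-mutation samples
#'   otherwise absent from `variants` get TMB 0).
#' @param cutoff high/low boundary, default 10.
#' @return data.frame with columns `sample_id`, `tmb`, `high`.
#' @export
compute_tmb <- function(variants, capture_mb, samples = NULL, cutoff = 10) {
  if (!is.numeric(capture_mb) || length(capture_mb) != 1 || capture_mb <= 0)
    stop("capture_mb must be a single positive number")
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  ns <- variants[variants$effect_class == "nonsynonymous", , drop = FALSE]
  counts <- table(factor(ns$sample_id, levels = samples))
  tmb <- as.numeric(counts) / capture_mb
  data.frame(sample_id = samples, tmb = tmb, high = tmb > cutoff,
             stringsAsFactors = FALSE)
}

#' Driver-gene mutation flags
#'
#' @param variants as in [compute_tmb()].
#' @param genes genes to flag (default KRAS, STK11, POLE, PTEN).
#' @param samples sample ids to report.
#' @return binary matrix, genes x samples; 1 iff the sample carries at least
#'   one nonsynonymous variant in the gene.
#' @export
mutation_flags <- function(variants, genes = c("KRAS", "STK11", "POLE", "PTEN"),
                           samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  out <- matrix(0L, length(genes), length(samples),
                dimnames = list(paste0("mut_", genes), samples))
  ns <- variants[variants$effect_class == "nonsynonymous" &
                   variants$gene %in% genes, , drop = FALSE]
  ns <- ns[ns$sample_id %in% samples, , drop = FALSE]
  if (nrow(ns))
    out[cbind(match(paste0("mut_", ns$gene), rownames(out)),
              match(ns$sample_id, samples))] <- 1L
  out
}

#' HLA presence and homozygosity features
#'
#' Builds a binary feature matrix from typed HLA alleles: one presence
#' column per observed allele, a homozygosity flag per locus (both called
#' alleles identical), and - when a superfamily map is supplied - presence
#' and homozygosity per superfamily. Alleles absent from the map keep their
#' presence feature; only their superfamily columns are skipped, with a
#' warning.
#'
#' @param hla data.frame with columns `sample_id`, `locus`, `allele1`,
#'   `allele2`.
#' @param superfamily_map optional data.frame with columns `allele`,
#'   `superfamily`.
#' @return binary matrix, features x samples. Feature names:
#'   `hla_<allele>`, `hla_hom_<locus>`, `hla_sf_<superfamily>`,
#'   `hla_sf_hom_<superfamily>`.
#' @export
hla_features <- function(hla, superfamily_map = NULL) {
  samples <- sort(unique(hla$sample_id))
  alleles <- sort(unique(c(hla$allele1, hla$allele2)))
  loci <- sort(unique(hla$locus))
  feats <- list()
  pres <- matrix(0L, length(alleles), length(samples),
                 dimnames = list(paste0("hla_", alleles), samples))
  for (k in seq_len(nrow(hla))) {
    j <- match(hla$sample_id[k], samples)
    pres[paste0("hla_", hla$allele1[k]), j] <- 1L
    pres[paste0("hla_", hla$allele2[k]), j] <- 1L
  }
  feats$presence <- pres
  hom <- matrix(0L, length(loci), length(samples),
                dimnames = list(paste0("hla_hom_", loci), samples))
  hz <- hla$allele1 == hla$allele2
  hom[cbind(match(paste0("hla_hom_", hla$locus), rownames(hom)),
            match(hla$sample_id, samples))] <- as.integer(hz)
  feats$homozygosity <- hom
  if (!is.null(superfamily_map)) {
    unmapped <- setdiff(alleles, superfamily_map$allele)
    if (length(unmapped))
      warning("allele(s) missing from superfamily map, superfamily columns skipped: ",
              paste(utils::head(unmapped, 5), collapse = ", "))
    sf_of <- stats::setNames(superfamily_map$superfamily, superfamily_map$allele)
    sfs <- sort(unique(superfamily_map$superfamily))
    sfp <- matrix(0L, length(sfs), length(samples),
                  dimnames = list(paste0("hla_sf_", sfs), samples))
    sfh <- matrix(0L, length(sfs), length(samples),
                  dimnames = list(paste0("hla_sf_hom_", sfs), samples))
    for (k in seq_len(nrow(hla))) {
      j <- match(hla$sample_id[k], samples)
      s1 <- sf_of[hla$allele1[k]]; s2 <- sf_of[hla$allele2[k]]
      if (!is.na(s1)) sfp[paste0("hla_sf_", s1), j] <- 1L
      if (!is.na(s2)) sfp[paste0("hla_sf_", s2), j] <- 1L
      if (!is.na(s1) && !is.na(s2) && s1 == s2)
        sfh[paste0("hla_sf_hom_", s1), j] <- 1L
    }
    feats$superfamily <- sfp
    feats$superfamily_hom <- sfh
  }
  do.call(rbind, feats)
}

#' T-cell-inflamed gene expression profile (GEP) score
#'
#' Weighted sum of housekeeping-normalized log2 TPM values:
#' `sum_g w_g * (log2(TPM_g + 1) - mean_h log2(TPM_h + 1))` where h runs over
#' the housekeeping set. Weights and the housekeeping list are configuration
#' inputs (published externally, not bundled).
#'
#' @param tpm `expr_matrix` at stage `"tpm"`.
#' @param weights named numeric vector, gene -> weight.
#' @param housekeeping character vector of housekeeping gene ids.
#' @return named numeric vector of per-sample scores.
#' @export
gep_score <- function(tpm, weights, housekeeping) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (expr_stage(tpm) != "tpm") stop("GEP requires TPM input")
  m <- as_plain_matrix(tpm)
  missing <- setdiff(names(weights), rownames(m))
  if (length(missing))
    stop("weighted gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  missing_hk <- setdiff(housekeeping, rownames(m))
  if (length(missing_hk))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(missing_hk, collapse = ", "))
  l2 <- log2(m + 1)
  hk_mean <- colMeans(l2[housekeeping, , drop = FALSE])
  centered <- sweep(l2[names(weights), , drop = FALSE], 2, hk_mean)
  drop(crossprod(centered, weights))[colnames(m)]
}

#' Combined TMB + GEP category
#'
#' Concordant samples are classified `high_high` (TMB high and GEP above
#' threshold) or `low_low`; discordant samples are `mixed` and are excluded
#' from the two-group comparison downstream.
#'
#' @param tmb data.frame from [compute_tmb()].
#' @param gep named numeric GEP scores (names = sample ids).
#' @param gep_threshold GEP high/low boundary (typically the PFS-optimized
#'   threshold).
#' @return character vector named by sample id, values in
#'   \{"high_high", "low_low", "mixed"\}.
#' @export
tmb_gep_category <- function(tmb, gep, gep_threshold) {
  common <- intersect(tmb$sample_id, names(gep))
  t_high <- stats::setNames(tmb$high, tmb$sample_id)[common]
  g_high <- gep[common] > gep_threshold
  out <- ifelse(t_high & g_high, "high_high",
                ifelse(!t_high & !g_high, "low_low", "mixed"))
  stats::setNames(out, common)
}
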