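# Pathways with activator/repressor roles, interactome merging, gene-centric
# pathway construction, and pathway activation level (PAL) scoring.

#' The nine molecular interaction types
#'
#' Edge labels recognised in interactome edge lists.
#' @export
interaction_types <- c("activation", "coupling", "inhibition",
                       "phosphorylation", "dissociation", "repression",
                       "dephosphorylation", "binding/association",
                       "ubiquitination")

ARR_DOMAIN <- c(-1, -0.5, 0, 0.5, 1)

#' Construct a pathway
#'
#' A pathway is a mapping from member genes to activator/repressor roles
#' (ARR): -1 repressor, 1 activator, 0 both, +/-0.5 weak activator/repressor.
#'
#' @param id pathway identifier.
#' @param roles named numeric vector, gene -> ARR value in
#'   \{-1, -0.5, 0, 0.5, 1\}.
#' @param origin `"curated"` or `"gene_centric"`.
#' @param center center gene for gene-centric pathways (otherwise `NA`).
#' @param edges optional data.frame of typed edges (`source`, `type`,
#'   `target`) among the member genes, used when merging into an interactome.
#' @return object of class `pathway`.
#' @export
pathway <- function(id, roles, origin = c("curated", "gene_centric"),
                    center = NA_character_, edges = NULL) {
  origin <- match.arg(origin)
  if (length(roles) == 0) stop("pathway roles must be non-empty")
  if (is.null(names(roles))) stop("roles must be a named vector (gene -> ARR)")
  if (!all(roles %in% ARR_DOMAIN))
    stop("ARR values must be in {-1, -0.5, 0, 0.5, 1}")
  if (!is.null(edges)) edges <- validate_edges(edges)
  structure(list(id = id, roles = roles, origin = origin, center = center,
                 edges = edges),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s (%s): %d genes\n", x$id,
              if (x$origin == "gene_centric") paste0("centered on ", x$center)
              else x$origin,
              length(x$roles)))
  invisible(x)
}

validate_edges <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "type", "target") %in% names(edges)))
  bad <- setdiff(unique(edges$type), interaction_types)
  if (length(bad))
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "))
  edges[c("source", "type", "target")]
}

#' Merge pathway graphs into a single interactome
#'
#' Takes the union of the typed edges of all input pathways, deduplicates by
#' (source, type, target), and restricts the graph to its largest connected
#' component so that any two retained gene products are linked.
#'
#' @param pathways list of [pathway()] objects carrying `edges`.
#' @return object of class `interactome`: list with `nodes` and `edges`.
#' @export
merge_interactome <- function(pathways) {
  if (length(pathways) == 0) stop("no pathways to merge")
  edge_list <- lapply(pathways, function(p) {
    if (is.null(p$edges)) stop("pathway '", p$id, "' has no edge annotations")
    p$edges
  })
  edges <- unique(do.call(rbind, edge_list))
  g <- igraph::graph_from_data_frame(edges[c("source", "target")],
                                     directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  edges <- edges[edges$source %in% keep & edges$target %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(keep), edges = edges), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d nodes, %d typed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Default mapping from interaction type to activator/repressor role
#'
#' Activating chemistry (activation, phosphorylation) maps to +1; inhibitory
#' chemistry (inhibition, repression, dephosphorylation, ubiquitination) to
#' -1; neutral physical association (coupling, binding/association,
#' dissociation) to +0.5, treated as weak activation. The table is an
#' argument of [build_gene_centric_pathway()] so alternatives are testable.
#'
#' @return named numeric vector, interaction type -> role.
#' @export
default_edge_roles <- function() {
  c(activation = 1, phosphorylation = 1,
    inhibition = -1, repression = -1, dephosphorylation = -1,
    ubiquitination = -1,
    coupling = 0.5, "binding/association" = 0.5, dissociation = 0.5)
}

#' Build a gene-centric pathway around a center gene
#'
#' Members are the center plus all nodes within `radius` hops (edge direction
#' ignored for reachability). Each member's ARR is derived from the types of
#' its edges toward the center: the types of all edges linking the member to
#' any node one hop closer to the center are mapped through `edge_roles`; if
#' both positive and negative roles occur the member gets 0, otherwise the
#' largest-magnitude role with the common sign. The center gene itself is an
#' activator (+1).
#'
#' @param net an `interactome` from [merge_interactome()].
#' @param center gene identifier, must be a node of `net`.
#' @param radius hop count (default 1 = direct interactors).
#' @param edge_roles type -> role table, default [default_edge_roles()].
#' @return a [pathway()] with origin `"gene_centric"`.
#' @export
build_gene_centric_pathway <- function(net, center, radius = 1,
                                       edge_roles = default_edge_roles()) {
  stopifnot(inherits(net, "interactome"))
  if (!center %in% net$nodes)
    stop("center gene '", center, "' is not in the interactome")
  g <- igraph::graph_from_data_frame(net$edges[c("source", "target")],
                                     directed = TRUE,
                                     vertices = net$nodes)
  dist <- igraph::distances(g, v = center, mode = "all")[1, ]
  members <- names(dist)[is.finite(dist) & dist <= radius]
  roles <- stats::setNames(numeric(length(members)), members)
  for (m in members) {
    if (m == center) { roles[m] <- 1; next }
    # nodes one hop closer to the center than m
    closer <- names(dist)[is.finite(dist) & dist == dist[m] - 1]
    sel <- (net$edges$source == m & net$edges$target %in% closer) |
           (net$edges$target == m & net$edges$source %in% closer)
    r <- unname(edge_roles[net$edges$type[sel]])
    r <- r[!is.na(r)]
    roles[m] <- combine_edge_roles(r)
  }
  pathway(id = paste0("centric_", center), roles = roles,
          origin = "gene_centric", center = center)
}

combine_edge_roles <- function(r) {
  if (length(r) == 0) return(0)
  if (any(r > 0) && any(r < 0)) return(0)
  if (all(r == 0)) return(0)
  s <- sign(sum(r))
  s * max(abs(r))
}

#' Pathway activation level (PAL)
#'
#' PAL of pathway p is the signed sum over member genes of
#' ARR x BTIF x ln(CNR): positive for net upregulation relative to the
#' control panel, negative for downregulation, zero when no member gene
#' deviates significantly.
#'
#' @param p a [pathway()].
#' @param activity data.frame from [gene_activity()] (columns `gene`, `cnr`,
#'   `btif`). Pathway genes absent from `activity` are skipped with a
#'   message (profiles routinely drop genes); non-positive CNR is an error.
#' @return list with `id`, `pal`, `n_contributing` (genes with btif = 1 that
#'   entered the sum).
#' @export
compute_pal <- function(p, activity) {
  stopifnot(inherits(p, "pathway"))
  idx <- match(names(p$roles), activity$gene)
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(p$id, ": ", dropped, " pathway gene(s) absent from activity vector, skipped")
  keep <- !is.na(idx)
  cnr <- activity$cnr[idx[keep]]
  btif <- activity$btif[idx[keep]]
  arr <- p$roles[keep]
  if (any(cnr <= 0)) stop("non-positive CNR for pathway gene")
  pal <- sum(arr * btif * log(cnr))
  list(id = p$id, pal = pal, n_contributing = sum(btif == 1))
}

#' PAL matrix for a pathway collection over many samples
#'
#' @param pathways list of [pathway()] objects.
#' @param norm_samples `expr_matrix` of normalized tumor samples
#'   (pseudo-counted).
#' @param controls `expr_matrix` of the normalized control panel.
#' @param alpha BTIF significance level.
#' @return numeric matrix, pathways x samples.
#' @export
pal_matrix <- function(pathways, norm_samples, controls, alpha = 0.05) {
  ids <- vapply(pathways, function(p) p$id, character(1))
  out <- matrix(NA_real_, length(pathways), ncol(norm_samples),
                dimnames = list(ids, colnames(norm_samples)))
  for (j in seq_len(ncol(norm_samples))) {
    sample <- stats::setNames(as_plain_matrix(norm_samples)[, j],
                              rownames(norm_samples))
    act <- gene_activity(sample, controls, alpha = alpha)
    for (i in seq_along(pathways))
      out[i, j] <- suppressMessages(compute_pal(pathways[[i]], act)$pal)
  }
  out
}

#' Group-averaged PAL
#'
#' PAL of an averaged group profile: normalized expression is averaged across
#' the group's samples before CNR/BTIF, rather than averaging per-sample PALs.
#'
#' @param p a [pathway()].
#' @param norm_samples `expr_matrix` of the group's normalized samples.
#' @param controls normalized control panel.
#' @param alpha BTIF significance level.
#' @return as [compute_pal()].
#' @export
compute_group_pal <- function(p, norm_samples, controls, alpha = 0.05) {
  avg <- rowMeans(as_plain_matrix(norm_samples))
  act <- gene_activity(avg, controls, alpha = alpha)
  compute_pal(p, act)
}

# ---- serialization ---------------------------------------------------------

#' Read / write pathway collections and interactomes
#'
#' JSON layout: a list of objects `{id, origin, center, roles: {gene: arr},
#' edges: [{source, type, target}]}`. The SIF-like interactome format is a
#' 3-column TSV (source, type, target). The GMT writer emits standard GMT
#' (id, description, genes...) plus a `<path>.roles` sidecar TSV with columns
#' pathway, gene, arr.
#'
#' @param pathways list of [pathway()] objects.
#' @param path file path.
#' @name pathway_io
#' @return readers return the parsed objects; writers return `path`
#'   invisibly.
NULL

#' @rdname pathway_io
#' @export
write_pathways_json <- function(pathways, path) {
  obj <- lapply(pathways, function(p) {
    list(id = p$id, origin = p$origin, center = p$center,
         roles = as.list(p$roles),
         edges = if (is.null(p$edges)) NULL else p$edges)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pathway_io
#' @export
read_pathways_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(o) {
    edges <- if (!is.null(o$edges))
      do.call(rbind, lapply(o$edges, function(e)
        data.frame(source = e$source, type = e$type, target = e$target,
                   stringsAsFactors = FALSE)))
    pathway(id = o$id, roles = unlist(o$roles), origin = o$origin,
            center = if (is.null(o$center) || is.na(o$center)) NA_character_
                     else o$center,
            edges = edges)
  })
}

#' @rdname pathway_io
#' @export
write_pathways_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$id, p$origin, names(p$roles)), collapse = "\t"), character(1))
  writeLines(lines, path)
  roles <- do.call(rbind, lapply(pathways, function(p)
    data.frame(pathway = p$id, gene = names(p$roles), arr = unname(p$roles),
               stringsAsFactors = FALSE)))
  data.table::fwrite(roles, paste0(path, ".roles"), sep = "\t")
  invisible(path)
}

#' @rdname pathway_io
#' @param net an `interactome`.
#' @export
write_interactome_sif <- function(net, path) {
  data.table::fwrite(net$edges, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname pathway_io
#' @export
read_interactome_sif <- function(path) {
  edges <- data.table::fread(path, sep = "\t", header = FALSE,
                             col.names = c("source", "type", "target"),
                             data.table = FALSE)
  edges <- validate_edges(edges)
  structure(list(nodes = sort(unique(c(edges$source, edges$target))),
                 edges = edges),
            class = "interactome")
}
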