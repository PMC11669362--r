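toy_pathway <- function(id, genes, roles, edges = NULL)
  pathway(id, setNames(roles, genes), edges = edges)

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], type = m[, 2], target = m[, 3],
             stringsAsFactors = FALSE)
}

test_that("pathway construction enforces the ARR domain", {
  expect_error(toy_pathway("p", "a", 0.3), "ARR")
  expect_error(pathway("p", numeric(0)), "non-empty")
  p <- toy_pathway("p", c("a", "b"), c(1, -0.5))
  expect_identical(p$origin, "curated")
})

test_that("merge_interactome unions, deduplicates, keeps largest component", {
  p1 <- toy_pathway("p1", c("a", "b"), c(1, 1),
                    edges = edge_df("a", "activation", "b"))
  p2 <- toy_pathway("p2", c("b", "c"), c(1, -1),
                    edges = edge_df("b", "inhibition", "c",
                                    "a", "activation", "b")) # duplicate edge
  net <- merge_interactome(list(p1, p2))
  expect_setequal(net$nodes, c("a", "b", "c"))
  expect_equal(nrow(net$edges), 2)
  # disjoint smaller component dropped
  p3 <- toy_pathway("p3", c("x", "y"), c(1, 1),
                    edges = edge_df("x", "coupling", "y"))
  net2 <- merge_interactome(list(p1, p2, p3))
  expect_setequal(net2$nodes, c("a", "b", "c"))
  # idempotence: merging a collection with itself is a no-op
  net3 <- merge_interactome(list(p1, p2, p1, p2))
  expect_identical(net3$edges, net$edges)
  expect_error(merge_interactome(list()), "no pathways")
})

test_that("gene-centric construction maps edge types to roles", {
  edges <- edge_df("a1", "activation", "ctr",
                   "a2", "phosphorylation", "ctr",
                   "a3", "activation", "ctr",
                   "i1", "inhibition", "ctr",
                   "ctr", "repression", "i2",
                   "w1", "binding/association", "ctr",
                   "m1", "activation", "ctr",
                   "m1", "inhibition", "ctr")
  net <- structure(list(nodes = sort(unique(c(edges$source, edges$target))),
                        edges = edges), class = "interactome")
  p <- build_gene_centric_pathway(net, "ctr")
  expect_identical(p$origin, "gene_centric")
  expect_identical(p$center, "ctr")
  expect_equal(p$roles[["ctr"]], 1)   # center is an activator
  expect_equal(unname(p$roles[c("a1", "a2", "a3")]), c(1, 1, 1))
  expect_equal(unname(p$roles[c("i1", "i2")]), c(-1, -1))
  expect_equal(p$roles[["w1"]], 0.5)  # weak association
  expect_equal(p$roles[["m1"]], 0)    # mixed signs
  expect_error(build_gene_centric_pathway(net, "absent"), "absent")
})

test_that("gene-centric membership equals brute-force BFS on random graphs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    nodes <- paste0("n", seq_len(n))
    m <- sample(n:(3 * n), 1)
    edges <- data.frame(
      source = sample(nodes, m, replace = TRUE),
      type = sample(interaction_types, m, replace = TRUE),
      target = sample(nodes, m, replace = TRUE),
      stringsAsFactors = FALSE)
    edges <- edges[edges$source != edges$target, , drop = FALSE]
    if (nrow(edges) == 0) next
    net <- structure(list(nodes = nodes, edges = edges), class = "interactome")
    center <- sample(unique(c(edges$source, edges$target)), 1)
    radius <- sample(1:3, 1)
    p <- build_gene_centric_pathway(net, center, radius = radius)
    expect_identical(sort(names(p$roles)),
                     oracle_bfs_members(edges, center, radius))
  }
})

test_that("isolated center yields a pathway of size one", {
  edges <- edge_df("a", "activation", "b")
  net <- structure(list(nodes = c("a", "b", "lone"), edges = edges),
                   class = "interactome")
  p <- build_gene_centric_pathway(net, "lone")
  expect_identical(names(p$roles), "lone")
})

test_that("PAL matches the hand-evaluated formula", {
  act <- data.frame(gene = c("A", "B", "C"), cnr = c(2, 0.5, 4),
                    btif = c(1L, 1L, 1L))
  p <- toy_pathway("p", c("A", "B", "C"), c(1, -1, 0.5))
  expect_equal(compute_pal(p, act)$pal, 3 * log(2), tolerance = 1e-12)
  expect_equal(compute_pal(p, act)$pal, 2.0794, tolerance = 1e-4)
  # all flags zero -> PAL 0; single activator at cnr = e -> 1
  act0 <- transform(act, btif = 0L)
  expect_equal(compute_pal(p, act0)$pal, 0)
  expect_equal(compute_pal(p, act0)$n_contributing, 0)
  pe <- toy_pathway("pe", "A", 1)
  expect_equal(compute_pal(pe, data.frame(gene = "A", cnr = exp(1),
                                          btif = 1L))$pal, 1)
  expect_error(compute_pal(p, transform(act, cnr = c(2, -1, 4))),
               "non-positive")
  expect_message(compute_pal(toy_pathway("px", c("A", "ZZ"), c(1, 1)), act),
                 "skipped")
})

test_that("PAL linearity, sign-flip and scale properties hold", {
  set.seed(99)
  for (rep in 1:25) {
    ng <- sample(3:30, 1)
    genes <- paste0("g", seq_len(ng))
    act <- data.frame(gene = genes, cnr = exp(rnorm(ng)),
                      btif = rbinom(ng, 1, 0.6))
    roles <- sample(c(-1, -0.5, 0, 0.5, 1), ng, replace = TRUE)
    p <- toy_pathway("p", genes, roles)
    pal <- compute_pal(p, act)$pal
    # partition additivity
    cut <- sample(ng - 1, 1)
    p1 <- toy_pathway("p1", genes[1:cut], roles[1:cut])
    p2 <- toy_pathway("p2", genes[-(1:cut)], roles[-(1:cut)])
    expect_equal(compute_pal(p1, act)$pal + compute_pal(p2, act)$pal, pal,
                 tolerance = 1e-12)
    # sign flip
    expect_equal(compute_pal(toy_pathway("pn", genes, -roles), act)$pal, -pal,
                 tolerance = 1e-12)
    # scale: multiplying CNR by c adds (sum ARR*BTIF) * log(c)
    cc <- exp(runif(1, -1, 1))
    act2 <- transform(act, cnr = cnr * cc)
    expect_equal(compute_pal(p, act2)$pal,
                 pal + sum(roles * act$btif) * log(cc), tolerance = 1e-10)
  }
})

test_that("group PAL averages expression before CNR", {
  ctrl <- expr_matrix(matrix(c(2, 4, 8, 4), 2,
                             dimnames = list(c("A", "B"), c("n1", "n2"))),
                      "normalized")
  grp <- expr_matrix(matrix(c(2, 4, 14, 4), 2,
                            dimnames = list(c("A", "B"), c("t1", "t2"))),
                     "normalized")
  p <- toy_pathway("p", c("A", "B"), c(1, 1))
  res <- compute_group_pal(p, grp, ctrl, alpha = 0.5)
  # average profile (8, 4) vs geomeans (4, 4)
  avg <- c(A = 8, B = 4)
  act <- gene_activity(avg, ctrl, alpha = 0.5)
  expect_equal(res$pal, compute_pal(p, act)$pal)
})

test_that("pathway JSON / GMT / SIF round-trips preserve structure", {
  p1 <- toy_pathway("p1", c("a", "b"), c(1, -0.5),
                    edges = edge_df("a", "activation", "b"))
  p2 <- build_gene_centric_pathway(
    merge_interactome(list(p1)), "a")
  path <- withr::local_tempfile(fileext = ".json")
  write_pathways_json(list(p1, p2), path)
  back <- read_pathways_json(path)
  expect_equal(back[[1]]$roles, p1$roles)
  expect_equal(back[[1]]$edges, p1$edges)
  expect_identical(back[[2]]$origin, "gene_centric")
  expect_identical(back[[2]]$center, "a")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_pathways_gmt(list(p1), gmt)
  expect_match(readLines(gmt)[1], "^p1\tcurated\ta\tb$")
  sif <- withr::local_tempfile(fileext = ".sif")
  net <- merge_interactome(list(p1))
  write_interactome_sif(net, sif)
  expect_equal(read_interactome_sif(sif)$edges, net$edges)
})
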