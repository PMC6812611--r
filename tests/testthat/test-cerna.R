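test_that("target/DE intersection is an exact set intersection", {
  expect_identical(intersectTargets(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  expect_identical(intersectTargets(c("A"), c("B")), character(0))
  expect_identical(intersectTargets(c("B", "A"), c("C", "A", "B", "D")),
                   c("A", "B"))
})

test_that("ceRNA p-value matches enumeration and handles degenerate cases", {
  expect_identical(cernaPvalue(0, 5, 5, 20), 1)
  expect_identical(cernaPvalue(4, 4, 4, 4), 1)
  expect_equal(cernaPvalue(3, 5, 5, 20), enumCernaTail(3, 5, 5, 20),
               tolerance = 1e-12)
  expect_error(cernaPvalue(6, 5, 5, 20), "exceeds")
  expect_error(cernaPvalue(1, 21, 5, 20), "exceed N")
})

test_that("ceRNA p-value is non-increasing in the shared count", {
  for (cfg in list(c(K = 6, n = 5, N = 15), c(K = 10, n = 8, N = 30))) {
    p <- vapply(0:min(cfg["K"], cfg["n"]), function(cc)
      cernaPvalue(cc, cfg[["K"]], cfg[["n"]], cfg[["N"]]), 0)
    expect_true(all(diff(p) <= 1e-14))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("Pearson edges reproduce textbook r and p", {
  x <- c(1, 2, 3, 4, 5)
  e <- pearsonEdge(x, 2 * x + 1)
  expect_equal(e$r, 1)
  expect_equal(e$p_value, 0)
  expect_equal(pearsonEdge(x, -x)$r, -1)

  y <- c(2, 1, 4, 3, 6)
  e2 <- pearsonEdge(x, y, idA = "c1", idB = "g1")
  # recompute from the definition
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((5 - 2) / (1 - r^2))
  expect_equal(e2$r, r, tolerance = 1e-12)
  expect_equal(e2$p_value, 2 * pt(abs(tt), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(e2$n_samples, 5L)
  expect_error(pearsonEdge(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearsonEdge(1:2, 1:2), "at least 3")
})

test_that("null Pearson p-values are uniform at the tail", {
  set.seed(99)
  p <- replicate(1000, pearsonEdge(rnorm(6), rnorm(6))$p_value)
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

simpleMre <- data.frame(circ_id = "c1", rank = 1:2,
                        mirna_id = c("m1", "m2"),
                        stringsAsFactors = FALSE)

test_that("network assembly wires circRNA->miRNA->mRNA and counts match", {
  targets <- list(m1 = c("g1"), m2 = c("g2"))
  net <- buildNetwork(simpleMre, targets, deGenes = c("g1", "g2"))
  nn <- networkNodes(net); ne <- networkEdges(net)
  expect_equal(table(nn$node_type)[c("circRNA", "miRNA", "mRNA")],
               c(circRNA = 1, miRNA = 2, mRNA = 2), ignore_attr = TRUE)
  expect_equal(sum(ne$edge_type == "sponges"), 2)
  expect_equal(sum(ne$edge_type == "targets"), 2)

  # empty DE set: only circ (and optionally leaf miRNAs) remain
  net0 <- buildNetwork(simpleMre, targets, deGenes = character(),
                       keepLeafMirnas = TRUE)
  nn0 <- networkNodes(net0)
  expect_equal(sum(nn0$node_type == "mRNA"), 0)
  expect_equal(sum(nn0$node_type == "miRNA"), 2)
  expect_equal(sum(networkEdges(net0)$edge_type == "targets"), 0)
  netDrop <- buildNetwork(simpleMre, targets, deGenes = character())
  expect_equal(sum(networkNodes(netDrop)$node_type == "miRNA"), 0)

  expect_error(buildNetwork(simpleMre, list(m1 = "g1"), "g1"), "m2")
})

test_that("correlation and ceRNA filters prune failing gene reaches", {
  targets <- list(m1 = c("g1", "g2"), m2 = c("g1"))
  corr <- data.frame(circ_id = "c1", gene_id = c("g1", "g2"),
                     r = c(0.99, 0.10), p_value = c(0.001, 0.8))
  net <- buildNetwork(simpleMre, targets, deGenes = c("g1", "g2"),
                      correlationFilter = corr)
  nn <- networkNodes(net)
  expect_true("g1" %in% nn$node_id)
  expect_false("g2" %in% nn$node_id)

  # hypergeometric filter: with N=4, K=2, n=2, c=2 -> p = 1/6 < 0.25
  netH <- buildNetwork(simpleMre, targets, deGenes = c("g1", "g2"),
                       nMirnaUniverse = 4, useCernaFilter = TRUE,
                       cernaAlpha = 0.25)
  expect_true("g1" %in% networkNodes(netH)$node_id)  # c=2: p=1/6
  expect_false("g2" %in% networkNodes(netH)$node_id) # c=1: p=1-C(2,2)/C(4,2)
})

test_that("degree summary splits miRNA degree and satisfies handshake", {
  targets <- list(m1 = c("g1", "g2", "g3", "g4"), m2 = "g1")
  net <- buildNetwork(simpleMre, targets,
                      deGenes = c("g1", "g2", "g3", "g4"))
  deg <- degreeSummary(net)
  expect_equal(deg$degree_mrna[deg$node_id == "m1"], 4)
  expect_equal(deg$degree[deg$node_id == "c1"], 2)
  expect_equal(sum(deg$degree), 2 * nrow(networkEdges(net)))
})

test_that("functional-module extraction keeps only module genes and labels them", {
  targets <- list(m1 = c("g1", "g2"), m2 = c("g3"))
  net <- buildNetwork(simpleMre, targets, deGenes = c("g1", "g2", "g3"))
  catalog <- list(survival = c("g1"), neuron = c("g3"), channel = c("zz"))
  sub <- extractFunctionalModule(net, catalog, names(catalog))
  nn <- networkNodes(sub)
  expect_setequal(nn$node_id[nn$node_type == "mRNA"], c("g1", "g3"))
  expect_identical(nn$module[nn$node_id == "g1"], "survival")
  expect_identical(nn$module[nn$node_id == "g3"], "neuron")
  expect_true(all(c("m1", "m2", "c1") %in% nn$node_id))

  # no module genes in network -> mRNA layer empties
  none <- extractFunctionalModule(net, list(s = "absent"), "s")
  expect_equal(sum(networkNodes(none)$node_type == "mRNA"), 0)
  # all genes -> identity on the mRNA layer
  all3 <- extractFunctionalModule(net, list(s = c("g1", "g2", "g3")), "s")
  expect_equal(sum(networkNodes(all3)$node_type == "mRNA"), 3)
  expect_error(extractFunctionalModule(net, catalog, "nope"), "nope")
})

test_that("tripartiteness is enforced by the class validator", {
  nodes <- data.frame(node_id = c("c1", "m1", "g1"),
                      node_type = c("circRNA", "miRNA", "mRNA"),
                      direction = c("up", "n/a", "down"))
  expect_error(cernaNetwork(nodes, data.frame(
    from = "c1", to = "g1", edge_type = "targets")), "miRNA")
  expect_error(cernaNetwork(nodes, data.frame(
    from = "m1", to = "c1", edge_type = "sponges")), "circRNA")
  expect_error(cernaNetwork(nodes, data.frame(
    from = "c1", to = "mX", edge_type = "sponges")), "unknown")
})
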