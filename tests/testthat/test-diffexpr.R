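makeExpr <- function(x, groups = NULL, flags = NULL, scale = "linear") {
  if (is.null(groups)) {
    half <- ncol(x) %/% 2
    groups <- stats::setNames(
      rep(c("control", "treated"), c(ncol(x) - half, half)), colnames(x))
  }
  CernaExpression(x, groups, flags = flags, scale = scale)
}

test_that("quantile normalization equalizes distributions by rank", {
  x <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(x) <- paste0("p", 1:3)
  qn <- intensities(quantileNormalize(makeExpr(x)))
  expect_equal(unname(qn[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "s2"]), c(2.5, 3.5, 4.5))

  # identical value multisets are a fixed point up to reordering
  x2 <- cbind(s1 = c(5, 1, 9), s2 = c(9, 5, 1))
  rownames(x2) <- paste0("p", 1:3)
  qn2 <- intensities(quantileNormalize(makeExpr(x2)))
  expect_equal(apply(qn2, 2, sort), apply(x2, 2, sort),
               ignore_attr = TRUE)
  expect_equal(unname(qn2[, "s1"]), c(5, 1, 9))

  # two-way tie takes the mean of the two reference quantiles
  x3 <- cbind(s1 = c(1, 1, 3), s2 = c(4, 5, 6))
  rownames(x3) <- paste0("p", 1:3)
  qn3 <- intensities(quantileNormalize(makeExpr(x3)))
  ref <- rowMeans(apply(x3, 2, sort))   # 2.5, 3.0, 4.5
  expect_equal(unname(qn3[, "s1"]),
               unname(c(mean(ref[1:2]), mean(ref[1:2]), ref[3])))

  expect_error(quantileNormalize(makeExpr(
    matrix(1:3, 3, 1, dimnames = list(paste0("p", 1:3), "s1")),
    groups = c(s1 = "control"))), "2 samples")
})

test_that("quantile normalization matches a first-principles oracle", {
  set.seed(7)
  x <- matrix(runif(200, 1, 100), 40, 5,
              dimnames = list(sprintf("p%02d", 1:40), paste0("s", 1:5)))
  qn <- intensities(quantileNormalize(makeExpr(x)))
  expect_equal(qn, naiveQuantileNormalize(x), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("detection filter keeps exactly probes with enough P/M calls", {
  x <- matrix(10, 3, 4, dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  f <- rbind(c("P", "P", "M", "A"),
             c("A", "A", "A", "A"),
             c("P", "A", "A", "A"))
  dimnames(f) <- dimnames(x)
  ce <- makeExpr(x, flags = f)
  expect_identical(rownames(detectionFilter(ce, 3)), "p1")
  expect_identical(rownames(detectionFilter(ce, 1)), c("p1", "p3"))
  expect_identical(rownames(detectionFilter(ce, 0)), rownames(x))
  expect_error(detectionFilter(ce, 5), "exceeds")
})

test_that("differential expression computes gate, direction and p-values", {
  set.seed(11)
  ctrl <- matrix(8, 4, 3) + rnorm(12, 0, 1e-3)
  trt <- matrix(9.17, 4, 3) + rnorm(12, 0, 1e-3)
  x <- cbind(ctrl, trt)
  dimnames(x) <- list(paste0("p", 1:4), paste0("s", 1:6))
  x[4, ] <- 8  # identical in both groups
  ce <- makeExpr(x, scale = "log2")
  de <- differentialExpression(ce, controlGroup = "control")
  expect_equal(de$fold_change[1:3], rep(2^1.17, 3), tolerance = 1e-2)
  expect_true(all(de$direction[1:3] == "up"))
  expect_true(all(de$significant[1:3]))
  expect_equal(de$fold_change[4], 1)
  expect_false(de$significant[4])

  # p-values match t.test on each probe (pooled and Welch)
  for (welch in c(FALSE, TRUE)) {
    deW <- differentialExpression(ce, welch = welch,
                                  controlGroup = "control")
    pRef <- apply(x[1:3, ], 1, function(v)
      t.test(v[4:6], v[1:3], var.equal = !welch)$p.value)
    expect_equal(deW$p_value[1:3], unname(pRef), tolerance = 1e-12)
  }
  expect_error(differentialExpression(ce[, 1:3]), "two groups")
})

test_that("the significance gate is strict at both thresholds", {
  x <- cbind(matrix(2, 2, 3), matrix(2 * 1.5, 2, 3))
  dimnames(x) <- list(c("pA", "pB"), paste0("s", 1:6))
  ce <- makeExpr(x)
  de <- differentialExpression(ce, controlGroup = "control")
  expect_equal(de$fold_change, c(1.5, 1.5))
  expect_true(all(de$p_value < 0.05))
  expect_false(any(de$significant))  # FC must exceed 1.5 strictly
  # independent re-check of the gate over a random DE table
  set.seed(3)
  xr <- matrix(2^rnorm(600, 8, 1), 50, 12,
               dimnames = list(sprintf("p%02d", 1:50), paste0("s", 1:12)))
  der <- differentialExpression(makeExpr(xr))
  expect_identical(der$significant,
                   der$fold_change > 1.5 & der$p_value < 0.05)
  expect_identical(der$direction,
                   ifelse(der$mean_treated > der$mean_control, "up", "down"))
})

test_that("circRNA type summaries count significant probes by direction", {
  de <- data.frame(probe_id = c("c1", "c2", "c3", "c4"),
                   direction = c("up", "up", "down", "up"),
                   significant = c(TRUE, TRUE, TRUE, FALSE))
  ann <- data.frame(probe_id = c("c1", "c2", "c3", "c4"),
                    circ_type = c("exonic", "exonic", "intronic", "exonic"),
                    chromosome = c("chr1", "chr2", "chr1", "chr3"))
  ts <- summarizeCircTypes(de, ann)
  expect_equal(ts$counts_by_type["up", "exonic"], 2, ignore_attr = TRUE)
  expect_equal(ts$counts_by_type["down", "intronic"], 1, ignore_attr = TRUE)
  expect_equal(sum(ts$counts_by_type), 3)
  expect_equal(ts$counts_by_chromosome["up", "chr2"], 1, ignore_attr = TRUE)

  none <- summarizeCircTypes(de[de$probe_id == "c4", ], ann)
  expect_equal(sum(none$counts_by_type), 0)
  expect_error(summarizeCircTypes(de, ann[-1, ]), "c1")
})

test_that("hierarchical ordering groups correlated profiles together", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
             c = c(4, 3, 2, 1), d = c(9, 1, 8, 2))
  colnames(x) <- paste0("s", 1:4)
  ce <- makeExpr(2^x)
  ord <- hierarchicalClusterOrder(ce, axis = "probes")
  expect_setequal(ord, rownames(x))
  # a and b are perfectly correlated: adjacent leaves
  expect_equal(abs(diff(match(c("a", "b"), ord))), 1)
  # permuting rows leaves the order invariant (deterministic tie-breaks)
  ce2 <- makeExpr(2^x[c(3, 1, 4, 2), ])
  expect_identical(hierarchicalClusterOrder(ce2, axis = "probes"), ord)
})
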