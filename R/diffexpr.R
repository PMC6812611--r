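#' @importFrom stats pt p.adjust cor hclust as.dendrogram order.dendrogram
#'   setNames quantile rnorm runif var sd
NULL

#' Quantile-normalize an expression matrix
#'
#' Classic rank-wise quantile normalization: each sample's values are replaced
#' by the across-sample mean of the order statistics at the corresponding
#' rank, so that all samples share one intensity distribution. Ties within a
#' sample receive the mean of the tied ranks' reference values (the standard
#' microarray tie convention). Delegates to [limma::normalizeQuantiles()]
#' behind this interface.
#'
#' @param object a linear-scale [CernaExpression-class] with at least two
#'   samples.
#' @return a [CernaExpression-class] with normalized intensities; flags,
#'   groups and scale tag are preserved.
#' @export
quantileNormalize <- function(object) {
  stopifnot(is(object, "CernaExpression"))
  if (ncol(object) < 2)
    stop("quantile normalization needs at least 2 samples")
  x <- limma::normalizeQuantiles(intensities(object), ties = TRUE)
  dimnames(x) <- dimnames(intensities(object))
  CernaExpression(x, sampleGroups(object), flags = detectionFlags(object),
                  scale = intensityScale(object))
}

#' Filter probes on detection flags
#'
#' Retains exactly the probes whose count of `P` or `M` detection calls
#' across all samples reaches `minPresent` — the classic "present in at least
#' k of n samples" filter applied between normalization and differential
#' expression.
#'
#' @param object a [CernaExpression-class].
#' @param minPresent minimum number of samples flagged `P`/`M`; 0 keeps all.
#' @return the filtered [CernaExpression-class].
#' @export
detectionFilter <- function(object, minPresent) {
  stopifnot(is(object, "CernaExpression"))
  minPresent <- as.integer(minPresent)
  if (minPresent < 0) stop("minPresent must be >= 0")
  if (minPresent > ncol(object))
    stop("minPresent (", minPresent, ") exceeds sample count (",
         ncol(object), ")")
  f <- detectionFlags(object)
  keep <- rowSums(matrix(f %in% c("P", "M"), nrow(f))) >= minPresent
  object[keep, ]
}

.asLog2 <- function(object) {
  x <- intensities(object)
  if (intensityScale(object) == "linear") {
    if (any(x <= 0)) stop("non-positive linear intensities cannot be logged")
    x <- log2(x)
  }
  x
}

#' Two-group differential expression with the FC/P gate
#'
#' Per probe: group means on the log2 scale, a linear fold change
#' `2^|mean_treated - mean_control|` (always >= 1, with a `direction`
#' column), a two-sided unpaired t-test p-value (pooled-variance Student by
#' default, Welch optionally) and Benjamini-Hochberg adjusted p-values
#' (reported alongside, not used for the gate). A probe is `significant` iff
#' strictly `fold_change > fcThreshold` and `p_value < pThreshold`.
#'
#' @param object a normalized [CernaExpression-class] with exactly two
#'   groups, each of size >= 2.
#' @param fcThreshold linear fold-change gate (strict `>`), default 1.5.
#' @param pThreshold raw p-value gate (strict `<`), default 0.05.
#' @param welch use the Welch unequal-variance t-test instead of the pooled
#'   Student test.
#' @param controlGroup which group is the baseline; defaults to the first
#'   group label in sorted order.
#' @return data.frame with one row per probe: `probe_id`, `mean_control`,
#'   `mean_treated`, `fold_change`, `direction`, `p_value`, `adjusted_p`,
#'   `significant`.
#' @export
differentialExpression <- function(object, fcThreshold = 1.5,
                                   pThreshold = 0.05, welch = FALSE,
                                   controlGroup = NULL) {
  stopifnot(is(object, "CernaExpression"))
  grp <- sampleGroups(object)
  lv <- sort(unique(grp))
  if (length(lv) != 2)
    stop("differential expression needs exactly two groups, found: ",
         paste(lv, collapse = ", "))
  if (is.null(controlGroup)) controlGroup <- lv[1]
  if (!controlGroup %in% lv) stop("unknown control group: ", controlGroup)
  treatedGroup <- setdiff(lv, controlGroup)
  x <- .asLog2(object)
  a <- x[, grp == controlGroup, drop = FALSE]
  b <- x[, grp == treatedGroup, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2)
    stop("each group needs >= 2 samples (found ", n1, " and ", n2, ")")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  d <- m2 - m1
  tstat <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf * sign(d)))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  fc <- 2^abs(d)
  out <- data.frame(
    probe_id = rownames(x),
    mean_control = m1, mean_treated = m2,
    fold_change = fc,
    direction = ifelse(d > 0, "up", "down"),
    p_value = p,
    adjusted_p = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$fold_change > fcThreshold & out$p_value < pThreshold
  out
}

#' Summarize significant circRNAs by type and chromosome
#'
#' Counts significant circRNA probes by circRNA class (exonic, intronic,
#' sense overlapping, antisense, intergenic) and by chromosome, split into
#' up- and downregulated — the tabular content behind the usual
#' type/chromosome distribution figures.
#'
#' @param de data.frame from [differentialExpression()].
#' @param annotations data.frame from [readAnnotationTable()]; must cover all
#'   significant probes.
#' @return list with matrices `counts_by_type` (directions x types) and
#'   `counts_by_chromosome` (directions x chromosomes).
#' @export
summarizeCircTypes <- function(de, annotations) {
  sig <- de[de$significant, , drop = FALSE]
  miss <- setdiff(sig$probe_id, annotations$probe_id)
  if (length(miss))
    stop("significant probe(s) without annotation: ",
         paste(miss, collapse = ", "))
  ann <- annotations[match(sig$probe_id, annotations$probe_id), ]
  dir <- factor(sig$direction, c("up", "down"))
  byType <- table(dir, factor(ann$circ_type, .CIRC_TYPES))
  chroms <- sort(unique(annotations$chromosome))
  byChrom <- table(dir, factor(ann$chromosome, chroms))
  list(counts_by_type = unclass(byType),
       counts_by_chromosome = unclass(byChrom))
}

#' Hierarchical clustering leaf order on a correlation distance
#'
#' Average-linkage agglomerative clustering with distance `1 - Pearson r`,
#' the conventional expression-heatmap ordering. Zero-variance items, whose
#' correlation is undefined, sit at distance 1 from everything. Items are
#' pre-sorted lexicographically so the leaf order is deterministic under
#' input permutation.
#'
#' @param object a [CernaExpression-class] (log2 taken internally if linear).
#' @param axis cluster `"probes"` (rows) or `"samples"` (columns).
#' @return character vector of ids in dendrogram leaf order.
#' @export
hierarchicalClusterOrder <- function(object, axis = c("probes", "samples")) {
  axis <- match.arg(axis)
  x <- .asLog2(object)
  if (axis == "samples") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 items to cluster")
  x <- x[order(rownames(x), method = "radix"), , drop = FALSE]
  sds <- apply(x, 1, sd)
  r <- suppressWarnings(cor(t(x)))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- hclust(stats::as.dist(d), method = "average")
  rownames(x)[order.dendrogram(as.dendrogram(hc))]
}
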