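#' Intersect predicted miRNA targets with differentially expressed genes
#'
#' The Venn step of ceRNA inference: only genes that are both predicted
#' miRNA targets and differentially expressed survive into the network.
#'
#' @param predictedGenes character vector of predicted target gene ids.
#' @param deGenes character vector of differentially expressed gene ids.
#' @return sorted character vector, the exact set intersection.
#' @export
intersectTargets <- function(predictedGenes, deGenes) {
  sort(intersect(unique(predictedGenes), unique(deGenes)))
}

#' Hypergeometric shared-miRNA ceRNA p-value
#'
#' The probability, under random draws from a pool of `N` miRNAs, that a
#' candidate ceRNA interacting with `n` miRNAs shares at least `c` of them
#' with a gene interacting with `K`:
#' \deqn{P = \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}}
#' Computed as a log-space tail sum for numerical safety; `c = 0` returns
#' exactly 1.
#'
#' @param c shared miRNA count.
#' @param K miRNAs interacting with the gene of interest.
#' @param n miRNAs interacting with the candidate ceRNA.
#' @param N total miRNAs used for prediction.
#' @return the tail probability, in `(0, 1]`.
#' @examples
#' cernaPvalue(3, 5, 5, 20)
#' @export
cernaPvalue <- function(c, K, n, N) {
  if (any(c < 0 | K < 0 | n < 0 | N < 1)) stop("negative argument")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (c > min(K, n))
    stop("c (", c, ") exceeds min(K, n) = ", min(K, n))
  if (c == 0) return(1)
  i <- c:min(K, n)
  logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logTerms)
  p <- exp(mx) * sum(exp(logTerms - mx))
  min(p, 1)
}

#' Pearson correlation edge between two expression profiles
#'
#' Sample Pearson `r` over paired observations with the two-sided p-value
#' from `t = r * sqrt((m - 2) / (1 - r^2))` on `m - 2` degrees of freedom
#' (`|r| = 1` gives `p = 0`).
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @param idA,idB ids recorded in the output.
#' @return one-row data.frame: `id_a`, `id_b`, `r`, `p_value`, `n_samples`.
#' @export
pearsonEdge <- function(x, y, idA = "a", idB = "b") {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance profile: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(id_a = idA, id_b = idB, r = unname(ct$estimate),
             p_value = ct$p.value, n_samples = length(x),
             stringsAsFactors = FALSE)
}

#' Correlation edges for circRNA-gene pairs across shared samples
#'
#' Pairs profiles by declared sample id (the circRNA and mRNA arrays may
#' cover different sample subsets) and computes [pearsonEdge()] per requested
#' pair on the log2 scale.
#'
#' @param circExpr,mrnaExpr [CernaExpression-class] objects.
#' @param pairs data.frame with columns `circ_id`, `gene_id`.
#' @return data.frame of [pearsonEdge()] rows (named `circ_id`, `gene_id`).
#' @export
correlationEdges <- function(circExpr, mrnaExpr, pairs) {
  shared <- intersect(colnames(circExpr), colnames(mrnaExpr))
  if (length(shared) < 3)
    stop("fewer than 3 shared sample ids between the two arrays")
  xc <- .asLog2(circExpr)[, shared, drop = FALSE]
  xm <- .asLog2(mrnaExpr)[, shared, drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ci <- pairs$circ_id[i]; gi <- pairs$gene_id[i]
    if (!ci %in% rownames(xc)) stop("unknown circRNA probe: ", ci)
    if (!gi %in% rownames(xm)) stop("unknown gene probe: ", gi)
    e <- pearsonEdge(xc[ci, ], xm[gi, ], idA = ci, idB = gi)
    names(e)[1:2] <- c("circ_id", "gene_id")
    e
  })
  do.call(rbind, rows)
}

#' Assemble the tripartite ceRNA network
#'
#' Nodes are the circRNAs of `mrePredictions`, their top-K miRNAs, and the
#' predicted target genes that are differentially expressed
#' ([intersectTargets()]). Edges are `sponges` (circRNA -> miRNA, one per MRE
#' row) and `targets` (miRNA -> mRNA). Optional filters: a gene is dropped
#' from a circRNA's reach when its Pearson edge with that circRNA fails
#' `p < corrAlpha`, and (when `useCernaFilter`) when the shared-miRNA
#' [cernaPvalue()] of the (circRNA, gene) pair is `>= cernaAlpha`. miRNAs
#' left without any mRNA edge are pruned unless `keepLeafMirnas`.
#'
#' @param mrePredictions data.frame from [rankMirnasForCirc()] rows
#'   (`circ_id`, `mirna_id`, ...).
#' @param mirnaTargets named list: miRNA id -> character vector of predicted
#'   target gene ids. Every miRNA in `mrePredictions` must have an entry
#'   (possibly empty).
#' @param deGenes character vector of differentially expressed gene ids.
#' @param correlationFilter optional data.frame from [correlationEdges()];
#'   when supplied, (circ, gene) reaches failing `p_value < corrAlpha` are
#'   removed. Pairs absent from the table are kept.
#' @param directions optional named vector id -> `up`/`down` used for node
#'   regulation attributes (miRNAs are always `n/a`).
#' @param nMirnaUniverse total miRNA count `N` for the ceRNA test; defaults
#'   to `length(mirnaTargets)`.
#' @param cernaAlpha,corrAlpha significance gates, default 0.05.
#' @param useCernaFilter apply the hypergeometric pair filter (off by
#'   default).
#' @param keepLeafMirnas keep miRNAs with no surviving mRNA edge.
#' @return a [CernaNetwork-class].
#' @export
buildNetwork <- function(mrePredictions, mirnaTargets, deGenes,
                         correlationFilter = NULL, directions = NULL,
                         nMirnaUniverse = length(mirnaTargets),
                         cernaAlpha = 0.05, corrAlpha = 0.05,
                         useCernaFilter = FALSE, keepLeafMirnas = FALSE) {
  if (!all(c("circ_id", "mirna_id") %in% names(mrePredictions)))
    stop("mrePredictions needs circ_id and mirna_id columns")
  missTargets <- setdiff(unique(mrePredictions$mirna_id), names(mirnaTargets))
  if (length(missTargets))
    stop("miRNA(s) without a target entry: ",
         paste(missTargets, collapse = ", "))
  deGenes <- unique(as.character(deGenes))
  circs <- unique(mrePredictions$circ_id)
  dirOf <- function(id) {
    if (!is.null(directions) && id %in% names(directions))
      unname(directions[id]) else "n/a"
  }
  corrOk <- function(ci, gi) {
    if (is.null(correlationFilter)) return(TRUE)
    hit <- correlationFilter$circ_id == ci & correlationFilter$gene_id == gi
    if (!any(hit)) return(TRUE)
    any(correlationFilter$p_value[hit] < corrAlpha)
  }
  geneHits <- lapply(mirnaTargets, intersectTargets, deGenes = deGenes)
  sponges <- unique(mrePredictions[c("circ_id", "mirna_id")])
  targetRows <- list()
  for (ci in circs) {
    mir <- sponges$mirna_id[sponges$circ_id == ci]
    nCirc <- length(mir)
    reach <- unique(unlist(geneHits[mir], use.names = FALSE))
    for (gi in reach) {
      if (!corrOk(ci, gi)) next
      if (useCernaFilter) {
        Kg <- sum(vapply(geneHits, function(g) gi %in% g, TRUE))
        cShared <- sum(vapply(geneHits[mir], function(g) gi %in% g, TRUE))
        if (cernaPvalue(cShared, Kg, nCirc, nMirnaUniverse) >= cernaAlpha)
          next
      }
      for (mi in mir[vapply(geneHits[mir], function(g) gi %in% g, TRUE)])
        targetRows[[length(targetRows) + 1L]] <-
          data.frame(from = mi, to = gi, edge_type = "targets")
    }
  }
  targets <- if (length(targetRows)) unique(do.call(rbind, targetRows)) else
    data.frame(from = character(), to = character(),
               edge_type = character())
  keepMir <- unique(sponges$mirna_id)
  if (!keepLeafMirnas)
    keepMir <- intersect(keepMir, unique(targets$from))
  spongeEdges <- sponges[sponges$mirna_id %in% keepMir, , drop = FALSE]
  edges <- rbind(
    if (nrow(spongeEdges))
      data.frame(from = spongeEdges$circ_id, to = spongeEdges$mirna_id,
                 edge_type = "sponges") else NULL,
    targets)
  nodeIds <- c(circs, keepMir, unique(targets$to))
  nodeTypes <- c(rep("circRNA", length(circs)),
                 rep("miRNA", length(keepMir)),
                 rep("mRNA", length(unique(targets$to))))
  nodes <- data.frame(
    node_id = nodeIds, node_type = nodeTypes,
    direction = vapply(nodeIds, dirOf, ""), stringsAsFactors = FALSE)
  nodes$direction[nodes$node_type == "miRNA"] <- "n/a"
  net <- cernaNetwork(nodes, edges)
  validObject(net)
  net
}

#' Per-node degree table
#'
#' miRNA degree is reported split into the circRNA side (`degree_circ`) and
#' the mRNA side (`degree_mrna`); `degree` is their sum. This is the
#' statistic behind "miRNA X had k targeted mRNAs" summaries.
#'
#' @param network a [CernaNetwork-class].
#' @return data.frame: `node_id`, `node_type`, `degree`, `degree_circ`,
#'   `degree_mrna`.
#' @export
degreeSummary <- function(network) {
  n <- networkNodes(network); e <- networkEdges(network)
  cnt <- function(ids) {
    tab <- table(factor(ids, levels = n$node_id))
    as.integer(tab)
  }
  sp <- e[e$edge_type == "sponges", ]; tg <- e[e$edge_type == "targets", ]
  dCirc <- cnt(c(sp$from, sp$to))   # circ side of sponges edges
  dMrna <- cnt(c(tg$from, tg$to))
  data.frame(node_id = n$node_id, node_type = n$node_type,
             degree = dCirc + dMrna, degree_circ = dCirc,
             degree_mrna = dMrna, stringsAsFactors = FALSE)
}

#' Restrict a network to named functional modules
#'
#' Keeps mRNA nodes belonging to the union of the named gene sets, miRNAs
#' retaining at least one mRNA edge, and circRNAs retaining at least one
#' miRNA. Retained mRNAs are annotated with their (comma-joined) module
#' memberships in a `module` node column.
#'
#' @param network a [CernaNetwork-class].
#' @param catalog gene-set catalog from [readGeneSets()] (named list).
#' @param moduleNames which sets define the modules.
#' @return a [CernaNetwork-class] sub-network.
#' @export
extractFunctionalModule <- function(network, catalog, moduleNames) {
  unknown <- setdiff(moduleNames, names(catalog))
  if (length(unknown))
    stop("unknown module name(s): ", paste(unknown, collapse = ", "))
  n <- networkNodes(network); e <- networkEdges(network)
  memberOf <- function(g) {
    hits <- moduleNames[vapply(moduleNames,
                               function(s) g %in% catalog[[s]], TRUE)]
    paste(hits, collapse = ",")
  }
  mrna <- n$node_id[n$node_type == "mRNA"]
  keepGenes <- mrna[vapply(mrna, function(g) nzchar(memberOf(g)), TRUE)]
  tg <- e[e$edge_type == "targets" & e$to %in% keepGenes, , drop = FALSE]
  keepMir <- unique(tg$from)
  sp <- e[e$edge_type == "sponges" & e$to %in% keepMir, , drop = FALSE]
  keepCirc <- unique(sp$from)
  keep <- c(keepCirc, keepMir, keepGenes)
  nodes <- n[n$node_id %in% keep, , drop = FALSE]
  nodes$module <- ifelse(nodes$node_type == "mRNA",
                         vapply(nodes$node_id, memberOf, ""), "")
  net <- cernaNetwork(nodes, rbind(sp, tg))
  validObject(net)
  net
}
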