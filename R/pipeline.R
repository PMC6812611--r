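#' Run the full ceRNA inference pipeline on a fixture directory
#'
#' Executes the stages in the canonical order — quantile normalization,
#' detection filtering, differential expression (both arrays), top-K MRE
#' prediction for significant circRNAs, gene-target prediction for the
#' selected miRNAs, intersection with DE genes, circRNA-mRNA Pearson
#' filtering, tripartite network assembly, functional-module extraction,
#' over-representation enrichment, and qPCR concordance — writing every
#' intermediate table plus a JSON run report with stage-level counts and the
#' exact thresholds used.
#'
#' The input directory must follow the layout emitted by
#' [generateSyntheticData()]: `expr_circ.tsv`, `expr_mrna.tsv`,
#' `groups.tsv`, `circ.fa`, `mirnas.fa`, `utr.fa`, `annotations.tsv`,
#' `modules.gmt`, and optionally `ct.tsv`.
#'
#' @param inputDir fixture directory.
#' @param outDir output directory for intermediates and the report
#'   (defaults to `inputDir`).
#' @param minPresentCirc,minPresentMrna detection-filter thresholds
#'   (defaults 3 and 6, the usual "at least k of n samples P/M" values for
#'   a 6+6 design).
#' @param fcThreshold,pThreshold DE gate (defaults 1.5 and 0.05).
#' @param topK MREs kept per circRNA (default 5).
#' @param corrAlpha Pearson edge gate (default 0.05).
#' @param cernaAlpha,useCernaFilter hypergeometric pair filter (default off).
#' @param enrichAlpha,nTopTerms enrichment gate and top-term count
#'   (defaults 0.05 and 10).
#' @param welch use Welch instead of pooled t.
#' @param keepLeafMirnas keep miRNAs without surviving mRNA edges.
#' @param writeFiles write intermediates and report to `outDir`.
#' @return invisibly, the run report list (also serialized to
#'   `report.json`). Key fields: per-stage counts, `sponge_ranking`
#'   (circRNAs by distinct reachable mRNA count), `network` composition,
#'   `top_terms`, `qpcr` concordance.
#' @export
runAll <- function(inputDir, outDir = inputDir,
                   minPresentCirc = 3L, minPresentMrna = 6L,
                   fcThreshold = 1.5, pThreshold = 0.05, topK = 5L,
                   corrAlpha = 0.05, cernaAlpha = 0.05,
                   useCernaFilter = FALSE, enrichAlpha = 0.05,
                   nTopTerms = 10L, welch = FALSE, keepLeafMirnas = FALSE,
                   writeFiles = TRUE) {
  inp <- function(f) {
    path <- file.path(inputDir, f)
    if (!file.exists(path)) stop("missing pipeline input: ", path)
    path
  }
  if (writeFiles) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, f) {
    if (writeFiles)
      write.table(df, file.path(outDir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  grp <- .readTsv(inp("groups.tsv"))
  groupMap <- stats::setNames(grp$group, grp$sample_id)

  ## normalize + filter + DE, per array
  circRaw <- readExpressionTable(inp("expr_circ.tsv"), groupMap)
  mrnaRaw <- readExpressionTable(inp("expr_mrna.tsv"), groupMap)
  circN <- quantileNormalize(circRaw)
  mrnaN <- quantileNormalize(mrnaRaw)
  circF <- detectionFilter(circN, minPresentCirc)
  mrnaF <- detectionFilter(mrnaN, minPresentMrna)
  deCirc <- differentialExpression(circF, fcThreshold, pThreshold,
                                   welch = welch,
                                   controlGroup = "control")
  deMrna <- differentialExpression(mrnaF, fcThreshold, pThreshold,
                                   welch = welch,
                                   controlGroup = "control")
  emit(deCirc, "de_circ.tsv"); emit(deMrna, "de_mrna.tsv")
  sigCirc <- deCirc[deCirc$significant, , drop = FALSE]
  sigMrna <- deMrna[deMrna$significant, , drop = FALSE]

  annotations <- readAnnotationTable(inp("annotations.tsv"))
  typeDist <- summarizeCircTypes(deCirc, annotations)

  ## MRE prediction for significant circRNAs
  circSeqs <- readFasta(inp("circ.fa"), topology = "circular")
  mirnaSeqs <- readFasta(inp("mirnas.fa"), topology = "linear")
  mirnaChr <- stats::setNames(as.character(mirnaSeqs), names(mirnaSeqs))
  mreCircs <- intersect(sigCirc$probe_id, names(circSeqs))
  mre <- do.call(rbind, lapply(mreCircs, function(ci)
    rankMirnasForCirc(as.character(circSeqs[[ci]]), mirnaChr, k = topK,
                      circId = ci)))
  if (is.null(mre))
    mre <- data.frame(circ_id = character(), rank = integer(),
                      mirna_id = character(), best_site_type = character(),
                      n_sites = integer(), max_au_score = numeric())
  emit(mre, "mre.tsv")

  ## gene targets of the selected miRNAs, intersected with DE genes
  utrSeqs <- readFasta(inp("utr.fa"), topology = "linear")
  utrChr <- stats::setNames(as.character(utrSeqs), names(utrSeqs))
  usedMirnas <- sort(unique(mre$mirna_id))
  mirnaTargets <- stats::setNames(lapply(usedMirnas, function(mi)
    predictGeneTargets(mirnaChr[[mi]], utrChr)), usedMirnas)
  targetRows <- do.call(rbind, lapply(usedMirnas, function(mi) {
    g <- mirnaTargets[[mi]]
    if (length(g)) data.frame(mirna_id = mi, gene_id = g) else NULL
  }))
  if (!is.null(targetRows)) emit(targetRows, "targets.tsv")

  ## correlation filter over candidate (circ, gene) reaches
  candPairs <- do.call(rbind, lapply(mreCircs, function(ci) {
    mir <- mre$mirna_id[mre$circ_id == ci]
    g <- intersectTargets(unlist(mirnaTargets[mir], use.names = FALSE),
                          sigMrna$probe_id)
    if (length(g)) data.frame(circ_id = ci, gene_id = g) else NULL
  }))
  corr <- if (!is.null(candPairs) && nrow(candPairs))
    correlationEdges(circF, mrnaF, candPairs) else NULL
  if (!is.null(corr)) emit(corr, "correlations.tsv")

  directions <- c(stats::setNames(deCirc$direction, deCirc$probe_id),
                  stats::setNames(deMrna$direction, deMrna$probe_id))
  net <- buildNetwork(mre, mirnaTargets, sigMrna$probe_id,
                      correlationFilter = corr, directions = directions,
                      nMirnaUniverse = length(mirnaSeqs),
                      cernaAlpha = cernaAlpha, corrAlpha = corrAlpha,
                      useCernaFilter = useCernaFilter,
                      keepLeafMirnas = keepLeafMirnas)
  if (writeFiles) writeNetwork(net, file.path(outDir, "net"))
  deg <- degreeSummary(net)
  emit(deg, "degrees.tsv")

  ## mRNA-reachability ranking of circRNAs (sponge candidates)
  e <- networkEdges(net)
  reachCount <- vapply(mreCircs, function(ci) {
    mir <- e$to[e$edge_type == "sponges" & e$from == ci]
    length(unique(e$to[e$edge_type == "targets" & e$from %in% mir]))
  }, 0L)
  ranking <- data.frame(circ_id = mreCircs, reachable_mrnas = reachCount,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$reachable_mrnas, ranking$circ_id), ,
                     drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  emit(ranking, "sponge_ranking.tsv")

  ## functional modules + enrichment
  modulesPath <- file.path(inputDir, "modules.gmt")
  moduleNet <- NULL; enr <- NULL; top <- NULL
  if (file.exists(modulesPath)) {
    catalog <- readGeneSets(modulesPath)
    moduleNet <- extractFunctionalModule(net, catalog, names(catalog))
    if (writeFiles) writeNetwork(moduleNet, file.path(outDir, "module_net"))
    netGenes <- networkNodes(net)
    netGenes <- netGenes$node_id[netGenes$node_type == "mRNA"]
    if (length(netGenes)) {
      enr <- enrich(netGenes, catalog, background = rownames(mrnaF))
      top <- topTerms(enr, topK = nTopTerms, alpha = enrichAlpha)
      emit(enr, "enrichment.tsv")
    }
  }

  ## qPCR validation
  qpcr <- NULL
  ctPath <- file.path(inputDir, "ct.tsv")
  if (file.exists(ctPath)) {
    ct <- readCtTable(ctPath, refAssay = "GAPDH",
                      controlGroup = "control")
    rq <- relativeQuantityAll(ct)
    rq <- rq[names(rq) %in% deCirc$probe_id]
    if (length(rq)) {
      qpcr <- qpcrConcordance(rq, deCirc)
      emit(qpcr, "qpcr_concordance.tsv")
    }
  }

  nn <- networkNodes(net)
  report <- list(
    thresholds = list(min_present_circ = minPresentCirc,
                      min_present_mrna = minPresentMrna,
                      fc_threshold = fcThreshold, p_threshold = pThreshold,
                      top_k = topK, corr_alpha = corrAlpha,
                      cerna_alpha = cernaAlpha,
                      use_cerna_filter = useCernaFilter,
                      enrich_alpha = enrichAlpha, welch = welch),
    probes_retained = list(circ = nrow(circF), mrna = nrow(mrnaF)),
    de = list(circ_up = sum(sigCirc$direction == "up"),
              circ_down = sum(sigCirc$direction == "down"),
              mrna_up = sum(sigMrna$direction == "up"),
              mrna_down = sum(sigMrna$direction == "down")),
    circ_type_counts = typeDist$counts_by_type,
    mirnas_per_circ = if (nrow(mre))
      as.list(table(mre$circ_id)) else list(),
    network = list(n_circ = sum(nn$node_type == "circRNA"),
                   n_mirna = sum(nn$node_type == "miRNA"),
                   n_mrna = sum(nn$node_type == "mRNA"),
                   n_nodes = nrow(nn), n_edges = nrow(e)),
    sponge_ranking = ranking,
    top_terms = top,
    n_significant_terms = if (is.null(enr)) 0L else
      sum(enr$p_value < enrichAlpha),
    qpcr = qpcr)
  if (writeFiles)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(report)
}
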