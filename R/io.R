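#' @importFrom utils read.delim write.table count.fields
NULL

.CIRC_TYPES <- c("exonic", "intronic", "sense overlapping", "antisense",
                 "intergenic")

.readTsv <- function(path, ...) {
  nf <- unique(count.fields(path, sep = "\t", comment.char = "#",
                            quote = ""))
  if (length(nf) > 1)
    stop("ragged TSV (rows with ", paste(nf, collapse = "/"),
         " fields): ", path)
  read.delim(path, comment.char = "#", quote = "", check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

#' Read a probe-by-sample expression table
#'
#' Expects a TSV whose first column holds probe ids and whose remaining
#' columns are sample intensities, optionally paired with detection-flag
#' columns named `<sample>.flag` holding `P`/`M`/`A` calls. Probes missing
#' flag columns are treated as detected (`P`) everywhere.
#'
#' @param path TSV path; `#` lines are ignored.
#' @param groupMap named character vector, sample id -> group label. All its
#'   names must appear in the header.
#' @param scale scale tag for the stored intensities.
#' @return a [CernaExpression-class].
#' @export
readExpressionTable <- function(path, groupMap, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- .readTsv(path)
  probes <- as.character(tab[[1L]])
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  cols <- names(tab)[-1L]
  flagCols <- grep("\\.flag$", cols, value = TRUE)
  sampleCols <- setdiff(cols, flagCols)
  miss <- setdiff(names(groupMap), sampleCols)
  if (length(miss))
    stop("group map names sample(s) absent from header: ",
         paste(miss, collapse = ", "))
  sampleCols <- intersect(sampleCols, names(groupMap))
  x <- as.matrix(tab[, sampleCols, drop = FALSE])
  rownames(x) <- probes
  f <- matrix("P", nrow(x), ncol(x), dimnames = dimnames(x))
  for (s in sampleCols) {
    fc <- paste0(s, ".flag")
    if (fc %in% flagCols) f[, s] <- as.character(tab[[fc]])
  }
  CernaExpression(x, groupMap, flags = f, scale = scale)
}

#' Write a CernaExpression to TSV
#'
#' Inverse of [readExpressionTable()]: intensities plus one `<sample>.flag`
#' column per sample.
#'
#' @param object a [CernaExpression-class].
#' @param path output TSV path.
#' @export
writeExpressionTable <- function(object, path) {
  x <- intensities(object); f <- detectionFlags(object)
  out <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in colnames(x)) out[[paste0(s, ".flag")]] <- f[, s]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.normalizeCircType <- function(x) {
  y <- tolower(trimws(gsub("[ _]+", " ", x)))
  bad <- setdiff(unique(y), .CIRC_TYPES)
  if (length(bad))
    stop("unknown circRNA type value(s): ",
         paste(sprintf('"%s"', x[y %in% bad][1]), collapse = ", "))
  y
}

#' Read a circRNA probe annotation table
#'
#' Schema (tab-separated): probe id, regulation hint (`up`/`down`, optional
#' content), p-value, fold change, circRNA type, chromosome, best transcript,
#' gene symbol. circRNA types are normalized case/whitespace-insensitively to
#' the closed set exonic / intronic / sense overlapping / antisense /
#' intergenic.
#'
#' @param path TSV path (header row required).
#' @return data.frame with columns `probe_id`, `regulation`, `p_value`,
#'   `fold_change`, `circ_type`, `chromosome`, `best_transcript`,
#'   `gene_symbol`.
#' @export
readAnnotationTable <- function(path) {
  tab <- .readTsv(path)
  if (ncol(tab) < 8)
    stop("annotation table needs 8 columns, found ", ncol(tab))
  names(tab)[1:8] <- c("probe_id", "regulation", "p_value", "fold_change",
                       "circ_type", "chromosome", "best_transcript",
                       "gene_symbol")
  tab$circ_type <- .normalizeCircType(as.character(tab$circ_type))
  if (any(!nzchar(tab$chromosome))) stop("empty chromosome field")
  tab
}

#' Read FASTA sequences as RNA
#'
#' DNA-style `T` is unified to `U`; ids are the first whitespace-delimited
#' header token. Characters outside `A/C/G/U/T` are rejected.
#'
#' @param path FASTA path.
#' @param topology `"linear"` or `"circular"`, applied to the whole file and
#'   recorded in `mcols()$topology`.
#' @return a [Biostrings::RNAStringSet] with a `topology` metadata column.
#' @export
readFasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("no sequences in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  seqs <- chartr("acgtu", "ACGUU", chartr("T", "U", as.character(x)))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("non-ACGU/T character in sequence(s): ",
         paste(names(x)[bad], collapse = ", "))
  if (any(!nchar(seqs))) stop("empty sequence in ", path)
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- names(x)
  S4Vectors::mcols(out)$topology <- topology
  out
}

#' Write sequences to FASTA
#' @param seqs an XStringSet (or named character vector of RNA sequences).
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a gene-set catalog in GMT format
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Members are deduplicated; duplicate set names and empty member lists are
#' errors.
#'
#' @param path GMT path.
#' @return named list of character vectors of member genes, with a
#'   `descriptions` attribute.
#' @export
readGeneSets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup))
    stop("duplicate gene-set name(s): ", paste(dup, collapse = ", "))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    stop("gene set(s) with no members: ", paste(empty, collapse = ", "))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(lines, function(z) if (length(z) >= 2) z[2] else "", "")
  names(desc) <- vapply(lines, `[`, "", 1L)
  sets <- lapply(sets, unique)
  attr(sets, "descriptions") <- desc[names(sets)]
  sets
}

#' Write a gene-set catalog in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `group`, `assay_id`, `ct`. The reference
#' assay (endogenous control, e.g. GAPDH) and the control group are declared
#' here and carried as attributes for downstream 2^-ddCt quantification.
#'
#' @param path TSV path.
#' @param refAssay reference assay id; must be measured in every sample.
#' @param controlGroup the baseline group label.
#' @return data.frame with attributes `ref_assay` and `control_group`.
#' @export
readCtTable <- function(path, refAssay, controlGroup) {
  tab <- .readTsv(path)
  need <- c("sample_id", "group", "assay_id", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab[c("sample_id", "assay_id")]))
    stop("duplicated (sample, assay) measurement(s)")
  samples <- unique(tab$sample_id)
  noRef <- setdiff(samples, tab$sample_id[tab$assay_id == refAssay])
  if (length(noRef))
    stop("reference assay '", refAssay, "' missing for sample(s): ",
         paste(noRef, collapse = ", "))
  if (!controlGroup %in% tab$group)
    stop("control group '", controlGroup, "' absent from table")
  attr(tab, "ref_assay") <- refAssay
  attr(tab, "control_group") <- controlGroup
  tab
}

#' Export a network in Cytoscape-compatible formats
#'
#' Writes `<prefix>.sif` (interaction labels `sponges` / `targets`),
#' `<prefix>.nodes.tsv` (node id, type, regulation direction, and module
#' labels when present) and `<prefix>.graphml`. Output row order is
#' deterministic, so two writes of the same network are byte-identical.
#'
#' @param network a [CernaNetwork-class].
#' @param outPrefix path prefix for the three files.
#' @return invisibly, the three file paths.
#' @export
writeNetwork <- function(network, outPrefix) {
  validObject(network)
  n <- networkNodes(network); e <- networkEdges(network)
  sif <- file.path(paste0(outPrefix, ".sif"))
  nodesTsv <- paste0(outPrefix, ".nodes.tsv")
  graphml <- paste0(outPrefix, ".graphml")
  writeLines(if (nrow(e)) paste(e$from, e$edge_type, e$to) else character(),
             sif)
  write.table(n, nodesTsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(e)) data.frame(from = e$from, to = e$to,
                            interaction = e$edge_type) else
      data.frame(from = character(), to = character(),
                 interaction = character()),
    directed = TRUE, vertices = data.frame(name = n$node_id, n[-1]))
  igraph::write_graph(g, graphml, format = "graphml")
  invisible(c(sif = sif, nodes = nodesTsv, graphml = graphml))
}

#' Read a network back from GraphML
#'
#' Inverse of the GraphML leg of [writeNetwork()].
#'
#' @param path GraphML path.
#' @return a [CernaNetwork-class].
#' @export
readNetworkGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(node_id = va$name, node_type = va$node_type,
                      direction = va$direction, stringsAsFactors = FALSE)
  if (!is.null(va$module)) nodes$module <- va$module
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      edge_type = igraph::edge_attr(g, "interaction"),
                      stringsAsFactors = FALSE)
  cernaNetwork(nodes, edges)
}
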