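#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' CernaExpression: probe-by-sample intensities with detection flags
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding the substrate of
#' normalization and differential expression: an `intensities` assay (raw
#' linear or log2 scale, tracked by `metadata()$scale`), a `flags` assay of
#' per-cell detection calls (`"P"` present, `"M"` marginal, `"A"` absent), and
#' a two-level sample grouping in `colData()$group`.
#'
#' @slot .Data inherited SummarizedExperiment machinery.
#' @seealso [CernaExpression()] constructor, [intensities()], [detectionFlags()],
#'   [sampleGroups()], [intensityScale()]
#' @export
setClass("CernaExpression", contains = "SummarizedExperiment")

.validCernaExpression <- function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("intensities", "flags") %in% an))
    msgs <- c(msgs, "assays must contain 'intensities' and 'flags'")
  else {
    x <- SummarizedExperiment::assay(object, "intensities")
    f <- SummarizedExperiment::assay(object, "flags")
    if (!is.numeric(x) || any(!is.finite(x)))
      msgs <- c(msgs, "intensities must be finite numeric")
    if (!all(f %in% c("P", "M", "A")))
      msgs <- c(msgs, "flags must be drawn from {P, M, A}")
  }
  if (is.null(colData(object)$group) || anyNA(colData(object)$group))
    msgs <- c(msgs, "every sample needs a group label in colData()$group")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("linear", "log2"))
    msgs <- c(msgs, "metadata()$scale must be 'linear' or 'log2'")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate probe ids")
  if (length(msgs)) msgs else TRUE
}
setValidity("CernaExpression", .validCernaExpression)

#' Construct a CernaExpression object
#'
#' @param intensities numeric probe x sample matrix with row and column names.
#' @param groups named character vector or factor mapping sample id to group
#'   label; names must cover all columns of `intensities`.
#' @param flags character matrix over `{P,M,A}` of the same shape as
#'   `intensities`; defaults to all-`"P"` when detection calls are unavailable.
#' @param scale `"linear"` (raw intensities) or `"log2"`.
#' @return a validated [CernaExpression-class] object.
#' @examples
#' x <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' grp <- setNames(rep(c("control", "treated"), each = 2), colnames(x))
#' ce <- CernaExpression(x, grp)
#' intensityScale(ce)
#' @export
CernaExpression <- function(intensities, groups,
                            flags = NULL, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensities must carry probe (row) and sample (column) names")
  if (is.null(flags)) {
    flags <- matrix("P", nrow(intensities), ncol(intensities),
                    dimnames = dimnames(intensities))
  }
  flags <- as.matrix(flags)
  dimnames(flags) <- dimnames(intensities)
  miss <- setdiff(colnames(intensities), names(groups))
  if (length(miss))
    stop("samples without a group label: ", paste(miss, collapse = ", "))
  cd <- S4Vectors::DataFrame(
    group = as.character(groups[colnames(intensities)]),
    row.names = colnames(intensities))
  se <- SummarizedExperiment(
    assays = list(intensities = intensities, flags = flags), colData = cd)
  metadata(se)$scale <- scale
  new("CernaExpression", se)
}

#' @describeIn CernaExpression the intensity matrix.
#' @param object,x a `CernaExpression`.
#' @export
intensities <- function(object) SummarizedExperiment::assay(object, "intensities")

#' @describeIn CernaExpression the detection-flag matrix.
#' @export
detectionFlags <- function(object) SummarizedExperiment::assay(object, "flags")

#' @describeIn CernaExpression named vector sample id -> group.
#' @export
sampleGroups <- function(object) {
  stats::setNames(as.character(colData(object)$group), colnames(object))
}

#' @describeIn CernaExpression the scale tag, `"linear"` or `"log2"`.
#' @export
intensityScale <- function(object) metadata(object)$scale

setMethod("show", "CernaExpression", function(object) {
  cat("CernaExpression:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  scale:", intensityScale(object),
      " groups:", paste(names(table(sampleGroups(object))),
                        table(sampleGroups(object)), collapse = ", "), "\n")
  pm <- mean(detectionFlags(object) %in% c("P", "M"))
  cat("  fraction P/M flags:", format(round(pm, 3)), "\n")
})

.NODE_TYPES <- c("circRNA", "miRNA", "mRNA")
.EDGE_TYPES <- c(sponges = "sponges", targets = "targets")

#' CernaNetwork: a typed tripartite circRNA-miRNA-mRNA graph
#'
#' Nodes are typed (`circRNA`, `miRNA`, `mRNA`) and carry a regulation
#' direction (`up`, `down`, or `n/a`); edges are `"sponges"`
#' (circRNA -> miRNA) or `"targets"` (miRNA -> mRNA). Validity enforces strict
#' tripartiteness: no other edge type or orientation is representable.
#'
#' @slot nodes data.frame with columns `node_id`, `node_type`, `direction`
#'   (and, after module extraction, `module`).
#' @slot edges data.frame with columns `from`, `to`, `edge_type`.
#' @seealso [cernaNetwork()], [networkNodes()], [networkEdges()],
#'   [degreeSummary()], [writeNetwork()]
#' @export
setClass("CernaNetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

.validCernaNetwork <- function(object) {
  n <- object@nodes; e <- object@edges
  msgs <- character()
  if (!all(c("node_id", "node_type", "direction") %in% names(n)))
    msgs <- c(msgs, "nodes need node_id, node_type, direction")
  if (!all(c("from", "to", "edge_type") %in% names(e)))
    msgs <- c(msgs, "edges need from, to, edge_type")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(n$node_id)) msgs <- c(msgs, "duplicate node ids")
  if (!all(n$node_type %in% .NODE_TYPES))
    msgs <- c(msgs, "node_type outside {circRNA, miRNA, mRNA}")
  if (!all(n$direction %in% c("up", "down", "n/a")))
    msgs <- c(msgs, "direction outside {up, down, n/a}")
  if (nrow(e)) {
    if (!all(e$edge_type %in% .EDGE_TYPES))
      msgs <- c(msgs, "edge_type outside {sponges, targets}")
    unknown <- setdiff(c(e$from, e$to), n$node_id)
    if (length(unknown))
      msgs <- c(msgs, paste("edge references unknown node(s):",
                            paste(unknown, collapse = ", ")))
    else {
      ty <- stats::setNames(n$node_type, n$node_id)
      sp <- e$edge_type == "sponges"
      if (any(ty[e$from[sp]] != "circRNA") || any(ty[e$to[sp]] != "miRNA"))
        msgs <- c(msgs, "'sponges' edges must run circRNA -> miRNA")
      if (any(ty[e$from[!sp]] != "miRNA") || any(ty[e$to[!sp]] != "mRNA"))
        msgs <- c(msgs, "'targets' edges must run miRNA -> mRNA")
    }
    if (anyDuplicated(e[c("from", "to", "edge_type")]))
      msgs <- c(msgs, "duplicate edges")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("CernaNetwork", .validCernaNetwork)

.sortNetworkTables <- function(nodes, edges) {
  nodes$node_type <- as.character(nodes$node_type)
  ord <- order(match(nodes$node_type, .NODE_TYPES), nodes$node_id,
               method = "radix")
  nodes <- nodes[ord, , drop = FALSE]
  if (nrow(edges)) {
    ord <- order(match(edges$edge_type, .EDGE_TYPES), edges$from, edges$to,
                 method = "radix")
    edges <- edges[ord, , drop = FALSE]
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Construct a CernaNetwork from node and edge tables
#'
#' Rows are sorted deterministically (nodes by type then id; edges by type,
#' source, target) so that serializations are byte-stable.
#'
#' @param nodes data.frame with `node_id`, `node_type`, `direction`.
#' @param edges data.frame with `from`, `to`, `edge_type`.
#' @return a validated [CernaNetwork-class].
#' @export
cernaNetwork <- function(nodes, edges) {
  if (missing(edges) || is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        edge_type = character(), stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  st <- .sortNetworkTables(nodes, edges)
  new("CernaNetwork", nodes = st$nodes, edges = st$edges)
}

#' @describeIn cernaNetwork the node table.
#' @param network a `CernaNetwork`.
#' @export
networkNodes <- function(network) network@nodes

#' @describeIn cernaNetwork the edge table.
#' @export
networkEdges <- function(network) network@edges

setMethod("show", "CernaNetwork", function(object) {
  tt <- table(factor(object@nodes$node_type, .NODE_TYPES))
  cat("CernaNetwork:", paste(tt, names(tt), collapse = ", "),
      "|", nrow(object@edges), "edges\n")
})
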