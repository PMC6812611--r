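#' 2^-ddCt relative quantification for one assay
#'
#' Classic Livak arithmetic: per sample, `dCt = Ct_assay - Ct_reference`;
#' `ddCt = dCt - mean(dCt of the control group)`; `RQ = 2^-ddCt`. The
#' control group's geometric-mean RQ is 1 by construction (its `log2(RQ)`
#' values have mean exactly 0).
#'
#' @param ct a Ct table from [readCtTable()].
#' @param assayId which assay to quantify (not the reference assay).
#' @return data.frame with one row per sample carrying the assay:
#'   `sample_id`, `group`, `dct`, `ddct`, `rq`.
#' @export
relativeQuantity <- function(ct, assayId) {
  refAssay <- attr(ct, "ref_assay")
  controlGroup <- attr(ct, "control_group")
  if (is.null(refAssay) || is.null(controlGroup))
    stop("Ct table lacks ref_assay / control_group attributes; ",
         "use readCtTable()")
  if (assayId == refAssay)
    stop("cannot quantify the reference assay against itself")
  a <- ct[ct$assay_id == assayId, , drop = FALSE]
  if (!nrow(a)) stop("no measurements for assay: ", assayId)
  r <- ct[ct$assay_id == refAssay, , drop = FALSE]
  refCt <- stats::setNames(r$ct, r$sample_id)
  noRef <- setdiff(a$sample_id, names(refCt))
  if (length(noRef))
    stop("missing reference Ct for sample(s): ",
         paste(noRef, collapse = ", "))
  dct <- a$ct - refCt[a$sample_id]
  ctrl <- a$group == controlGroup
  if (!any(ctrl)) stop("assay has no control-group measurements")
  ddct <- dct - mean(dct[ctrl])
  out <- data.frame(sample_id = a$sample_id, group = a$group,
                    dct = unname(dct), ddct = unname(ddct),
                    rq = 2^(-unname(ddct)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "control_group") <- controlGroup
  out
}

#' Quantify all non-reference assays
#'
#' @param ct a Ct table from [readCtTable()].
#' @return named list of [relativeQuantity()] tables, one per assay.
#' @export
relativeQuantityAll <- function(ct) {
  assays <- setdiff(sort(unique(ct$assay_id)), attr(ct, "ref_assay"))
  stats::setNames(lapply(assays, relativeQuantity, ct = ct), assays)
}

#' Direction concordance between qPCR and microarray calls
#'
#' The qPCR direction is `up` when the treated group's mean RQ exceeds 1,
#' else `down` (the RQ = 1 tie resolves to `down` and is flagged
#' `ambiguous`). Concordant assays agree with the microarray call.
#'
#' @param rqTables named list from [relativeQuantityAll()] (or a single
#'   table in a named list).
#' @param de data.frame from [differentialExpression()].
#' @param assayProbeMap named character vector assay id -> probe id;
#'   defaults to the identity mapping.
#' @return data.frame: `assay_id`, `mean_rq_treated`, `qpcr_direction`,
#'   `array_direction`, `concordant`, `ambiguous`.
#' @export
qpcrConcordance <- function(rqTables, de, assayProbeMap = NULL) {
  ids <- names(rqTables)
  if (is.null(assayProbeMap)) assayProbeMap <- stats::setNames(ids, ids)
  rows <- lapply(ids, function(aid) {
    probe <- assayProbeMap[[aid]]
    if (is.null(probe) || !probe %in% de$probe_id)
      stop("assay '", aid, "' does not map to a probe in the DE table")
    rq <- rqTables[[aid]]
    controlGroup <- attr(rq, "control_group")
    if (is.null(controlGroup))
      stop("RQ table lacks its control_group attribute")
    meanRq <- mean(rq$rq[rq$group != controlGroup])
    dirQ <- if (meanRq > 1) "up" else "down"
    data.frame(assay_id = aid, mean_rq_treated = meanRq,
               qpcr_direction = dirQ,
               array_direction = de$direction[de$probe_id == probe][1],
               ambiguous = meanRq == 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$concordant <- out$qpcr_direction == out$array_direction
  out[c("assay_id", "mean_rq_treated", "qpcr_direction", "array_direction",
        "concordant", "ambiguous")]
}
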