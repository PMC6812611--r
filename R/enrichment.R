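#' Over-representation analysis against a gene-set catalog
#'
#' For each catalog set, tests whether the gene list overlaps it more than
#' chance given a background universe, using the hypergeometric upper tail
#' (the same tail sum as [cernaPvalue()] with `c = k`, `K = K_set`,
#' `n = n_list`, `N = N_bg`). Catalog members are intersected with the
#' background before testing; sets with zero list overlap are omitted.
#' Results carry `fold_enrichment = (k / n_list) / (K_set / N_bg)` and
#' `enrichment_score = -log10(p)`.
#'
#' @param geneList character vector, a subset of `background`.
#' @param catalog named list of gene sets ([readGeneSets()]).
#' @param background character vector, the gene universe (e.g. all genes
#'   surviving the detection filter).
#' @return data.frame sorted by `p_value` then `set_name`: `set_name`, `k`,
#'   `K_set`, `n_list`, `N_bg`, `p_value`, `fold_enrichment`,
#'   `enrichment_score`.
#' @export
enrich <- function(geneList, catalog, background) {
  background <- unique(as.character(background))
  geneList <- unique(as.character(geneList))
  if (!length(background)) stop("empty background")
  if (!length(geneList)) stop("empty gene list")
  outside <- setdiff(geneList, background)
  if (length(outside))
    stop("gene list not contained in background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(background); n <- length(geneList)
  rows <- lapply(names(catalog), function(nm) {
    members <- intersect(unique(catalog[[nm]]), background)
    K <- length(members)
    k <- length(intersect(geneList, members))
    if (k == 0) return(NULL)
    p <- cernaPvalue(k, K, n, N)
    data.frame(set_name = nm, k = k, K_set = K, n_list = n, N_bg = N,
               p_value = p,
               fold_enrichment = (k / n) / (K / N),
               enrichment_score = -log10(p),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(set_name = character(), k = integer(),
                      K_set = integer(), n_list = integer(),
                      N_bg = integer(), p_value = numeric(),
                      fold_enrichment = numeric(),
                      enrichment_score = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set_name, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top significant enrichment terms
#'
#' The first `topK` results passing `p < alpha` — the data behind a top-10
#' enrichment bubble plot (`k` is the bubble-size analog). Ties in p are
#' already broken by set name in [enrich()], so the selection is stable.
#'
#' @param results output of [enrich()].
#' @param topK maximum rows, default 10.
#' @param alpha significance cut-off on the raw p-value, default 0.05.
#' @return data.frame with `set_name`, `k`, `p_value`, `enrichment_score`.
#' @export
topTerms <- function(results, topK = 10L, alpha = 0.05) {
  sig <- results[results$p_value < alpha, , drop = FALSE]
  out <- utils::head(sig, topK)[, c("set_name", "k", "p_value",
                                    "enrichment_score")]
  rownames(out) <- NULL
  out
}
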