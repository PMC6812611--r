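.SITE_TIERS <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

.rnaRevComp <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

.checkRna <- function(s, what) {
  if (grepl("[^ACGU]", s))
    stop(what, " contains characters outside {A,C,G,U}")
  s
}

.seqChar <- function(x) {
  if (is.character(x)) toupper(x) else as.character(x)
}

#' Site-type tier rank (1 = strongest)
#' @param type character vector of site types.
#' @return integer tier ranks: 8mer = 1, 7mer-m8 = 2, 7mer-A1 = 3, 6mer = 4.
#' @export
siteTier <- function(type) match(type, .SITE_TIERS)

.fixedMatchStarts <- function(pattern, text) {
  # zero-width lookahead so overlapping occurrences are all reported
  m <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Find canonical miRNA seed-match sites on a target sequence
#'
#' Scans the target (5'->3') for perfect Watson-Crick reverse complements of
#' the miRNA seed, no G:U wobble: an `8mer` pairs miRNA positions 2-8 with an
#' adenosine on the target opposite miRNA position 1; `7mer-m8` pairs
#' positions 2-8; `7mer-A1` pairs positions 2-7 plus the opposite-position-1
#' A; `6mer` pairs positions 2-7. On the target the position-1 partner sits
#' immediately 3' of the seed match. Each target window (keyed by that
#' position-1 anchor) is reported once at its highest tier, so a 6mer inside
#' an 8mer is not double-counted.
#'
#' Circular targets (covalently closed circRNAs) are scanned across the
#' back-splice junction by extending the sequence with its first 7
#' nucleotides; positions are reported modulo the target length and wrapped
#' duplicates suppressed.
#'
#' @param mirna miRNA sequence (character or RNAString-like), length >= 8,
#'   5'->3'.
#' @param target target sequence, length >= 6.
#' @param circular is the target covalently closed?
#' @param mirnaId,targetId ids used in the output table.
#' @return data.frame with columns `mirna_id`, `target_id`, `site_type`,
#'   `start` (0-based start of the seed-paired region, modulo length for
#'   circular targets), `au_score` (filled by [auScore()]).
#' @examples
#' findSeedSites("UGCUGGUCAAAAAAAAAAAAAA", "CCCGACCAGCACCC",
#'               mirnaId = "m", targetId = "t")
#' @export
findSeedSites <- function(mirna, target, circular = FALSE,
                          mirnaId = "miRNA", targetId = "target") {
  m <- .checkRna(.seqChar(mirna), "miRNA")
  t <- .checkRna(.seqChar(target), "target")
  if (nchar(m) < 8) stop("miRNA must be at least 8 nt")
  L <- nchar(t)
  if (L < 6) stop("target must be at least 6 nt")
  seed78 <- substr(m, 2, 8)
  p7 <- .rnaRevComp(seed78)      # 7-nt target match for positions 2-8
  p6 <- substr(p7, 2, 7)         # 6-nt target match for positions 2-7
  ext <- if (circular)
    substr(strrep(t, 1L + ceiling(7 / L)), 1L, L + 7L) else t
  extLen <- nchar(ext)
  hit <- function(starts, width) {
    # anchor = target position opposite miRNA position 1 (1-based, on ext)
    data.frame(start = starts, anchor = starts + width,
               a1 = substr(rep(ext, length(starts)), starts + width,
                           starts + width) == "A" &
                    (circular | starts + width <= L))
  }
  s7 <- .fixedMatchStarts(p7, ext)
  s6 <- .fixedMatchStarts(p6, ext)
  if (circular) { s7 <- s7[s7 <= L]; s6 <- s6[s6 <= L] }
  rows <- list()
  if (length(s7)) {
    h <- hit(s7, 7L)
    rows[[1]] <- data.frame(start = h$start, anchor = h$anchor,
                            site_type = ifelse(h$a1, "8mer", "7mer-m8"))
  }
  if (length(s6)) {
    h <- hit(s6, 6L)
    rows[[2]] <- data.frame(start = h$start, anchor = h$anchor,
                            site_type = ifelse(h$a1, "7mer-A1", "6mer"))
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), target_id = character(),
                      site_type = character(), start = integer(),
                      au_score = numeric(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (circular) df$anchor <- ((df$anchor - 1L) %% L) + 1L
  # best tier per anchor window
  df <- df[order(df$anchor, siteTier(df$site_type)), , drop = FALSE]
  df <- df[!duplicated(df$anchor), , drop = FALSE]
  start0 <- if (circular) (df$start - 1L) %% L else df$start - 1L
  out <- data.frame(mirna_id = mirnaId, target_id = targetId,
                    site_type = df$site_type, start = as.integer(start0),
                    au_score = NA_real_, stringsAsFactors = FALSE)
  out <- out[order(out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out$au_score <- vapply(seq_len(nrow(out)), function(i) {
    auScore(t, out$start[i], out$site_type[i], circular = circular)
  }, 0)
  out
}

.siteSpan <- function(type) c("8mer" = 8L, "7mer-m8" = 7L,
                              "7mer-A1" = 7L, "6mer" = 6L)[[type]]

#' AU content of a site's flanking context
#'
#' Fraction of A/U nucleotides among up to `flank` nucleotides on each side
#' of the site (seed-paired region plus the position-1 adenosine where the
#' type includes it). Flanks wrap around the junction for circular targets
#' and truncate at the ends of linear ones.
#'
#' @param target target sequence.
#' @param start 0-based site start as reported by [findSeedSites()].
#' @param siteType one of `8mer`, `7mer-m8`, `7mer-A1`, `6mer`.
#' @param flank context width per side, default 30.
#' @param circular is the target circular?
#' @return AU fraction in `[0, 1]`; `NaN`-free (a site with no flank at all
#'   scores 0).
#' @export
auScore <- function(target, start, siteType, flank = 30L, circular = FALSE) {
  t <- .checkRna(.seqChar(target), "target")
  L <- nchar(t)
  span <- .siteSpan(siteType)
  if (start < 0 || start >= L) stop("site start outside target")
  chars <- strsplit(t, "")[[1]]
  idx <- function(i) chars[((i - 1L) %% L) + 1L]
  left <- (start - flank + 1L):start            # 1-based positions
  right <- (start + span + 1L):(start + span + flank)
  if (!circular) {
    left <- left[left >= 1L]
    right <- right[right <= L]
  } else {
    # never wrap into the site itself on short circles
    avail <- L - span
    left <- utils::tail(left, min(length(left), ceiling(avail / 2)))
    right <- utils::head(right, min(length(right), floor(avail / 2)))
  }
  fl <- c(vapply(left, idx, ""), vapply(right, idx, ""))
  if (!length(fl)) return(0)
  mean(fl %in% c("A", "U"))
}

#' Rank a miRNA library against one circRNA and keep the top K
#'
#' Aggregates every miRNA's sites on the circRNA and ranks by (1) best site
#' tier (8mer > 7mer-m8 > 7mer-A1 > 6mer), (2) number of distinct site
#' windows, (3) maximum flank AU score, (4) miRNA id — a total order, so the
#' returned list is invariant to library shuffling. miRNAs with no site are
#' excluded.
#'
#' @param circ circRNA sequence (treated as circular).
#' @param mirnaLibrary named character vector or RNAStringSet of mature miRNA
#'   sequences.
#' @param k how many miRNA response elements to keep (default 5).
#' @param circId id used in the output.
#' @return data.frame: `circ_id`, `rank`, `mirna_id`, `best_site_type`,
#'   `n_sites`, `max_au_score`.
#' @export
rankMirnasForCirc <- function(circ, mirnaLibrary, k = 5L, circId = "circ") {
  if (k < 1) stop("k must be >= 1")
  seqs <- .seqChar(mirnaLibrary)
  if (is.null(names(seqs)) && !is.null(names(mirnaLibrary)))
    names(seqs) <- names(mirnaLibrary)
  if (is.null(names(seqs))) stop("miRNA library must be named")
  rows <- lapply(names(seqs), function(id) {
    s <- findSeedSites(seqs[[id]], circ, circular = TRUE, mirnaId = id,
                       targetId = circId)
    if (!nrow(s)) return(NULL)
    data.frame(circ_id = circId, mirna_id = id,
               best_site_type = .SITE_TIERS[min(siteTier(s$site_type))],
               n_sites = nrow(s), max_au_score = max(s$au_score),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(circ_id = character(), rank = integer(),
                      mirna_id = character(), best_site_type = character(),
                      n_sites = integer(), max_au_score = numeric()))
  df <- do.call(rbind, rows)
  ord <- order(siteTier(df$best_site_type), -df$n_sites, -df$max_au_score,
               df$mirna_id, method = "radix")
  df <- df[utils::head(ord, k), , drop = FALSE]
  df <- data.frame(circ_id = df$circ_id, rank = seq_len(nrow(df)),
                   df[-1], stringsAsFactors = FALSE, row.names = NULL)
  df
}

#' Predict a miRNA's gene targets over a 3'UTR library
#'
#' A gene is a predicted target when its (linear) UTR carries at least one
#' site at or above `minTier`.
#'
#' @param mirna miRNA sequence.
#' @param utrLibrary named character vector or RNAStringSet of 3'UTRs,
#'   one per gene.
#' @param minTier weakest accepted site type (default `7mer-A1`).
#' @return sorted character vector of gene ids.
#' @export
predictGeneTargets <- function(mirna, utrLibrary, minTier = "7mer-A1") {
  tierCut <- siteTier(minTier)
  if (is.na(tierCut)) stop("unknown site tier: ", minTier)
  m <- .checkRna(.seqChar(mirna), "miRNA")
  seed78 <- substr(m, 2, 8)
  p7 <- .rnaRevComp(seed78)
  p6 <- substr(p7, 2, 7)
  utrs <- .seqChar(utrLibrary)
  if (is.null(names(utrs)) && !is.null(names(utrLibrary)))
    names(utrs) <- names(utrLibrary)
  # every tier cut is a union of at most two fixed target strings:
  # 8mer = p7+"A", 7mer-m8 = p7, 7mer-A1 = p6+"A", 6mer = p6
  hits <- switch(tierCut,
    grepl(paste0(p7, "A"), utrs, fixed = TRUE),
    grepl(p7, utrs, fixed = TRUE),
    grepl(p7, utrs, fixed = TRUE) |
      grepl(paste0(p6, "A"), utrs, fixed = TRUE),
    grepl(p6, utrs, fixed = TRUE))
  sort(names(utrs)[hits])
}
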