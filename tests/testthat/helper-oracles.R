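# Independent oracles used across the suite. These deliberately avoid the
# package's internals: the scanner oracle walks the target position by
# position with an explicit complement table, and the hypergeometric oracle
# enumerates draws with combn().

randomRna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

rotateSeq <- function(s, offset) {
  L <- nchar(s)
  k <- offset %% L
  if (k == 0) return(s)
  paste0(substr(s, k + 1, L), substr(s, 1, k))
}

# brute-force canonical seed-site scanner
bruteSeedSites <- function(mirna, target, circular = FALSE) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(target, "")[[1]]
  L <- length(t)
  at <- function(i) t[((i - 1) %% L) + 1]
  inb <- function(i) circular || i <= L
  cand <- list()
  for (s in 1:L) {
    # target s..s+6 pairs miRNA positions 8..2
    m78 <- all(vapply(0:6, function(j)
      inb(s + j) && at(s + j) == comp[[m[8 - j]]], TRUE))
    m67 <- all(vapply(0:5, function(j)
      inb(s + j) && at(s + j) == comp[[m[7 - j]]], TRUE))
    if (m78) {
      a <- s + 7L
      hasA <- inb(a) && at(a) == "A"
      cand[[length(cand) + 1]] <- data.frame(
        start = s - 1L, anchor = if (circular) ((a - 1L) %% L) + 1L else a,
        tier = if (hasA) 1L else 2L)
    }
    if (m67) {
      a <- s + 6L
      hasA <- inb(a) && at(a) == "A"
      cand[[length(cand) + 1]] <- data.frame(
        start = s - 1L, anchor = if (circular) ((a - 1L) %% L) + 1L else a,
        tier = if (hasA) 3L else 4L)
    }
  }
  if (!length(cand))
    return(data.frame(site_type = character(), start = integer()))
  df <- do.call(rbind, cand)
  df <- df[order(df$anchor, df$tier), , drop = FALSE]
  df <- df[!duplicated(df$anchor), , drop = FALSE]
  tiers <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  out <- data.frame(site_type = tiers[df$tier],
                    start = as.integer(df$start),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# reverse complement used only to *plant* sites in oracle fixtures
plantSite8mer <- function(mirna) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seed <- strsplit(substr(mirna, 2, 8), "")[[1]]
  paste0(paste(comp[rev(seed)], collapse = ""), "A")
}

writeIntoCircle <- function(seq, site, start1) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- ((start1 - 1 + seq_len(nchar(site)) - 1) %% L) + 1
  chars[pos] <- strsplit(site, "")[[1]]
  paste(chars, collapse = "")
}

# exhaustive hypergeometric tail: enumerate all size-n draws from 1..N,
# gene set = {1..K}, count overlaps >= c
enumCernaTail <- function(c, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= c)
}

# quantile normalization by first principles on a tie-free matrix
naiveQuantileNormalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) ref[rank(col)])
}
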