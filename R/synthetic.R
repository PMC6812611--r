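#' Configuration of the synthetic two-group microarray study
#'
#' Captures the desk-scale analogue of a two-group (control vs treated)
#' circRNA/mRNA microarray experiment with a planted ceRNA sponge: a miRNA
#' library, circular RNAs carrying exact seed sites for their planted
#' miRNAs (one site spanning the back-splice junction of the designated
#' sponge), gene 3'UTRs carrying sites for the sponge miRNAs, log-normal
#' intensities with planted log2 fold changes, a shared latent factor
#' coupling the sponge circRNA to its reachable mRNAs, detection flags,
#' annotations, three disjoint functional modules and a qPCR Ct table.
#'
#' @param nCirc,nMirna,nGene probe counts for the three species.
#' @param nControl,nTreated samples per group.
#' @param spongeCircCount planted sponge circRNAs.
#' @param mirnasPerCirc planted miRNAs per circRNA.
#' @param sitesPerMirna planted seed sites per (circRNA, miRNA) pair.
#' @param targetsPerMirna planted target genes per sponge miRNA.
#' @param deFraction fraction of probes with a planted group effect.
#' @param effectLog2 planted |log2 fold change| of DE probes.
#' @param sigmaLog2 within-probe log2 noise SD.
#' @param coupling latent-factor weight tying the sponge circRNA to its
#'   reachable mRNAs (induces positive Pearson correlation).
#' @param flagAbsentQuantile intensity quantile below which a cell is
#'   flagged `A` (cells up to 1.5x this quantile are `M`).
#' @param ctSigma qPCR Ct noise SD (cycles).
#' @param nPerGroupQpcr qPCR replicates per group.
#' @param circLength,utrLength sequence lengths (nt).
#' @param seed RNG seed; the same config yields byte-identical outputs.
#' @return a `simConfig` list.
#' @export
simConfig <- function(nCirc = 40L, nMirna = 60L, nGene = 800L,
                      nControl = 6L, nTreated = 6L, spongeCircCount = 1L,
                      mirnasPerCirc = 2L, sitesPerMirna = 2L,
                      targetsPerMirna = 8L, deFraction = 0.1,
                      effectLog2 = 1.2, sigmaLog2 = 0.3, coupling = 0.8,
                      flagAbsentQuantile = 0.05, ctSigma = 0.15,
                      nPerGroupQpcr = 3L, circLength = 300L,
                      utrLength = 150L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$nCirc >= 1, cfg$nMirna >= 1, cfg$nGene >= 1,
            cfg$nControl >= 2, cfg$nTreated >= 2,
            cfg$deFraction >= 0, cfg$deFraction <= 1,
            cfg$coupling >= 0, cfg$coupling <= 1,
            cfg$spongeCircCount >= 0, cfg$spongeCircCount <= cfg$nCirc)
  structure(cfg, class = "simConfig")
}

.randSeq <- function(n, len, alphabet = c("A", "C", "G", "U")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

# independent re-derivation of the 8mer target site (complement lookup,
# not shared with the scanner's pattern construction)
.plantSiteSeq <- function(mirnaSeq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seed <- strsplit(substr(mirnaSeq, 2, 8), "")[[1]]
  paste0(paste(comp[rev(seed)], collapse = ""), "A")
}

.overwriteWrapped <- function(seq, site, start1) {
  # write `site` into circular `seq` starting at 1-based start1, wrapping
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- ((start1 - 1L + seq_len(nchar(site)) - 1L) %% L) + 1L
  chars[pos] <- strsplit(site, "")[[1]]
  paste(chars, collapse = "")
}

#' Generate a synthetic ceRNA study with known ground truth
#'
#' All randomness flows from `config$seed` through one stream in a fixed
#' order, so the emitted objects (and files, when `outDir` is given) are
#' reproducible bit for bit. Emits miRNA/circRNA/UTR FASTA, circRNA and
#' mRNA expression tables with detection flags, circRNA annotations, a
#' three-module GMT catalog, a qPCR Ct table and a ground-truth JSON.
#'
#' @param config a [simConfig()].
#' @param outDir optional output directory; created if missing. An existing
#'   non-empty directory is refused unless `force`.
#' @param force overwrite an existing non-empty `outDir`.
#' @return invisibly, a list with the in-memory objects (`mirnas`, `circs`,
#'   `utrs`, `circExpr`, `mrnaExpr`, `annotations`, `modules`, `ct`,
#'   `groundTruth`, and `paths` when written).
#' @export
generateSyntheticData <- function(config = simConfig(), outDir = NULL,
                                  force = FALSE) {
  stopifnot(inherits(config, "simConfig"))
  if (!is.null(outDir) && dir.exists(outDir) &&
      length(list.files(outDir)) && !force)
    stop("output directory exists and is non-empty (use force = TRUE): ",
         outDir)
  set.seed(config$seed)
  cfg <- config

  mirnaIds <- sprintf("mir%03d", seq_len(cfg$nMirna))
  circIds <- sprintf("circ%03d", seq_len(cfg$nCirc))
  geneIds <- sprintf("gene%04d", seq_len(cfg$nGene))

  ## 1. miRNA library (mature, 22 nt)
  mirnas <- stats::setNames(.randSeq(cfg$nMirna, 22L), mirnaIds)

  ## 2. planted circRNA -> miRNA map and circular sequences
  mreMap <- stats::setNames(lapply(circIds, function(ci)
    sort(sample(mirnaIds, cfg$mirnasPerCirc))), circIds)
  spongeIds <- circIds[seq_len(cfg$spongeCircCount)]
  junctionCirc <- if (length(spongeIds)) spongeIds[1] else NA_character_
  circs <- stats::setNames(.randSeq(cfg$nCirc, cfg$circLength), circIds)
  siteGap <- 40L
  for (ci in circIds) {
    planted <- mreMap[[ci]]
    slot <- 0L
    for (mi in planted) {
      site <- .plantSiteSeq(mirnas[[mi]])
      for (s in seq_len(cfg$sitesPerMirna)) {
        start1 <- 30L + slot * siteGap
        if (identical(ci, junctionCirc) && slot == 0L)
          start1 <- cfg$circLength - 3L   # spans the back-splice junction
        circs[[ci]] <- .overwriteWrapped(circs[[ci]], site, start1)
        slot <- slot + 1L
      }
    }
  }

  ## 3. planted miRNA -> gene targets (sponge miRNAs only) and UTRs
  spongeMirnas <- sort(unique(unlist(mreMap[spongeIds], use.names = FALSE)))
  pool <- geneIds
  targetMap <- stats::setNames(lapply(spongeMirnas, function(mi) {
    g <- sort(sample(pool, cfg$targetsPerMirna))
    pool <<- setdiff(pool, g)
    g
  }), spongeMirnas)
  utrs <- stats::setNames(.randSeq(cfg$nGene, cfg$utrLength), geneIds)
  for (mi in spongeMirnas) {
    site <- .plantSiteSeq(mirnas[[mi]])
    for (g in targetMap[[mi]])
      utrs[[g]] <- .overwriteWrapped(utrs[[g]], site, 51L)
  }
  plantedGenes <- sort(unique(unlist(targetMap, use.names = FALSE)))

  ## 4. differential-expression ground truth
  nExtraCirc <- round(cfg$deFraction * cfg$nCirc)
  extraCirc <- sample(setdiff(circIds, spongeIds), min(nExtraCirc,
                      cfg$nCirc - length(spongeIds)))
  extraDir <- rep(c("down", "up"), length.out = length(extraCirc))
  deCirc <- stats::setNames(c(rep("up", length(spongeIds)), extraDir),
                            c(spongeIds, extraCirc))
  nExtraGene <- round(cfg$deFraction * cfg$nGene)
  freeGenes <- setdiff(geneIds, plantedGenes)
  extraGene <- sample(freeGenes, min(nExtraGene, length(freeGenes)))
  deGene <- stats::setNames(
    c(rep("up", length(plantedGenes)),
      sample(c("up", "down"), length(extraGene), replace = TRUE)),
    c(plantedGenes, extraGene))

  ## 5. expression matrices
  sampleIds <- c(sprintf("A%d", seq_len(cfg$nControl)),
                 sprintf("B%d", seq_len(cfg$nTreated)))
  groups <- stats::setNames(rep(c("control", "treated"),
                                c(cfg$nControl, cfg$nTreated)), sampleIds)
  treatedCol <- groups == "treated"
  ## shared latent noise: the sponge circRNA carries it outright and each
  ## coupled mRNA mixes it in at weight `coupling`, with its own noise scaled
  ## so the marginal per-probe noise SD stays sigmaLog2 (correlation without
  ## variance inflation)
  latent <- rnorm(length(sampleIds), 0, cfg$sigmaLog2)
  buildExpr <- function(ids, deMap, coupled, latentWeight) {
    base <- rnorm(length(ids), 8, 1.5)
    names(base) <- ids
    base[coupled] <- rnorm(length(coupled), 9, 0.8)
    x <- matrix(rnorm(length(ids) * length(sampleIds), 0, cfg$sigmaLog2),
                length(ids), length(sampleIds),
                dimnames = list(ids, sampleIds))
    if (length(coupled) && latentWeight > 0) {
      w <- latentWeight
      x[coupled, ] <- sqrt(1 - w^2) * x[coupled, , drop = FALSE] +
        matrix(w * latent, length(coupled), length(sampleIds), byrow = TRUE)
    }
    x <- x + base
    de <- intersect(ids, names(deMap))
    sgn <- ifelse(deMap[de] == "up", 1, -1)
    x[de, treatedCol] <- x[de, treatedCol] + sgn * cfg$effectLog2
    lin <- 2^x
    q <- stats::quantile(lin, cfg$flagAbsentQuantile)
    flags <- matrix("P", nrow(lin), ncol(lin), dimnames = dimnames(lin))
    flags[lin < 1.5 * q] <- "M"
    flags[lin < q] <- "A"
    CernaExpression(lin, groups, flags = flags, scale = "linear")
  }
  circExpr <- buildExpr(circIds, deCirc, spongeIds, 1)
  mrnaExpr <- buildExpr(geneIds, deGene, plantedGenes, cfg$coupling)

  ## 6. circRNA annotations (exonic modal, chromosome skew as in mouse)
  types <- sample(.CIRC_TYPES, cfg$nCirc, replace = TRUE,
                  prob = c(0.50, 0.12, 0.20, 0.10, 0.08))
  chromPool <- c(paste0("chr", 1:19), "chrX")
  chromW <- rep(1, 20)
  chromW[c(1, 2, 5, 7, 11)] <- 3
  chroms <- sample(chromPool, cfg$nCirc, replace = TRUE, prob = chromW)
  annotations <- data.frame(
    probe_id = circIds,
    regulation = ifelse(circIds %in% names(deCirc),
                        deCirc[circIds], ""),
    p_value = ifelse(circIds %in% names(deCirc), 0.01, 0.8),
    fold_change = ifelse(circIds %in% names(deCirc),
                         round(2^cfg$effectLog2, 2), 1),
    circ_type = types, chromosome = chroms,
    best_transcript = sprintf("NM_%06d", seq_len(cfg$nCirc)),
    gene_symbol = sprintf("Sym%03d", seq_len(cfg$nCirc)),
    stringsAsFactors = FALSE)

  ## 7. functional modules: three disjoint sets over planted + filler genes
  moduleNames <- c("survival", "neuron", "channel")
  assign <- stats::setNames(
    moduleNames[(seq_along(plantedGenes) - 1L) %% 3L + 1L], plantedGenes)
  filler <- sample(setdiff(geneIds, c(plantedGenes, extraGene)),
                   min(60L, length(setdiff(geneIds,
                                           c(plantedGenes, extraGene)))))
  fillAssign <- stats::setNames(
    moduleNames[(seq_along(filler) - 1L) %% 3L + 1L], filler)
  moduleAssign <- c(assign, fillAssign)
  modules <- lapply(moduleNames, function(m)
    sort(names(moduleAssign)[moduleAssign == m]))
  names(modules) <- moduleNames

  ## 8. qPCR Ct table: sponge + up to 3 more DE circ assays; two assays
  ##    planted discordant with the array call (as validation often finds)
  qSamples <- c(sprintf("C%d", seq_len(cfg$nPerGroupQpcr)),
                sprintf("T%d", seq_len(cfg$nPerGroupQpcr)))
  qGroups <- rep(c("control", "treated"), each = cfg$nPerGroupQpcr)
  downCirc <- names(deCirc)[deCirc == "down"]
  upCirc <- setdiff(names(deCirc)[deCirc == "up"], spongeIds)
  assayIds <- c(if (length(spongeIds)) spongeIds[1],
                if (length(downCirc) >= 1) downCirc[1],
                if (length(upCirc) >= 1) upCirc[1],
                if (length(downCirc) >= 2) downCirc[2])
  trueRq <- stats::setNames(
    c(2^cfg$effectLog2, 0.25, 0.5, 1.8)[seq_along(assayIds)], assayIds)
  refCt <- stats::setNames(rnorm(length(qSamples), 18, 0.2), qSamples)
  ctRows <- data.frame(sample_id = qSamples, group = qGroups,
                       assay_id = "GAPDH", ct = unname(refCt),
                       stringsAsFactors = FALSE)
  for (aid in assayIds) {
    dctBase <- 5
    shift <- ifelse(qGroups == "treated", -log2(trueRq[[aid]]), 0)
    ctRows <- rbind(ctRows, data.frame(
      sample_id = qSamples, group = qGroups, assay_id = aid,
      ct = unname(refCt) + dctBase + shift +
        rnorm(length(qSamples), 0, cfg$ctSigma),
      stringsAsFactors = FALSE))
  }
  attr(ctRows, "ref_assay") <- "GAPDH"
  attr(ctRows, "control_group") <- "control"

  groundTruth <- list(
    de_circ = as.list(deCirc), de_gene = as.list(deGene),
    sponge_circ_ids = spongeIds, junction_circ = junctionCirc,
    mre_map = mreMap, target_map = targetMap,
    module_assignment = as.list(moduleAssign),
    true_rq = as.list(trueRq),
    expected_concordant = as.list(stats::setNames(
      (trueRq > 1) == (deCirc[assayIds] == "up"), assayIds)))

  out <- list(mirnas = mirnas, circs = circs, utrs = utrs,
              circExpr = circExpr, mrnaExpr = mrnaExpr,
              annotations = annotations, modules = modules, ct = ctRows,
              groundTruth = groundTruth, config = cfg)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)
    writeFasta(mirnas, p("mirnas.fa"))
    writeFasta(circs, p("circ.fa"))
    writeFasta(utrs, p("utr.fa"))
    writeExpressionTable(circExpr, p("expr_circ.tsv"))
    writeExpressionTable(mrnaExpr, p("expr_mrna.tsv"))
    write.table(annotations, p("annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeGeneSets(modules, p("modules.gmt"))
    write.table(ctRows, p("ct.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(groundTruth, p("ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    grp <- data.frame(sample_id = sampleIds, group = unname(groups))
    write.table(grp, p("groups.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- vapply(c("mirnas.fa", "circ.fa", "utr.fa",
                          "expr_circ.tsv", "expr_mrna.tsv",
                          "annotations.tsv", "modules.gmt", "ct.tsv",
                          "ground_truth.json", "groups.tsv"), p, "")
  }
  invisible(out)
}
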