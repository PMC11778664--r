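#' Read genotype + phenotype data into a GenotypeDataset
#'
#' Two text formats are supported. \code{"dosage"}: a tab-delimited table
#' with header \code{subject_id} followed by SNP identifiers, one row per
#' subject, entries 0/1/2/NA counting minor alleles; SNP map fields are read
#' from the sidecar table \code{snpPath} (columns \code{snp_id},
#' \code{chrom}, \code{pos_bp}, \code{allele_major}, \code{allele_minor})
#' when supplied, otherwise a placeholder map is synthesised.
#' \code{"ped_map"}: a PLINK text pair; the .ped holds FID, IID, PAT, MAT,
#' SEX, PHENO (1 = control, 2 = case) then two allele tokens per SNP
#' ("0" = missing); the .map holds chrom, snp_id, cM, bp.
#'
#' The minor allele of each SNP is the less frequent allele in the loaded
#' sample, ties broken lexicographically by allele string.
#'
#' @param genotypePath path to the dosage table or .ped file
#' @param phenotypePath optional tab-delimited phenotype table with header
#'   \code{subject_id status subtype arm_id}; overrides/augments the ped
#'   phenotype column
#' @param format \code{"dosage"} or \code{"ped_map"}
#' @param mapPath .map path (defaults to the .ped path with extension
#'   swapped)
#' @param snpPath optional SNP metadata sidecar for the dosage format
#' @return A \linkS4class{GenotypeDataset}.
#' @export
readGenotypes <- function(genotypePath, phenotypePath = NULL,
                          format = c("dosage", "ped_map"),
                          mapPath = NULL, snpPath = NULL) {
  format <- match.arg(format)
  if (format == "dosage") {
    tab <- read.table(genotypePath, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(tab)[1] != "subject_id")
      stop("dosage table must start with a 'subject_id' column")
    calls <- as.matrix(tab[, -1, drop = FALSE])
    ok <- calls[!is.na(calls)]
    if (length(ok) && !all(ok %in% c(0, 1, 2))) {
      bad <- which(apply(calls, 1, function(r)
        any(!is.na(r) & !(r %in% c(0, 1, 2)))))[1]
      stop(sprintf("malformed dosage entry at line %d of %s",
                   bad + 1L, genotypePath))
    }
    rownames(calls) <- tab$subject_id
    if (!is.null(snpPath)) {
      snps <- read.table(snpPath, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
      if (!identical(snps$snp_id, colnames(calls)))
        stop("snp table does not match dosage header")
    } else {
      snps <- data.frame(snp_id = colnames(calls), chrom = "1",
                         pos_bp = seq_len(ncol(calls)),
                         allele_major = "A", allele_minor = "B",
                         stringsAsFactors = FALSE)
    }
    snps$maf <- NULL
    subjects <- .readPhenotype(phenotypePath, rownames(calls))
  } else {
    if (is.null(mapPath)) mapPath <- sub("\\.ped$", ".map", genotypePath)
    map <- read.table(mapPath, header = FALSE, sep = "",
                      stringsAsFactors = FALSE,
                      col.names = c("chrom", "snp_id", "cM", "pos_bp"))
    lines <- readLines(genotypePath)
    toks <- strsplit(trimws(lines), "[ \t]+")
    S <- nrow(map)
    want <- 6 + 2 * S
    nt <- lengths(toks)
    if (any(nt != want))
      stop(sprintf("malformed line %d in %s: %d fields, expected %d",
                   which(nt != want)[1], genotypePath,
                   nt[which(nt != want)[1]], want))
    ped <- do.call(rbind, toks)
    ids <- ped[, 2]
    a1 <- ped[, 6 + 2 * seq_len(S) - 1, drop = FALSE]
    a2 <- ped[, 6 + 2 * seq_len(S), drop = FALSE]
    calls <- matrix(NA_integer_, nrow = length(ids), ncol = S,
                    dimnames = list(ids, map$snp_id))
    allele_major <- allele_minor <- character(S)
    for (s in seq_len(S)) {
      al <- c(a1[, s], a2[, s])
      obs <- al[al != "0"]
      lev <- sort(unique(obs))
      if (length(lev) > 2)
        stop(sprintf("SNP %s has more than two alleles: %s", map$snp_id[s],
                     paste(lev, collapse = "/")))
      if (length(lev) == 0) lev <- c("A", "B")
      if (length(lev) == 1) lev <- c(lev, lev)
      cnt <- c(sum(obs == lev[1]), sum(obs == lev[2]))
      # minor = less frequent; ties broken lexicographically
      minor <- if (cnt[1] < cnt[2]) lev[1] else
               if (cnt[2] < cnt[1]) lev[2] else min(lev)
      major <- setdiff(lev, minor)[1]
      if (is.na(major)) major <- minor
      allele_major[s] <- major
      allele_minor[s] <- minor
      miss <- a1[, s] == "0" | a2[, s] == "0"
      calls[, s] <- (a1[, s] == minor) + (a2[, s] == minor)
      calls[miss, s] <- NA_integer_
    }
    snps <- data.frame(snp_id = map$snp_id, chrom = as.character(map$chrom),
                       pos_bp = map$pos_bp, allele_major = allele_major,
                       allele_minor = allele_minor, stringsAsFactors = FALSE)
    subjects <- .readPhenotype(phenotypePath, ids,
                               pedStatus = c("control", "case")[
                                 match(ped[, 6], c("1", "2"))])
  }
  GenotypeDataset(calls, subjects, snps)
}

.readPhenotype <- function(phenotypePath, ids, pedStatus = NULL) {
  if (is.null(phenotypePath)) {
    if (is.null(pedStatus))
      stop("a phenotype table is required for the dosage format")
    return(data.frame(subject_id = ids, status = pedStatus,
                      subtype = "unknown", arm_id = "arm1",
                      stringsAsFactors = FALSE))
  }
  ph <- read.table(phenotypePath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  missing <- setdiff(ids, ph$subject_id)
  extra <- setdiff(ph$subject_id, ids)
  if (length(missing) || length(extra))
    stop("phenotype/genotype subject mismatch; missing from phenotype: [",
         paste(missing, collapse = ", "), "]; absent from genotypes: [",
         paste(extra, collapse = ", "), "]")
  ph <- ph[match(ids, ph$subject_id), , drop = FALSE]
  if (is.null(ph$subtype)) ph$subtype <- "unknown"
  if (is.null(ph$arm_id)) ph$arm_id <- "arm1"
  ph
}

#' Write a GenotypeDataset to disk
#'
#' Writes the genotype matrix plus phenotype table (and, for the dosage
#' format, the SNP metadata sidecar) in the formats \code{\link{readGenotypes}}
#' reads; a write/read round trip reproduces calls, labels and map fields.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @param dir output directory (created if needed)
#' @param format \code{"dosage"} or \code{"ped_map"}
#' @param prefix file name prefix
#' @return named character vector of the files written, invisibly
#' @export
writeGenotypes <- function(ds, dir, format = c("dosage", "ped_map"),
                           prefix = "arm") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  si <- as.data.frame(subjectInfo(ds))
  ph <- si[, c("subject_id", "status", "subtype", "arm_id")]
  phPath <- file.path(dir, paste0(prefix, ".phenotype.tsv"))
  write.table(ph, phPath, sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- callMatrix(ds)
  sn <- as.data.frame(snpInfo(ds))
  if (format == "dosage") {
    gPath <- file.path(dir, paste0(prefix, ".dosage.tsv"))
    sPath <- file.path(dir, paste0(prefix, ".snps.tsv"))
    out <- data.frame(subject_id = rownames(calls), calls,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(out, gPath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sn[, c("snp_id", "chrom", "pos_bp", "allele_major",
                       "allele_minor")],
                sPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(genotypes = gPath, snps = sPath, phenotype = phPath))
  } else {
    pPath <- file.path(dir, paste0(prefix, ".ped"))
    mPath <- file.path(dir, paste0(prefix, ".map"))
    write.table(data.frame(sn$chrom, sn$snp_id, 0, sn$pos_bp),
                mPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    al <- rbind(sn$allele_major, sn$allele_minor)
    lines <- vapply(seq_len(nrow(calls)), function(j) {
      g <- calls[j, ]
      t1 <- ifelse(is.na(g), "0", ifelse(g >= 1, al[2, ], al[1, ]))
      t2 <- ifelse(is.na(g), "0", ifelse(g == 2, al[2, ], al[1, ]))
      paste(c(rownames(calls)[j], rownames(calls)[j], 0, 0, 0,
              ifelse(si$status[j] == "case", 2, 1),
              as.vector(rbind(t1, t2))), collapse = " ")
    }, character(1))
    writeLines(lines, pPath)
    invisible(c(genotypes = pPath, map = mPath, phenotype = phPath))
  }
}

#' Keep SNPs with minor-allele frequency strictly above a threshold
#'
#' Common-variant filter: retains SNPs whose sample maf exceeds
#' \code{threshold} (strict inequality); the subject set is unchanged.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @param threshold maf threshold in [0, 0.5]; default 0.25
#' @return the filtered \linkS4class{GenotypeDataset}
#' @export
filterByMaf <- function(ds, threshold = 0.25) {
  .assertScalarFraction(threshold, "threshold", 0, 0.5)
  keep <- SummarizedExperiment::rowData(ds)$maf > threshold
  ds[keep, ]
}

#' Expand genotype calls into signed allele-combination features
#'
#' Each SNP yields three allele-combinations (homozygous major,
#' heterozygous, homozygous minor). A call of 0/1/2 sets the matching
#' combination to +1 and the other two to -1; a missing call yields NA for
#' all three.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @return a \linkS4class{ComboMatrix} with 3 x nSNP combos in SNP order
#' @export
expandAlleleCombinations <- function(ds) {
  calls <- callMatrix(ds)
  if (!nrow(calls) || !ncol(calls)) stop("empty dataset")
  S <- ncol(calls)
  kinds <- c("hom_major", "het", "hom_minor")
  blocks <- lapply(0:2, function(k) {
    v <- (calls == k) * 2 - 1
    v[is.na(calls)] <- NA
    v
  })
  wide <- do.call(cbind, blocks)
  perm <- as.vector(rbind(seq_len(S), S + seq_len(S), 2 * S + seq_len(S)))
  values <- wide[, perm, drop = FALSE]
  info <- data.frame(
    combo_id = paste(rep(colnames(calls), each = 3), rep(kinds, S),
                     sep = "_"),
    snp_id = rep(colnames(calls), each = 3),
    kind = rep(kinds, S), stringsAsFactors = FALSE)
  rownames(values) <- rownames(calls)
  ComboMatrix(values, info)
}

#' Szymkiewicz-Simpson overlap coefficient between two SNP panels
#'
#' @param panelA,panelB character vectors of SNP identifiers (non-empty)
#' @return |A n B| / min(|A|, |B|)
#' @export
snpOverlapCoefficient <- function(panelA, panelB) {
  panelA <- unique(panelA)
  panelB <- unique(panelB)
  if (!length(panelA) || !length(panelB)) stop("empty SNP panel")
  length(intersect(panelA, panelB)) / min(length(panelA), length(panelB))
}

#' Restrict a ComboMatrix to the combos of a SNP panel
#'
#' @param cm a \linkS4class{ComboMatrix}
#' @param snpPanel character vector of SNP identifiers to keep
#' @return a \linkS4class{ComboMatrix} with combos of panel SNPs, in the
#'   original order
#' @export
restrictToPanel <- function(cm, snpPanel) {
  keep <- cm@comboInfo$snp_id %in% snpPanel
  ComboMatrix(cm@values[, keep, drop = FALSE],
              cm@comboInfo[keep, , drop = FALSE])
}

#' Read a covariate table
#'
#' Tab-delimited with header \code{subject_id} then covariate columns
#' (genome-wide principal components in typical use).
#'
#' @param path file path
#' @return data.frame of numeric covariates with subject_id rownames
#' @export
readCovariateTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  rownames(tab) <- tab$subject_id
  tab$subject_id <- NULL
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("covariate columns must be numeric")
  tab
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (pathway_id, description, gene ids...)
#' @return list with \code{pathways} (named list of gene-id vectors) and
#'   \code{universe} (union of all pathway genes)
#' @export
readGmt <- function(path) {
  toks <- strsplit(readLines(path), "\t")
  pathways <- lapply(toks, function(x) unique(x[-(1:2)]))
  names(pathways) <- vapply(toks, `[`, character(1), 1)
  list(pathways = pathways, universe = unique(unlist(pathways)))
}

#' Read a gene-to-SNP annotation table
#'
#' @param path two-column tab-delimited file (gene_id, snp_id) with header
#' @return data.frame with columns gene_id, snp_id
#' @export
readGeneSnpAnnotation <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "snp_id") %in% colnames(tab)))
  tab[, c("gene_id", "snp_id")]
}
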