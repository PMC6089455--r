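# Plain-text readers and writers for the exchange formats: summary-statistic
# TSV (SNP CHR BP EA OA EAF BETA SE P N), score-weight TSV, FAM-style
# pedigree files, genotype panel TSV and a minimal VCF writer.

.SUMSTAT_MAP <- c(SNP = "snp", CHR = "chr", BP = "bp", EA = "ea", OA = "oa",
                  EAF = "eaf", BETA = "beta", SE = "se", P = "p", N = "n",
                  STUDY = "study")

#' Read / write summary statistics TSV
#'
#' Tab-separated dialect with required header
#' `SNP CHR BP EA OA EAF BETA SE P N` (optional `STUDY`); `EAF` and `N` may
#' be `NA`.
#'
#' @param path File path.
#' @return `read_sumstats()`: a summary-statistic `data.frame` in internal
#'   (lower-case) column naming.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .required_cols(df, setdiff(names(.SUMSTAT_MAP), "STUDY"), "summary statistics file")
  names(df) <- ifelse(names(df) %in% names(.SUMSTAT_MAP),
                      .SUMSTAT_MAP[names(df)], names(df))
  .check_alleles(df$ea, df$oa, basename(path))
  if (any(!is.na(df$se) & df$se <= 0)) stop("SE must be positive")
  df
}

#' @param stats Summary-statistic `data.frame` (internal naming).
#' @rdname read_sumstats
#' @export
write_sumstats <- function(stats, path) {
  .required_cols(stats, unname(.SUMSTAT_MAP[1:10]), "summary statistics")
  out <- stats[, unname(.SUMSTAT_MAP[seq_len(10 + ("study" %in% names(stats)))]),
               drop = FALSE]
  names(out) <- names(.SUMSTAT_MAP)[seq_along(out)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write score weights TSV (`SNP EA WEIGHT P_SOURCE`)
#'
#' @param path File path.
#' @return `read_weights()`: a [score_weights()]-shaped `data.frame`.
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .required_cols(df, c("SNP", "EA", "WEIGHT"), "weights file")
  data.frame(snp = df$SNP, ea = df$EA, oa = df$OA %||% NA_character_,
             weight = df$WEIGHT,
             p_source = df$P_SOURCE %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' @param weights A [score_weights()] table.
#' @rdname read_weights
#' @export
write_weights <- function(weights, path) {
  .required_cols(weights, c("snp", "ea", "weight"), "weights")
  out <- data.frame(SNP = weights$snp, EA = weights$ea,
                    WEIGHT = weights$weight,
                    P_SOURCE = weights$p_source %||% NA_real_)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a FAM-style pedigree file
#'
#' Whitespace-delimited `FID IID PAT MAT SEX PHENO` with `0` for an unknown
#' parent, `SEX` 0 (unknown)/1/2 and `PHENO` 1 = unaffected, 2 = affected.
#' One family per trio: the child row links to its parents.
#'
#' @param trios A [trio_set()].
#' @param path File path.
#' @export
write_fam <- function(trios, path) {
  n <- nrow(trios)
  fid <- paste0("FAM", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    fa <- trios$father[i]; mo <- trios$mother[i]
    rows[[length(rows) + 1L]] <- data.frame(
      FID = fid[i], IID = trios$child[i],
      PAT = ifelse(is.na(fa), "0", fa), MAT = ifelse(is.na(mo), "0", mo),
      SEX = 0L, PHENO = ifelse(trios$child_affected[i], 2L, 1L))
    if (!is.na(fa)) rows[[length(rows) + 1L]] <- data.frame(
      FID = fid[i], IID = fa, PAT = "0", MAT = "0", SEX = 1L,
      PHENO = ifelse(isTRUE(trios$father_affected[i]), 2L, 1L))
    if (!is.na(mo)) rows[[length(rows) + 1L]] <- data.frame(
      FID = fid[i], IID = mo, PAT = "0", MAT = "0", SEX = 2L,
      PHENO = ifelse(isTRUE(trios$mother_affected[i]), 2L, 1L))
  }
  utils::write.table(do.call(rbind, rows), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fam
#' @return `read_fam()`: a [trio_set()] (without transmission annotations).
#' @export
read_fam <- function(path) {
  df <- utils::read.table(path, stringsAsFactors = FALSE,
                          col.names = c("FID", "IID", "PAT", "MAT", "SEX",
                                        "PHENO"))
  kids <- df[df$PAT != "0" | df$MAT != "0", , drop = FALSE]
  aff <- function(id) {
    hit <- match(id, df$IID)
    ifelse(is.na(hit), NA, df$PHENO[hit] == 2L)
  }
  trio_set(data.frame(
    child = kids$IID,
    father = ifelse(kids$PAT == "0", NA_character_, kids$PAT),
    mother = ifelse(kids$MAT == "0", NA_character_, kids$MAT),
    child_affected = kids$PHENO == 2L,
    father_affected = aff(ifelse(kids$PAT == "0", NA, kids$PAT)),
    mother_affected = aff(ifelse(kids$MAT == "0", NA, kids$MAT)),
    stringsAsFactors = FALSE))
}

#' Write / read a genotype panel as TSV
#'
#' One row per SNP: metadata columns `SNP CHR BP EA OA EAF` followed by one
#' dosage column per sample (`NA` for missing).
#'
#' @param panel A [genotype_panel()].
#' @param path File path.
#' @export
write_panel_tsv <- function(panel, path) {
  meta <- panel$snps
  out <- cbind(data.frame(SNP = meta$snp, CHR = meta$chr, BP = meta$bp,
                          EA = meta$ea, OA = meta$oa, EAF = meta$eaf),
               as.data.frame(t(panel$dosage)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @return `read_panel_tsv()`: a [genotype_panel()].
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .required_cols(df, c("SNP", "CHR", "BP", "EA", "OA", "EAF"), "panel file")
  meta <- data.frame(snp = df$SNP, chr = df$CHR, bp = df$BP, ea = df$EA,
                     oa = df$OA, eaf = df$EAF, stringsAsFactors = FALSE)
  dos <- t(as.matrix(df[, setdiff(names(df), c("SNP", "CHR", "BP", "EA",
                                               "OA", "EAF")), drop = FALSE]))
  colnames(dos) <- meta$snp
  genotype_panel(meta, dos)
}

#' Write a genotype panel as a minimal VCF
#'
#' VCFv4.2 with one biallelic record per SNP (`REF` = other allele, `ALT` =
#' effect allele) and a `GT` field derived from the dosage (`0/0`, `0/1`,
#' `1/1`, `./.` for missing). Phase is not represented. Reading VCFs back is
#' available through [read_panel_vcf()] when the `vcfR` package is
#' installed.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (plain text).
#' @export
write_panel_vcf <- function(panel, path) {
  meta <- panel$snps
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(panel$dosage)),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(meta))) {
    d <- panel$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_map[as.character(d)])
    writeLines(paste(c(meta$chr[j], meta$bp[j], meta$snp[j], meta$oa[j],
                       meta$ea[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype panel from a VCF (requires vcfR)
#'
#' Converts `GT` calls of biallelic sites to effect-allele (ALT) dosages.
#'
#' @param path VCF path.
#' @return A [genotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_panel_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  meta <- data.frame(snp = fix$ID, chr = as.integer(fix$CHROM),
                     bp = as.integer(fix$POS), ea = fix$ALT, oa = fix$REF,
                     eaf = colMeans(t(dose), na.rm = TRUE) / 2,
                     stringsAsFactors = FALSE)
  genotype_panel(meta, t(dose))
}

#' Read / write a phenotype table TSV
#'
#' @param path File path.
#' @return `read_pheno()`: a [pheno_table()].
#' @export
read_pheno <- function(path) {
  pheno_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param pheno A [pheno_table()].
#' @rdname read_pheno
#' @export
write_pheno <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
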