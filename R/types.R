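# Lightweight containers: a genotype panel (dosage matrix plus SNP metadata),
# a trio/duo pedigree index, and a phenotype/covariate table. Plain base-R
# structures with validating constructors, in the style of summary-statistic
# toolkits rather than S4 assay containers.

#' Construct a genotype panel
#'
#' @param snps `data.frame` with one row per SNP and columns `snp`, `chr`,
#'   `bp` (1-based), `ea` (effect allele), `oa` (other allele), `eaf`.
#'   `(chr, bp)` must be strictly increasing within each chromosome.
#' @param dosage Numeric matrix, samples x SNPs, entries in `{0, 1, 2}` or
#'   `NA`; column names must match `snps$snp`, row names are sample ids.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(snps, dosage) {
  .required_cols(snps, c("snp", "chr", "bp", "ea", "oa", "eaf"), "snps")
  if (ncol(dosage) != nrow(snps)) {
    stop("dosage must have one column per SNP metadata row")
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp
  if (!identical(colnames(dosage), as.character(snps$snp))) {
    stop("dosage column names must match snps$snp")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  .check_alleles(snps$ea, snps$oa, "panel SNP metadata")
  for (ch in unique(snps$chr)) {
    bp <- snps$bp[snps$chr == ch]
    if (any(diff(bp) <= 0)) {
      stop(sprintf("bp must be strictly increasing within chromosome %s", ch))
    }
  }
  structure(list(snps = as.data.frame(snps), dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(panel) ncol(panel$dosage)

#' Subset a genotype panel by samples and/or SNPs
#'
#' @param panel A `genotype_panel`.
#' @param samples Optional character vector of sample ids to keep.
#' @param snps Optional character vector of SNP ids to keep.
#' @return A `genotype_panel`.
#' @export
panel_subset <- function(panel, samples = NULL, snps = NULL) {
  dos <- panel$dosage
  meta <- panel$snps
  if (!is.null(snps)) {
    keep <- match(snps, meta$snp)
    if (anyNA(keep)) stop("unknown SNP id(s) in subset")
    meta <- meta[keep, , drop = FALSE]
    dos <- dos[, keep, drop = FALSE]
  }
  if (!is.null(samples)) {
    keep <- match(samples, rownames(dos))
    if (anyNA(keep)) stop("unknown sample id(s) in subset")
    dos <- dos[keep, , drop = FALSE]
  }
  genotype_panel(meta, dos)
}

#' Construct a trio/duo set
#'
#' One row per trio (or duo, with one parent `NA`). Transmission annotations
#' produced by [simulate_trios()] are carried as attributes `transmit_father`
#' and `transmit_mother`: trio x SNP matrices counting the effect alleles the
#' parent transmitted (0/1, `NA` for a masked parent).
#'
#' @param df `data.frame` with columns `child`, `father`, `mother`,
#'   `child_affected`, `father_affected`, `mother_affected`.
#' @param panel Optional `genotype_panel` against which all ids are checked.
#' @param transmit_father,transmit_mother Optional transmission matrices.
#' @return An object of class `trio_set` (a `data.frame`).
#' @export
trio_set <- function(df, panel = NULL,
                     transmit_father = NULL, transmit_mother = NULL) {
  .required_cols(df, c("child", "father", "mother", "child_affected",
                       "father_affected", "mother_affected"), "trio table")
  if (any(df$child == df$father | df$child == df$mother, na.rm = TRUE)) {
    stop("a sample cannot be its own parent")
  }
  if (!is.null(panel)) {
    ids <- c(df$child, df$father, df$mother)
    ids <- ids[!is.na(ids)]
    if (!all(ids %in% rownames(panel$dosage))) {
      stop("trio set references samples absent from the panel")
    }
  }
  out <- as.data.frame(df)
  attr(out, "transmit_father") <- transmit_father
  attr(out, "transmit_mother") <- transmit_mother
  class(out) <- c("trio_set", "data.frame")
  out
}

#' Construct a phenotype/covariate table
#'
#' @param df `data.frame` with columns `sample`, `phenotype` (mm) and any of
#'   the covariates `sex` (0/1), `age` (years), `height` (cm), `pc1`..`pc4`.
#' @return The table with class `pheno_table` prepended.
#' @export
pheno_table <- function(df) {
  .required_cols(df, c("sample", "phenotype"), "phenotype table")
  if (anyDuplicated(df$sample)) stop("one row per sample required")
  num <- df[vapply(df, is.numeric, logical(1))]
  if (length(num) && any(vapply(num, function(x) any(is.infinite(x)), logical(1)))) {
    stop("phenotype and covariates must be finite where present")
  }
  out <- as.data.frame(df)
  class(out) <- c("pheno_table", "data.frame")
  out
}
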