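#' Genotype matrix with sample metadata
#'
#' Samples-by-loci matrix of biallelic genotype codes (0/1/2 copies of the
#' alternate allele, `NA` = missing) plus per-sample metadata: collection site,
#' ecotope (domestic or wild), collection year and projected coordinates.
#'
#' @param geno integer matrix, samples x loci, values in `{0, 1, 2, NA}`.
#' @param meta data.frame with one row per sample and columns `sample_id`,
#'   `site_id`, `ecotope`, `year`, `x`, `y`.
#' @param locus_ids optional character vector of locus names.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, meta, locus_ids = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  need <- c("sample_id", "site_id", "ecotope", "year", "x", "y")
  if (!all(need %in% names(meta))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(meta) != nrow(geno)) stop("metadata rows do not match genotype rows")
  if (anyNA(meta$site_id)) stop("every sample needs a site_id")
  if (any(!is.finite(meta$x)) || any(!is.finite(meta$y))) {
    stop("sample coordinates must be finite")
  }
  if (!all(meta$ecotope %in% c("domestic", "wild"))) {
    stop("ecotope must be 'domestic' or 'wild'")
  }
  if (is.null(locus_ids)) locus_ids <- colnames(geno)
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(geno)))
  dimnames(geno) <- list(as.character(meta$sample_id), locus_ids)
  meta <- as.data.frame(meta)[, need]
  structure(list(geno = geno, meta = meta), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci\n",
              nrow(x$geno), ncol(x$geno)))
  cat(sprintf("  %d sites, %d domestic / %d wild samples, %.2f%% missing\n",
              length(unique(x$meta$site_id)),
              sum(x$meta$ecotope == "domestic"), sum(x$meta$ecotope == "wild"),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a `genotype_matrix`.
#' @param samples logical/integer/character index over samples (optional).
#' @param loci logical/integer/character index over loci (optional).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  g <- gm$geno; m <- gm$meta
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    m <- m[samples, , drop = FALSE]
  }
  if (!is.null(loci)) g <- g[, loci, drop = FALSE]
  genotype_matrix(g, m, colnames(g))
}

## group label per sample: "site", "ecotope", or "site_ecotope"
group_labels <- function(gm, grouping = c("site", "ecotope", "site_ecotope")) {
  grouping <- match.arg(grouping)
  switch(grouping,
         site = as.character(gm$meta$site_id),
         ecotope = as.character(gm$meta$ecotope),
         site_ecotope = paste(gm$meta$site_id, gm$meta$ecotope, sep = ":"))
}

#' Write genotypes and metadata to plain-text files
#'
#' Writes a minimal biallelic VCF (GT field only, `./.` for missing), a
#' samples-by-loci CSV of 0/1/2/NA codes, and the sample metadata CSV.
#'
#' @param gm a `genotype_matrix`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the written file paths.
#' @export
write_genotypes <- function(gm, dir, prefix = "genotypes") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  csv <- file.path(dir, paste0(prefix, ".csv"))
  meta_csv <- file.path(dir, paste0(prefix, "_meta.csv"))

  gt <- t(gm$geno)
  gt_str <- matrix("./.", nrow(gt), ncol(gt))
  gt_str[!is.na(gt) & gt == 0] <- "0/0"
  gt_str[!is.na(gt) & gt == 1] <- "0/1"
  gt_str[!is.na(gt) & gt == 2] <- "1/1"
  body <- cbind("1", seq_len(nrow(gt)), rownames(gt), "A", "T", ".", "PASS",
                ".", "GT", gt_str)
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$geno)), collapse = "\t")),
             con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)

  utils::write.csv(data.frame(sample_id = rownames(gm$geno), gm$geno,
                              check.names = FALSE),
                   csv, row.names = FALSE)
  utils::write.csv(gm$meta, meta_csv, row.names = FALSE)
  invisible(c(vcf = vcf, csv = csv, meta = meta_csv))
}

#' Read genotypes from VCF or CSV plus a metadata CSV
#'
#' VCF input is parsed with the vcfR package (GT field, biallelic records
#' only); CSV input is the samples-by-loci 0/1/2/NA table written by
#' [write_genotypes()].
#'
#' @param path VCF (`.vcf`) or CSV genotype file.
#' @param meta_path sample metadata CSV (`sample_id`, `site_id`, `ecotope`,
#'   `year`, `x`, `y`).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, meta_path) {
  meta <- utils::read.csv(meta_path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    gt <- gsub("|", "/", gt, fixed = TRUE)
    code[gt %in% "0/0"] <- 0L
    code[gt %in% c("0/1", "1/0")] <- 1L
    code[gt %in% "1/1"] <- 2L
    geno <- t(code)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    geno <- as.matrix(tab[, -1, drop = FALSE])
    rownames(geno) <- tab[[1]]
  }
  ord <- match(rownames(geno), meta$sample_id)
  if (anyNA(ord)) stop("metadata is missing samples present in the genotype file")
  genotype_matrix(geno, meta[ord, ], colnames(geno))
}
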