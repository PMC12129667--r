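#' Genotype matrix container
#'
#' A `geno_matrix` holds biallelic SNP genotypes as alternate-allele dosages
#' (0, 1, 2 or `NA` for missing) for a set of samples with population labels,
#' together with per-variant metadata. It is the substrate of every analysis
#' stage: QC, population-structure statistics, the selection scan, and
#' association testing all consume it.
#'
#' @param calls Integer matrix, samples in rows and variants in columns, with
#'   entries in `{0, 1, 2, NA}`. Row names are sample ids, column names
#'   variant ids.
#' @param samples Data frame with columns `sample_id` and `population`, one
#'   row per row of `calls`, in the same order.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, one row per column of `calls`, in the same order.
#'   Positions must be strictly increasing within each chromosome.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, samples, variants) {
  calls <- as.matrix(calls)
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  if (nrow(calls) != nrow(samples)) {
    abort("`calls` must have one row per sample.")
  }
  if (ncol(calls) != nrow(variants)) {
    abort("`calls` must have one column per variant.")
  }
  if (!all(c("sample_id", "population") %in% names(samples))) {
    abort("`samples` needs columns `sample_id` and `population`.")
  }
  if (!all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants))) {
    abort("`variants` needs columns `id`, `chrom`, `pos`, `ref`, `alt`.")
  }
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad) > 0) {
    abort("Genotype dosages must be 0, 1, 2 or NA.")
  }
  by_chrom <- split(variants$pos, variants$chrom)
  if (any(vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1)))) {
    abort("Variant positions must be strictly increasing within a chromosome.")
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- variants$id
  structure(
    list(calls = calls, samples = samples, variants = variants),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  pops <- table(x$samples$population)
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants\n",
    nrow(x$calls), ncol(x$calls)
  ))
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat("  chromosomes:",
      paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Number of samples / variants
#' @param geno A [geno_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(geno) nrow(geno$calls)

#' @rdname n_samples
#' @export
n_variants <- function(geno) ncol(geno$calls)

#' Subset a genotype matrix
#'
#' @param geno A [geno_matrix()].
#' @param sample_ids,variant_ids Character vectors of ids to keep; `NULL`
#'   keeps everything on that margin.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(geno, sample_ids = NULL, variant_ids = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  si <- if (is.null(sample_ids)) seq_len(nrow(geno$calls)) else
    match(sample_ids, geno$samples$sample_id)
  vi <- if (is.null(variant_ids)) seq_len(ncol(geno$calls)) else
    match(variant_ids, geno$variants$id)
  if (anyNA(si)) abort("Unknown sample id in `sample_ids`.")
  if (anyNA(vi)) abort("Unknown variant id in `variant_ids`.")
  geno_matrix(
    geno$calls[si, vi, drop = FALSE],
    geno$samples[si, ], geno$variants[vi, ]
  )
}

#' Read genotypes from a VCF file
#'
#' Reads a (possibly gzipped) VCF with GT fields, keeps biallelic SNP records,
#' and converts genotypes to alternate-allele dosage. Population labels are
#' joined from a sample table.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param sample_table Data frame with `sample_id` and `population`. Samples
#'   absent from the table get population `NA`.
#' @return A [geno_matrix()].
#' @export
read_vcf_geno <- function(path, sample_table = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT %||% "") & !is.na(fix$ALT)
  vcf <- vcf[biallelic, ]
  fix <- fix[biallelic, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  samples <- tibble(sample_id = colnames(gt))
  if (!is.null(sample_table)) {
    samples <- left_join(samples, as_tibble(sample_table), by = "sample_id")
  } else {
    samples$population <- NA_character_
  }
  geno_matrix(t(dos), samples, variants)
}

#' Write genotypes to a VCF file
#'
#' Emits a biallelic, GT-only VCF v4.2 via \pkg{vcfR} (the file is gzipped, so
#' use a `.vcf.gz` extension).
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_geno <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  v <- geno$variants
  fix <- cbind(
    CHROM = as.character(v$chrom), POS = as.character(v$pos), ID = v$id,
    REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS", INFO = "."
  )
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_body <- matrix("./.", nrow = ncol(geno$calls), ncol = nrow(geno$calls))
  dos <- t(geno$calls)
  ok <- !is.na(dos)
  gt_body[ok] <- code[as.character(dos[ok])]
  gt <- cbind(FORMAT = "GT", gt_body)
  colnames(gt) <- c("FORMAT", geno$samples$sample_id)
  vcf <- new("vcfR",
    meta = c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
    ),
    fix = fix, gt = gt
  )
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}
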