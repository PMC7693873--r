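## Readers for the plain-text pipeline inputs: genotype matrices (TSV or
## bi-allelic VCF), subject, phenotype and variant-annotation tables.

#' Read a genotype matrix from TSV or VCF
#'
#' TSV layout: header row of variant ids, first column `subject_id`, entries
#' in \{0, 1, 2, NA\}. VCF: one bi-allelic record per variant, per-sample
#' diploid GT fields converted to alternate-allele counts (`0/1` -> 1,
#' `1|1` -> 2, `./.` -> `NA`); variant ids become `CHROM:POS:REF:ALT`.
#' Multi-allelic records must be pre-split and raise an error.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @return Subjects x variants integer matrix with dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id")
    stop("genotype TSV must have `subject_id` as its first column", call. = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(is.na(G) | G %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed genotype at row %d (subject %s): entries must be 0/1/2/NA",
                 bad[1, 1] + 1L, df$subject_id[bad[1, 1]]), call. = FALSE)
  storage.mode(G) <- "integer"
  rownames(G) <- df$subject_id
  G
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop(sprintf("multi-allelic record(s) at %s; pre-split into bi-allelic records",
                 paste(utils::head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 3L),
                       collapse = ", ")), call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (length(alleles) != 2L)
      stop(sprintf("non-diploid GT field `%s`", x), call. = FALSE)
    if (any(alleles == ".")) return(NA_integer_)
    if (!all(alleles %in% c("0", "1")))
      stop(sprintf("unexpected allele index in GT `%s`", x), call. = FALSE)
    sum(alleles == "1")
  })
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")
  G <- t(counts)
  colnames(G) <- ids
  storage.mode(G) <- "integer"
  G
}

#' Read the subject table
#'
#' Mandatory columns: `subject_id`, `status` (0/1), `age`, `sex`, `bmi`.
#' Unknown columns are preserved but ignored downstream.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_subjects <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "status", "age", "sex", "bmi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("subject table missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(df$status %in% c(0L, 1L)))
    stop("subject `status` must be 0 or 1", call. = FALSE)
  df
}

#' Read the phenotype (outcome) table
#'
#' Mandatory column `subject_id`; the remaining columns are outcome
#' variables. Variables absent from the table are simply not evaluated.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df))
    stop("phenotype table missing mandatory column: subject_id", call. = FALSE)
  df
}

#' Read the variant annotation table
#'
#' Mandatory columns: `variant_id`, `gene_region`, `class_source1..3`
#' (functional classes from the closed vocabulary) and `reference_freq` in
#' `[0, 1]`.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "gene_region", "class_source1", "class_source2",
            "class_source3", "reference_freq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("annotation table missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(df$reference_freq) | df$reference_freq < 0 |
          df$reference_freq > 1))
    stop_field("reference_freq", "must lie in [0, 1] for all variants")
  cls <- unlist(df[, c("class_source1", "class_source2", "class_source3")])
  bad <- setdiff(unique(cls), FUNCTIONAL_CLASSES)
  if (length(bad))
    stop(sprintf("unknown functional class value(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  df
}
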