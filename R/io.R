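#' Write and read dosage matrices as tab-delimited text
#'
#' Marker-by-individual layout: columns `marker`, `chrom`, `pos`, then one
#' column per individual with dosage codes 1/0/-1 and NA for missing.
#'
#' @param geno Dosage matrix (individuals x markers).
#' @param map Marker map matching the columns of `geno`.
#' @param file Path.
#' @return `write_dosage` returns the path invisibly; `read_dosage` returns
#'   a list with `geno` and `map`.
#' @export
write_dosage <- function(geno, map, file) {
  df <- data.frame(marker = map$id, chrom = map$chrom, pos = map$pos,
                   t(geno), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  map <- data.frame(id = df$marker, chrom = df$chrom, pos = df$pos,
                    stringsAsFactors = FALSE)
  geno <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  colnames(geno) <- map$id
  storage.mode(geno) <- "integer"
  list(geno = geno, map = map)
}

#' Write genotypes (or phased haplotypes) as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT fields only. Allele "A" (the allele counted
#' by the dosage coding) is written as REF. With `haps` given, genotypes
#' are written phased (`|` separator, haplotype 1 first); otherwise the
#' dosage matrix is written unphased (1 -> 0/0, 0 -> 0/1, -1 -> 1/1,
#' NA -> ./.).
#'
#' @param geno Dosage matrix (individuals x markers), or NULL.
#' @param haps List with `h1`, `h2` 0/1 haplotype matrices, or NULL.
#' @param map Marker map.
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(geno = NULL, haps = NULL, map, file) {
  if (is.null(geno) && is.null(haps)) stopf("write_vcf: supply geno or haps")
  if (!is.null(haps)) {
    ids <- rownames(haps$h1)
    gt <- matrix(paste0(1L - haps$h1, "|", 1L - haps$h2),
                 nrow(haps$h1), ncol(haps$h1))
  } else {
    ids <- rownames(geno)
    code <- c(`1` = "0/0", `0` = "0/1", `-1` = "1/1")
    gt <- matrix("./.", nrow(geno), ncol(geno))
    obs <- !is.na(geno)
    gt[obs] <- code[as.character(geno[obs])]
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  body <- cbind(map$chrom, map$pos, map$id, "A", "T", ".", ".", ".", "GT", t(gt))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(file)
}

#' Read a GT-only VCF into a dosage matrix
#'
#' Uses the vcfR package when available; falls back to a plain-text parse of
#' GT-only VCFs such as those written by [write_vcf()].
#'
#' @param file Path to an uncompressed VCF.
#' @return List with `geno` (dosage matrix) and `map`.
#' @export
read_vcf <- function(file) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    map <- data.frame(id = rownames(gt),
                      chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                      stringsAsFactors = FALSE)
    gtv <- gsub("|", "/", gt, fixed = TRUE)
  } else {
    lines <- readLines(file)
    hdr <- grep("^#CHROM", lines)
    cols <- strsplit(lines[hdr], "\t")[[1]]
    body <- do.call(rbind, strsplit(lines[-seq_len(hdr)], "\t"))
    map <- data.frame(id = body[, 3], chrom = utils::type.convert(body[, 1], as.is = TRUE),
                      pos = as.integer(body[, 2]), stringsAsFactors = FALSE)
    gtv <- gsub("|", "/", body[, -(1:9), drop = FALSE], fixed = TRUE)
    dimnames(gtv) <- list(map$id, cols[-(1:9)])
  }
  dose <- matrix(NA_integer_, nrow(gtv), ncol(gtv), dimnames = dimnames(gtv))
  dose[gtv %in% c("0/0")] <- 1L
  dose[gtv %in% c("0/1", "1/0")] <- 0L
  dose[gtv %in% c("1/1")] <- -1L
  list(geno = t(dose), map = map)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param file Path.
#' @return `write_sim_config` the path invisibly; `read_sim_config` a
#'   validated `sim_config`.
#' @export
write_sim_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  do.call(sim_config, yaml::read_yaml(file))
}

#' Write an accuracy or prediction report as JSON
#'
#' @param report An `accuracy_report` or `prediction_report` (or any list /
#'   data frame).
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, file) {
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(file)
}
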