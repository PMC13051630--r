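#' Read a genotype matrix from VCF or numeric TSV
#'
#' VCF genotypes are taken from the GT field of biallelic SNP records and
#' coded `0/0 -> -1`, `0/1` or `1/0 -> 0`, `1/1 -> 1` (phased separators
#' accepted). Records that are multi-allelic or contain a missing call in
#' any sample are dropped panel-wide with a reported count. TSV input must
#' already be numeric-coded (rows = accessions, first column = accession
#' id, header = locus ids).
#'
#' @param path input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return accessions x loci genotype matrix in \{-1, 0, 1\}.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("VCF contains no records", call. = FALSE)
  keep_bi <- vcfR::is.biallelic(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt == "0/0"] <- -1
  code[gt %in% c("0/1", "1/0")] <- 0
  code[gt == "1/1"] <- 1
  usable <- keep_bi & apply(code, 1, function(x) !anyNA(x))
  dropped <- sum(!usable)
  if (dropped > 0)
    message(dropped, " site(s) dropped (multi-allelic or missing calls)")
  if (!any(usable))
    stop("no usable biallelic fully called sites in VCF", call. = FALSE)
  g <- t(code[usable, , drop = FALSE])
  fix <- v@fix[usable, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(g) <- ids
  check_geno(g)
}

read_genotypes_tsv <- function(path) {
  d <- read.delim(path, row.names = 1, check.names = FALSE)
  g <- as.matrix(d)
  if (!is.numeric(g))
    stop("TSV genotype table must be numeric-coded", call. = FALSE)
  check_geno(g)
}

#' Write a genotype matrix to VCF or numeric TSV
#'
#' The VCF writer emits uncompressed VCF v4.2 text with a GT-only FORMAT.
#' Locus ids of the form `chrom:pos` populate CHROM/POS; other ids are
#' placed on a single pseudo-chromosome at their column index. The seed
#' (if given) is recorded in the header.
#'
#' @param g genotype matrix in \{-1, 0, 1\}.
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`.
#' @param seed optional integer recorded in the VCF header / TSV comment.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "tsv"), seed = NULL) {
  check_geno(g)
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
    writeLines(paste(c("accession", colnames(g)), collapse = "\t"), con)
    utils::write.table(g, con, sep = "\t", quote = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  ids <- colnames(g)
  cp <- regmatches(ids, regexec("^([^:]+):([0-9]+)$", ids))
  has_cp <- lengths(cp) == 3
  chrom <- ifelse(has_cp, vapply(cp, function(x) x[2], ""), "1")
  pos <- ifelse(has_cp, vapply(cp, function(x) x[3], ""),
                as.character(seq_along(ids)))
  gtmap <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(ids), function(j) {
    paste(c(chrom[j], pos[j], ids[j], "A", "G", ".", "PASS", ".", "GT",
            gtmap[g[, j] + 2]), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=crossgp", utils::packageVersion("crossgp")),
              if (!is.null(seed)) paste0("##crossgp_seed=", seed),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
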