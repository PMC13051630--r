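# internal helpers shared across modules

#' Alternate-allele frequencies of a genotype matrix
#'
#' Genotype codes are -1 (homozygous reference), 0 (heterozygous),
#' 1 (homozygous alternate), so the alternate-allele frequency at locus j
#' is `(2 * n11 + n01) / (2 n)`, i.e. `(mean(x_j) + 1) / 2`.
#'
#' @param g numeric genotype matrix, accessions in rows, loci in columns.
#' @return named numeric vector of per-locus alternate-allele frequencies.
#' @export
allele_freqs <- function(g) {
  check_geno(g)
  (colMeans(g) + 1) / 2
}

# validate a genotype matrix: numeric, codes in {-1,0,1}, dimnames present
check_geno <- function(g, arg = deparse(substitute(g))) {
  if (!is.matrix(g) || !is.numeric(g))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  bad <- !(g %in% c(-1, 0, 1))
  if (any(bad))
    stop(sprintf("`%s` contains %d genotype codes outside {-1, 0, 1}",
                 arg, sum(bad)), call. = FALSE)
  if (is.null(rownames(g)) || is.null(colnames(g)))
    stop(sprintf("`%s` must carry accession rownames and locus colnames", arg),
         call. = FALSE)
  invisible(g)
}

check_crosses <- function(crosses) {
  need <- c("f1_id", "mother_id", "father_id")
  if (!is.data.frame(crosses) || !all(need %in% names(crosses)))
    stop("`crosses` must be a data.frame with columns f1_id, mother_id, father_id",
         call. = FALSE)
  if (anyDuplicated(crosses$f1_id))
    stop("duplicated f1_id in cross table", call. = FALSE)
  if (any(crosses$mother_id == crosses$father_id))
    stop("self-crosses are not allowed", call. = FALSE)
  invisible(crosses)
}

# significance stars matching conventional table footnotes
sig_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "N.S."))))
}

# Pearson correlation with t-based two-sided p; NA (with reason) on zero
# variance or n < 3
cor_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = if (n < 3) "n < 3" else "zero variance"))
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n, reason = NA_character_)
}

#' @importFrom stats pt
NULL
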