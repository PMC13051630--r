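#' Filter loci by minor allele frequency
#'
#' Retains loci whose minor allele frequency strictly exceeds `threshold`
#' (the panel rule "MAF greater than 0.05" uses a strict inequality).
#' Locus order and the accession set are preserved; the operation is
#' idempotent.
#'
#' @param g genotype matrix in \{-1, 0, 1\}.
#' @param threshold MAF threshold in `[0, 0.5)`.
#' @return the filtered genotype matrix.
#' @export
filter_maf <- function(g, threshold = 0.05) {
  check_geno(g)
  if (threshold < 0 || threshold >= 0.5)
    stop("threshold must be in [0, 0.5)", call. = FALSE)
  p <- allele_freqs(g)
  keep <- pmin(p, 1 - p) > threshold
  if (!any(keep))
    stop("all loci removed by MAF filter (threshold = ", threshold, ")",
         call. = FALSE)
  g[, keep, drop = FALSE]
}

#' Estimate F1 genotypes from parental genotypes
#'
#' The F1 genotypic value at each locus is the mean of the parental codes,
#' `gF1 = (gP1 + gP2) / 2`; the fractions arising from a heterozygous
#' parent (-0.5 and 0.5) are then adjusted to -1 and 1 so all codes stay
#' in \{-1, 0, 1\}. Segregation at heterozygous parental loci is not
#' modelled — the estimate is deterministic given the parents.
#'
#' @param g genotype matrix containing all parents.
#' @param crosses cross table (`f1_id`, `mother_id`, `father_id`).
#' @return F1 x loci genotype matrix in \{-1, 0, 1\}, rows named by
#'   `f1_id`.
#' @export
estimate_f1_genotypes <- function(g, crosses) {
  check_geno(g)
  check_crosses(crosses)
  missing <- setdiff(unique(c(crosses$mother_id, crosses$father_id)),
                     rownames(g))
  if (length(missing))
    stop("parents missing from genotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  gf1 <- (g[crosses$mother_id, , drop = FALSE] +
            g[crosses$father_id, , drop = FALSE]) / 2
  gf1[gf1 == 0.5] <- 1
  gf1[gf1 == -0.5] <- -1
  rownames(gf1) <- crosses$f1_id
  check_geno(gf1)
  gf1
}

#' Euclidean genetic distance between the parents of each cross
#'
#' `distance = sqrt(sum_j (gP1_j - gP2_j)^2)` over the shared locus set;
#' symmetric in parent order and zero iff the parents carry identical
#' genotype vectors.
#'
#' @param g genotype matrix containing all parents.
#' @param crosses cross table.
#' @return data.frame `f1_id`, `mother_id`, `father_id`, `distance`.
#' @export
parental_distance <- function(g, crosses) {
  check_geno(g)
  check_crosses(crosses)
  missing <- setdiff(unique(c(crosses$mother_id, crosses$father_id)),
                     rownames(g))
  if (length(missing))
    stop("parents missing from genotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  diffs <- g[crosses$mother_id, , drop = FALSE] -
    g[crosses$father_id, , drop = FALSE]
  data.frame(f1_id = crosses$f1_id, mother_id = crosses$mother_id,
             father_id = crosses$father_id,
             distance = sqrt(rowSums(diffs^2)),
             stringsAsFactors = FALSE, row.names = NULL)
}
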