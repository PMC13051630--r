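#' Genomic relationship (kernel) matrices
#'
#' Builds the marker-derived relationship matrix of the requested kind
#' from \{-1, 0, 1\} genotype codes:
#' \describe{
#'   \item{additive}{VanRaden-style: codes centered per locus by
#'     `2(p_j - 0.5)`, `K = W W' / (2 sum_j p_j (1 - p_j))`.}
#'   \item{dominance}{heterozygosity design `H_ij = 1[x_ij = 0]` centered
#'     per locus by `2 p_j (1 - p_j)`,
#'     `K_D = V V' / sum_j (2 p_j (1 - p_j))^2`.}
#'   \item{gaussian}{`K_ij = exp(-D_ij^2 / theta)` with `D` the Euclidean
#'     distance on the raw codes and bandwidth `theta` the median nonzero
#'     squared distance (overridable); unit diagonal by construction.}
#' }
#' Allele frequencies default to the supplied panel and are stored so that
#' prediction kernels can be built with the training-panel frequencies.
#'
#' @param g genotype matrix (training panel).
#' @param kind `"additive"`, `"dominance"` or `"gaussian"`.
#' @param bandwidth Gaussian bandwidth `theta`; `NULL` = median heuristic.
#' @param freqs optional per-locus alternate-allele frequencies to center
#'   with (defaults to `allele_freqs(g)`).
#' @return object of class `kernel_matrix`: list with `kind`, `K`,
#'   `accession_ids`, `freqs`, `bandwidth`.
#' @export
build_kernel <- function(g, kind = c("additive", "dominance", "gaussian"),
                         bandwidth = NULL, freqs = NULL) {
  kind <- match.arg(kind)
  check_geno(g)
  if (nrow(g) < 2) stop("need at least 2 accessions", call. = FALSE)
  if (is.null(freqs)) freqs <- allele_freqs(g)
  K <- switch(kind,
    additive = {
      denom <- 2 * sum(freqs * (1 - freqs))
      if (denom <= 0)
        stop("monomorphic input: additive kernel undefined", call. = FALSE)
      W <- sweep(g, 2, 2 * (freqs - 0.5))
      tcrossprod(W) / denom
    },
    dominance = {
      hfreq <- 2 * freqs * (1 - freqs)
      denom <- sum(hfreq^2)
      if (denom <= 0)
        stop("monomorphic input: dominance kernel undefined", call. = FALSE)
      V <- sweep((g == 0) * 1, 2, hfreq)
      tcrossprod(V) / denom
    },
    gaussian = {
      D2 <- as.matrix(stats::dist(g))^2
      if (is.null(bandwidth)) {
        nz <- D2[upper.tri(D2)][D2[upper.tri(D2)] > 0]
        if (!length(nz))
          stop("all accessions identical: Gaussian bandwidth undefined",
               call. = FALSE)
        bandwidth <- median(nz)
      }
      exp(-D2 / bandwidth)
    })
  K <- (K + t(K)) / 2
  structure(list(kind = kind, K = K, accession_ids = rownames(g),
                 freqs = freqs, bandwidth = bandwidth),
            class = "kernel_matrix")
}

#' Cross-kernel between new and training accessions
#'
#' Relationship values between prediction candidates (e.g. estimated F1
#' genotypes) and the training panel, using the training-panel allele
#' frequencies and (for the Gaussian kind) the training bandwidth, frozen
#' at training time.
#'
#' @param g_new genotype matrix of prediction candidates.
#' @param g_train training genotype matrix (same loci, same order).
#' @param kernel the training [build_kernel()] object.
#' @return n_new x n_train numeric matrix.
#' @export
cross_kernel <- function(g_new, g_train, kernel) {
  stopifnot(inherits(kernel, "kernel_matrix"))
  check_geno(g_new); check_geno(g_train)
  if (!identical(colnames(g_new), colnames(g_train)))
    stop("locus sets/order differ between new and training genotypes",
         call. = FALSE)
  freqs <- kernel$freqs
  switch(kernel$kind,
    additive = {
      denom <- 2 * sum(freqs * (1 - freqs))
      Wn <- sweep(g_new, 2, 2 * (freqs - 0.5))
      Wt <- sweep(g_train, 2, 2 * (freqs - 0.5))
      tcrossprod(Wn, Wt) / denom
    },
    dominance = {
      hfreq <- 2 * freqs * (1 - freqs)
      Vn <- sweep((g_new == 0) * 1, 2, hfreq)
      Vt <- sweep((g_train == 0) * 1, 2, hfreq)
      tcrossprod(Vn, Vt) / sum(hfreq^2)
    },
    gaussian = {
      if (is.null(kernel$bandwidth))
        stop("training kernel carries no bandwidth", call. = FALSE)
      # squared Euclidean distances between rows of g_new and g_train
      D2 <- outer(rowSums(g_new^2), rowSums(g_train^2), "+") -
        2 * tcrossprod(g_new, g_train)
      D2[D2 < 0] <- 0
      exp(-D2 / kernel$bandwidth)
    })
}
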