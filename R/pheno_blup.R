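#' Derive composite pungency traits from the base measurements
#'
#' From the per-accession-per-year base traits — capsaicin and
#' dihydrocapsaicin content per unit placental dry weight (`CAPgDW`,
#' `DCAPgDW`, ug/gDW) and placental dry weight per fruit (`DWP`,
#' g/fruit) — appends the total content `TCAPgDW = CAPgDW + DCAPgDW` and
#' the per-fruit contents `CAPFL = CAPgDW * DWP`,
#' `DCAPFL = DCAPgDW * DWP`, `TCAPFL = TCAPgDW * DWP` (ug/gDW x g/fruit =
#' ug/fruit).
#'
#' @param records long-format phenotype records (`accession`, `year`,
#'   `trait`, `value`) containing the three base traits for every cell.
#' @return the input records with the four derived traits appended.
#' @export
derive_traits <- function(records) {
  need <- c("CAPgDW", "DCAPgDW", "DWP")
  wide <- stats::reshape(
    records[records$trait %in% need, c("accession", "year", "trait", "value")],
    idvar = c("accession", "year"), timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (!all(need %in% names(wide)) || anyNA(wide[need]))
    stop("CAPgDW, DCAPgDW and DWP must be present for every accession-year",
         call. = FALSE)
  wide$TCAPgDW <- wide$CAPgDW + wide$DCAPgDW
  wide$CAPFL  <- wide$CAPgDW * wide$DWP
  wide$DCAPFL <- wide$DCAPgDW * wide$DWP
  wide$TCAPFL <- wide$TCAPgDW * wide$DWP
  derived <- do.call(rbind, lapply(c("TCAPgDW", "CAPFL", "DCAPFL", "TCAPFL"),
                                   function(tr) {
    data.frame(accession = wide$accession, year = wide$year, trait = tr,
               value = wide[[tr]], stringsAsFactors = FALSE)
  }))
  out <- rbind(records, derived)
  rownames(out) <- NULL
  out
}

#' Summarize multi-year phenotypes as BLUPs
#'
#' Fits `value ~ 0 + year + (1 | accession)` by REML (year fixed,
#' accession random) and reports, per accession, the BLUP on the trait
#' scale: the unweighted mean of the year fixed effects plus the shrunken
#' accession effect. Variance components and broad-sense heritability
#' `h_b^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / n) * 100` (n = number of
#' years) are attached to every row.
#'
#' @param records long-format phenotype records.
#' @param trait trait label to fit; defaults to the single trait present.
#' @return data.frame `accession`, `trait`, `blup`, `sigma2_g`,
#'   `sigma2_e`, `n_reps`, `h2_b`.
#' @export
fit_blup <- function(records, trait = NULL) {
  if (is.null(trait)) {
    trait <- unique(records$trait)
    if (length(trait) != 1)
      stop("records contain several traits; specify `trait`", call. = FALSE)
  }
  d <- records[records$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for trait ", trait, call. = FALSE)
  if (anyDuplicated(d[c("accession", "year")]))
    stop("more than one record per accession-year", call. = FALSE)
  n_years <- length(unique(d$year))
  if (n_years < 2)
    stop("at least 2 years are required to split genetic and residual ",
         "variance", call. = FALSE)
  if (length(unique(d$accession)) < 2)
    stop("at least 2 accessions required", call. = FALSE)
  d$year <- factor(d$year)
  d$accession <- factor(d$accession)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ 0 + year + (1 | accession), data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sg2 <- vc$vcov[vc$grp == "accession"]
  se2 <- vc$vcov[vc$grp == "Residual"]
  baseline <- mean(lme4::fixef(fit))
  re <- lme4::ranef(fit)$accession
  blup <- baseline + re[, "(Intercept)"]
  data.frame(accession = rownames(re), trait = trait, blup = blup,
             sigma2_g = sg2, sigma2_e = se2, n_reps = n_years,
             h2_b = heritability(sg2, se2, n_years),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit BLUPs for every trait in a record set
#'
#' @param records long-format phenotype records with one or more traits.
#' @return row-bound [fit_blup()] tables over all traits.
#' @export
fit_blup_all <- function(records) {
  out <- do.call(rbind, lapply(unique(records$trait),
                               function(tr) fit_blup(records, tr)))
  rownames(out) <- NULL
  out
}

#' Broad-sense heritability on the accession-mean basis
#'
#' `h_b^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / n) * 100`, where n is the
#' number of replicate years entering each accession mean.
#'
#' @param sigma2_g genetic variance (>= 0).
#' @param sigma2_e residual variance (>= 0).
#' @param n replicate count (>= 1).
#' @return heritability in percent, in `[0, 100]`.
#' @export
heritability <- function(sigma2_g, sigma2_e, n) {
  if (any(sigma2_g < 0) || any(sigma2_e < 0))
    stop("variances must be nonnegative", call. = FALSE)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(sigma2_g + sigma2_e == 0))
    stop("heritability undefined when both variances are zero",
         call. = FALSE)
  sigma2_g / (sigma2_g + sigma2_e / n) * 100
}
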