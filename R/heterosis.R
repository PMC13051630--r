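#' Mid-parent and high-parent heterosis
#'
#' `MP(%) = (P_F1 - P_mid) / P_mid * 100` with
#' `P_mid = (P_P1 + P_P2) / 2`, and
#' `HP(%) = (P_F1 - P_max) / P_max * 100` with
#' `P_max = max(P_P1, P_P2)`. Percent heterosis assumes positive-valued
#' traits; records with a non-positive denominator are returned as `NA`
#' with a reported count and must be excluded from summaries.
#'
#' @param p_f1 F1 phenotypic values (BLUPs).
#' @param p_p1,p_p2 parental phenotypic values (BLUPs); vectorized.
#' @return data.frame `mp_heterosis`, `hp_heterosis` (percent).
#' @export
mp_hp_heterosis <- function(p_f1, p_p1, p_p2) {
  p_mid <- (p_p1 + p_p2) / 2
  p_max <- pmax(p_p1, p_p2)
  bad <- p_mid <= 0 | p_max <= 0
  if (any(bad))
    message(sum(bad), " record(s) with non-positive parental denominator ",
            "flagged NA")
  mp <- ifelse(bad, NA_real_, (p_f1 - p_mid) / p_mid * 100)
  hp <- ifelse(bad, NA_real_, (p_f1 - p_max) / p_max * 100)
  data.frame(mp_heterosis = mp, hp_heterosis = hp)
}

#' Additive effect of a cross
#'
#' Half the absolute phenotypic difference between the two parents,
#' `|P_P1 - P_P2| / 2`; symmetric and nonnegative.
#'
#' @param p_p1,p_p2 parental phenotypic values; vectorized.
#' @return numeric vector of additive effects (trait units).
#' @export
additive_effect <- function(p_p1, p_p2) {
  abs(p_p1 - p_p2) / 2
}

#' Classify F1s into heterosis groups
#'
#' Non-heterosis: MP < 0; medium heterosis: MP > 0 and HP < 0; strong
#' heterosis: HP > 0. Boundary ties (probability ~0 on continuous data)
#' go to the less extreme group: MP = 0 is non, HP = 0 is medium.
#'
#' @param mp,hp mid-/high-parent heterosis in percent; vectorized.
#' @return character vector in `c("non", "medium", "strong")` (`NA` in,
#'   `NA` out).
#' @export
classify_heterosis <- function(mp, hp) {
  ifelse(is.na(mp) | is.na(hp), NA_character_,
         ifelse(mp <= 0, "non", ifelse(hp <= 0, "medium", "strong")))
}

#' Per-F1, per-trait heterosis table
#'
#' Joins F1 and parental BLUPs through the cross table and computes MP/HP
#' heterosis, the additive effect and the heterosis group for every F1 and
#' trait.
#'
#' @param blups BLUP table from [fit_blup_all()] covering F1s and parents.
#' @param crosses cross table.
#' @return data.frame `f1_id`, `trait`, `p_f1`, `p_p1`, `p_p2`, `p_mid`,
#'   `p_max`, `mp_heterosis`, `hp_heterosis`, `additive_effect`, `group`.
#' @export
heterosis_table <- function(blups, crosses) {
  check_crosses(crosses)
  out <- do.call(rbind, lapply(unique(blups$trait), function(tr) {
    b <- blups[blups$trait == tr, ]
    val <- setNames(b$blup, b$accession)
    need <- unique(c(crosses$f1_id, crosses$mother_id, crosses$father_id))
    missing <- setdiff(need, names(val))
    if (length(missing))
      stop("accessions without BLUPs for trait ", tr, ": ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    p_f1 <- val[crosses$f1_id]
    p_p1 <- val[crosses$mother_id]
    p_p2 <- val[crosses$father_id]
    het <- suppressMessages(mp_hp_heterosis(p_f1, p_p1, p_p2))
    data.frame(f1_id = crosses$f1_id, trait = tr, p_f1 = p_f1, p_p1 = p_p1,
               p_p2 = p_p2, p_mid = (p_p1 + p_p2) / 2,
               p_max = pmax(p_p1, p_p2),
               mp_heterosis = het$mp_heterosis,
               hp_heterosis = het$hp_heterosis,
               additive_effect = additive_effect(p_p1, p_p2),
               group = classify_heterosis(het$mp_heterosis,
                                          het$hp_heterosis),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Distribution and group summary of heterosis per trait
#'
#' @param table heterosis table from [heterosis_table()].
#' @return list with `stats` (per trait and heterosis type: mean, sd,
#'   median, min, max over classifiable records) and `groups` (per trait:
#'   percent of classifiable F1s in the non/medium/strong groups, summing
#'   to 100).
#' @export
heterosis_summary <- function(table) {
  if (nrow(table) == 0) stop("empty heterosis table", call. = FALSE)
  stats_tab <- do.call(rbind, lapply(unique(table$trait), function(tr) {
    d <- table[table$trait == tr & !is.na(table$mp_heterosis), ]
    do.call(rbind, lapply(c(mp = "mp_heterosis", hp = "hp_heterosis"),
                          function(col) {
      x <- d[[col]]
      data.frame(trait = tr, heterosis = sub("_heterosis", "", col),
                 mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
                 median = median(x), min = min(x), max = max(x),
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(stats_tab) <- NULL
  groups <- do.call(rbind, lapply(unique(table$trait), function(tr) {
    g <- table$group[table$trait == tr]
    g <- g[!is.na(g)]
    counts <- table(factor(g, levels = c("non", "medium", "strong")))
    data.frame(trait = tr, non = 100 * counts[["non"]] / length(g),
               medium = 100 * counts[["medium"]] / length(g),
               strong = 100 * counts[["strong"]] / length(g),
               n = length(g), stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(stats = stats_tab, groups = groups)
}

#' Correlate heterosis with additive effect and parental distance
#'
#' Per trait, Pearson r (t-based two-sided p, df = n - 2, significance
#' stars at 0.05/0.01/0.001) of MP and HP heterosis against the additive
#' effect and the parental Euclidean genetic distance.
#'
#' @param table heterosis table.
#' @param distances table from [parental_distance()].
#' @return data.frame `trait`, `heterosis`, `factor`, `r`, `p`, `n`,
#'   `stars`.
#' @export
heterosis_correlates <- function(table, distances) {
  d <- merge(table, distances[c("f1_id", "distance")], by = "f1_id")
  out <- do.call(rbind, lapply(unique(d$trait), function(tr) {
    dd <- d[d$trait == tr, ]
    grid <- expand.grid(heterosis = c("mp", "hp"),
                        factor = c("additive_effect", "distance"),
                        stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      ct <- cor_with_p(dd[[paste0(grid$heterosis[i], "_heterosis")]],
                       dd[[grid$factor[i]]])
      data.frame(trait = tr, heterosis = grid$heterosis[i],
                 factor = grid$factor[i], r = ct$r, p = ct$p, n = ct$n,
                 stars = sig_stars(ct$p), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Parental-combination matrix of HP heterosis
#'
#' Builds the parents x parents matrix of HP heterosis for one trait:
#' the cell for the actual crossing direction (mother row, father column)
#' is tagged `R`; the mirror cell carries the identical value tagged `F`
#' (reciprocal differences are ignored by design); combinations never
#' crossed stay `NA` / empty. Parental BLUPs are attached as margins.
#'
#' @param table heterosis table.
#' @param trait trait to extract.
#' @param crosses cross table.
#' @param parent_blups optional named vector of parental BLUPs for the
#'   margins.
#' @return list with `values` (numeric matrix), `tags` (character matrix
#'   of `"R"`, `"F"`, `""`), `parent_values` (margins).
#' @export
export_cross_matrix <- function(table, trait, crosses, parent_blups = NULL) {
  d <- merge(table[table$trait == trait, ],
             crosses[c("f1_id", "mother_id", "father_id")], by = "f1_id")
  if (nrow(d) == 0) stop("no crosses for trait ", trait, call. = FALSE)
  parents <- sort(unique(c(d$mother_id, d$father_id)))
  vals <- matrix(NA_real_, length(parents), length(parents),
                 dimnames = list(parents, parents))
  tags <- matrix("", length(parents), length(parents),
                 dimnames = list(parents, parents))
  for (i in seq_len(nrow(d))) {
    m <- d$mother_id[i]; f <- d$father_id[i]; v <- d$hp_heterosis[i]
    if (!is.na(vals[m, f]) && !isTRUE(all.equal(vals[m, f], v)))
      stop("conflicting duplicate values for unordered pair ", m, " x ", f,
           "; reciprocal differences are ignored by design, pre-average ",
           "duplicates", call. = FALSE)
    vals[m, f] <- v; tags[m, f] <- "R"
    vals[f, m] <- v
    if (tags[f, m] == "") tags[f, m] <- "F"
  }
  pv <- if (is.null(parent_blups)) setNames(rep(NA_real_, length(parents)),
                                            parents)
        else parent_blups[parents]
  list(values = vals, tags = tags, parent_values = pv)
}
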