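# shared fixtures, all generated in code

# small genotype matrix with explicit values
toy_geno <- function(values, acc = NULL, loci = NULL) {
  g <- as.matrix(values)
  rownames(g) <- acc %||% sprintf("A%02d", seq_len(nrow(g)))
  colnames(g) <- loci %||% sprintf("M%03d", seq_len(ncol(g)))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compact simulated panel: founders + crosses + an additive trait
small_panel <- function(n_inbred = 40, n_loci = 200, n_parents = 8,
                        n_f1 = 20, dominance_ratio = 0, h2 = 0.9,
                        seed = 101, n_qtl = 30, het = 0.1) {
  n_qtl <- min(n_qtl, n_loci)
  cfg <- sim_config(n_inbred = n_inbred, n_loci = n_loci,
                    n_parents = n_parents, n_f1 = n_f1,
                    residual_het_rate = het, h2_target = h2,
                    dominance_ratio = dominance_ratio, seed = seed)
  g <- simulate_founder_genotypes(cfg)
  parents <- sort(sample(rownames(g), n_parents))
  cr <- make_crosses(g, parents, n_f1, seed = seed + 1)
  ar <- simulate_architecture(n_loci, n_qtl, dominance_ratio,
                              seed = seed + 2, genotypes = g, intercept = 10)
  allg <- rbind(g, cr$f1_genotypes)
  ph <- simulate_phenotypes(allg, ar, cfg, trait = "trait1")
  list(config = cfg, genotypes = g, crosses = cr$crosses,
       f1_genotypes = cr$f1_genotypes, arch = ar, phenotypes = ph,
       all_genotypes = allg)
}

# write a small VCF fixture as plain text; returns the path
write_vcf_fixture <- function(lines_body, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, lines_body), path)
  path
}
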