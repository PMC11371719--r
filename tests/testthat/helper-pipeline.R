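# End-to-end pipeline fixture: two genus exposures (one with a real effect
# on the disease, one null, each with its own instrument set) and a
# rare-disease outcome, built so the forward run flags exactly one pair and
# the reverse run finds exactly two disease instruments (so MR-Egger / WME
# come back not-estimable, the "/" convention of reported reverse-MR
# tables).
build_pipeline_fixture <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(seed, {
    n_iv <- 8
    iv_a <- sprintf("rs%06d", 1:n_iv)
    iv_b <- sprintf("rs%06d", 11:(10 + n_iv))
    dz <- c("rsX00001", "rsX00002")  # disease instruments for reverse MR
    all_ids <- c(iv_a, iv_b, dz)
    bx_a <- rnorm(n_iv, 0.10, 0.015)
    bx_b <- rnorm(n_iv, 0.10, 0.015)
    se_x <- 0.015

    genus_tab <- function(name, ids, bx) {
      # own instruments + the two disease SNPs (null genus effects, so the
      # reverse run can look them up in this table as the outcome)
      association_table(make_assoc_df(
        SNP = c(ids, dz),
        effect_allele = "A", other_allele = "G",
        eaf = runif(n_iv + 2, 0.1, 0.4),
        beta = c(bx, rnorm(2, 0, 0.002)),
        se = c(rep(se_x, n_iv), 0.02, 0.02),
        n = 18340), study_meta(name, "continuous", 18340))
    }
    genus_a <- genus_tab("genusA", iv_a, bx_a)
    genus_b <- genus_tab("genusB", iv_b, bx_b)

    # Disease outcome: genusA instruments transmit theta = 1.2, genusB
    # instruments carry pure noise, and the two dedicated disease SNPs are
    # genome-wide significant for the disease itself.
    se_y <- 0.12
    disease <- association_table(make_assoc_df(
      SNP = all_ids, effect_allele = "A", other_allele = "G",
      eaf = runif(length(all_ids), 0.1, 0.4),
      beta = c(1.2 * bx_a + rnorm(n_iv, 0, se_y / 4),
               rnorm(n_iv, 0, se_y / 4), 0.5, 0.45),
      se = c(rep(se_y, 2 * n_iv), 0.05, 0.05),
      n = 213353), study_meta("disease", "binary", 213353, 208, 213145))

    paths <- list(
      genus_a = file.path(dir, "genus_a.tsv"),
      genus_b = file.path(dir, "genus_b.tsv"),
      disease = file.path(dir, "disease.tsv"),
      ld = file.path(dir, "ld.tsv"),
      excl = file.path(dir, "exclusions.txt"))
    write_association_table(genus_a, paths$genus_a)
    write_association_table(genus_b, paths$genus_b)
    write_association_table(disease, paths$disease)
    write_ld_matrix(ld_matrix(all_ids, diag(length(all_ids))), paths$ld)
    writeLines(c("# confounder-associated", "rs000008\tsmoking"),
               paths$excl)

    cfg <- run_config(
      exposures = list(
        list(name = "genusA", path = paths$genus_a, ld_path = paths$ld,
             meta = list(trait_name = "genusA", trait_type = "continuous",
                         n_total = 18340)),
        list(name = "genusB", path = paths$genus_b, ld_path = paths$ld,
             meta = list(trait_name = "genusB", trait_type = "continuous",
                         n_total = 18340))),
      outcomes = list(
        list(name = "disease", path = paths$disease, ld_path = paths$ld,
             meta = list(trait_name = "disease", trait_type = "binary",
                         n_total = 213353, n_cases = 208,
                         n_controls = 213145))),
      seed = seed,
      exclusion_list_path = paths$excl,
      output_dir = file.path(dir, "out"))
    list(config = cfg, paths = paths)
  })
}
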