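# The synthetic-data generator: determinism, limit cases and the
# statistical properties the downstream validation relies on.

test_that("generator is deterministic and conserves the site universe", {
  cfg <- tiny_config(seed = 21L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- quiet(generate_dataset(cfg, d1))
  b2 <- quiet(generate_dataset(cfg, d2))
  m1 <- fread(file.path(d1, "manifest.tsv"))
  m2 <- fread(file.path(d2, "manifest.tsv"))
  expect_equal(m1, m2)  # byte-identical bundle

  # every assigned cytosine appears in every CX report, zero-coverage
  # rows included
  sites <- quiet(assign_contexts(quiet(read_fasta(b1$paths$fasta))))
  cx <- quiet(read_cx_report(b1$paths$cx[[1L]]))
  expect_equal(nrow(cx), nrow(sites))
  expect_equal(
    as.data.frame(cx[order(chrom, pos, strand), .(chrom, pos, strand, context)]),
    as.data.frame(sites[order(chrom, pos, strand), .(chrom, pos, strand, context)]))
})

test_that("variant simulation obeys its limit cases", {
  cfg <- tiny_config(seed = 4L)
  gen <- quiet(simulate_genome(cfg))
  none <- quiet(simulate_variants(gen$genome, sim_config(seed = 4L, het_ct_rate = 0)))
  expect_equal(nrow(none), 0L)

  all_cfg <- sim_config(seed = 4L, het_ct_rate = 1)
  g2 <- c(c1 = "CCGG")
  v <- quiet(simulate_variants(Biostrings::DNAStringSet(g2), all_cfg))
  expect_equal(nrow(v), 4L)  # 2 C>T and 2 G>A forced
  expect_equal(sort(v$ref), c("C", "C", "G", "G"))
  expect_true(all(v$genotype == "het"))
})

test_that("gc_fraction 0 yields an AT-only genome; overfull placement errors", {
  cfg <- sim_config(seed = 2L, genome_length = 50000L, n_chroms = 1L,
                    n_genes = 5L, n_tes = 0L, gc_fraction = 0)
  gen <- quiet(simulate_genome(cfg))
  expect_equal(sort(unique(strsplit(as.character(gen$genome[[1L]]), "")[[1L]])),
               c("A", "T"))
  bad <- sim_config(seed = 2L, genome_length = 30000L, n_chroms = 1L,
                    n_genes = 50L, n_tes = 0L)
  expect_error(quiet(simulate_genome(bad)), "cannot hold")
})

test_that("methylome means match the Beta model and zero delta is identity", {
  cfg <- tiny_config(seed = 9L)
  gen <- quiet(simulate_genome(cfg))
  v <- quiet(simulate_variants(gen$genome, cfg))
  m <- quiet(simulate_methylome(gen$genome, gen$features, v, cfg))

  # CG control mean within 3 SE of the configured mean (analytic Beta
  # moments; per-gene region effects are zero-mean so they only add a
  # second-order variance term, absorbed by the SE bound)
  cg <- m$sites[context == "CG"]
  mu <- cfg$context_means[["CG"]]
  beta_var <- mu * (1 - mu) / (cfg$site_dispersion + 1)
  se <- sqrt(beta_var / nrow(cg))
  expect_gt(nrow(cg), 5e3)
  expect_lt(abs(mean(cg$true_level_control) - mu), 3 * se + 0.01)

  # delta = 0 everywhere: treated methylome equals control exactly
  cfg0 <- tiny_config(seed = 9L)
  cfg0$planted_dmrs$delta <- rep(0, nrow(cfg0$planted_dmrs))
  m0 <- quiet(simulate_methylome(gen$genome, gen$features, v, cfg0))
  expect_identical(m0$sites$true_level_control, m0$sites$true_level_treated)

  # planted shifts apply to every site of the class, clipped to [0, 1]
  p1 <- m$planted[1L]
  idx <- m$sites[chrom == p1$chrom & pos >= p1$start & pos < p1$end &
                   context == p1$context, which = TRUE]
  expect_equal(m$sites$true_level_treated[idx],
               pmin(pmax(m$sites$true_level_control[idx] + p1$delta, 0), 1))
})

test_that("het sites halve the methylated-looking read fraction (allele dilution)", {
  # one CG site with true level 1.0 on a het background, perfect conversion:
  # expected observed level is 0.5 by binomial allele sampling
  cfg <- sim_config(seed = 13L, genome_length = 60000L, n_chroms = 1L,
                    n_genes = 4L, n_tes = 0L, genes_per_dmr_class = 0L,
                    conversion_rate = 1, het_ct_rate = 0.05,
                    coverage_mean = 20, n_replicates = 1L)
  fx <- sim_site_samples(cfg)
  s <- fx$samples[["control-0d_r1"]]
  truth <- fx$methylome$sites
  hv <- which(truth$is_variant)
  expect_gt(length(hv), 100L)
  obs <- sum(s$count_meth[hv]) / sum(s$count_meth[hv] + s$count_unmeth[hv])
  expected <- mean(truth$true_level_control[hv]) / 2
  tot <- sum(s$count_meth[hv] + s$count_unmeth[hv])
  se <- sqrt(expected * (1 - expected) / tot) +
    sqrt(0.25 * stats::var(truth$true_level_control[hv]) / length(hv))
  expect_lt(abs(obs - expected), 3 * se + 0.01)

  # bias existence: naive CG level strictly below the truth-table level
  cg_naive <- weighted_level(copy(s)[, masked := FALSE], "CG")
  cg_true <- truth[is_variant == FALSE & context == "CG",
                   mean(true_level_control)]
  expect_lt(cg_naive, cg_true)
})

test_that("pileup limit cases: full methylation and zero coverage", {
  cfg <- sim_config(seed = 5L, genome_length = 20000L, n_chroms = 1L,
                    n_genes = 2L, n_tes = 0L, genes_per_dmr_class = 0L,
                    conversion_rate = 1, het_ct_rate = 0, n_replicates = 1L)
  gen <- quiet(simulate_genome(cfg))
  sites <- quiet(assign_contexts(gen$genome))
  # hand-built methylome: every site truly fully methylated, no variants
  sites[, `:=`(true_level_control = 1, true_level_treated = 1,
               is_variant = FALSE)]
  pile <- quiet(simulate_pileup(list(sites = sites), cfg))
  expect_equal(sum(pile[[1L]]$count_unmeth), 0L)
  expect_gt(sum(pile[[1L]]$count_meth), 0L)

  zcfg <- sim_config(seed = 5L, genome_length = 20000L, n_chroms = 1L,
                     n_genes = 2L, n_tes = 0L, genes_per_dmr_class = 0L,
                     coverage_mean = 1e-9, n_replicates = 1L)
  pz <- quiet(simulate_pileup(list(sites = sites), zcfg))
  expect_equal(sum(pz[[1L]]$count_meth + pz[[1L]]$count_unmeth), 0L)
  expect_equal(nrow(pz[[1L]]), nrow(sites))  # still a valid, full CX table
})

test_that("expression fold-changes follow the sign-pairing rules", {
  cfg <- tiny_config(seed = 17L, nb_dispersion = 1e-4, n_replicates = 3L)
  fx <- sim_site_samples(cfg)
  expr <- quiet(simulate_expression(fx$features, fx$methylome, cfg))
  med <- expr$truth_expr$mediated
  expect_gt(nrow(med), 0L)
  # negative-sign combos pair hyper with down / hypo with up; the
  # positive-sign combo (up2k CHH) is reversed
  expect_true(all(
    (med$sign < 0 & ((med$dmr_direction == "hyper" & med$deg_direction == "down") |
                     (med$dmr_direction == "hypo" & med$deg_direction == "up"))) |
    (med$sign > 0 & ((med$dmr_direction == "hyper" & med$deg_direction == "up") |
                     (med$dmr_direction == "hypo" & med$deg_direction == "down")))))

  # empirical log2FC of a mediated gene close to the planted magnitude at
  # tiny NB dispersion (NB moments oracle)
  cm <- expr$counts
  s3 <- grep("^treated-3d", names(cm), value = TRUE)
  s0 <- grep("^control-0d", names(cm), value = TRUE)
  # use the most highly expressed mediated gene so count noise is negligible
  ctl_tot <- rowSums(cm[, s0, with = FALSE])
  g <- cm$gene_id[ctl_tot == max(ctl_tot[cm$gene_id %in% med$gene_id]) &
                    cm$gene_id %in% med$gene_id][1L]
  fc <- log2(mean(unlist(cm[gene_id == g, s3, with = FALSE])) /
             mean(unlist(cm[gene_id == g, s0, with = FALSE])))
  sgn <- if (med[gene_id == g, deg_direction][1L] == "up") 1 else -1
  expect_lt(abs(fc - sgn * cfg$deg_log2fc), 0.3)

  # every mediated gene appears exactly once
  expect_equal(anyDuplicated(med$gene_id), 0L)
})
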