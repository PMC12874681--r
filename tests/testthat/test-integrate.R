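# DEG calling, core-set classification, correlation and mediation rules.

mk_counts <- function(mat, genes = sprintf("g%02d", seq_len(nrow(mat)))) {
  dt <- data.table(gene_id = genes)
  for (j in seq_len(ncol(mat))) dt[[sprintf("s%d", j)]] <- mat[, j]
  dt
}

test_that("the built-in DEG caller is null on identical groups and finds planted shifts", {
  set.seed(12)
  base <- matrix(rnbinom(50 * 6, mu = 200, size = 20), 50)
  cnt <- mk_counts(cbind(base[, 1:3], base[, 1:3]))
  none <- quiet(call_degs(cnt, paste0("s", 1:3), paste0("s", 4:6)))
  expect_equal(nrow(none), 0L)

  shifted <- base
  shifted[1:5, 4:6] <- matrix(rnbinom(15, mu = 200 * 8, size = 20), 5)
  cnt2 <- mk_counts(shifted)
  degs <- quiet(call_degs(cnt2, paste0("s", 1:3), paste0("s", 4:6)))
  planted <- sprintf("g%02d", 1:5)
  expect_true(all(planted %in% degs$gene_id))
  expect_true(all(degs[gene_id %in% planted, direction] == "up"))
  expect_true(all(degs[gene_id %in% planted, log2fc] > 1))

  # all-zero genes are skipped, single replicates fall back to fc-only mode
  z <- mk_counts(rbind(matrix(0L, 1, 2), matrix(c(10L, 80L), 1)))
  fc <- quiet(call_degs(z, "s1", "s2"))
  expect_equal(attr(fc, "mode"), "fc_only")
  expect_equal(attr(fc, "n_tested"), 1L)
  expect_true(all(is.na(fc$qvalue)))
})

test_that("core / period-specific / discordant classification partitions the DEG universe", {
  d3 <- data.table(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(2, -2, 2, 2), qvalue = 0.01,
                   direction = c("up", "down", "up", "up"), comparison = "3d")
  d7 <- data.table(gene_id = c("a", "b", "d", "e"),
                   log2fc = c(2, -2, -2, 2), qvalue = 0.01,
                   direction = c("up", "down", "down", "up"), comparison = "7d")
  cs <- classify_core_degs(d3, d7)
  expect_equal(cs$core_up, "a")        # up at both days
  expect_equal(cs$core_down, "b")      # down at both days
  expect_setequal(cs$period_specific, c("c", "e"))  # exactly one day
  expect_equal(cs$discordant, "d")     # opposite directions
  universe <- union(d3$gene_id, d7$gene_id)
  parts <- c(cs$core_up, cs$core_down, cs$period_specific, cs$discordant)
  expect_setequal(parts, universe)
  expect_equal(anyDuplicated(parts), 0L)
})

test_that("cross-stress intersections match brute-force set algebra", {
  salt <- structure(list(core_up = c("a", "b"), core_down = c("x", "y"),
                         period_specific = character(),
                         discordant = character()), class = "hm_core_sets")
  alk <- structure(list(core_up = c("b", "c"), core_down = character(),
                        period_specific = character(),
                        discordant = character()), class = "hm_core_sets")
  cr <- cross_stress_core(salt, alk)
  expect_equal(cr$common_core_up, "b")
  expect_equal(cr$common_core_down, character())
  expect_equal(cr$salt_only_up, "a")
  expect_equal(cr$alkali_only_up, "c")
  expect_equal(cr$salt_only_down, c("x", "y"))
  # pairwise disjoint within direction
  expect_equal(intersect(cr$common_core_up, cr$salt_only_up), character())
  expect_equal(intersect(cr$common_core_up, cr$alkali_only_up), character())
})

test_that("correlation handles perfect, degenerate and under-sized inputs", {
  rl <- data.table(feature_id = sprintf("g%d", 1:12),
                   level = seq(0.9, 0.35, length.out = 12))
  expr <- setNames(seq_len(12), rl$feature_id)
  ct <- methylation_expression_correlation(rl, expr)
  expect_equal(ct$rho, -1)
  expect_equal(ct$n, 12L)

  const <- copy(rl)[, level := 0.5]
  expect_error(methylation_expression_correlation(const, expr), "constant")
  expect_error(methylation_expression_correlation(rl[1:5], expr), ">= 10")
})

test_that("mediation follows the five sign rules exactly", {
  feats <- data.table(feature_id = c("g", "h", "k"), chrom = "c1",
                      start = c(10000L, 20000L, 30000L),
                      end = c(12000L, 22000L, 32000L),
                      strand = "+", kind = "gene")
  degs <- data.table(gene_id = c("g", "h", "k"),
                     log2fc = c(-3, 3, -3), qvalue = 0.001,
                     direction = c("down", "up", "down"), comparison = "3d")
  dmrs <- data.table(
    chrom = "c1",
    start = c(10500L, 18500L, 28500L),
    end = c(10600L, 18600L, 28600L),
    context = c("CHG", "CHH", "CHH"),
    direction = c("hyper", "hyper", "hyper"))
  med <- quiet(identify_mediated_degs(degs, dmrs, feats))
  # hyper CHG in g's body + down-DEG: mediated (negative combo)
  # hyper CHH in h's up2k + up-DEG: mediated (positive combo)
  # hyper CHH in k's up2k + down-DEG: sign mismatch, not mediated
  expect_setequal(med$mediated$gene_id, c("g", "h"))
  expect_equal(med$mediated[gene_id == "g", combo_id], "body_CHG")
  expect_equal(med$mediated[gene_id == "h", combo_id], "up2k_CHH")
  expect_equal(med$nonredundant[order(direction)],
               data.table(direction = c("down", "up"), n_genes = c(1L, 1L)))

  # label swap: inverting all DMR and DEG directions leaves the set unchanged
  degs2 <- copy(degs)[, direction := fifelse(direction == "up", "down", "up")]
  dmrs2 <- copy(dmrs)[, direction := fifelse(direction == "hyper", "hypo", "hyper")]
  med2 <- quiet(identify_mediated_degs(degs2, dmrs2, feats))
  expect_equal(med2$mediated[, .(gene_id, combo_id)],
               med$mediated[, .(gene_id, combo_id)])

  # a rule table that is not the canonical five is rejected without override
  custom <- region_context_combos()[1:3]
  expect_error(quiet(identify_mediated_degs(degs, dmrs, feats, combos = custom)),
               "canonical")
  expect_silent(suppressMessages(
    identify_mediated_degs(degs, dmrs, feats, combos = custom,
                           allow_custom_combos = TRUE)))
})
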