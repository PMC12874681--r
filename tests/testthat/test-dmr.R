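# Exact tests, DMP/DMR calling, merging and annotation.

test_that("vectorised Fisher p-values match stats::fisher.test exactly", {
  set.seed(42)
  n <- 60L
  a <- rbinom(n, 40, 0.5); b <- 40L - a
  c_ <- rbinom(n, 40, 0.3); d <- 40L - c_
  p_pkg <- fisher_exact_2x2(a, b, c_, d)
  p_ref <- vapply(seq_len(n), function(i) {
    stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2L,
                              byrow = TRUE))$p.value
  }, numeric(1L))
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)

  # exhaustive-enumeration oracle on the canonical strongly-shifted table
  expect_equal(fisher_exact_2x2(9L, 1L, 1L, 9L), bf_fisher_p(9L, 1L, 1L, 9L),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0L, 0L, 0L, 0L), 1)
})

test_that("replicate pooling sums counts and enforces alignment", {
  r1 <- data.table(chrom = "c1", pos = c(1L, 5L), strand = "+",
                   context = "CG", count_meth = c(3L, 0L),
                   count_unmeth = c(1L, 2L))
  r2 <- copy(r1)[, `:=`(count_meth = c(2L, 1L), count_unmeth = c(4L, 0L))]
  pooled <- pool_group_counts(list(r1, r2))
  expect_equal(pooled$count_meth, c(5L, 1L))
  expect_equal(pooled$count_unmeth, c(5L, 2L))
  expect_equal(pool_group_counts(list(r1)), r1)  # single replicate: identity
  r3 <- copy(r2)[1L, pos := 2L]
  expect_error(pool_group_counts(list(r1, r3)), "misaligned")
})

test_that("DMP calling applies coverage, q and delta thresholds", {
  mk <- function(meth, unmeth) {
    data.table(chrom = "c1", pos = seq_along(meth) * 10L, strand = "+",
               context = "CG", count_meth = as.integer(meth),
               count_unmeth = as.integer(unmeth), masked = FALSE)
  }
  # 30 null sites keep BH honest, one strongly shifted site
  set.seed(3)
  ctl <- mk(c(rep(10L, 30L), 18L), c(rep(10L, 30L), 2L))
  trt <- mk(c(rep(10L, 30L), 2L), c(rep(10L, 30L), 18L))
  dmps <- quiet(call_dmps(ctl, trt, delta_min = c(CG = 0.4, CHG = 0.2, CHH = 0.1)))
  expect_equal(nrow(dmps), 1L)
  expect_equal(dmps$start, 310L)
  expect_equal(dmps$direction, "hypo")
  expect_equal(dmps$delta, -0.8)
  expect_equal(dmps$p_value, bf_fisher_p(18L, 2L, 2L, 18L), tolerance = 1e-12)

  # identical counts never reported; low-coverage sites never tested
  same <- quiet(call_dmps(ctl, ctl))
  expect_equal(nrow(same), 0L)
  ctl2 <- copy(ctl)[31L, `:=`(count_meth = 1L, count_unmeth = 1L)]
  d2 <- quiet(call_dmps(ctl2, trt))
  expect_equal(nrow(d2), 0L)
})

test_that("windowed DMR caller matches the brute-force oracle on a toy chromosome", {
  # 2 kb chromosome, mixed contexts, two planted shifted blocks and noise
  set.seed(19)
  pos <- sort(sample(0:1999, 320))
  ctx <- sample(c("CG", "CHG", "CHH"), 320, TRUE)
  lvl_ctl <- fifelse(ctx == "CG", 0.8, fifelse(ctx == "CHG", 0.6, 0.1))
  lvl_trt <- lvl_ctl
  lvl_trt[pos >= 300 & pos < 700 & ctx == "CHH"] <- 0.6    # hyper block
  lvl_trt[pos >= 1200 & pos < 1500 & ctx == "CHG"] <- 0.1  # hypo block
  cov <- rpois(320, 30) + 4L
  mk <- function(lvl) data.table(
    chrom = "toy", pos = pos, strand = "+", context = ctx,
    count_meth = rbinom(320, cov, lvl),
    count_unmeth = NA_integer_, masked = FALSE)
  ctl <- mk(lvl_ctl); ctl[, count_unmeth := cov - count_meth]
  trt <- mk(lvl_trt); trt[, count_unmeth := cov - count_meth]

  got <- quiet(call_dmrs(ctl, trt))
  ref <- bf_call_dmrs(ctl, trt)
  expect_gt(nrow(got), 0L)
  cols <- c("chrom", "start", "end", "context", "direction", "n_windows")
  expect_equal(as.data.frame(got[, cols, with = FALSE]),
               as.data.frame(ref[, cols, with = FALSE]))
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-9)
  expect_equal(got$delta, ref$delta, tolerance = 1e-12)
  expect_equal(got$q_value, ref$q_value, tolerance = 1e-12)
})

test_that("extreme windows, merging and min_sites behave as specified", {
  mk_run <- function(meth_frac, pos) data.table(
    chrom = "c1", pos = as.integer(pos), strand = "+", context = "CHH",
    count_meth = as.integer(round(10 * meth_frac)),
    count_unmeth = as.integer(round(10 * (1 - meth_frac))), masked = FALSE)
  # five fully-switched sites in one window -> hyper DMR with delta 1
  pos5 <- c(10, 20, 30, 40, 50)
  d <- quiet(call_dmrs(mk_run(0, pos5), mk_run(1, pos5)))
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hyper")
  expect_equal(d$delta, 1)

  # two significant windows 50 bp apart merge into one region
  pos2 <- c(pos5, pos5 + 250)
  d2 <- quiet(call_dmrs(mk_run(0, pos2), mk_run(1, pos2), merge_gap_bp = 100L))
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$n_windows, 2L)
  expect_equal(d2$start, 0L)
  expect_equal(d2$end, 300L)
  # but not when the allowed gap is smaller than the separation
  d3 <- quiet(call_dmrs(mk_run(0, pos2), mk_run(1, pos2), merge_gap_bp = 50L))
  expect_equal(nrow(d3), 2L)

  # three testable sites under min_sites = 4: nothing tested
  d4 <- quiet(call_dmrs(mk_run(0, pos5[1:3]), mk_run(1, pos5[1:3])))
  expect_equal(nrow(d4), 0L)
})

test_that("direction partitions and swaps with the group labels", {
  fx <- sim_site_samples(tiny_config(seed = 23L))
  pooled <- pool_by_group(fx$samples)
  a <- pooled[["control-0d"]]; b <- pooled[["treated-3d"]]
  fwd <- quiet(call_dmrs(a, b))
  bwd <- quiet(call_dmrs(b, a))
  expect_true(all(fwd$direction %in% c("hyper", "hypo")))
  setorder(fwd, chrom, start, context)
  setorder(bwd, chrom, start, context)
  expect_equal(fwd[, .(chrom, start, end, context)],
               bwd[, .(chrom, start, end, context)])
  expect_equal(fwd$direction == "hyper", bwd$direction == "hypo")
  expect_equal(fwd$p_value, bwd$p_value, tolerance = 1e-12)
  expect_equal(fwd$delta, -bwd$delta, tolerance = 1e-12)
})

test_that("annotation priority is promoter > body > downstream > distal", {
  feats <- data.table(
    feature_id = c("gA", "gB"), chrom = "c1",
    start = c(5000L, 2600L), end = c(6000L, 3400L),
    strand = c("+", "+"), kind = "gene")
  dmrs <- data.table(
    chrom = "c1",
    start = c(4500L, 3300L, 6100L, 20000L),
    end = c(4600L, 3500L, 6200L, 20100L),
    context = "CG", direction = "hyper")
  ann <- annotate_dmrs(dmrs, feats)
  # 4500: promoter of gA only. 3300: body of gB AND promoter of gA ->
  # promoter wins. 6100: downstream of gA. 20000: distal.
  expect_equal(ann$annotation,
               c("promoter", "promoter", "downstream", "distal_intergenic"))
  expect_equal(ann$feature_id, c("gA", "gA", "gA", NA))

  # minus-strand gene: promoter sits to the right of the body
  fm <- data.table(feature_id = "gM", chrom = "c1", start = 5000L,
                   end = 6000L, strand = "-", kind = "gene")
  am <- annotate_dmrs(data.table(chrom = "c1", start = 6100L, end = 6200L,
                                 context = "CG", direction = "hyper"), fm)
  expect_equal(am$annotation, "promoter")
})
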