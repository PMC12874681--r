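# DMP and DMR calling between a treated and a control group: pooled counts,
# two-sided Fisher exact tests, BH control per context, window merging, and
# feature annotation.

#' Two-sided Fisher exact test for 2x2 count tables, vectorised
#'
#' Exact two-sided p-values for tables
#' `rbind(c(meth_a, unmeth_a), c(meth_b, unmeth_b))` by hypergeometric
#' enumeration: all tables with the observed margins whose probability does
#' not exceed the observed table's (with a 1e-7 relative tolerance for
#' floating-point ties, as in [stats::fisher.test()]) contribute to p.
#' Implemented in-package because per-site calling runs this at up to a few
#' million sites, where `fisher.test`'s per-call overhead dominates.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b Integer vectors of equal length.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_2x2 <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- length(meth_a)
  stopifnot(length(unmeth_a) == n, length(meth_b) == n, length(unmeth_b) == n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- meth_a[i] + meth_b[i]
    u <- unmeth_a[i] + unmeth_b[i]
    k <- meth_a[i] + unmeth_a[i]
    lo <- max(0L, k - u)
    hi <- min(k, m)
    d <- stats::dhyper(lo:hi, m, u, k)
    p[i] <- min(1, sum(d[d <= d[meth_a[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

#' Pool replicate counts within a sample group
#'
#' Sums methylated/unmethylated counts across a group's replicate CX tables,
#' site by site. All replicates must describe exactly the same site set
#' (same genome, same mask); misalignment is an error, not a silent join.
#'
#' @param cx_list List of CX/site tables sharing `chrom`, `pos`, `strand`
#'   (and optionally `context`, `trinucleotide`, `masked`).
#' @return One table with summed `count_meth`/`count_unmeth`.
#' @export
pool_group_counts <- function(cx_list) {
  stopifnot(length(cx_list) >= 1L)
  ref <- as.data.table(cx_list[[1L]])
  key_cols <- c("chrom", "pos", "strand")
  pooled <- copy(ref)
  for (j in seq_along(cx_list)[-1L]) {
    cur <- as.data.table(cx_list[[j]])
    if (nrow(cur) != nrow(ref) ||
        !identical(cur[, key_cols, with = FALSE],
                   ref[, key_cols, with = FALSE])) {
      stop_hm("replicate %d is misaligned with replicate 1 (site sets differ)", j)
    }
    if ("masked" %in% names(cur) && "masked" %in% names(ref) &&
        !identical(cur$masked, ref$masked)) {
      stop_hm("replicate %d carries a different mask than replicate 1", j)
    }
    pooled[, `:=`(count_meth = count_meth + cur$count_meth,
                  count_unmeth = count_unmeth + cur$count_unmeth)]
  }
  pooled[]
}

DELTA_MIN_DEFAULT <- c(CG = 0.4, CHG = 0.2, CHH = 0.1)

.empty_dmr_table <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             context = character(), n_sites = integer(),
             level_control = numeric(), level_treated = numeric(),
             delta = numeric(), p_value = numeric(), q_value = numeric(),
             direction = character(), n_windows = integer())
}

.testable <- function(ctl, trt, min_coverage) {
  m <- merge(
    as.data.table(ctl)[, .(chrom, pos, strand, context,
                           masked = if ("masked" %in% names(ctl)) masked else FALSE,
                           meth_a = count_meth, unmeth_a = count_unmeth)],
    as.data.table(trt)[, .(chrom, pos, strand,
                           meth_b = count_meth, unmeth_b = count_unmeth)],
    by = c("chrom", "pos", "strand")
  )
  m[, eligible := !masked & (meth_a + unmeth_a) >= min_coverage &
      (meth_b + unmeth_b) >= min_coverage]
  m
}

#' Call differentially methylated positions (DMPs)
#'
#' Per unmasked site covered at least `min_coverage` in both pooled groups:
#' a two-sided Fisher exact test on the 2x2 methylated/unmethylated by
#' control/treated table, Benjamini-Hochberg adjustment across all tested
#' sites of the same context, and reporting of sites with `q <= q_max` and
#' an absolute level difference of at least the context's `delta_min`
#' (defaults CG 0.4, CHG 0.2, CHH 0.1). `hyper` means higher in treated.
#'
#' @param pooled_control,pooled_treated Pooled site tables from
#'   [pool_group_counts()] (control and treated groups).
#' @param min_coverage Per-group coverage floor (default 4).
#' @param delta_min Named per-context minimum |delta|.
#' @param q_max BH-FDR threshold (default 0.05).
#' @return `data.table` of DMP records: `chrom`, `start`, `end`
#'   (`start + 1`), `strand`, `context`, `level_control`, `level_treated`,
#'   `delta`, `p_value`, `q_value`, `direction`.
#' @export
call_dmps <- function(pooled_control, pooled_treated, min_coverage = 4L,
                      delta_min = DELTA_MIN_DEFAULT, q_max = 0.05) {
  m <- .testable(pooled_control, pooled_treated, min_coverage)
  t_ <- m[eligible == TRUE]
  if (nrow(t_) == 0L) stop_hm("no testable site for DMP calling")
  t_[, p_value := fisher_exact_2x2(meth_a, unmeth_a, meth_b, unmeth_b)]
  t_[, q_value := stats::p.adjust(p_value, method = "BH"), by = context]
  t_[, `:=`(level_control = meth_a / (meth_a + unmeth_a),
            level_treated = meth_b / (meth_b + unmeth_b))]
  t_[, delta := level_treated - level_control]
  out <- t_[q_value <= q_max & abs(delta) >= delta_min[context]]
  out[, direction := fifelse(delta > 0, "hyper", "hypo")]
  res <- out[, .(chrom, start = pos, end = pos + 1L, strand, context,
                 level_control, level_treated, delta, p_value, q_value,
                 direction)]
  setorder(res, chrom, start, context)
  hm_log("dmr", "DMPs: %d tested, %d reported (%d hyper / %d hypo)",
         nrow(t_), nrow(res), sum(res$direction == "hyper"),
         sum(res$direction == "hypo"))
  res[]
}

#' Call differentially methylated regions (DMRs)
#'
#' Tiles each chromosome into non-overlapping `window_bp` windows. Every
#' window with at least `min_sites` testable sites (unmasked, covered
#' `min_coverage`+ in both groups) per context gets a Fisher exact test on
#' the summed counts and a weighted level difference; BH runs across windows
#' per context. Significant windows of the same direction separated by at
#' most `merge_gap_bp` merge into one DMR whose delta and p-value are
#' recomputed on the merged counts; the reported q is the smallest member
#' window's (q is controlled at the pre-merge window stage).
#'
#' @inheritParams call_dmps
#' @param window_bp Window width (default 100).
#' @param min_sites Minimum testable sites per window (default 4).
#' @param merge_gap_bp Maximum gap between merged windows (default 100).
#' @return `data.table` of DMR records: `chrom`, `start`, `end`, `context`,
#'   `n_sites`, `level_control`, `level_treated`, `delta`, `p_value`,
#'   `q_value`, `direction`, `n_windows`.
#' @export
call_dmrs <- function(pooled_control, pooled_treated, window_bp = 100L,
                      min_sites = 4L, min_coverage = 4L,
                      delta_min = DELTA_MIN_DEFAULT, q_max = 0.05,
                      merge_gap_bp = 100L) {
  if (window_bp <= 0L) stop_hm("window_bp must be positive")
  m <- .testable(pooled_control, pooled_treated, min_coverage)
  t_ <- m[eligible == TRUE]
  if (nrow(t_) == 0L) stop_hm("no testable site for DMR calling")
  t_[, win := pos %/% as.integer(window_bp)]
  w <- t_[, .(n_sites = .N, meth_a = sum(meth_a), unmeth_a = sum(unmeth_a),
              meth_b = sum(meth_b), unmeth_b = sum(unmeth_b)),
          by = .(chrom, context, win)]
  w <- w[n_sites >= min_sites]
  if (nrow(w) == 0L) {
    hm_log("dmr", "DMRs: no window with >= %d testable sites", min_sites)
    return(.empty_dmr_table())
  }
  w[, p_value := fisher_exact_2x2(meth_a, unmeth_a, meth_b, unmeth_b)]
  w[, q_value := stats::p.adjust(p_value, method = "BH"), by = context]
  w[, delta := meth_b / (meth_b + unmeth_b) - meth_a / (meth_a + unmeth_a)]
  w[, sig := q_value <= q_max & abs(delta) >= delta_min[context]]
  sigw <- w[sig == TRUE]
  if (nrow(sigw) == 0L) {
    hm_log("dmr", "DMRs: %d windows tested, none significant", nrow(w))
    return(.empty_dmr_table())
  }
  sigw[, direction := fifelse(delta > 0, "hyper", "hypo")]
  sigw[, `:=`(start = win * as.integer(window_bp),
              end = (win + 1L) * as.integer(window_bp))]
  setorder(sigw, context, chrom, start)
  # same-direction runs with gaps <= merge_gap_bp become one region;
  # context/chrom/direction are grouping keys, so only the gap matters here
  sigw[, block := cumsum(c(TRUE, start[-1L] - end[-.N] > merge_gap_bp)),
       by = .(context, chrom, direction)]
  merged <- sigw[, .(
    start = min(start), end = max(end), n_sites = sum(n_sites),
    meth_a = sum(meth_a), unmeth_a = sum(unmeth_a),
    meth_b = sum(meth_b), unmeth_b = sum(unmeth_b),
    q_value = min(q_value), n_windows = .N
  ), by = .(context, chrom, direction, block)]
  merged[, p_value := fisher_exact_2x2(meth_a, unmeth_a, meth_b, unmeth_b)]
  merged[, `:=`(level_control = meth_a / (meth_a + unmeth_a),
                level_treated = meth_b / (meth_b + unmeth_b))]
  merged[, delta := level_treated - level_control]
  res <- merged[, .(chrom, start, end, context, n_sites, level_control,
                    level_treated, delta, p_value, q_value, direction,
                    n_windows)]
  setorder(res, chrom, start, context)
  hm_log("dmr", "DMRs: %d windows tested, %d significant, %d merged regions (%d hyper / %d hypo)",
         nrow(w), nrow(sigw), nrow(res), sum(res$direction == "hyper"),
         sum(res$direction == "hypo"))
  res[]
}

#' Annotate DMRs (or DMPs) to genomic features
#'
#' Assigns each record the highest-priority label among overlapping
#' (>= 1 bp) feature regions: `promoter` ( `[TSS - promoter_bp, TSS)` in
#' transcriptional orientation) beats `gene_body`, which beats `downstream`
#' (`[TES, TES + downstream_bp)`); records overlapping nothing are
#' `distal_intergenic`. Within a priority level, ties go to the feature
#' with the nearest TSS, then to the lexicographically smallest id.
#'
#' @param dmrs DMR/DMP table with `chrom`, `start`, `end`.
#' @param features Feature table.
#' @param promoter_bp,downstream_bp Flank widths (defaults 2000).
#' @return The input plus `annotation` and `feature_id` columns (a copy;
#'   `feature_id` is `NA` for distal records).
#' @export
annotate_dmrs <- function(dmrs, features, promoter_bp = 2000L,
                          downstream_bp = 2000L) {
  dmrs <- copy(as.data.table(dmrs))
  f <- as.data.table(features)
  if (nrow(dmrs) == 0L) {
    dmrs[, `:=`(annotation = character(), feature_id = character())]
    return(dmrs[])
  }
  dgr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  tss <- fifelse(f$strand == "+", f$start, f$end - 1L)
  region_gr <- function(region_class, flank) {
    r <- feature_regions(f, region_class, flank)
    r[, start := pmax(start, 0L)]
    GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$start + 1L, r$end))
  }
  levels <- list(
    promoter = region_gr("up2k", promoter_bp),
    gene_body = region_gr("body", 0L),
    downstream = region_gr("down2k", downstream_bp)
  )
  hits <- rbindlist(lapply(seq_along(levels), function(li) {
    ov <- GenomicRanges::findOverlaps(dgr, levels[[li]])
    data.table(dmr = S4Vectors::queryHits(ov),
               feat = S4Vectors::subjectHits(ov), prio = li)
  }))
  dmrs[, `:=`(annotation = "distal_intergenic", feature_id = NA_character_)]
  if (nrow(hits)) {
    hits[, feature_id := f$feature_id[feat]]
    hits[, tss_dist := {
      t <- tss[feat]
      pmax(0L, pmax(dmrs$start[dmr] - t, t - (dmrs$end[dmr] - 1L)))
    }]
    setorder(hits, dmr, prio, tss_dist, feature_id)
    best <- hits[, .SD[1L], by = dmr]
    lab <- names(levels)
    dmrs[best$dmr, `:=`(annotation = lab[best$prio],
                        feature_id = best$feature_id)]
  }
  dmrs[]
}

#' Hyper/hypo tallies per context
#'
#' Summarises a DMP or DMR table into counts by context and direction — the
#' per-comparison tally of hyper- versus hypomethylated calls.
#'
#' @param records DMP/DMR table with `context` and `direction`.
#' @return `data.table`: `context`, `n_hyper`, `n_hypo`.
#' @export
dm_summary <- function(records) {
  r <- as.data.table(records)
  out <- r[, .(n_hyper = sum(direction == "hyper"),
               n_hypo = sum(direction == "hypo")), by = context]
  setorder(out, context)
  out[]
}
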