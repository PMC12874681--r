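# Expression-side integration: a minimal DEG caller for the synthetic
# pipeline, core / period-specific DEG classification, region-by-context
# methylation-expression correlation, and DMR-mediated DEG identification.

#' Library-size-normalised log2 expression
#'
#' Counts-per-million per sample, then `log2(CPM + 1)`.
#'
#' @param counts Count table (`gene_id` plus one column per sample).
#' @param samples Sample columns to keep (default: all).
#' @return Matrix of log2(CPM+1), genes in rows.
#' @export
log2_cpm <- function(counts, samples = NULL) {
  dt <- as.data.table(counts)
  samples <- samples %||% setdiff(names(dt), "gene_id")
  m <- as.matrix(dt[, samples, with = FALSE])
  rownames(m) <- dt$gene_id
  libsize <- colSums(m)
  if (any(libsize == 0)) stop_hm("sample with zero total counts")
  log2(sweep(m, 2L, libsize, "/") * 1e6 + 1)
}

#' Call differentially expressed genes (built-in minimal caller)
#'
#' A stand-in DEG caller for the synthetic pipeline: per gene, a two-sided
#' Welch (unequal-variance) t-test on `log2(CPM + 1)` between the two
#' groups, BH adjustment across genes, and a DEG call iff `q <= q_max` and
#' `|log2fc| >= log2fc_min` (log2fc is group_b minus group_a). With a
#' single replicate per group the caller switches to fold-change-only mode
#' (no p-values; flagged in the `mode` attribute). Genes with zero counts
#' in every sample are skipped and logged. Externally produced DEG tables
#' can be used instead anywhere a DEG table is consumed.
#'
#' @param counts Count table (`gene_id` plus sample columns).
#' @param group_a,group_b Sample column names (reference group first).
#' @param log2fc_min Minimum absolute log2 fold-change (default 1).
#' @param q_max BH-FDR threshold (default 0.05).
#' @param comparison Label stored on every record.
#' @return DEG `data.table` (`gene_id`, `log2fc`, `qvalue`, `direction`,
#'   `comparison`) containing only the significant genes; attributes
#'   `n_tested` and `mode` (`"welch"` or `"fc_only"`).
#' @export
call_degs <- function(counts, group_a, group_b, log2fc_min = 1,
                      q_max = 0.05, comparison = "treated_vs_control") {
  dt <- as.data.table(counts)
  missing_cols <- setdiff(c(group_a, group_b), names(dt))
  if (length(missing_cols)) {
    stop_hm("sample column(s) not in counts: %s",
            paste(missing_cols, collapse = ", "))
  }
  lc <- log2_cpm(dt, c(group_a, group_b))
  allzero <- rowSums(as.matrix(dt[, c(group_a, group_b), with = FALSE])) == 0
  if (any(allzero)) {
    hm_log("integrate", "skipping %d all-zero gene(s)", sum(allzero))
    lc <- lc[!allzero, , drop = FALSE]
  }
  a <- lc[, group_a, drop = FALSE]
  b <- lc[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  log2fc <- mb - ma
  fc_only <- na < 2L || nb < 2L
  if (fc_only) {
    res <- data.table(gene_id = rownames(lc), log2fc = log2fc,
                      qvalue = NA_real_)
    sig <- abs(res$log2fc) >= log2fc_min
  } else {
    va <- apply(a, 1L, stats::var)
    vb <- apply(b, 1L, stats::var)
    se2 <- va / na + vb / nb
    tt <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    # degenerate zero-variance rows: identical groups are null, different
    # groups are as extreme as possible
    p[se2 == 0] <- as.numeric(ma[se2 == 0] == mb[se2 == 0])
    q <- stats::p.adjust(p, method = "BH")
    res <- data.table(gene_id = rownames(lc), log2fc = log2fc, qvalue = q)
    sig <- res$qvalue <= q_max & abs(res$log2fc) >= log2fc_min
  }
  out <- res[sig]
  out[, `:=`(direction = fifelse(log2fc > 0, "up", "down"),
             comparison = comparison)]
  setattr(out, "n_tested", nrow(res))
  setattr(out, "mode", if (fc_only) "fc_only" else "welch")
  hm_log("integrate", "DEGs (%s): %d tested, %d called (%d up / %d down)%s",
         comparison, nrow(res), nrow(out), sum(out$direction == "up"),
         sum(out$direction == "down"),
         if (fc_only) " [fold-change-only mode]" else "")
  out[]
}

#' Classify core versus period-specific DEGs for one stress
#'
#' A gene differentially expressed at both day 3 and day 7 (relative to day
#' 0) with the same direction is a core DEG of that direction; a gene
#' differentially expressed at exactly one day is period-specific; a gene
#' significant at both days with opposite directions belongs to neither set
#' and is tallied separately as discordant. The three parts partition the
#' union of the two DEG lists.
#'
#' @param degs_3d,degs_7d DEG tables for the day-3 and day-7 comparisons.
#' @return An `hm_core_sets` list: `core_up`, `core_down`,
#'   `period_specific`, `discordant` (character vectors of gene ids).
#' @export
classify_core_degs <- function(degs_3d, degs_7d) {
  d3 <- as.data.table(degs_3d)
  d7 <- as.data.table(degs_7d)
  both <- merge(d3[, .(gene_id, dir3 = direction)],
                d7[, .(gene_id, dir7 = direction)], by = "gene_id")
  core_up <- both[dir3 == "up" & dir7 == "up", gene_id]
  core_down <- both[dir3 == "down" & dir7 == "down", gene_id]
  discordant <- both[dir3 != dir7, gene_id]
  period_specific <- setdiff(union(d3$gene_id, d7$gene_id), both$gene_id)
  out <- list(core_up = sort(core_up), core_down = sort(core_down),
              period_specific = sort(period_specific),
              discordant = sort(discordant))
  structure(out, class = "hm_core_sets")
}

#' @export
print.hm_core_sets <- function(x, ...) {
  cat(sprintf("core DEG sets: %d core-up, %d core-down, %d period-specific, %d discordant\n",
              length(x$core_up), length(x$core_down),
              length(x$period_specific), length(x$discordant)))
  invisible(x)
}

#' Cross-stress core DEG intersections
#'
#' Intersects the core DEG sets of two stresses per direction and reports
#' the common and stress-specific sets — the cross-stress Venn tallies.
#'
#' @param core_a,core_b `hm_core_sets` for the two stresses.
#' @param labels Stress labels used in the output names.
#' @return List with `common_core_up`, `common_core_down`, and per-stress
#'   `only` sets (e.g. `salt_only_up`).
#' @export
cross_stress_core <- function(core_a, core_b, labels = c("salt", "alkali")) {
  out <- list(
    common_core_up = sort(intersect(core_a$core_up, core_b$core_up)),
    common_core_down = sort(intersect(core_a$core_down, core_b$core_down))
  )
  out[[paste0(labels[1L], "_only_up")]] <- sort(setdiff(core_a$core_up, core_b$core_up))
  out[[paste0(labels[2L], "_only_up")]] <- sort(setdiff(core_b$core_up, core_a$core_up))
  out[[paste0(labels[1L], "_only_down")]] <- sort(setdiff(core_a$core_down, core_b$core_down))
  out[[paste0(labels[2L], "_only_down")]] <- sort(setdiff(core_b$core_down, core_a$core_down))
  out
}

#' Methylation-expression correlation for one region-by-context class
#'
#' Spearman rank correlation between per-gene region methylation levels and
#' per-gene expression (`log2(CPM + 1)` averaged over a sample group).
#' Genes without a methylation level are dropped; fewer than 10 usable
#' genes, or constant levels (rank correlation undefined), is an error.
#'
#' @param region_levels `data.table` from [gene_region_levels()]
#'   (`feature_id`, `level`).
#' @param expression Named numeric vector of per-gene expression (names are
#'   gene ids).
#' @param context,region_class Labels recorded in the result.
#' @return List: `rho`, `p`, `n`, `context`, `region_class`.
#' @export
methylation_expression_correlation <- function(region_levels, expression,
                                               context = NA_character_,
                                               region_class = NA_character_) {
  rl <- as.data.table(region_levels)
  rl <- rl[!is.na(level) & feature_id %in% names(expression)]
  if (nrow(rl) < 10L) {
    stop_hm("only %d gene(s) with both methylation and expression (need >= 10)",
            nrow(rl))
  }
  x <- rl$level
  y <- unname(expression[rl$feature_id])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_hm("correlation undefined: constant %s",
            if (stats::sd(x) == 0) "methylation levels" else "expression")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(rl),
       context = context, region_class = region_class)
}

#' Identify DMR-mediated DEGs under the five region-by-context rules
#'
#' For each DEG and each active combination, the gene is "mediated" if a
#' DMR of the combination's context overlaps (>= 1 bp, transcriptional
#' orientation) the combination's region of that gene and the DMR/DEG
#' direction pair satisfies the combination's sign rule: for
#' negative-correlation combinations hyper pairs with down and hypo with
#' up; for the positive one (upstream-2kb mCHH) hyper pairs with up and
#' hypo with down. Mediation is an association label — overlap plus sign
#' consistency — not a causal claim.
#'
#' @param degs DEG table (one comparison).
#' @param dmrs DMR table from [call_dmrs()] (same comparison).
#' @param features Feature table (genes).
#' @param combos Combination table; must equal [region_context_combos()]
#'   unless `allow_custom_combos = TRUE`.
#' @param flank_bp Flank width for up2k/down2k regions (default 2000).
#' @param allow_custom_combos Permit a non-default rule table.
#' @return List: `mediated` (`gene_id`, `deg_direction`, `combo_id`,
#'   `dmr_direction`, `chrom`, `dmr_start`, `dmr_end`, `comparison`) and
#'   `nonredundant` (distinct mediated genes per DEG direction).
#' @export
identify_mediated_degs <- function(degs, dmrs, features,
                                   combos = region_context_combos(),
                                   flank_bp = 2000L,
                                   allow_custom_combos = FALSE) {
  combos <- as.data.table(combos)
  canon <- region_context_combos()
  if (!allow_custom_combos &&
      !isTRUE(all.equal(combos[order(combo_id)], canon[order(combo_id)]))) {
    stop_hm("combos differ from the five canonical region-context rules; set allow_custom_combos = TRUE to override")
  }
  degs <- as.data.table(degs)
  dmrs <- as.data.table(dmrs)
  genes <- as.data.table(features)[kind == "gene"]
  hits <- list()
  for (ci in seq_len(nrow(combos))) {
    cb <- combos[ci]
    dm <- dmrs[context == cb$context]
    dg <- degs[gene_id %in% genes$feature_id]
    if (nrow(dm) == 0L || nrow(dg) == 0L) next
    reg <- feature_regions(genes[feature_id %in% dg$gene_id], cb$region_class,
                           flank_bp)
    reg[, start := pmax(start, 0L)]
    rgr <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start + 1L, reg$end))
    dgr <- GenomicRanges::GRanges(dm$chrom, IRanges::IRanges(dm$start + 1L, dm$end))
    ov <- GenomicRanges::findOverlaps(rgr, dgr)
    if (length(ov) == 0L) next
    cand <- data.table(gene_id = reg$feature_id[S4Vectors::queryHits(ov)],
                       dmr_idx = S4Vectors::subjectHits(ov))
    cand <- merge(cand, dg[, .(gene_id, deg_direction = direction,
                               comparison)], by = "gene_id",
                  allow.cartesian = TRUE)
    cand[, dmr_direction := dm$direction[dmr_idx]]
    ok <- if (cb$sign < 0) {
      (cand$dmr_direction == "hyper" & cand$deg_direction == "down") |
        (cand$dmr_direction == "hypo" & cand$deg_direction == "up")
    } else {
      (cand$dmr_direction == "hyper" & cand$deg_direction == "up") |
        (cand$dmr_direction == "hypo" & cand$deg_direction == "down")
    }
    cand <- cand[ok]
    if (nrow(cand) == 0L) next
    cand[, `:=`(combo_id = cb$combo_id, chrom = dm$chrom[dmr_idx],
                dmr_start = dm$start[dmr_idx], dmr_end = dm$end[dmr_idx])]
    hits[[length(hits) + 1L]] <- cand[, .(gene_id, deg_direction, combo_id,
                                          dmr_direction, chrom, dmr_start,
                                          dmr_end, comparison)]
  }
  mediated <- if (length(hits)) rbindlist(hits) else
    data.table(gene_id = character(), deg_direction = character(),
               combo_id = character(), dmr_direction = character(),
               chrom = character(), dmr_start = integer(),
               dmr_end = integer(), comparison = character())
  setorder(mediated, gene_id, combo_id)
  nonredundant <- mediated[, .(n_genes = length(unique(gene_id))),
                           by = .(direction = deg_direction)]
  hm_log("integrate", "mediated DEGs: %d pairings over %d distinct gene(s)",
         nrow(mediated), length(unique(mediated$gene_id)))
  list(mediated = mediated[], nonredundant = nonredundant[])
}
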