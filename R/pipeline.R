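# End-to-end orchestration: simulate -> quantify -> profile -> dmr ->
# integrate, with every stage also callable on files (the CLI surface).

#' Quantification stage: contexts, masking, weighted levels
#'
#' Reads the reference, assigns contexts, masks variant-confounded
#' cytosines, attaches each sample's CX counts and writes the per-sample
#' weighted-level report plus the masked-site BED.
#'
#' @param fasta_path Reference FASTA.
#' @param vcf_path Resequencing VCF.
#' @param cx_paths Named character vector of CX report paths (names are
#'   sample ids).
#' @param out_dir Output directory.
#' @param min_coverage Per-site coverage floor.
#' @return Invisibly, `list(sites, samples, report)`: the masked site
#'   template, per-sample site tables with counts, and the combined report.
#' @export
stage_quantify <- function(fasta_path, vcf_path, cx_paths, out_dir,
                           min_coverage = 4L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_fasta(fasta_path)
  sites <- assign_contexts(genome)
  variants <- read_vcf_variants(vcf_path)
  sites <- mask_variant_cytosines(sites, variants, genome)
  samples <- list()
  reports <- list()
  for (sid in names(cx_paths)) {
    cx <- read_cx_report(cx_paths[[sid]])
    s <- attach_counts(sites, cx)
    samples[[sid]] <- s
    reports[[sid]] <- weighted_level_report(s, min_coverage, sample_id = sid)
  }
  report <- rbindlist(reports)
  fwrite(report, file.path(out_dir, "weighted_levels.tsv"), sep = "\t")
  masked <- sites[masked == TRUE,
                  .(chrom, start = pos, end = pos + 1L, name = ".",
                    score = ".", strand)]
  fwrite(masked, file.path(out_dir, "masked_sites.bed"), sep = "\t",
         col.names = FALSE)
  invisible(list(sites = sites, samples = samples, report = report))
}

# group label from a replicate sample id ("control-0d_r2" -> "control-0d")
sample_group <- function(sample_ids) sub("_r[0-9]+$", "", sample_ids)

#' Pool replicate site tables into per-group pooled counts
#'
#' Splits a named list of per-sample site tables by group (the sample name
#' up to the `_r<k>` replicate suffix) and sums counts within each group
#' via [pool_group_counts()].
#'
#' @param samples Named list of site tables with counts.
#' @return Named list of pooled site tables, one per group.
#' @export
pool_by_group <- function(samples) {
  grp <- sample_group(names(samples))
  lapply(split(names(samples), grp), function(ids) {
    pool_group_counts(samples[ids])
  })
}

#' Metagene-profile stage
#'
#' Computes pooled metagene profiles for every (feature kind, context,
#' sample group) and writes one long-format table.
#'
#' @param pooled Named list of pooled site tables (one per group).
#' @param feature_sets Named list of feature tables (e.g. gene, TE).
#' @param out_dir Output directory.
#' @param min_coverage Per-site coverage floor.
#' @return Invisibly, the long profile table.
#' @export
stage_profile <- function(pooled, feature_sets, out_dir, min_coverage = 4L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (gname in names(pooled)) {
    for (fs in names(feature_sets)) {
      for (ctx in CONTEXTS) {
        pr <- compute_profile(pooled[[gname]], feature_sets[[fs]], ctx,
                              min_coverage = min_coverage, sample_id = gname)
        rows[[length(rows) + 1L]] <- as.data.table(pr)
      }
    }
  }
  prof <- rbindlist(rows)
  fwrite(prof, file.path(out_dir, "metagene_profiles.tsv"), sep = "\t")
  invisible(prof)
}

#' Differential-methylation stage
#'
#' Calls DMPs and DMRs for each comparison (treated group versus the
#' control group on the pooled counts), annotates DMRs to features and
#' writes per-comparison tables plus the hyper/hypo summary.
#'
#' @param pooled Named list of pooled site tables; must include the control
#'   group.
#' @param control_group Name of the control group in `pooled`.
#' @param features Combined feature table for annotation.
#' @param out_dir Output directory.
#' @param dm_params List of caller parameters (see [call_dmps()] and
#'   [call_dmrs()]).
#' @return Invisibly, `list(dmps, dmrs)` keyed by comparison.
#' @export
stage_dmr <- function(pooled, control_group, features, out_dir,
                      dm_params = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- utils::modifyList(list(min_coverage = 4L, window_bp = 100L,
                              min_sites = 4L, delta_min = DELTA_MIN_DEFAULT,
                              q_max = 0.05, merge_gap_bp = 100L), dm_params)
  ctl <- pooled[[control_group]]
  dmps <- list(); dmrs <- list(); summaries <- list()
  for (gname in setdiff(names(pooled), control_group)) {
    cmp <- sprintf("%s_vs_%s", gname, control_group)
    dmp <- call_dmps(ctl, pooled[[gname]], min_coverage = p$min_coverage,
                     delta_min = p$delta_min, q_max = p$q_max)
    dmr <- call_dmrs(ctl, pooled[[gname]], window_bp = p$window_bp,
                     min_sites = p$min_sites, min_coverage = p$min_coverage,
                     delta_min = p$delta_min, q_max = p$q_max,
                     merge_gap_bp = p$merge_gap_bp)
    dmr <- annotate_dmrs(dmr, features)
    dmps[[cmp]] <- dmp
    dmrs[[cmp]] <- dmr
    fwrite(dmp, file.path(out_dir, sprintf("dmps_%s.tsv", cmp)), sep = "\t")
    fwrite(dmr, file.path(out_dir, sprintf("dmrs_%s.tsv", cmp)), sep = "\t")
    s <- rbind(dm_summary(dmp)[, `:=`(kind = "DMP", comparison = cmp)],
               dm_summary(dmr)[, `:=`(kind = "DMR", comparison = cmp)])
    summaries[[cmp]] <- s
  }
  fwrite(rbindlist(summaries), file.path(out_dir, "dm_summary.tsv"),
         sep = "\t")
  invisible(list(dmps = dmps, dmrs = dmrs))
}

#' Expression-integration stage
#'
#' Calls DEGs for the day-3 and day-7 comparisons, classifies core versus
#' period-specific sets, computes the five region-by-context correlations
#' on the control group, and identifies DMR-mediated DEGs per comparison.
#'
#' @param counts Expression count table.
#' @param pooled Named list of pooled site tables (for region levels).
#' @param dmrs Named list of annotated DMR tables keyed as produced by
#'   [stage_dmr()].
#' @param features Feature table (genes used).
#' @param control_group,treated_groups Group names; treated groups must be
#'   ordered day 3 then day 7.
#' @param out_dir Output directory.
#' @param log2fc_min,q_max DEG thresholds.
#' @param min_coverage Coverage floor for region methylation levels.
#' @return Invisibly, a list with `degs`, `core_sets`, `correlations`,
#'   `mediated`.
#' @export
stage_integrate <- function(counts, pooled, dmrs, features, control_group,
                            treated_groups, out_dir, log2fc_min = 1,
                            q_max = 0.05, min_coverage = 4L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samp <- setdiff(names(as.data.table(counts)), "gene_id")
  grp <- sample_group(samp)
  genes <- as.data.table(features)[kind == "gene"]

  degs <- list()
  for (tg in treated_groups) {
    cmp <- sprintf("%s_vs_%s", tg, control_group)
    degs[[cmp]] <- call_degs(counts, samp[grp == control_group],
                             samp[grp == tg], log2fc_min = log2fc_min,
                             q_max = q_max, comparison = cmp)
  }
  deg_all <- rbindlist(degs)
  write_deg_table(
    deg_all[, .(gene_id, log2fc, qvalue, direction, comparison)],
    file.path(out_dir, "degs.tsv"))

  core <- classify_core_degs(degs[[1L]], degs[[2L]])
  core_dt <- rbindlist(lapply(names(core), function(nm) {
    if (length(core[[nm]])) data.table(set = nm, gene_id = core[[nm]])
    else data.table(set = character(), gene_id = character())
  }))
  fwrite(core_dt, file.path(out_dir, "core_sets.tsv"), sep = "\t")

  lc <- log2_cpm(counts, samp[grp == control_group])
  expr <- rowMeans(lc)
  combos <- region_context_combos()
  cors <- rbindlist(lapply(seq_len(nrow(combos)), function(ci) {
    rl <- gene_region_levels(pooled[[control_group]], genes,
                             combos$region_class[ci], combos$context[ci],
                             min_coverage = min_coverage)
    ct <- methylation_expression_correlation(rl, expr, combos$context[ci],
                                             combos$region_class[ci])
    data.table(combo_id = combos$combo_id[ci], context = ct$context,
               region_class = ct$region_class, rho = ct$rho, p = ct$p,
               n = ct$n, expected_sign = combos$sign[ci])
  }))
  fwrite(cors, file.path(out_dir, "correlations.tsv"), sep = "\t")

  med_rows <- list(); med_counts <- list()
  for (cmp in names(degs)) {
    if (is.null(dmrs[[cmp]])) next
    med <- identify_mediated_degs(degs[[cmp]], dmrs[[cmp]], features)
    med_rows[[cmp]] <- med$mediated
    mc <- med$nonredundant
    if (nrow(mc)) mc[, comparison := cmp]
    med_counts[[cmp]] <- mc
  }
  mediated <- rbindlist(med_rows)
  fwrite(mediated, file.path(out_dir, "mediated_degs.tsv"), sep = "\t")
  fwrite(rbindlist(med_counts, fill = TRUE),
         file.path(out_dir, "mediated_counts.tsv"), sep = "\t")

  invisible(list(degs = degs, core_sets = core, correlations = cors,
                 mediated = mediated))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Generates the dataset bundle for `config`, then runs quantification,
#' metagene profiling, DMP/DMR calling (day-3 and day-7 comparisons) and
#' expression integration, writing every stage's tables under `out_dir`
#' and finally a manifest with an MD5 checksum per output file. The run is
#' fully deterministic: the same config yields a byte-identical manifest.
#'
#' @param config An [sim_config()] object.
#' @param out_dir Output directory.
#' @param dm_params Optional overrides for the differential-methylation
#'   caller.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, dm_params = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  bundle <- generate_dataset(config, data_dir)

  q <- stage_quantify(bundle$paths$fasta, bundle$paths$vcf, bundle$paths$cx,
                      file.path(out_dir, "quantify"),
                      min_coverage = config$min_coverage)
  pooled <- pool_by_group(q$samples)

  genes <- read_features(bundle$paths$genes, "gene")
  tes <- read_features(bundle$paths$tes, "TE")
  features <- rbind(genes, tes)

  prof <- stage_profile(pooled, list(gene = genes, TE = tes),
                        file.path(out_dir, "profile"),
                        min_coverage = config$min_coverage)

  control_group <- "control-0d"
  dm <- stage_dmr(pooled, control_group, features,
                  file.path(out_dir, "dmr"), dm_params)

  counts <- read_counts(bundle$paths$counts)
  integ <- stage_integrate(counts, pooled, dm$dmrs, features, control_group,
                           treated_groups = c("treated-3d", "treated-7d"),
                           out_dir = file.path(out_dir, "integrate"),
                           min_coverage = config$min_coverage)

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "run_manifest.tsv"]
  manifest <- data.table(
    file = sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
               "", files),
    md5 = unname(tools::md5sum(files)))
  setorder(manifest, file)
  fwrite(manifest, file.path(out_dir, "run_manifest.tsv"), sep = "\t")
  hm_log("pipeline", "run complete: %d files under %s", nrow(manifest), out_dir)
  invisible(list(truth = bundle$truth, quantify = q, profile = prof,
                 dm = dm, integrate = integ, manifest = manifest))
}
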