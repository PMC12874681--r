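# Synthetic WGBS + expression dataset with a machine-readable truth table.
# The generator states the world the rest of the package is validated
# against: a small genome with strand-resolved contexts, heterozygous C/T
# (and reverse-strand G/A) sites whose T-allele reads dilute methylated
# calls, per-context mean levels matching plant-methylome magnitudes,
# planted condition-specific DMRs in gene-relative regions, and
# negative-binomial expression counts coupled to methylation through the
# five region-by-context rules.

# The five active region-by-context combinations and their expected
# methylation-expression correlation signs.
#' Region-by-context pairing rules
#'
#' The five region-by-context combinations used for methylation-expression
#' integration, with the expected correlation sign: negative for
#' downstream-2kb mCG, gene-body mCHG, downstream-2kb mCHG and gene-body
#' mCHH; positive for upstream-2kb mCHH.
#'
#' @return `data.table` with columns `combo_id`, `region_class`
#'   (`up2k`/`body`/`down2k`), `context`, `sign` (`+1`/`-1`).
#' @export
region_context_combos <- function() {
  data.table(
    combo_id = c("down2k_CG", "body_CHG", "down2k_CHG", "up2k_CHH", "body_CHH"),
    region_class = c("down2k", "body", "down2k", "up2k", "body"),
    context = c("CG", "CHG", "CHG", "CHH", "CHH"),
    sign = c(-1L, -1L, -1L, 1L, -1L)
  )
}

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults state the simulated world: per-context mean levels of 0.90 (CG),
#' 0.70 (CHG) and 0.08 (CHH) matching the magnitudes reported for the tea
#' plant methylome, a 1% per-cytosine C/T heterozygosity rate, 20x mean
#' coverage, bisulfite conversion 0.995, three replicates per group, and
#' planted DMRs of |delta| = 0.4 in each of the five region-by-context
#' classes. Directions per class balance the induced up/down expression
#' effects (keeping library composition stable for CPM) while staying
#' detectable: CG shifts down from 0.90 and CHH up from 0.08 (the full 0.4
#' realised); CHG shifts up from 0.70, partially clipped to about +0.3,
#' still well above the CHG calling floor of 0.2.
#'
#' @param seed Master seed; every random stage derives its own stream from it.
#' @param ... Overrides for any default listed below.
#' @return An object of class `hm_config` (a named list).
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = 1500000L,
    n_chroms = 3L,
    gc_fraction = 0.40,
    n_genes = 240L,
    n_tes = 80L,
    gene_length_range = c(1000L, 2000L),
    te_length_range = c(400L, 1200L),
    flank_clearance = 2000L,
    context_means = c(CG = 0.90, CHG = 0.70, CHH = 0.08),
    site_dispersion = 30,
    het_ct_rate = 0.01,
    coverage_mean = 20,
    conversion_rate = 0.995,
    n_replicates = 3L,
    planted_dmrs = data.table(
      region_class = c("down2k", "body", "down2k", "up2k", "body"),
      context = c("CG", "CHG", "CHG", "CHH", "CHH"),
      delta = c(-0.4, 0.4, 0.4, 0.4, 0.4)
    ),
    genes_per_dmr_class = 8L,
    planted_mediated_fraction = 0.8,
    region_effect_scale = c(CG = 0.08, CHG = 0.15, CHH = 0.05),
    n_background_genes = 1760L,
    expression_coupling_log2 = 1.0,
    baseline_log2_mean = 9,
    baseline_log2_sd = 1.0,
    expression_floor_log2 = 6,
    nb_dispersion = 0.01,
    deg_log2fc = 3,
    n_unmediated_degs = 300L,
    shared_direction_prob = 0.3,
    min_coverage = 4L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_hm("unknown config key(s): %s",
                               paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "hm_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$gc_fraction, cfg$het_ct_rate, cfg$conversion_rate,
             cfg$planted_mediated_fraction, cfg$shared_direction_prob,
             cfg$context_means)
  if (any(probs < 0 | probs > 1)) stop_hm("config probabilities must lie in [0, 1]")
  if (cfg$coverage_mean <= 0) stop_hm("coverage_mean must be > 0")
  if (cfg$site_dispersion <= 0) stop_hm("site_dispersion must be > 0")
  pd <- cfg$planted_dmrs
  if (nrow(pd)) {
    m <- cfg$context_means[pd$context]
    if (any(pmin(pmax(m + pd$delta, 0), 1) == m & pd$delta != 0)) {
      stop_hm("a planted delta is entirely clipped away at its context mean")
    }
  }
  invisible(TRUE)
}

#' @export
print.hm_config <- function(x, ...) {
  cat("hetmethyl simulation config\n")
  cat(sprintf("  seed %d | genome %d bp x %d chrom | %d genes, %d TEs\n",
              x$seed, x$genome_length, x$n_chroms, x$n_genes, x$n_tes))
  cat(sprintf("  context means CG=%.2f CHG=%.2f CHH=%.2f | het C/T rate %.3g\n",
              x$context_means[["CG"]], x$context_means[["CHG"]],
              x$context_means[["CHH"]], x$het_ct_rate))
  cat(sprintf("  coverage %g | conversion %.3f | %d replicates/group\n",
              x$coverage_mean, x$conversion_rate, x$n_replicates))
  cat(sprintf("  planted DMR classes: %d | mediated fraction %.2f\n",
              nrow(x$planted_dmrs), x$planted_mediated_fraction))
  invisible(x)
}

#' Simulate a genome with non-overlapping gene and TE features
#'
#' Bases are i.i.d. at the stated GC fraction. Genes and TEs are placed
#' without overlap, keeping at least `flank_clearance` bp from chromosome
#' ends and from each other so that every 2 kb flank is unambiguous; strands
#' are assigned at random. Deterministic for a fixed seed.
#'
#' @param config An [sim_config()] object.
#' @return `list(genome = DNAStringSet, features = data.table)`.
#' @export
simulate_genome <- function(config) {
  set.seed(derive_seed(config$seed, "genome"))
  n_chr <- config$n_chroms
  chr_len <- rep(config$genome_length %/% n_chr, n_chr)
  chr_len[n_chr] <- chr_len[n_chr] + config$genome_length %% n_chr
  chr_names <- sprintf("chr%d", seq_len(n_chr))
  p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
         G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  seqs <- vapply(chr_len, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1L))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chr_names

  set.seed(derive_seed(config$seed, "placement"))
  n_feat <- config$n_genes + config$n_tes
  lens <- c(
    if (config$n_genes) sample(config$gene_length_range[1L]:config$gene_length_range[2L],
                               config$n_genes, replace = TRUE),
    if (config$n_tes) sample(config$te_length_range[1L]:config$te_length_range[2L],
                             config$n_tes, replace = TRUE)
  )
  feat <- data.table(
    feature_id = c(sprintf("g%04d", seq_len(config$n_genes)),
                   sprintf("te%04d", seq_len(config$n_tes))),
    kind = rep(c("gene", "TE"), c(config$n_genes, config$n_tes)),
    len = lens
  )
  # shuffle, deal across chromosomes, then lay out left-to-right with the
  # leftover slack spread randomly over the gaps
  feat <- feat[sample(.N)]
  feat[, chrom := chr_names[1L + (seq_len(.N) - 1L) %% n_chr]]
  clr <- config$flank_clearance
  placed <- feat[, {
    L <- chr_len[match(.BY$chrom, chr_names)]
    need <- sum(len) + clr * (.N + 1L)
    if (need > L) {
      stop_hm("chromosome %s (%d bp) cannot hold %d features with %d bp clearance",
              .BY$chrom, L, .N, clr)
    }
    extra <- as.vector(stats::rmultinom(1L, L - need, rep(1, .N + 1L)))
    starts <- clr + cumsum(c(0L, len[-.N] + clr)) + cumsum(extra[-(.N + 1L)])
    list(feature_id = feature_id, kind = kind, start = starts,
         end = starts + len)
  }, by = chrom]
  placed[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  features <- placed[, .(feature_id, chrom, start, end, strand, kind)]
  setorder(features, chrom, start)
  hm_log("simulate", "genome: %d chrom, %d bp; placed %d features",
         n_chr, sum(chr_len), nrow(features))
  list(genome = genome, features = features)
}

#' Simulate heterozygous C/T variant sites
#'
#' Every forward-strand C becomes a het C>T variant with probability
#' `het_ct_rate`; every forward-strand G becomes a het G>A variant with the
#' same probability (the reverse-strand C/T case). All genotypes are het.
#'
#' @param genome Genome from [simulate_genome()].
#' @param config An [sim_config()] object.
#' @return Variant `data.table` (`chrom`, `pos` 0-based, `ref`, `alt`,
#'   `genotype`).
#' @export
simulate_variants <- function(genome, config) {
  set.seed(derive_seed(config$seed, "variants"))
  out <- rbindlist(lapply(names(genome), function(cn) {
    b <- strsplit(as.character(genome[[cn]]), "", fixed = TRUE)[[1L]]
    cand <- which(b %in% c("C", "G"))
    if (config$het_ct_rate <= 0 || length(cand) == 0L) {
      return(data.table(chrom = character(), pos = integer(),
                        ref = character(), alt = character()))
    }
    hit <- cand[stats::runif(length(cand)) < config$het_ct_rate]
    data.table(chrom = cn, pos = hit - 1L, ref = b[hit],
               alt = ifelse(b[hit] == "C", "T", "A"))
  }))
  out[, genotype := rep("het", .N)]
  hm_log("simulate", "planted %d het variant(s)", nrow(out))
  out[]
}

# region interval of one class for every feature, in transcriptional
# orientation; 0-based half-open, possibly clipped at chromosome bounds
feature_regions <- function(features, region_class, flank_bp = 2000L) {
  f <- as.data.table(features)
  switch(region_class,
    body = f[, .(feature_id, chrom, start, end, strand)],
    up2k = f[, .(feature_id, chrom,
                 start = fifelse(strand == "+", start - flank_bp, end),
                 end = fifelse(strand == "+", start, end + flank_bp),
                 strand)],
    down2k = f[, .(feature_id, chrom,
                   start = fifelse(strand == "+", end, start - flank_bp),
                   end = fifelse(strand == "+", end + flank_bp, start),
                   strand)],
    stop_hm("unknown region_class '%s' (expected body, up2k or down2k)",
            region_class)
  )
}

#' Simulate true per-site methylation for control and treated conditions
#'
#' Each cytosine's true level is drawn from a Beta distribution with mean
#' `context_means[context]` and concentration `site_dispersion`. On top of
#' the context mean, every gene carries a small per-(region, context) random
#' effect shared by both conditions; expression baselines are later coupled
#' to the same effects, which is what gives the five region-by-context
#' correlations their signs. The treated condition copies the control and
#' then applies the planted DMRs: for each planted (region class, context,
#' delta), all sites of that context in that region of the selected genes
#' are shifted by `delta` and clipped to `[0, 1]`. At variant sites the
#' drawn level is the C allele's level (the T allele carries no cytosine).
#'
#' @param genome,config See [simulate_genome()].
#' @param features Feature table from [simulate_genome()].
#' @param variants Variant table from [simulate_variants()].
#' @return `list(sites, gene_effects, planted)`: `sites` is the assigned
#'   site table plus `true_level_control`, `true_level_treated` and
#'   `is_variant`; `planted` records each planted DMR's gene, region
#'   interval, context, delta and direction.
#' @export
simulate_methylome <- function(genome, features, variants, config) {
  sites <- assign_contexts(genome)
  set.seed(derive_seed(config$seed, "methylome"))
  combos <- region_context_combos()
  genes <- as.data.table(features)[kind == "gene"]

  # per-gene latent region effects, one per combo, shared by both conditions
  gene_effects <- data.table(
    gene_id = rep(genes$feature_id, each = nrow(combos)),
    combo_id = rep(combos$combo_id, nrow(genes)),
    z = stats::runif(nrow(genes) * nrow(combos), -1, 1)
  )

  mu <- config$context_means[sites$context]
  # add the latent effects inside each combo's region
  setkey(sites, chrom, pos)
  for (ci in seq_len(nrow(combos))) {
    reg <- feature_regions(genes, combos$region_class[ci])
    reg <- reg[, .(chrom, start, end, feature_id)]
    setkey(reg, chrom, start, end)
    sdt <- data.table(chrom = sites$chrom, start = sites$pos,
                      end = sites$pos + 1L, idx = seq_len(nrow(sites)))
    ov <- foverlaps(sdt, reg, type = "within", nomatch = NULL)
    ov <- ov[sites$context[ov$idx] == combos$context[ci]]
    if (nrow(ov)) {
      z <- gene_effects[combo_id == combos$combo_id[ci]][ov, on = c(gene_id = "feature_id"), z]
      mu[ov$idx] <- mu[ov$idx] +
        config$region_effect_scale[[combos$context[ci]]] * z
    }
  }
  mu <- pmin(pmax(mu, 0.005), 0.995)
  conc <- config$site_dispersion
  ctl <- stats::rbeta(nrow(sites), mu * conc, (1 - mu) * conc)

  # treated copies control, then planted DMRs shift whole gene regions
  trt <- ctl
  pd <- as.data.table(config$planted_dmrs)
  planted <- NULL
  if (nrow(pd)) {
    eligible <- genes$feature_id
    n_need <- nrow(pd) * config$genes_per_dmr_class
    if (n_need > length(eligible)) {
      stop_hm("planted DMR classes need %d genes but only %d exist",
              n_need, length(eligible))
    }
    pick <- sample(eligible, n_need)
    pd_gene <- pd[rep(seq_len(.N), each = config$genes_per_dmr_class)]
    pd_gene[, gene_id := pick]
    planted_rows <- vector("list", nrow(pd_gene))
    for (i in seq_len(nrow(pd_gene))) {
      g <- genes[feature_id == pd_gene$gene_id[i]]
      reg <- feature_regions(g, pd_gene$region_class[i])
      idx <- sites[, which(chrom == reg$chrom & pos >= reg$start &
                             pos < reg$end & context == pd_gene$context[i])]
      if (length(idx) == 0L) {
        hm_log("simulate", "gene %s has no %s site in %s; DMR skipped",
               pd_gene$gene_id[i], pd_gene$context[i], pd_gene$region_class[i])
        next
      }
      trt[idx] <- pmin(pmax(ctl[idx] + pd_gene$delta[i], 0), 1)
      planted_rows[[i]] <- data.table(
        gene_id = pd_gene$gene_id[i], chrom = reg$chrom,
        start = reg$start, end = reg$end,
        region_class = pd_gene$region_class[i],
        context = pd_gene$context[i], delta = pd_gene$delta[i],
        direction = if (pd_gene$delta[i] > 0) "hyper" else "hypo",
        n_sites = length(idx)
      )
    }
    planted <- rbindlist(planted_rows)
  }

  sites[, `:=`(true_level_control = ctl, true_level_treated = trt)]
  v <- as.data.table(variants)
  sites[, is_variant := FALSE]
  if (nrow(v)) {
    sites[v[ref == "C"], on = c("chrom", "pos"), is_variant := is_variant | (strand == "+")]
    sites[v[ref == "G"], on = c("chrom", "pos"), is_variant := is_variant | (strand == "-")]
  }
  hm_log("simulate", "methylome: %d sites, %d variant-confounded, %d planted DMRs",
         nrow(sites), sum(sites$is_variant),
         if (is.null(planted)) 0L else nrow(planted))
  list(sites = sites[], gene_effects = gene_effects,
       planted = planted %||% data.table())
}

#' Simulate per-sample bisulfite pileups (CX reports)
#'
#' For every site and replicate, coverage is Poisson(`coverage_mean`). At a
#' non-variant site each read looks methylated with probability
#' `p + (1 - p) (1 - conversion_rate)` (a methylated molecule always reports
#' C; an unmethylated one reports T only if conversion succeeded). At a het
#' variant site each read first picks an allele (fair coin): T/A-allele
#' reads always look unmethylated — the bias the masking step removes —
#' while C-allele reads follow the site's level. Samples follow the study
#' layout: `control-0d`, `treated-3d`, `treated-7d`, each with
#' `n_replicates`; the treated methylome underlies both treated groups.
#'
#' @param methylome Result of [simulate_methylome()].
#' @param config An [sim_config()] object.
#' @return Named list of CX `data.table`s, one per sample, each with the
#'   columns of [read_cx_report()] and one row per assigned cytosine
#'   (zero-coverage rows included).
#' @export
simulate_pileup <- function(methylome, config) {
  sites <- methylome$sites
  groups <- data.table(
    group = c("control-0d", "treated-3d", "treated-7d"),
    condition = c("control", "treated", "treated")
  )
  cr <- config$conversion_rate
  out <- list()
  for (gi in seq_len(nrow(groups))) {
    p <- if (groups$condition[gi] == "control") sites$true_level_control else sites$true_level_treated
    q <- p + (1 - p) * (1 - cr)
    q <- fifelse(sites$is_variant, 0.5 * q, q)
    for (r in seq_len(config$n_replicates)) {
      sid <- sprintf("%s_r%d", groups$group[gi], r)
      set.seed(derive_seed(config$seed, paste0("pileup_", sid)))
      cov <- stats::rpois(nrow(sites), config$coverage_mean)
      meth <- stats::rbinom(nrow(sites), cov, q)
      out[[sid]] <- data.table(
        chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
        count_meth = meth, count_unmeth = cov - meth,
        context = sites$context, trinucleotide = sites$trinucleotide
      )
    }
  }
  hm_log("simulate", "pileup: %d samples x %d sites", length(out), nrow(sites))
  out
}

#' Simulate expression counts coupled to the planted methylation structure
#'
#' Baseline per-gene log2 means are normal; on top, each gene's baseline is
#' shifted by `expression_coupling_log2 * sign(combo) * z(gene, combo)`
#' using the same latent region effects as the methylome, which plants the
#' five correlation signs. Planted-DMR genes are marked mediated with
#' probability `planted_mediated_fraction`; a mediated gene's treated mean
#' at both day 3 and day 7 is scaled by `2^(s * deg_log2fc)` where `s`
#' follows the pairing rule (negative-sign combos: hyper DMR pushes
#' expression down, hypo up; the positive-sign combo reversed). A disjoint
#' pool of unmediated DEGs receives day-specific effects (same direction on
#' both days with probability `shared_direction_prob`, otherwise one random
#' day), exercising core versus period-specific classification. Counts are
#' negative binomial with dispersion `nb_dispersion`. All DEG effects
#' (mediated and unmediated) are planted only on genes whose *smaller*
#' group mean stays at or above `2^expression_floor_log2` (for a
#' down-shifted gene that is the treated mean): planting fold-changes on
#' near-zero-count genes would make the truth table measure small-sample
#' test power rather than pipeline correctness, mirroring the universal
#' RNA-seq practice of filtering low-count genes. Alongside the on-genome
#' genes, `n_background_genes` unperturbed background genes fill out the
#' transcriptome so CPM library composition stays stable.
#'
#' @param features Feature table (genes are used).
#' @param methylome Result of [simulate_methylome()].
#' @param config An [sim_config()] object.
#' @return `list(counts, truth_expr)`: `counts` is a `data.table` (gene_id
#'   plus one column per sample); `truth_expr` records mediated genes,
#'   unmediated DEG effects per day and null genes.
#' @export
simulate_expression <- function(features, methylome, config) {
  set.seed(derive_seed(config$seed, "expression"))
  genes <- as.data.table(features)[kind == "gene"]
  combos <- region_context_combos()
  ge <- merge(methylome$gene_effects, combos, by = "combo_id")
  coupling <- ge[, .(shift = sum(sign * z) * config$expression_coupling_log2),
                 by = gene_id]
  # the assayed transcriptome is much larger than the genes on the
  # simulated contigs: background genes (never perturbed, no methylation
  # coupling) keep CPM library composition stable, as in a genome-scale
  # experiment where DEGs are a small fraction of all genes
  n_bg <- config$n_background_genes
  all_ids <- c(genes$feature_id,
               if (n_bg > 0L) sprintf("bg%04d", seq_len(n_bg)))
  base <- data.table(gene_id = all_ids,
                     b = stats::rnorm(length(all_ids),
                                      config$baseline_log2_mean,
                                      config$baseline_log2_sd))
  base <- merge(base, coupling, by = "gene_id", all.x = TRUE, sort = FALSE)
  base[is.na(shift), shift := 0]
  base[, log2_mu := b + shift]

  planted <- methylome$planted
  # DEG effects are planted only on genes whose *smaller* group mean stays
  # above the floor (for a down-shifted gene that is the treated mean):
  # detecting a fold-change on a near-zero count gene measures small-sample
  # test power, not pipeline correctness, so the truth table should not
  # contain such genes — the analogue of the low-count filter in RNA-seq
  # practice
  mu_of <- stats::setNames(base$log2_mu, base$gene_id)
  floor_for <- function(direction) {
    config$expression_floor_log2 +
      fifelse(direction == "down", config$deg_log2fc, 0)
  }
  mediated <- data.table()
  if (nrow(planted)) {
    pl <- merge(planted[, .(gene_id, region_class, context,
                            dmr_direction = direction)],
                region_context_combos(), by = c("region_class", "context"))
    pl[, deg_direction := fifelse(
      (sign < 0) == (dmr_direction == "hyper"), "down", "up")]
    n_med <- round(config$planted_mediated_fraction * nrow(pl))
    if (n_med > nrow(pl)) stop_hm("mediated fraction exceeds planted genes")
    eligible_idx <- which(mu_of[pl$gene_id] >= floor_for(pl$deg_direction))
    if (length(eligible_idx) < n_med) {
      hm_log("simulate", "only %d of %d planted genes pass the expression floor; capping mediated set",
             length(eligible_idx), nrow(pl))
      n_med <- length(eligible_idx)
    }
    mediated <- pl[sort(sample(eligible_idx, n_med))]
  }

  # unmediated DEGs come from the whole transcriptome (on-genome genes and
  # background alike); under severe stress a sizeable fraction of all genes
  # responds, which is also what keeps the BH threshold at a level the
  # 3-replicate Welch test can meet
  pool <- setdiff(base$gene_id, planted$gene_id)
  um_dir_pool <- sample(c("up", "down"), length(pool), replace = TRUE)
  um_ok <- mu_of[pool] >= floor_for(um_dir_pool)
  n_um <- min(config$n_unmediated_degs, sum(um_ok))
  keep <- sort(sample(which(um_ok), n_um))
  um_ids <- pool[keep]
  um_dir <- um_dir_pool[keep]
  um_both <- stats::runif(n_um) < config$shared_direction_prob
  um_day <- ifelse(um_both, "both", sample(c("3d", "7d"), n_um, replace = TRUE))
  unmediated <- data.table(gene_id = um_ids, direction = um_dir, days = um_day)

  eff <- function(day) {
    e <- stats::setNames(rep(0, nrow(base)), base$gene_id)
    if (nrow(mediated)) {
      s <- ifelse(mediated$deg_direction == "up", 1, -1)
      e[mediated$gene_id] <- s * config$deg_log2fc
    }
    hit <- unmediated[days %in% c("both", day)]
    if (nrow(hit)) {
      e[hit$gene_id] <- ifelse(hit$direction == "up", 1, -1) * config$deg_log2fc
    }
    e
  }
  layout <- data.table(
    group = c("control-0d", "treated-3d", "treated-7d"),
    day = c("0d", "3d", "7d")
  )
  counts <- data.table(gene_id = base$gene_id)
  for (gi in seq_len(nrow(layout))) {
    e <- if (layout$day[gi] == "0d") 0 else eff(layout$day[gi])
    mu <- 2^(base$log2_mu + e)
    for (r in seq_len(config$n_replicates)) {
      sid <- sprintf("%s_r%d", layout$group[gi], r)
      counts[[sid]] <- stats::rnbinom(nrow(base), mu = mu,
                                      size = 1 / config$nb_dispersion)
    }
  }
  null_genes <- setdiff(base$gene_id, c(mediated$gene_id, unmediated$gene_id))
  hm_log("simulate", "expression: %d genes, %d mediated, %d unmediated DEGs",
         nrow(base), nrow(mediated), nrow(unmediated))
  list(counts = counts,
       truth_expr = list(mediated = mediated, unmediated = unmediated,
                         null_genes = null_genes))
}

#' Generate a complete dataset bundle on disk
#'
#' Runs the whole generator and writes FASTA, VCF, BED features, per-sample
#' CX reports, the expression count table, a JSON truth table and a manifest
#' with an MD5 checksum per file. Identical configs produce byte-identical
#' bundles.
#'
#' @param config An [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `list(paths, truth)`.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  variants <- simulate_variants(gen$genome, config)
  methylome <- simulate_methylome(gen$genome, gen$features, variants, config)
  pile <- simulate_pileup(methylome, config)
  expr <- simulate_expression(gen$features, methylome, config)

  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    vcf = file.path(out_dir, "variants.vcf"),
    genes = file.path(out_dir, "genes.bed"),
    tes = file.path(out_dir, "tes.bed"),
    counts = file.path(out_dir, "counts.tsv"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  write_fasta(gen$genome, paths$fasta)
  write_vcf_variants(variants, paths$vcf)
  write_features(gen$features[kind == "gene"], paths$genes)
  write_features(gen$features[kind == "TE"], paths$tes)
  cx_dir <- file.path(out_dir, "cx")
  dir.create(cx_dir, showWarnings = FALSE)
  cx_paths <- vapply(names(pile), function(sid) {
    p <- file.path(cx_dir, sprintf("%s.cx.tsv", sid))
    write_cx_report(pile[[sid]], p)
    p
  }, character(1L))
  write_counts(expr$counts, paths$counts)

  # true genome-weighted levels: mean true level over non-variant sites
  s <- methylome$sites
  lvl <- s[is_variant == FALSE,
           .(control = mean(true_level_control),
             treated = mean(true_level_treated)), by = context]
  truth <- list(
    config_seed = config$seed,
    true_levels = lvl,
    n_variants = nrow(variants),
    variant_positions = variants[, .(chrom, pos, ref, alt)],
    planted_dmrs = methylome$planted,
    mediated = expr$truth_expr$mediated,
    unmediated_degs = expr$truth_expr$unmediated,
    null_genes = expr$truth_expr$null_genes
  )
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  files <- c(unlist(paths[c("fasta", "vcf", "genes", "tes", "counts", "truth")]),
             cx_paths)
  manifest <- data.table(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  setorder(manifest, file)
  fwrite(manifest, paths$manifest, sep = "\t")
  hm_log("simulate", "dataset bundle written to %s (%d files)",
         out_dir, nrow(manifest))
  invisible(list(paths = c(paths, list(cx = cx_paths)), truth = truth))
}
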