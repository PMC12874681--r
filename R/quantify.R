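# SNP-aware methylation quantification: context assignment from the
# reference, masking of polymorphism-confounded cytosines, per-site and
# genome-weighted levels.

#' Assign cytosine contexts from a reference genome
#'
#' Emits every forward-strand C and every reverse-strand C (a G on the
#' forward reference) with its sequence context read from the two bases
#' immediately 3' on the cytosine's own strand: next base G gives CG, else
#' next-next base G gives CHG, else CHH. Cytosines whose 3-base window runs
#' off the chromosome end or contains an N are excluded (a count is logged):
#' their context is undefined.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @return Keyed `data.table` of sites: `chrom`, `pos` (0-based, position of
#'   the cytosine on the forward reference), `strand`, `context`,
#'   `trinucleotide` (on the cytosine's strand), zeroed `count_meth` /
#'   `count_unmeth`, and `masked = FALSE`.
#' @export
assign_contexts <- function(genome) {
  seqs <- if (methods::is(genome, "DNAStringSet")) as.character(genome) else genome
  if (is.null(names(seqs))) stop_hm("genome must have chromosome names")
  n_excluded <- 0L
  per_chrom <- lapply(names(seqs), function(cn) {
    b <- strsplit(seqs[[cn]], "", fixed = TRUE)[[1L]]
    L <- length(b)
    # forward-strand cytosines: window [p, p+2] on the forward strand
    pf <- which(b == "C")
    pf <- pf[pf + 2L <= L]
    if (length(pf)) {
      tri_f <- paste0(b[pf], b[pf + 1L], b[pf + 2L])
      okf <- !grepl("N", tri_f, fixed = TRUE)
      n_excluded <<- n_excluded + sum(b == "C") - sum(okf)
      pf <- pf[okf]; tri_f <- tri_f[okf]
    } else {
      n_excluded <<- n_excluded + sum(b == "C")
      tri_f <- character()
    }
    # reverse-strand cytosines sit at forward-strand Gs; their downstream
    # window is [p-2, p] on the forward strand, complemented and reversed
    pr <- which(b == "G")
    pr <- pr[pr - 2L >= 1L]
    if (length(pr)) {
      tri_r <- paste0(COMPLEMENT[b[pr]], COMPLEMENT[b[pr - 1L]],
                      COMPLEMENT[b[pr - 2L]])
      okr <- !grepl("N", tri_r, fixed = TRUE)
      n_excluded <<- n_excluded + sum(b == "G") - sum(okr)
      pr <- pr[okr]; tri_r <- tri_r[okr]
    } else {
      n_excluded <<- n_excluded + sum(b == "G")
      tri_r <- character()
    }
    data.table(
      chrom = cn,
      pos = c(pf, pr) - 1L,
      strand = rep(c("+", "-"), c(length(pf), length(pr))),
      trinucleotide = c(tri_f, tri_r)
    )
  })
  sites <- rbindlist(per_chrom)
  sites[, context := context_from_tri(trinucleotide)]
  sites[, `:=`(count_meth = 0L, count_unmeth = 0L, masked = FALSE)]
  setkey(sites, chrom, pos, strand)
  hm_log("quantify", "assigned contexts: %d sites (%s), %d cytosines excluded",
         nrow(sites),
         paste(sprintf("%s=%d", CONTEXTS, sites[, table(factor(context, CONTEXTS))]),
               collapse = ", "),
         n_excluded)
  sites[]
}

#' Mask cytosines confounded by C/T heterozygosity
#'
#' In a bisulfite library a read from a T allele is indistinguishable from a
#' converted (unmethylated) C, so naive quantification at C/T polymorphic
#' sites is biased. A site is masked iff a variant sits exactly on the
#' cytosine position and the ref/alt pair is C/T for a forward-strand
#' cytosine or G/A for a reverse-strand one (the same polymorphism seen from
#' the other strand), with genotype `het` or `hom_alt`. Homozygous-alt sites
#' are masked too: the individual carries no cytosine there at all. Masked
#' sites are excluded from every level computation downstream.
#'
#' @param sites Site table from [assign_contexts()].
#' @param variants Variant table from [read_vcf_variants()].
#' @param genome Optional genome used to validate variant coordinates.
#' @return The site table with the `masked` flag set (a copy).
#' @export
mask_variant_cytosines <- function(sites, variants, genome = NULL) {
  sites <- copy(as.data.table(sites))
  v <- as.data.table(variants)
  if (nrow(v)) {
    if (!all(v$chrom %in% unique(sites$chrom))) {
      stop_hm("variant on chromosome absent from the site table: %s",
              paste(setdiff(unique(v$chrom), unique(sites$chrom)), collapse = ", "))
    }
    if (!is.null(genome)) {
      lens <- stats::setNames(Biostrings::width(genome), names(genome))
      if (any(v$pos < 0L | v$pos >= lens[v$chrom])) {
        stop_hm("variant position outside the genome")
      }
    }
    vmask <- v[genotype %in% c("het", "hom_alt")]
    plus <- vmask[ref == "C" & alt == "T"]
    minus <- vmask[ref == "G" & alt == "A"]
    sites[plus, on = c("chrom", "pos"), masked := masked | (strand == "+")]
    sites[minus, on = c("chrom", "pos"), masked := masked | (strand == "-")]
  }
  hm_log("quantify", "masked %d of %d sites against %d variant(s)",
         sum(sites$masked), nrow(sites), nrow(v))
  sites[]
}

#' Attach observed counts from a CX report to assigned sites
#'
#' @param sites Site table from [assign_contexts()] (optionally masked).
#' @param cx CX table from [read_cx_report()] for one sample.
#' @return Site table with `count_meth`/`count_unmeth` filled (a copy).
#' @export
attach_counts <- function(sites, cx) {
  sites <- copy(as.data.table(sites))
  cx <- as.data.table(cx)
  sites[, `:=`(count_meth = 0L, count_unmeth = 0L)]
  sites[cx, on = c("chrom", "pos", "strand"),
        `:=`(count_meth = i.count_meth, count_unmeth = i.count_unmeth)]
  n_hit <- nrow(sites[cx, on = c("chrom", "pos", "strand"), nomatch = NULL])
  if (n_hit < nrow(cx)) {
    warning(sprintf("%d CX record(s) had no matching assigned site",
                    nrow(cx) - n_hit), call. = FALSE)
  }
  sites[]
}

#' Per-site methylation levels
#'
#' `level = count_meth / (count_meth + count_unmeth)` for unmasked sites with
#' coverage at least `min_coverage`; all other sites get `NA`.
#'
#' @param sites Site table with counts attached.
#' @param min_coverage Minimum reads per site (default 4, the conventional
#'   WGBS floor).
#' @return The table plus `total` and `level` columns (a copy).
#' @export
site_levels <- function(sites, min_coverage = 4L) {
  out <- copy(as.data.table(sites))
  out[, total := count_meth + count_unmeth]
  out[, level := fifelse(!masked & total >= min_coverage,
                         count_meth / pmax(total, 1L), NA_real_)]
  out[]
}

#' Genome-weighted methylation level for one context
#'
#' The weighted level is total methylated reads over total reads across all
#' eligible (unmasked, covered) sites of the context — read-count weighted,
#' not a mean of per-site fractions.
#'
#' @inheritParams site_levels
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return A single level in `[0, 1]`.
#' @export
weighted_level <- function(sites, context, min_coverage = 4L) {
  stopifnot(context %in% CONTEXTS)
  dt <- as.data.table(sites)
  ctx <- context
  sel <- dt[context == ctx & !masked &
              (count_meth + count_unmeth) >= min_coverage]
  if (nrow(sel) == 0L) {
    stop_hm("no eligible %s site (all masked or below coverage %d)",
            ctx, min_coverage)
  }
  sum(sel$count_meth) / sum(sel$count_meth + sel$count_unmeth)
}

#' Per-context weighted-level report for one sample
#'
#' One row per context with the weighted level and a full accounting of
#' sites: `n_sites_used + n_sites_masked + n_sites_low_coverage` always
#' equals the number of assigned sites of that context.
#'
#' @inheritParams site_levels
#' @param sample_id Identifier recorded in the report.
#' @return `data.table` with columns `sample_id`, `context`, `level`,
#'   `n_sites_used`, `n_sites_masked`, `n_sites_low_coverage`,
#'   `total_meth_reads`, `total_reads`.
#' @export
weighted_level_report <- function(sites, min_coverage = 4L,
                                  sample_id = "sample") {
  dt <- as.data.table(sites)
  dt[, total := count_meth + count_unmeth]
  rep <- dt[, {
    used <- !masked & total >= min_coverage
    list(level = if (any(used)) sum(count_meth[used]) / sum(total[used]) else NA_real_,
         n_sites_used = sum(used),
         n_sites_masked = sum(masked),
         n_sites_low_coverage = sum(!masked & total < min_coverage),
         total_meth_reads = sum(count_meth[used]),
         total_reads = sum(total[used]))
  }, by = context]
  rep[, sample_id := sample_id]
  setorder(rep, context)
  setcolorder(rep, c("sample_id", "context"))
  rep[]
}
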