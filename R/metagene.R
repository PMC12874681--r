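# Binned methylation profiles over feature bodies and 2 kb flanks, plus the
# single-region mean levels used by the expression-integration step.

# map eligible sites of one context onto (feature, zone, bin); returns one
# row per site-feature assignment with pooled-countable meth/total
.zone_bins <- function(sites, features, context, flank_bp, n_flank_bins,
                       n_body_bins, min_coverage) {
  ctx <- context
  s <- as.data.table(sites)
  s <- s[context == ctx & !masked & (count_meth + count_unmeth) >= min_coverage]
  if (nrow(s) == 0L) return(data.table())
  s <- s[, .(chrom, pos, count_meth, total = count_meth + count_unmeth)]
  f <- as.data.table(features)
  binw <- flank_bp / n_flank_bins
  zones <- rbindlist(lapply(c("up", "body", "down"), function(z) {
    reg <- feature_regions(f, c(up = "up2k", body = "body", down = "down2k")[[z]],
                           flank_bp)
    reg[, zone := z]
    reg[, `:=`(fstart = f$start, fend = f$end)]
    reg
  }))
  n_clip <- zones[start < 0, .N]
  if (n_clip) {
    hm_log("profile", "%d flank interval(s) extend past a chromosome start; out-of-range bins get no contribution", n_clip)
  }
  zones[, `:=`(start = pmax(start, 0L))]
  setkey(zones, chrom, start, end)
  sdt <- s[, .(chrom, start = pos, end = pos + 1L, count_meth, total)]
  setkey(sdt, chrom, start, end)
  ov <- foverlaps(sdt, zones, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) return(data.table())
  # transcriptional-axis offset within the zone, then the right-open bin
  ov[, pos := i.start]
  ov[, offset := fifelse(
    zone == "body",
    fifelse(strand == "+", pos - fstart, fend - 1L - pos),
    fifelse(zone == "up",
            fifelse(strand == "+", pos - (fstart - flank_bp),
                    (fend + flank_bp - 1L) - pos),
            fifelse(strand == "+", pos - fend, (fstart - 1L) - pos)))]
  ov[zone == "body", bin := pmin(floor(offset / (fend - fstart) * n_body_bins),
                                 n_body_bins - 1L) + 1L]
  ov[zone != "body", bin := floor(offset / binw) + 1L]
  ov[, .(feature_id, zone, bin, count_meth, total)]
}

#' Metagene methylation profile over features and flanks
#'
#' Pools read counts over all features into `n_flank_bins` fixed-width bins
#' upstream, `n_body_bins` length-scaled bins across the body, and
#' `n_flank_bins` bins downstream, all in transcriptional orientation
#' (mirrored for minus-strand features). Bin values are weighted levels
#' (summed methylated reads over summed reads), not means of per-feature
#' means; bins that receive no eligible read are reported missing. Bin 1 of
#' the upstream zone is the most distal (at -`flank_bp`); downstream bin 1
#' starts at the transcript end.
#'
#' @param sites Quantified, masked site table with counts attached.
#' @param features Feature table (genes or TEs).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank_bp Flank width in bp (default 2000).
#' @param n_flank_bins,n_body_bins Bin counts (defaults 10 and 20).
#' @param min_coverage Per-site coverage floor (default 4).
#' @param sample_id Label recorded in the output.
#' @return An `hm_profile` `data.table`: `kind`, `context`, `sample_id`,
#'   `zone` (`up`/`body`/`down`), `bin_index`, `level`, `n_reads`,
#'   `n_sites`; every bin is present.
#' @export
compute_profile <- function(sites, features, context, flank_bp = 2000L,
                            n_flank_bins = 10L, n_body_bins = 20L,
                            min_coverage = 4L, sample_id = "sample") {
  f <- as.data.table(features)
  kind_lab <- if (nrow(f)) unique(f$kind)[1L] else NA_character_
  ov <- .zone_bins(sites, f, context, flank_bp, n_flank_bins, n_body_bins,
                   min_coverage)
  grid <- rbindlist(list(
    data.table(zone = "up", bin = seq_len(n_flank_bins)),
    data.table(zone = "body", bin = seq_len(n_body_bins)),
    data.table(zone = "down", bin = seq_len(n_flank_bins))
  ))
  if (nrow(ov)) {
    agg <- ov[, .(meth = sum(count_meth), n_reads = sum(total), n_sites = .N),
              by = .(zone, bin)]
    out <- merge(grid, agg, by = c("zone", "bin"), all.x = TRUE)
  } else {
    out <- copy(grid)[, `:=`(meth = NA_integer_, n_reads = NA_integer_,
                             n_sites = NA_integer_)]
  }
  out[is.na(n_reads), `:=`(meth = 0L, n_reads = 0L, n_sites = 0L)]
  out[, level := fifelse(n_reads > 0, meth / n_reads, NA_real_)]
  out[, `:=`(kind = kind_lab, context = context, sample_id = sample_id)]
  out[, zone := factor(zone, levels = c("up", "body", "down"))]
  setorder(out, zone, bin)
  res <- out[, .(kind, context, sample_id, zone = as.character(zone),
                 bin_index = bin, level, n_reads, n_sites)]
  setattr(res, "class", c("hm_profile", class(res)))
  setattr(res, "flank_bp", flank_bp)
  setattr(res, "n_flank_bins", n_flank_bins)
  setattr(res, "n_body_bins", n_body_bins)
  res
}

#' @export
print.hm_profile <- function(x, ...) {
  cat(sprintf("metagene profile: %s / %s, sample %s\n",
              x$kind[1L], x$context[1L], x$sample_id[1L]))
  cat(sprintf("  zones up(%d) body(%d) down(%d); mean level %.4f\n",
              sum(x$zone == "up"), sum(x$zone == "body"),
              sum(x$zone == "down"), mean(x$level, na.rm = TRUE)))
  NextMethod()
}

#' Plot a metagene profile
#'
#' @param x An `hm_profile` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hm_profile <- function(x, ...) {
  xx <- seq_len(nrow(x))
  graphics::plot(xx, x$level, type = "l", xaxt = "n",
                 xlab = "", ylab = sprintf("m%s level", x$context[1L]), ...)
  nb <- attr(x, "n_flank_bins")
  graphics::axis(1, at = c(1, nb + 0.5, nrow(x) - nb + 0.5, nrow(x)),
                 labels = c(sprintf("-%dkb", attr(x, "flank_bp") %/% 1000),
                            "start", "end",
                            sprintf("+%dkb", attr(x, "flank_bp") %/% 1000)))
  graphics::abline(v = c(nb + 0.5, nrow(x) - nb + 0.5), lty = 3)
  invisible(x)
}

#' Per-feature weighted level in one region class
#'
#' Weighted methylation level over the unmasked, covered sites of one
#' context inside a feature's body, 2 kb upstream or 2 kb downstream region
#' (transcriptional orientation). Features without an eligible site get
#' `NA`.
#'
#' @inheritParams compute_profile
#' @param region_class `"body"`, `"up2k"` or `"down2k"`.
#' @param flank_bp Flank width used for `up2k`/`down2k`.
#' @return `data.table`: `feature_id`, `level`, `n_sites`, `n_reads`.
#' @export
gene_region_levels <- function(sites, features, region_class, context,
                               flank_bp = 2000L, min_coverage = 4L) {
  if (!region_class %in% c("body", "up2k", "down2k")) {
    stop_hm("unknown region_class '%s' (expected body, up2k or down2k)",
            region_class)
  }
  ctx <- context
  f <- as.data.table(features)
  reg <- feature_regions(f, region_class, flank_bp)
  reg[, start := pmax(start, 0L)]
  setkey(reg, chrom, start, end)
  s <- as.data.table(sites)
  s <- s[context == ctx & !masked & (count_meth + count_unmeth) >= min_coverage]
  base <- data.table(feature_id = f$feature_id)
  if (nrow(s) == 0L) {
    return(base[, .(feature_id, level = NA_real_, n_sites = 0L, n_reads = 0L)])
  }
  sdt <- s[, .(chrom, start = pos, end = pos + 1L, count_meth,
               total = count_meth + count_unmeth)]
  setkey(sdt, chrom, start, end)
  ov <- foverlaps(sdt, reg, type = "within", nomatch = NULL)
  agg <- ov[, .(meth = sum(count_meth), n_reads = sum(total), n_sites = .N),
            by = feature_id]
  out <- merge(base, agg, by = "feature_id", all.x = TRUE, sort = FALSE)
  out[is.na(n_reads), `:=`(meth = 0L, n_reads = 0L, n_sites = 0L)]
  out[, level := fifelse(n_reads > 0, meth / n_reads, NA_real_)]
  out[, .(feature_id, level, n_sites, n_reads)]
}

#' @rdname gene_region_levels
#' @param feature A single-row feature table.
#' @return `region_mean_level()` returns one level (or `NA`).
#' @export
region_mean_level <- function(sites, feature, region_class, context,
                              flank_bp = 2000L, min_coverage = 4L) {
  f <- as.data.table(feature)
  if (nrow(f) != 1L) stop_hm("region_mean_level expects exactly one feature")
  gene_region_levels(sites, f, region_class, context, flank_bp,
                     min_coverage)$level[1L]
}
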