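# Shared fixtures and independent oracles used across the suite.

library(data.table)

quiet <- function(expr) suppressMessages(expr)

# small-but-complete simulation config for fast end-to-end tests
tiny_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, genome_length = 120000L, n_chroms = 2L,
             n_genes = 20L, n_tes = 6L, n_replicates = 2L,
             genes_per_dmr_class = 2L, ...)
}

# build per-sample site tables (counts + mask) from an in-memory simulation,
# without touching disk
sim_site_samples <- function(cfg) {
  gen <- quiet(simulate_genome(cfg))
  variants <- quiet(simulate_variants(gen$genome, cfg))
  methylome <- quiet(simulate_methylome(gen$genome, gen$features, variants, cfg))
  pile <- quiet(simulate_pileup(methylome, cfg))
  base <- quiet(mask_variant_cytosines(methylome$sites, variants))
  samples <- lapply(pile, function(cx) {
    s <- copy(base)
    s[, `:=`(count_meth = cx$count_meth, count_unmeth = cx$count_unmeth)]
    s
  })
  list(genome = gen$genome, features = gen$features, variants = variants,
       methylome = methylome, pile = pile, samples = samples)
}

# exhaustive two-sided Fisher p via explicit binomial-coefficient sums;
# independent of the package's dhyper-based path
bf_fisher_p <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  m <- meth_a + meth_b
  u <- unmeth_a + unmeth_b
  k <- meth_a + unmeth_a
  n <- m + u
  ks <- max(0L, k - u):min(k, m)
  pr <- vapply(ks, function(x) {
    exp(lchoose(m, x) + lchoose(u, k - x) - lchoose(n, k))
  }, numeric(1L))
  obs <- pr[ks == meth_a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# brute-force windowed DMR caller: explicit per-window loops with
# stats::fisher.test, then explicit merge loop
bf_call_dmrs <- function(ctl, trt, window_bp = 100L, min_sites = 4L,
                         min_coverage = 4L,
                         delta_min = c(CG = 0.4, CHG = 0.2, CHH = 0.1),
                         q_max = 0.05, merge_gap_bp = 100L) {
  ctl <- as.data.table(ctl); trt <- as.data.table(trt)
  key <- c("chrom", "pos", "strand")
  m <- merge(ctl, trt, by = key, suffixes = c("_a", "_b"))
  if (!"masked" %in% names(m)) {
    m[, masked := if ("masked_a" %in% names(m)) masked_a else FALSE]
  }
  rows <- list()
  for (cx in unique(m$context_a)) {
    for (ch in unique(m$chrom)) {
      sub <- m[context_a == cx & chrom == ch & !masked &
                 count_meth_a + count_unmeth_a >= min_coverage &
                 count_meth_b + count_unmeth_b >= min_coverage]
      if (nrow(sub) == 0L) next
      for (w in unique(sub$pos %/% window_bp)) {
        ws <- sub[pos %/% window_bp == w]
        if (nrow(ws) < min_sites) next
        a <- sum(ws$count_meth_a); b <- sum(ws$count_unmeth_a)
        c_ <- sum(ws$count_meth_b); d <- sum(ws$count_unmeth_b)
        p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
        rows[[length(rows) + 1L]] <- data.table(
          context = cx, chrom = ch, win = w, n_sites = nrow(ws),
          meth_a = a, unmeth_a = b, meth_b = c_, unmeth_b = d, p_value = p,
          delta = c_ / (c_ + d) - a / (a + b))
      }
    }
  }
  if (!length(rows)) return(data.table())
  w <- rbindlist(rows)
  w[, q_value := stats::p.adjust(p_value, "BH"), by = context]
  w[, `:=`(start = win * window_bp, end = (win + 1L) * window_bp)]
  sig <- w[q_value <= q_max & abs(delta) >= delta_min[context]]
  if (nrow(sig) == 0L) return(data.table())
  sig[, direction := ifelse(delta > 0, "hyper", "hypo")]
  out <- list()
  for (cx in unique(sig$context)) {
    for (ch in unique(sig$chrom)) {
      for (dr in c("hyper", "hypo")) {
        ss <- sig[context == cx & chrom == ch & direction == dr][order(start)]
        if (nrow(ss) == 0L) next
        i <- 1L
        while (i <= nrow(ss)) {
          j <- i
          while (j < nrow(ss) && ss$start[j + 1L] - ss$end[j] <= merge_gap_bp) {
            j <- j + 1L
          }
          blk <- ss[i:j]
          a <- sum(blk$meth_a); b <- sum(blk$unmeth_a)
          c_ <- sum(blk$meth_b); d <- sum(blk$unmeth_b)
          out[[length(out) + 1L]] <- data.table(
            chrom = ch, start = min(blk$start), end = max(blk$end),
            context = cx, direction = dr,
            delta = c_ / (c_ + d) - a / (a + b),
            p_value = stats::fisher.test(matrix(c(a, b, c_, d), 2L,
                                                byrow = TRUE))$p.value,
            q_value = min(blk$q_value), n_windows = j - i + 1L)
          i <- j + 1L
        }
      }
    }
  }
  res <- rbindlist(out)
  setorder(res, chrom, start, context)
  res[]
}

# sensitivity / precision of DMR calls against planted truth, matched by
# same-context same-direction >=1 bp overlap
dmr_recovery <- function(calls, planted) {
  calls <- as.data.table(calls); planted <- as.data.table(planted)
  hit_truth <- vapply(seq_len(nrow(planted)), function(i) {
    p <- planted[i]
    nrow(calls[chrom == p$chrom & context == p$context &
                 direction == p$direction & start < p$end & end > p$start]) > 0L
  }, logical(1L))
  hit_call <- vapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i]
    nrow(planted[chrom == cl$chrom & context == cl$context &
                   direction == cl$direction & start < cl$end &
                   end > cl$start]) > 0L
  }, logical(1L))
  list(sensitivity = mean(hit_truth), precision = mean(hit_call),
       n_planted = nrow(planted), n_called = nrow(calls))
}
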