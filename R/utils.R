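# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table data.table as.data.table setDT setkey setkeyv
#'   setorder setnames setcolorder setattr rbindlist fread fwrite copy
#'   foverlaps tstrsplit := .N .SD .BY fifelse
#' @importFrom stats setNames
#' @importFrom methods is
NULL

# Quiet R CMD check notes for data.table NSE column names.
utils::globalVariables(c(
  ".", "..keep", "chrom", "pos", "strand", "context", "trinucleotide",
  "count_meth", "count_unmeth", "masked", "level", "total", "start", "end",
  "feature_id", "kind", "gene_id", "sample_id", "window_id", "win",
  "meth_a", "unmeth_a", "meth_b", "unmeth_b", "n_sites", "p_value",
  "q_value", "direction", "delta", "level_control", "level_treated",
  "true_level", "true_level_control", "true_level_treated", "is_variant",
  "zone", "bin_index", "n_reads", "region_class", "comparison", "log2fc",
  "offset", "bin", "grp", "block", "sig", "eligible", "i.start", "i.end",
  "annotation", "combo_id", "dmr_start", "dmr_end", "dmr_direction",
  "x.start", "x.end"
))

# Stage-tagged logging to stderr; every pipeline stage reports record counts
# through this single channel.
hm_log <- function(stage, fmt, ...) {
  message(sprintf("[hetmethyl:%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}

# Derive a stream-specific seed from a master seed; keeps results independent
# across stages while remaining a pure function of (seed, stream). Stays
# below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    genome = 101L, variants = 211L, methylome = 307L, pileup = 401L,
    expression = 503L, placement = 601L, deg = 701L
  )
  off <- if (stream %in% names(offsets)) offsets[[stream]] else
    sum(utf8ToInt(stream)) %% 997L
  as.integer((as.numeric(seed) * 2654435.0 + off * 97.0) %% 2147483647)
}

stop_hm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop_hm("%s is missing required column(s): %s", what,
            paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

CONTEXTS <- c("CG", "CHG", "CHH")

# context implied by a trinucleotide on the cytosine's own strand
context_from_tri <- function(tri) {
  b2 <- substr(tri, 2L, 2L)
  b3 <- substr(tri, 3L, 3L)
  fifelse(b2 == "G", "CG", fifelse(b3 == "G", "CHG", "CHH"))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
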