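#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and any character outside `A/C/G/T` is mapped to
#' `N`, so downstream context assignment only ever sees the five-letter
#' alphabet. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_hm("FASTA file not found: %s", path)
  gs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(gs))
  if (anyDuplicated(nm)) {
    stop_hm("duplicate chromosome name(s) in %s: %s", path,
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(Biostrings::width(gs) == 0L)) {
    stop_hm("empty sequence record in %s", path)
  }
  seqs <- toupper(as.character(gs))
  seqs <- gsub("[^ACGT]", "N", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  hm_log("io", "read %d chromosome(s), %.0f bp total from %s",
         length(out), sum(Biostrings::width(out)), path)
  out
}

#' Write a genome to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# ---- CX report (per-cytosine bisulfite counts) ------------------------------

CX_COLS <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
             "context", "trinucleotide")

#' Read a per-cytosine CX report
#'
#' The CX report is a 7-column tab-separated table with one row per
#' strand-resolved cytosine: chromosome, 1-based position, strand,
#' methylated read count, unmethylated read count, context (`CG`/`CHG`/`CHH`)
#' and the trinucleotide on the cytosine's strand. Rows with zero total
#' coverage are retained: they still carry context information. Positions are
#' converted to the package's internal 0-based convention on read.
#'
#' @param path Path to the report.
#' @return A `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `count_meth`, `count_unmeth`, `context`, `trinucleotide`.
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) stop_hm("CX report not found: %s", path)
  dt <- if (file.size(path) == 0L) data.table() else
    fread(path, header = FALSE, sep = "\t",
          colClasses = list(character = c(1, 3, 6, 7),
                            integer = c(2, 4, 5)))
  if (nrow(dt) == 0L) {
    hm_log("io", "CX report %s is empty", path)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), count_meth = integer(),
                      count_unmeth = integer(), context = character(),
                      trinucleotide = character()))
  }
  if (ncol(dt) != 7L) stop_hm("CX report %s: expected 7 columns, got %d",
                              path, ncol(dt))
  setnames(dt, CX_COLS)
  if (anyNA(dt$pos) || anyNA(dt$count_meth) || anyNA(dt$count_unmeth)) {
    stop_hm("CX report %s: malformed numeric field(s)", path)
  }
  if (any(dt$count_meth < 0L) || any(dt$count_unmeth < 0L)) {
    stop_hm("CX report %s: negative count(s)", path)
  }
  if (!all(dt$strand %in% c("+", "-"))) {
    stop_hm("CX report %s: strand must be '+' or '-'", path)
  }
  implied <- context_from_tri(dt$trinucleotide)
  bad <- which(implied != dt$context)
  if (length(bad)) {
    stop_hm("CX report %s: context/trinucleotide mismatch at row %d (%s vs %s)",
            path, bad[1L], dt$context[bad[1L]], dt$trinucleotide[bad[1L]])
  }
  dt[, pos := pos - 1L]
  hm_log("io", "read %d cytosine records from %s", nrow(dt), path)
  dt[]
}

#' Write a per-cytosine CX report
#'
#' @param sites Site table with the columns of [read_cx_report()]
#'   (`pos` 0-based; converted to 1-based on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(sites, path) {
  assert_columns(sites, CX_COLS, "CX table")
  out <- as.data.table(sites)[, CX_COLS, with = FALSE]
  out[, pos := pos + 1L]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- VCF variants -----------------------------------------------------------

#' Read biallelic SNPs from a VCF
#'
#' Parses a single-sample VCF and keeps biallelic SNP records with a called
#' non-reference genotype. Multi-allelic and indel records are skipped (a
#' count is logged); homozygous-reference records are dropped. Genotypes are
#' collapsed to `het` / `hom_alt`. This is the resequencing input used to
#' mask polymorphism-confounded cytosines.
#'
#' @param path Path to an (uncompressed) VCF file.
#' @return `data.table` with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `genotype`.
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop_hm("VCF file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    hm_log("io", "VCF %s has no variant records", path)
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character()))
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(f) < 10L) stop_hm("VCF %s: no sample column (GT required)", path)
  dt <- data.table(chrom = f[[1L]], pos = as.integer(f[[2L]]), ref = f[[4L]],
                   alt = f[[5L]], format = f[[9L]], sample = f[[10L]])
  n_in <- nrow(dt)
  snp <- nchar(dt$ref) == 1L & nchar(dt$alt) == 1L & dt$alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  dt <- dt[snp]
  gt_idx <- vapply(strsplit(dt$format, ":", fixed = TRUE),
                   function(x) match("GT", x), integer(1L))
  if (anyNA(gt_idx)) stop_hm("VCF %s: record without GT in FORMAT", path)
  gt <- mapply(function(s, i) strsplit(s, ":", fixed = TRUE)[[1L]][i],
               dt$sample, gt_idx, USE.NAMES = FALSE)
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  gclass <- vapply(alleles, function(a) {
    a <- a[a != "."]
    if (length(a) == 0L) return(NA_character_)
    a <- as.integer(a)
    if (all(a == 0L)) "hom_ref" else if (all(a == 1L)) "hom_alt" else "het"
  }, character(1L))
  keep <- !is.na(gclass) & gclass != "hom_ref"
  out <- dt[keep, .(chrom, pos = pos - 1L, ref, alt)]
  out[, genotype := gclass[keep]]
  hm_log("io", "VCF %s: %d records, %d non-SNP skipped, %d variants kept",
         path, n_in, n_skip, nrow(out))
  out[]
}

#' Write variants to a minimal VCF
#'
#' @param variants Variant table as returned by [read_vcf_variants()].
#' @param path Output path.
#' @param sample_name Sample column header.
#' @return `path`, invisibly.
#' @export
write_vcf_variants <- function(variants, path, sample_name = "sample1") {
  assert_columns(variants, c("chrom", "pos", "ref", "alt", "genotype"), "variant table")
  gt <- ifelse(variants$genotype == "het", "0/1", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  rows <- paste(variants$chrom, variants$pos + 1L, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- genomic features (genes / TEs) ----------------------------------------

#' Read gene or TE features from BED or GFF3
#'
#' BED input (0-based half-open) is taken as-is; GFF3 (1-based closed) is
#' converted on read so both encodings of an interval yield identical internal
#' coordinates. Strand is required on every feature because upstream and
#' downstream flanks are defined in transcriptional orientation.
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` file.
#' @param kind Feature kind to assign, `"gene"` or `"TE"`.
#' @param chrom_names Optional character vector of known chromosome names;
#'   if given, features on unknown chromosomes raise an error.
#' @return `data.table` with columns `feature_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `kind`.
#' @export
read_features <- function(path, kind = c("gene", "TE"), chrom_names = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_hm("feature file not found: %s", path)
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  id <- if (fmt == "gff3") {
    as.character(gr$ID %||% gr$Name %||% seq_along(gr))
  } else {
    as.character(gr$name %||% seq_along(gr))
  }
  dt <- data.table(
    feature_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GRanges is 1-based closed
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind
  )
  if (any(dt$strand == "*")) {
    stop_hm("feature(s) without strand in %s: strand is required for flanks",
            path)
  }
  if (any(dt$end <= dt$start)) stop_hm("feature with end <= start in %s", path)
  if (!is.null(chrom_names) && !all(dt$chrom %in% chrom_names)) {
    stop_hm("feature(s) on unknown chromosome in %s: %s", path,
            paste(setdiff(unique(dt$chrom), chrom_names), collapse = ", "))
  }
  hm_log("io", "read %d %s feature(s) from %s", nrow(dt), kind, path)
  dt[]
}

#' Write features to BED6
#'
#' @param features Feature table (see [read_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  assert_columns(features, c("feature_id", "chrom", "start", "end", "strand"),
                 "feature table")
  out <- data.table(features$chrom, features$start, features$end,
                    features$feature_id, ".", features$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- expression counts and DEG tables --------------------------------------

#' Read a gene-level expression count table
#'
#' @param path TSV with a `gene_id` column followed by one integer column per
#'   sample.
#' @return `data.table`, `gene_id` first.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_hm("counts file not found: %s", path)
  dt <- fread(path, sep = "\t")
  if (names(dt)[1L] != "gene_id") stop_hm("counts %s: first column must be gene_id", path)
  if (anyDuplicated(dt$gene_id)) stop_hm("counts %s: duplicate gene ids", path)
  dt[]
}

#' @rdname read_counts
#' @param counts Count table to write.
#' @export
write_counts <- function(counts, path) {
  fwrite(as.data.table(counts), path, sep = "\t")
  invisible(path)
}

DEG_COLS <- c("gene_id", "log2fc", "qvalue", "direction", "comparison")

#' Read / write a DEG table
#'
#' The exchange format for differentially expressed genes:
#' `gene_id`, `log2fc`, `qvalue`, `direction` (`up`/`down`), `comparison`.
#' Tables from external callers are accepted as-is so real-data runs can
#' bypass the built-in caller.
#'
#' @param path TSV path.
#' @return `data.table` with the five DEG columns.
#' @export
read_deg_table <- function(path) {
  dt <- fread(path, sep = "\t")
  assert_columns(dt, DEG_COLS, "DEG table")
  if (!all(dt$direction %in% c("up", "down"))) {
    stop_hm("DEG table %s: direction must be 'up' or 'down'", path)
  }
  dt[]
}

#' @rdname read_deg_table
#' @param degs DEG table to write.
#' @export
write_deg_table <- function(degs, path) {
  fwrite(as.data.table(degs)[, DEG_COLS, with = FALSE], path, sep = "\t")
  invisible(path)
}

# ---- flat key=value config --------------------------------------------------

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric; comma-separated values become
#' vectors. All pipeline thresholds are config keys with in-package defaults.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_hm("config file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop_hm("config %s: malformed line: %s", path, lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, character(1L), 2L))
  vals <- trimws(vapply(kv, `[`, character(1L), 3L))
  parse1 <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  stats::setNames(lapply(vals, parse1), keys)
}

#' @rdname read_config
#' @param config Named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(format(config[[k]], scientific = FALSE,
                                       trim = TRUE), collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
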