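# Readers and writers for the external formats the pipeline consumes and
# produces.  Single source of coordinate-convention truth: everything in
# memory is 1-based inclusive; only write_bed() converts (to 0-based
# half-open).  Chromosome names are compared as exact strings.

BASES <- c("A", "C", "G", "T")
CONTEXTS <- c("CG", "CHG", "CHH")

# Read a TSV with a fixed header, erroring with a line number on ragged or
# non-numeric rows.  Line numbers are 1-based including the header.
read_tsv_strict <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) stop("empty file (no header): ", path)
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop("malformed line ", bad[1], " in ", path, ": expected ", nf[1],
         " tab-separated fields, found ", nf[bad[1]])
  }
  x <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(x))) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v) && !all(is.na(v) == (x[[col]] %in% c("NA", "")))) {
      first <- which(is.na(v) & !(x[[col]] %in% c("NA", "")))[1]
      stop("malformed line ", first + 1L, " in ", path,
           ": non-numeric value '", x[[col]][first], "' in column ", col)
    }
    x[[col]] <- v
  }
  x
}

#' Read a parental SNP table
#'
#' Reads a TSV of biallelic parent-distinguishing SNPs with columns
#' `chrom`, `pos`, `allele_a`, `allele_b`, `depth`.  Rows failing the
#' record invariants are dropped with a message: genotyping read depth
#' must exceed `min_depth - 1` (the default keeps sites with depth > 3),
#' the two parental alleles must differ, and both must be one of A/C/G/T.
#'
#' @param path Path to a tab-separated file with the header above.
#' @param min_depth Minimum genotyping depth retained (default 4, i.e.
#'   depth > 3).
#' @param quiet Suppress the dropped-record message.
#' @return A data.frame with columns `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `depth`, sorted by (chrom, pos).
#' @export
read_snp_table <- function(path, min_depth = 4, quiet = FALSE) {
  x <- read_tsv_strict(path, c("chrom", "pos", "allele_a", "allele_b", "depth"),
                       c("pos", "depth"))
  x <- x[, c("chrom", "pos", "allele_a", "allele_b", "depth")]
  x$allele_a <- toupper(x$allele_a)
  x$allele_b <- toupper(x$allele_b)
  keep <- x$depth >= min_depth &
    x$allele_a != x$allele_b &
    x$allele_a %in% BASES &
    x$allele_b %in% BASES
  n_drop <- sum(!keep)
  if (n_drop > 0 && !quiet) {
    message("read_snp_table: dropped ", n_drop,
            " record(s) violating SNP invariants")
  }
  x <- x[keep, , drop = FALSE]
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a per-SNP base-count table for one sample
#'
#' Pileup-derived per-site base counts: columns `chrom`, `pos`,
#' `count_A`, `count_C`, `count_G`, `count_T`.
#'
#' @param path Path to the TSV.
#' @return A data.frame sorted by (chrom, pos).
#' @export
read_base_counts <- function(path) {
  cols <- c("chrom", "pos", "count_A", "count_C", "count_G", "count_T")
  x <- read_tsv_strict(path, cols, cols[-1])
  x <- x[, cols]
  if (any(x[, 3:6] < 0)) stop("negative base count in ", path)
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read a Bismark-style cytosine report
#'
#' Headerless (or headered) TSV with columns chrom, pos, strand,
#' methylated count, unmethylated count, context; a seventh
#' trinucleotide column, if present, is ignored.  Context strings are
#' normalized to CG/CHG/CHH ("CpG" is accepted for CG).
#'
#' @param path Path to the report.
#' @return A data.frame with columns `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`, `context`, sorted by (chrom, pos).  An empty file yields a
#'   zero-row data.frame.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(chrom = character(), pos = numeric(),
                      strand = character(), meth = numeric(),
                      unmeth = numeric(), context = character(),
                      stringsAsFactors = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(empty)
  has_header <- grepl("^chrom\t", first)
  x <- utils::read.delim(path, header = has_header, sep = "\t", quote = "",
                         comment.char = "", stringsAsFactors = FALSE)
  if (nrow(x) == 0) return(empty)
  if (ncol(x) < 6) stop("cytosine report needs >= 6 columns: ", path)
  x <- x[, 1:6]
  names(x) <- c("chrom", "pos", "strand", "meth", "unmeth", "context")
  x$chrom <- as.character(x$chrom)
  x$context <- toupper(as.character(x$context))
  x$context[x$context == "CPG"] <- "CG"
  bad_ctx <- !(x$context %in% CONTEXTS)
  if (any(bad_ctx)) {
    stop("unknown methylation context '", x$context[which(bad_ctx)[1]],
         "' in ", path)
  }
  if (!is.numeric(x$meth) || !is.numeric(x$unmeth)) {
    stop("non-numeric methylation counts in ", path)
  }
  if (any(x$meth < 0) || any(x$unmeth < 0)) {
    stop("negative methylation count in ", path)
  }
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Write a cytosine report (Bismark-style, headerless)
#'
#' @param x Data.frame as returned by [read_cytosine_report()].
#' @param path Output path.
#' @export
write_cytosine_report <- function(x, path) {
  utils::write.table(x[, c("chrom", "pos", "strand", "meth", "unmeth",
                           "context")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation via `rtracklayer`, keeps gene-level features
#' only (mRNA/exon children are ignored: imprinting is called per gene),
#' and derives a coding/noncoding biotype flag from a `biotype` attribute
#' when present (values containing "lnc", "ncRNA" or "noncoding" map to
#' noncoding; anything else, or no attribute, to coding).
#'
#' @param path GFF3 file.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, sorted by (chrom, start).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md)) {
    gr <- gr[as.character(md$type) == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  if (all(is.na(id)) && "Name" %in% names(md)) id <- as.character(md$Name)
  if (anyNA(id)) stop("gene feature without ID attribute in ", path)
  if (anyDuplicated(id)) stop("duplicated gene_id in ", path)
  biotype <- rep("coding", length(gr))
  if ("biotype" %in% names(md)) {
    raw <- tolower(as.character(md$biotype))
    biotype[grepl("lnc|ncrna|noncoding", raw)] <- "noncoding"
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  out <- data.frame(gene_id = id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = strand,
                    biotype = biotype,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models as GFF3
#'
#' @param genes Data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype` (1-based inclusive coordinates).
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\timprintscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                   genes$chrom, as.integer(genes$start),
                   as.integer(genes$end), genes$strand, genes$gene_id,
                   genes$biotype)
  writeLines(lines, con)
  invisible(path)
}

#' Write intervals as BED
#'
#' Converts from the package's internal 1-based inclusive coordinates to
#' BED's 0-based half-open convention.  Optional `name` and `score`
#' columns populate BED columns 4-5 (e.g. an interval id and a q-value).
#' Intervals are written verbatim; no merging or sorting is performed.
#'
#' @param x Data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(x)) as.character(x$name) else "."
  score <- if ("score" %in% names(x)) as.character(x$score) else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", x$chrom,
                   as.integer(x$start) - 1L, as.integer(x$end), name, score)
  writeLines(lines, path)
  invisible(path)
}

# Generic TSV result writer/reader (header, no quoting).
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
}

#' Convert samtools mpileup text to a base-count table
#'
#' Optional adapter for single-sample `samtools mpileup` output
#' (chrom, pos, ref, depth, read bases, qualities).  Read-start
#' (`^` + mapping quality), read-end (`$`) markers and indel
#' specifications (`+N`/`-N` followed by N bases) are stripped; `.`/`,`
#' count toward the reference base; `*`, `N` and gap markers are
#' ignored.  The pre-tabulated TSV consumed by [read_base_counts()]
#' remains the primary input format.
#'
#' @param path Path to mpileup-format text.
#' @return A data.frame with columns `chrom`, `pos`, `count_A`,
#'   `count_C`, `count_G`, `count_T`, sorted by (chrom, pos).
#' @export
pileup_to_base_counts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), pos = numeric(),
                      count_A = numeric(), count_C = numeric(),
                      count_G = numeric(), count_T = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5)) {
    stop("malformed line ", which(lengths(fields) < 5)[1], " in ", path)
  }
  counts <- t(vapply(fields, function(f) {
    ref <- toupper(f[3])
    bases <- f[5]
    bases <- gsub("\\^.", "", bases)          # read starts carry a mapq char
    bases <- gsub("\\$", "", bases)
    # strip indel runs: [+-]<len><seq>
    while (grepl("[+-][0-9]+", bases)) {
      m <- regmatches(bases, regexpr("[+-][0-9]+", bases))
      len <- as.integer(sub("[+-]", "", m))
      bases <- sub(paste0("[+-][0-9]+", strrep("[ACGTNacgtn*]", len)), "",
                   bases)
    }
    bases <- toupper(chartr(".,", paste0(ref, ref), bases))
    ch <- strsplit(bases, "")[[1]]
    vapply(BASES, function(b) sum(ch == b), numeric(1))
  }, numeric(4)))
  out <- data.frame(chrom = vapply(fields, `[[`, character(1), 1),
                    pos = as.numeric(vapply(fields, `[[`, character(1), 2)),
                    count_A = counts[, 1], count_C = counts[, 2],
                    count_G = counts[, 3], count_T = counts[, 4],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
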