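#' @importFrom methods is
#' @importFrom stats median optim rnorm rpois runif rgamma cor pnorm
#'   wilcox.test setNames var sd qnorm rbinom quantile
#' @importFrom utils read.table write.table combn head
NULL

# All flat files use 0-based half-open coordinates; GRanges objects built from
# them are 1-based closed (the Bioconductor convention), converted on read.

#' Read probe-region definitions
#'
#' Reads a BED-like tab-separated file with six columns: chromosome, start
#' (0-based), end (exclusive), strand (`+`, `-` or `.`), probe id, and group
#' id. The group id is the summarisation unit a probe belongs to: a gene
#' identifier when emulating custom CDF style gene annotations, or a
#' probe-set identifier for the manufacturer's probe sets. Lines starting
#' with `#` are ignored; there is no header.
#'
#' @param path path to the probe TSV.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `probe_id`, `group_id`.
#' @export
read_probe_regions <- function(path) {
  df <- read_tsv_raw(path, c("chrom", "start", "end", "strand", "probe_id",
                             "group_id"),
                     colClasses = c("character", "integer", "integer",
                                    "character", "character", "character"))
  validate_probe_regions(df, path)
  df
}

validate_probe_regions <- function(df, path = "<probe regions>") {
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("%s: start >= end at line %d (%s)", path,
                 attr(df, "line_numbers")[bad[1]], df$probe_id[bad[1]]))
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop(sprintf("%s: duplicate probe_id '%s'", path, dup[1]))
  empty <- which(!nzchar(df$group_id))
  if (length(empty))
    stop(sprintf("%s: empty group_id at line %d", path,
                 attr(df, "line_numbers")[empty[1]]))
  if (!all(df$strand %in% c("+", "-", ".")))
    stop(sprintf("%s: strand must be one of +, -, .", path))
  invisible(df)
}

#' Read gene models (exon table)
#'
#' Reads a tab-separated exon table with five columns: gene id, chromosome,
#' exon start (0-based), exon end (exclusive), strand. Comment lines start
#' with `#`; no header. A gene's exons must lie on one chromosome and
#' strand.
#'
#' @param path path to the exon TSV.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_raw(path, c("gene_id", "chrom", "start", "end", "strand"),
                     colClasses = c("character", "character", "integer",
                                    "integer", "character"))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("%s: exon start >= end at line %d (%s)", path,
                 attr(df, "line_numbers")[bad[1]], df$gene_id[bad[1]]))
  nchr <- tapply(df$chrom, df$gene_id, function(x) length(unique(x)))
  if (any(nchr > 1))
    stop(sprintf("%s: gene '%s' has exons on more than one chromosome",
                 path, names(nchr)[which(nchr > 1)[1]]))
  df
}

read_tsv_raw <- function(path, col_names, colClasses) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) {
    df <- as.data.frame(setNames(
      lapply(colClasses, function(cl) vector(cl, 0L)), col_names))
    attr(df, "line_numbers") <- integer(0)
    return(df)
  }
  df <- read.table(text = lines[keep], sep = "\t", header = FALSE,
                   colClasses = colClasses, col.names = col_names,
                   quote = "", comment.char = "")
  attr(df, "line_numbers") <- which(keep)
  df
}

#' Expression tables
#'
#' An expression table is a numeric matrix of log2-scale expression values,
#' features in rows and samples in columns, tagged with the namespace of its
#' feature identifiers (`"gene"` or `"probeset"`).
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param namespace `"gene"` or `"probeset"`.
#' @return a matrix of class `expression_table` with a `namespace` attribute.
#' @export
expression_table <- function(values, namespace = c("gene", "probeset")) {
  namespace <- match.arg(namespace)
  values <- as.matrix(values)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("expression_table needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in expression table")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression table")
  structure(values, namespace = namespace,
            class = c("expression_table", class(values)))
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d %s features x %d samples\n",
              nrow(x), attr(x, "namespace"), ncol(x)))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read / write an expression table
#'
#' The on-disk dialect is a TSV whose first line is
#' `#namespace=<gene|probeset>`, followed by a header line `feature_id` plus
#' sample ids, then one row per feature. Values are written with full
#' precision so that a write/read round trip is bit-exact.
#'
#' @param path file path.
#' @return for the reader, an [expression_table()]; the writer returns
#'   `path` invisibly.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  namespace <- "gene"
  if (length(lines) && startsWith(lines[1], "#namespace=")) {
    namespace <- sub("^#namespace=", "", lines[1])
    lines <- lines[-1]
  }
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop(path, ": no header line")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "feature_id")
    stop(path, ": first header column must be 'feature_id'")
  sample_ids <- header[-1]
  if (length(lines) == 1L) {
    values <- matrix(numeric(0), 0, length(sample_ids),
                     dimnames = list(NULL, sample_ids))
    return(expression_table(values, namespace))
  }
  body <- read.table(text = lines[-1], sep = "\t", header = FALSE,
                     colClasses = c("character",
                                    rep("character", length(sample_ids))),
                     quote = "", comment.char = "")
  if (ncol(body) != length(header))
    stop(path, ": row width does not match header")
  values <- matrix(NA_real_, nrow(body), length(sample_ids),
                   dimnames = list(body[[1]], sample_ids))
  for (j in seq_along(sample_ids)) values[, j] <- as.numeric(body[[j + 1L]])
  if (anyNA(values)) stop(path, ": non-numeric or missing values")
  expression_table(values, namespace)
}

#' @rdname read_expression_table
#' @param table an [expression_table()].
#' @export
write_expression_table <- function(table, path) {
  stopifnot(is(table, "expression_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#namespace=%s", attr(table, "namespace")), con)
  writeLines(paste(c("feature_id", colnames(table)), collapse = "\t"), con)
  if (nrow(table)) {
    body <- apply(unclass(table), 2L, function(col)
      sprintf("%.17g", col))
    if (is.null(dim(body))) body <- matrix(body, nrow = nrow(table))
    writeLines(paste(rownames(table),
                     apply(body, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write probe regions / gene models
#'
#' Inverse of [read_probe_regions()] and [read_gene_models()]; round trips
#' are exact.
#'
#' @param df data frame in the reader's column layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_regions <- function(df, path) {
  validate_probe_regions(df)
  write.table(df[, c("chrom", "start", "end", "strand", "probe_id",
                     "group_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_regions
#' @export
write_gene_models <- function(df, path) {
  write.table(df[, c("gene_id", "chrom", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read aligned RNA-seq fragments
#'
#' Reads a SAM or BAM file into a set of fragments: one sequenced unit per
#' entry, each reduced to its aligned genomic blocks (gaps in the alignment,
#' e.g. splice junctions encoded as `N` CIGAR operations, split a fragment
#' into several blocks). In paired mode the two mates of a read pair are
#' merged into one fragment whose block set is the union of both mates'
#' blocks; a mate whose partner is missing is kept as a single-end fragment
#' and tallied as an orphan.
#'
#' An alignment is flagged *unique* when its `NH` tag equals 1 if the tag is
#' present, otherwise when its mapping quality is at least `unique_mapq`.
#' For merged pairs the fragment is unique only if both mates are.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @param paired_mode merge mates sharing a read name into one fragment.
#' @param unique_mapq mapping-quality threshold backing the uniqueness flag
#'   when no `NH` tag is present.
#' @return a [GenomicRanges::GRangesList] with one element per fragment,
#'   metadata column `unique`, and a `diagnostics` entry in
#'   [S4Vectors::metadata()] holding `n_records` (alignment records parsed),
#'   `n_skipped` (unmapped or CIGAR-less records), `n_fragments` and
#'   `n_orphans`.
#' @export
read_alignments <- function(path, paired_mode = FALSE, unique_mapq = 10L) {
  if (!file.exists(path)) stop("file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  n_records <- Rsamtools::countBam(bam)$records
  param <- Rsamtools::ScanBamParam(
    what = c("mapq", "flag"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, use.names = TRUE,
                                            param = param)
  n_skipped <- n_records - length(gal)
  if (n_skipped > 0L)
    warning(sprintf("%s: skipped %d unmapped or unusable record(s)",
                    path, n_skipped))
  nh <- S4Vectors::mcols(gal)$NH
  mq <- S4Vectors::mcols(gal)$mapq
  uniq <- ifelse(!is.na(nh), nh == 1L, !is.na(mq) & mq >= unique_mapq)
  blocks <- GenomicAlignments::grglist(gal)
  n_orphans <- 0L
  if (paired_mode && length(gal)) {
    nm <- names(gal)
    tab <- table(nm)
    n_orphans <- sum(tab == 1L & bitwAnd(S4Vectors::mcols(gal)$flag[
      match(names(tab), nm)], 1L) == 1L)
    flat <- unlist(blocks, use.names = FALSE)
    frags <- S4Vectors::split(flat, factor(rep(nm, lengths(blocks)),
                                           levels = unique(nm)))
    uniq <- as.logical(tapply(uniq, factor(nm, levels = unique(nm)), all))
  } else {
    frags <- blocks
    names(frags) <- names(gal)
  }
  S4Vectors::mcols(frags)$unique <- as.vector(uniq)
  S4Vectors::metadata(frags)$diagnostics <- list(
    n_records = n_records, n_skipped = n_skipped,
    n_fragments = length(frags), n_orphans = as.integer(n_orphans))
  frags
}
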