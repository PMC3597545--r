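#' @title IPD tables
#' @description
#' The package's working container for per-observation kinetic data is a
#' plain data frame with class `ipd_table` and columns `ref_name` (character),
#' `position` (integer, 0-based on the forward reference strand), `strand`
#' (`"+"` or `"-"`; strand is an attribute of the observation, never a
#' coordinate flip), `movie_id` (character; the data-acquisition batch unit)
#' and `ipd` (numeric). Attributes `chemistry_tag` and `scale` travel with the
#' table; `scale` is one of `"raw"` (seconds, strictly positive),
#' `"transformed"` (Box-Cox scale) or `"centered"` (Box-Cox scale, per-movie
#' means removed).
#'
#' @param records data frame with the five columns above
#' @param chemistry_tag character scalar labelling the sequencing chemistry
#' @param scale one of `"raw"`, `"transformed"`, `"centered"`
#' @return an `ipd_table`
#' @export
ipd_table <- function(records, chemistry_tag = "unknown", scale = "raw") {
  scale <- match.arg(scale, c("raw", "transformed", "centered"))
  need <- c("ref_name", "position", "strand", "movie_id", "ipd")
  if (!all(need %in% names(records)))
    stop("ipd_table needs columns: ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[, need]
  records$ref_name <- as.character(records$ref_name)
  records$position <- as.integer(records$position)
  records$strand <- as.character(records$strand)
  records$movie_id <- as.character(records$movie_id)
  records$ipd <- as.numeric(records$ipd)
  if (nrow(records)) {
    if (anyNA(records)) stop("ipd_table: NA values not allowed")
    if (!all(records$strand %in% .STRANDS))
      stop("ipd_table: strand must be '+' or '-'")
    if (any(records$position < 0L)) stop("ipd_table: negative position")
    if (scale == "raw" && any(records$ipd <= 0))
      stop("ipd_table: raw IPDs must be strictly positive")
  }
  structure(records,
            chemistry_tag = chemistry_tag, scale = scale,
            class = c("ipd_table", "data.frame"))
}

#' @export
print.ipd_table <- function(x, ...) {
  cat(sprintf("<ipd_table> %d observations, %d position(s), %d movie(s); chemistry=%s scale=%s\n",
              nrow(x), nrow(unique(x[c("ref_name", "position", "strand")])),
              length(unique(x$movie_id)),
              attr(x, "chemistry_tag"), attr(x, "scale")))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

.ipd_scale <- function(table) attr(table, "scale") %||% "raw"

.IPD_SCHEMA <- "#kinemod_ipd_v1"

#' Read an IPD table
#'
#' Reads the project's tab-separated IPD exchange format: a schema line
#' `#kinemod_ipd_v1`, an optional `#meta chemistry=<tag> scale=<scale>`
#' line, then a header `ref_name position strand movie_id ipd` and one row
#' per observation. Positions are 0-based on the forward reference strand.
#' Non-positive IPDs on the raw scale are rejected.
#'
#' @param path file path
#' @return an [ipd_table()]
#' @export
read_ipd_table <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!length(lines) || trimws(lines[1L]) != .IPD_SCHEMA)
    stop("not a ", .IPD_SCHEMA, " file: ", path)
  skip <- 1L
  chemistry <- "unknown"; scale <- "raw"
  if (length(lines) > 1L && startsWith(lines[2L], "#meta")) {
    skip <- 2L
    kv <- regmatches(lines[2L], gregexpr("[a-z_]+=[^ ]+", lines[2L]))[[1L]]
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1L]]
      if (p[1L] == "chemistry") chemistry <- p[2L]
      if (p[1L] == "scale") scale <- p[2L]
    }
  }
  df <- read.delim(path, skip = skip, header = TRUE,
                   colClasses = c(ref_name = "character", position = "integer",
                                  strand = "character", movie_id = "character",
                                  ipd = "numeric"),
                   check.names = FALSE)
  bad <- which(!complete.cases(df[c("position", "ipd")]))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1L] + skip + 1L, path))
  if (scale == "raw" && nrow(df) && any(df$ipd <= 0)) {
    ln <- which(df$ipd <= 0)[1L] + skip + 1L
    stop(sprintf("non-positive IPD at line %d of %s", ln, path))
  }
  ipd_table(df, chemistry_tag = chemistry, scale = scale)
}

#' Write an IPD table
#'
#' Inverse of [read_ipd_table()]; numeric values are written with 10
#' significant digits so read/write round-trips are lossless well beyond the
#' 6 significant digits the format guarantees.
#'
#' @param table an [ipd_table()]
#' @param path output path
#' @export
write_ipd_table <- function(table, path) {
  stopifnot(inherits(table, "ipd_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(.IPD_SCHEMA,
               sprintf("#meta chemistry=%s scale=%s",
                       attr(table, "chemistry_tag"), .ipd_scale(table))), con)
  out <- as.data.frame(table)
  out$ipd <- formatC(out$ipd, format = "g", digits = 10)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file
#' @return named character vector of uppercase sequences (IUPAC ambiguity
#'   codes preserved); names are the first whitespace-delimited token of each
#'   header
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  setNames(toupper(as.character(seqs)), nm)
}

#' Read a truth set of known-modified positions from BED6
#'
#' Standard BED convention: 0-based half-open intervals, strand in column 6.
#' Each interval contributes its start position as one modified site.
#'
#' @param path BED file
#' @return data frame with columns `ref_name`, `position` (0-based), `strand`
#' @export
read_truth_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  truth_set(data.frame(
    ref_name = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,   # GRanges is 1-based
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE))
}

#' Construct a truth set
#' @param entries data frame with `ref_name`, `position` (0-based), `strand`
#' @return a `truth_set` data frame
#' @export
truth_set <- function(entries) {
  need <- c("ref_name", "position", "strand")
  stopifnot(all(need %in% names(entries)))
  entries <- unique(as.data.frame(entries)[, need])
  entries$position <- as.integer(entries$position)
  if (nrow(entries) && !all(entries$strand %in% .STRANDS))
    stop("truth_set: strand must be '+' or '-'")
  entries <- entries[order(entries$ref_name, entries$position,
                           entries$strand), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, class = c("truth_set", "data.frame"))
}

#' Write a truth set as BED6
#' @param truth a [truth_set()]
#' @param path output path
#' @export
write_truth_bed <- function(truth, path) {
  gr <- GenomicRanges::GRanges(
    truth$ref_name,
    IRanges::IRanges(start = truth$position + 1L, width = 1L),
    strand = truth$strand)
  gr$name <- sprintf("mod_%d", seq_along(gr))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write detections as GFF3
#'
#' Emits one `modified_base` feature per score record with score at or above
#' `threshold`. Internal 0-based positions become 1-based inclusive GFF3
#' coordinates; attributes carry the marginal log-likelihood-ratio score,
#' native/control coverage, homolog count and sequence context.
#'
#' @param scores a score table from [scan_genome()]
#' @param threshold minimum score to emit
#' @param path output path
#' @export
write_detections_gff <- function(scores, threshold, path) {
  keep <- scores[!is.na(scores$score) & scores$score >= threshold, , drop = FALSE]
  if (!nrow(keep)) {   # header-only file; empty GRanges trip the exporter
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    if (nrow(keep)) keep$ref_name else character(),
    IRanges::IRanges(start = keep$position + 1L, width = rep(1L, nrow(keep))),
    strand = if (nrow(keep)) keep$strand else character())
  gr$source <- rep("kinemod", nrow(keep))
  gr$type <- rep("modified_base", nrow(keep))
  gr$score <- keep$score
  gr$ID <- sprintf("mod%06d", seq_len(nrow(keep)))
  gr$native_cov <- keep$native_cov
  gr$control_cov <- keep$control_cov
  gr$n_homologs <- keep$n_homologs
  gr$context <- keep$context
  gr$method <- keep$method
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read detections back from GFF3 (round-trip companion of
#' [write_detections_gff()])
#' @param path GFF3 file
#' @return data frame in score-table layout (0-based positions)
#' @export
read_detections_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- data.frame(
    ref_name = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    score = as.numeric(gr$score),
    stringsAsFactors = FALSE)
  for (col in c("native_cov", "control_cov", "n_homologs"))
    df[[col]] <- if (!is.null(S4Vectors::mcols(gr)[[col]]))
      as.integer(S4Vectors::mcols(gr)[[col]]) else NA_integer_
  df$context <- if (!is.null(gr$context)) as.character(gr$context) else NA_character_
  df$method <- if (!is.null(gr$method)) as.character(gr$method) else NA_character_
  df
}

#' Write a reference genome to FASTA
#' @param genome named character vector of sequences
#' @param path output path
#' @param width line-wrap width
#' @export
write_reference <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = width)
  invisible(path)
}
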