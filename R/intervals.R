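# Interval plumbing. Every user-facing table of genomic regions is a plain
# data.frame with columns chrom / start / end in 0-based half-open (BED)
# coordinates; overlap machinery is delegated to GenomicRanges/IRanges,
# converting to 1-based closed internally.

.assert_bed <- function(df, what = "interval table") {
  if (!is.data.frame(df))
    stop(what, " must be a data.frame", call. = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) && any(df$end < df$start))
    stop(what, " contains intervals with end < start", call. = FALSE)
  invisible(df)
}

# Shared seqlevels so GRanges pairs never disagree on chromosome universes.
.bed_gr <- function(df, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(as.character(df$chrom))
  if (!length(seqlevels)) seqlevels <- "chrUn"
  GenomicRanges::GRanges(
    seqnames = factor(as.character(df$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.gr_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.gr_pair <- function(a, b) {
  lv <- union(unique(as.character(a$chrom)), unique(as.character(b$chrom)))
  list(a = .bed_gr(a, lv), b = .bed_gr(b, lv))
}

#' Sort a BED-style interval table by (chrom, start, end)
#' @param df data.frame with chrom/start/end
#' @return the sorted data.frame
#' @export
bed_sort <- function(df) {
  .assert_bed(df)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Merge overlapping or bookended intervals
#' @param df data.frame with chrom/start/end (0-based half-open)
#' @return merged, sorted data.frame
#' @export
bed_merge <- function(df) {
  .assert_bed(df)
  if (!nrow(df)) return(df[, c("chrom", "start", "end")])
  bed_sort(.gr_bed(GenomicRanges::reduce(.bed_gr(df))))
}

#' Does each query interval overlap any subject interval (>= 1 bp)?
#' @param query,subject BED-style data.frames
#' @return logical vector along rows of `query`
#' @export
bed_overlaps_any <- function(query, subject) {
  .assert_bed(query, "query"); .assert_bed(subject, "subject")
  if (!nrow(query)) return(logical(0))
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  p <- .gr_pair(query, subject)
  GenomicRanges::countOverlaps(p$a, p$b, minoverlap = 1L) > 0L
}

# All pairwise >=1 bp intersections between rows of a and b; returns the
# intersected pieces with the contributing row indices.
.bed_intersect_pairs <- function(a, b) {
  .assert_bed(a, "a"); .assert_bed(b, "b")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), idx_a = integer(0),
                      idx_b = integer(0), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  p <- .gr_pair(a, b)
  hits <- GenomicRanges::findOverlaps(p$a, p$b, minoverlap = 1L)
  if (!length(hits)) return(empty)
  ia <- S4Vectors::queryHits(hits); ib <- S4Vectors::subjectHits(hits)
  pieces <- IRanges::pintersect(p$a[ia], p$b[ib])
  out <- .gr_bed(pieces)
  out$idx_a <- ia
  out$idx_b <- ib
  out
}

# Subtract intervals in b from a (per-base set difference), merged output.
.bed_setdiff <- function(a, b) {
  .assert_bed(a, "a"); .assert_bed(b, "b")
  if (!nrow(a)) return(a[, c("chrom", "start", "end")])
  if (!nrow(b)) return(bed_merge(a))
  p <- .gr_pair(a, b)
  bed_sort(.gr_bed(GenomicRanges::setdiff(p$a, p$b)))
}

#' Write a BED-style table, sorted, with a coordinate-convention header
#'
#' Extra columns beyond chrom/start/end are written in their current order.
#' @param df BED-style data.frame
#' @param path output file
#' @param extra_header additional comment lines (without leading "#")
#' @export
write_bed <- function(df, path, extra_header = character(0)) {
  .assert_bed(df)
  df <- bed_sort(df)
  first <- c("chrom", "start", "end")
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# coordinates: 0-based, half-open (BED)",
               paste0("# ", extra_header)[seq_along(extra_header)]), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-style file written by [write_bed()]
#' @param path file path
#' @param col_names names for the columns present in the file
#' @return data.frame
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end")) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- col_names[seq_len(ncol(df))]
  df
}

.write_tsv <- function(df, path, extra_header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# coordinates: 0-based, half-open (BED)",
               paste0("# ", extra_header)[seq_along(extra_header)]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
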