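# Interval helpers. Intervals are tibbles with `start`/`end` in bp, 0-based
# half-open, on a single arm. Set operations delegate to IRanges.

as_iranges0 <- function(iv) {
  # 0-based half-open -> IRanges (1-based closed)
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

from_iranges0 <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge overlapping intervals
#' @param iv Tibble with `start`, `end` (bp, 0-based half-open).
#' @return Merged, sorted tibble of disjoint intervals.
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(tibble(start = integer(0), end = integer(0)))
  from_iranges0(IRanges::reduce(as_iranges0(iv)))
}

# Total bp of iv covered inside [start, end) after merging overlaps.
covered_bp <- function(iv, start, end) {
  if (nrow(iv) == 0) return(0)
  m <- merge_intervals(iv)
  sum(pmax(0, pmin(m$end, end) - pmax(m$start, start)))
}

# bp of the intersection of two merged interval sets, clipped to [start, end).
intersect_bp <- function(a, b, start = -Inf, end = Inf) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ir <- IRanges::intersect(IRanges::reduce(as_iranges0(a)),
                           IRanges::reduce(as_iranges0(b)))
  iv <- from_iranges0(ir)
  sum(pmax(0, pmin(iv$end, end) - pmax(iv$start, start)))
}

# union of two interval sets as a merged tibble
union_intervals <- function(a, b) {
  merge_intervals(bind_rows(a, b))
}

#' Read a BED file as an interval tibble
#'
#' Coordinates come back 0-based half-open; the optional name column is kept.
#'
#' @param path BED file (3+ columns, tab-separated, uncompressed).
#' @return Tibble with `chrom`, `start`, `end` and `name` (if present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write an interval tibble as BED
#'
#' @param iv Tibble with `start`, `end` (bp, 0-based half-open), optional
#'   `chrom` and `name` columns.
#' @param path Output file.
#' @param chrom Arm label used when `iv` has no `chrom` column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path, chrom = "arm") {
  if (nrow(iv) == 0) {
    file.create(path)
    return(invisible(path))
  }
  chroms <- if ("chrom" %in% names(iv)) iv$chrom else chrom
  gr <- GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
  if ("name" %in% names(iv)) gr$name <- iv$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
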