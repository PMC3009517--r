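# Shared helpers: tiny in-memory records and temp-file writers.

`%||%` <- function(a, b) if (is.null(a)) b else a

skeleton_rec <- function(id, pts) {
  structure(list(skeleton_id = id, points = pts), class = "skeleton")
}

segment_rec <- function(id, start, end) {
  structure(list(segment_id = id, start = as.integer(start),
                 end = as.integer(end), sstype = "H"), class = "segment")
}

# straight skeleton along `dir` starting at `from`, length L, npts points
straight_skeleton <- function(id, from = c(0, 0, 0), dir = c(0, 0, 1),
                              L = 13, npts = 5) {
  dir <- dir / sqrt(sum(dir^2))
  tt <- seq(0, L, length.out = npts)
  skeleton_rec(id, outer(rep(1, npts), from) + outer(tt, dir))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

skeleton_tsv <- function(rows) {
  write_lines_tmp(c("skeleton_id\tpoint_index\tx\ty\tz", rows))
}

segments_tsv <- function(rows) {
  write_lines_tmp(c("segment_id\tstart\tend\tsstype", rows))
}
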