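# Topology spaces: ordered assignments of sequence helix segments to
# skeletons, with an N->C direction per skeleton, plus the distance and
# length screens that prune the space before any structure is built.

#' Screening parameters
#'
#' @param s_max Maximum sequence shift allowed per segment, residues.
#' @param loop_rate Loop extension rate, Angstrom per loop residue.
#' @param rise Axis rise used to estimate skeleton residue counts,
#'   Angstrom per residue.
#' @param length_tol Allowed fractional length difference between a skeleton
#'   and its assigned segment, relative to the skeleton length.
#' @param endpoint_convention If `TRUE` (default) the skeleton residue
#'   estimate counts both end residues: `round(L / rise) + 1`; otherwise
#'   `max(round(L / rise), 2)`.
#' @return Object of class `screening_params`.
#' @export
screening_params <- function(s_max = 2L, loop_rate = 3.8, rise = 1.3,
                             length_tol = 0.5, endpoint_convention = TRUE) {
  stopifnot(s_max >= 0, loop_rate > 0, rise > 0,
            length_tol > 0, length_tol <= 1)
  structure(list(s_max = as.integer(s_max), loop_rate = loop_rate,
                 rise = rise, length_tol = length_tol,
                 endpoint_convention = isTRUE(endpoint_convention)),
            class = "screening_params")
}

#' Number of topologies for N helix segments and K skeletons
#'
#' With K skeletons and N >= K predicted helix segments there are
#' N!/(N-K)! ordered ways to pick which segment sits on which skeleton and
#' 2^K direction choices, i.e. `N!/(N-K)! * 2^K` topologies.
#'
#' @param N Number of predicted helix segments.
#' @param K Number of skeletons, `1 <= K <= N`.
#' @return The exact count as a double (exact while below 2^53).
#' @export
count_topologies <- function(N, K) {
  if (K < 1 || K > N) stop("need 1 <= K <= N")
  count <- prod(seq(N, by = -1, length.out = K)) * 2^K
  if (count >= 2^53) warning("count exceeds exact double range")
  count
}

#' Enumerate all topologies for N segments and K skeletons
#'
#' Deterministic order: lexicographic in the segment-index tuple, and for
#' each tuple all direction vectors with -1 ordered before +1, the first
#' skeleton being the most significant position.
#'
#' @inheritParams count_topologies
#' @return Object of class `topology_set`: list with integer matrix
#'   `segments` (rows are topologies, K columns) and matrix `directions`
#'   (entries -1/+1).
#' @export
enumerate_topologies <- function(N, K) {
  if (K < 1 || K > N) stop("need 1 <= K <= N")
  perms <- k_permutations(as.integer(N), as.integer(K))
  ndir <- 2L^K
  bits <- matrix(0L, nrow = ndir, ncol = K)
  for (j in seq_len(K)) # first skeleton most significant; 0 -> -1 first
    bits[, j] <- ifelse(bitwAnd(seq_len(ndir) - 1L, bitwShiftL(1L, K - j)) > 0L,
                        1L, -1L)
  segs <- perms[rep(seq_len(nrow(perms)), each = ndir), , drop = FALSE]
  dirs <- bits[rep(seq_len(ndir), times = nrow(perms)), , drop = FALSE]
  topology_set(segs, dirs)
}

# Lexicographic K-permutations of 1..N as a matrix (rows).
k_permutations <- function(N, K) {
  if (K == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  out <- matrix(seq_len(N), ncol = 1L)
  for (depth in seq_len(K - 1L)) {
    pieces <- lapply(seq_len(nrow(out)), function(r) {
      used <- out[r, ]
      avail <- setdiff(seq_len(N), used)
      cbind(matrix(rep(used, each = length(avail)), nrow = length(avail)),
            avail)
    })
    out <- do.call(rbind, pieces)
  }
  dimnames(out) <- NULL
  out
}

topology_set <- function(segments, directions) {
  stopifnot(nrow(segments) == nrow(directions),
            ncol(segments) == ncol(directions))
  structure(list(segments = segments, directions = directions),
            class = "topology_set")
}

#' @export
length.topology_set <- function(x) nrow(x$segments)

#' @export
print.topology_set <- function(x, ...) {
  cat(sprintf("topology_set: %d topologies over %d skeleton(s)\n",
              length(x), ncol(x$segments)))
  invisible(x)
}

# Extract topology i as list(segments =, directions =).
topology_at <- function(set, i) {
  list(segments = set$segments[i, ], directions = set$directions[i, ])
}

#' Topology label string
#'
#' One token per skeleton in file order, `Hk+` / `Hk-`: sequence segment k
#' assigned parallel / antiparallel to the stored polyline direction.
#' @param topology List with `segments` and `directions` vectors.
#' @return Character scalar such as `"H2+ H1- H3+"`.
#' @export
topology_string <- function(topology) {
  paste0("H", topology$segments,
         ifelse(topology$directions > 0, "+", "-"), collapse = " ")
}

#' Estimated residue count of a skeleton
#'
#' The axis length divided by the rise (1.3 Angstrom per residue by
#' default), rounded, plus one end residue; never below 2.
#'
#' @param skeleton Skeleton record or point matrix.
#' @param params [screening_params()].
#' @return Integer residue count.
#' @export
estimate_skeleton_residues <- function(skeleton, params = screening_params()) {
  ax <- fit_axis_line(skeleton)
  n <- if (params$endpoint_convention) round(ax$length / params$rise) + 1
       else round(ax$length / params$rise)
  max(2L, as.integer(n))
}

#' Length screen for one skeleton / segment pair
#'
#' Passes when the residue-count difference is within `length_tol` of the
#' skeleton's estimated residue count (boundary inclusive).
#'
#' @param skeleton Skeleton record.
#' @param segment Segment record (list with `start`, `end`).
#' @param params [screening_params()].
#' @return Logical.
#' @export
length_screen <- function(skeleton, segment, params = screening_params()) {
  lsk <- estimate_skeleton_residues(skeleton, params)
  lseg <- segment$end - segment$start + 1L
  abs(lsk - lseg) <= params$length_tol * lsk
}

#' Distance screen (loop reachability) for one topology
#'
#' For each pair of skeletons carrying sequence-consecutive segments, the
#' gap between the C-terminal axis end of the earlier helix and the
#' N-terminal axis end of the later one must be coverable by the loop:
#' the topology is eliminated iff `d > loop_rate * (n_loop + 2 * s_max)`
#' for any pair, where `n_loop` counts residues strictly between the two
#' segments.
#'
#' @param topology List with `segments` and `directions` vectors (one entry
#'   per skeleton, in skeleton file order).
#' @param skeletons List of skeleton records (or pre-fitted axes).
#' @param segments List of segment records.
#' @param params [screening_params()].
#' @return `TRUE` when the topology is retained.
#' @export
distance_screen <- function(topology, skeletons, segments,
                            params = screening_params()) {
  axes <- lapply(skeletons, function(s)
    if (is.list(s) && !is.null(s$dir)) s else fit_axis_line(s))
  K <- length(topology$segments)
  ord <- order(topology$segments)   # skeletons in sequence order
  if (K < 2) return(TRUE)
  for (i in seq_len(K - 1L)) {
    ka <- ord[i]; kb <- ord[i + 1L]
    sa <- segments[[topology$segments[ka]]]
    sb <- segments[[topology$segments[kb]]]
    axa <- axes[[ka]]; axb <- axes[[kb]]
    cterm_a <- if (topology$directions[ka] > 0) axa$p1 else axa$p0
    nterm_b <- if (topology$directions[kb] > 0) axb$p0 else axb$p1
    d <- vnorm(cterm_a - nterm_b)
    n_loop <- sb$start - sa$end - 1L
    if (d > params$loop_rate * (n_loop + 2 * params$s_max)) return(FALSE)
  }
  TRUE
}

#' Topologies surviving the length and distance screens
#'
#' @param skeletons List of skeleton records.
#' @param segments List of segment records (sequence order).
#' @param params [screening_params()].
#' @return `topology_set` of survivors, with attributes `n_possible` and
#'   `n_valid`.
#' @export
valid_topologies <- function(skeletons, segments,
                             params = screening_params()) {
  K <- length(skeletons)
  N <- length(segments)
  if (K > N) stop("more skeletons than predicted helix segments")
  all_top <- enumerate_topologies(N, K)
  axes <- lapply(skeletons, fit_axis_line)

  # length screen is per (skeleton, segment) pair and direction-free
  len_ok <- matrix(FALSE, nrow = K, ncol = N)
  for (k in seq_len(K))
    for (j in seq_len(N))
      len_ok[k, j] <- length_screen(skeletons[[k]], segments[[j]], params)

  keep <- logical(length(all_top))
  for (i in seq_along(keep)) {
    tp <- topology_at(all_top, i)
    ok <- all(len_ok[cbind(seq_len(K), tp$segments)])
    keep[i] <- ok && distance_screen(tp, axes, segments, params)
  }
  out <- topology_set(all_top$segments[keep, , drop = FALSE],
                      all_top$directions[keep, , drop = FALSE])
  attr(out, "n_possible") <- count_topologies(N, K)
  attr(out, "n_valid") <- sum(keep)
  out
}
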