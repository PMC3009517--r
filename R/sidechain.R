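# Simplified rotamer library and greedy side-chain attachment.
#
# The library ships as a plain-text TSV (inst/extdata/rotamers.tsv): one row
# per atom, columns restype / rotamer / atom / x / y / z, with coordinates
# in a local frame anchored on the residue backbone: origin at CA,
# x along CA->N, y the component of CA->C orthogonal to x, z = x cross y.
# Each residue type carries 1-3 idealised conformations; glycine has an
# empty side chain and alanine a single CB. The downstream contact energy
# depends only on side-chain centroids, so this coarse library is enough to
# rank helix packings.

SIDECHAIN_ATOMS <- list(
  A = "CB",
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  N = c("CB", "CG", "OD1", "ND2"),
  D = c("CB", "CG", "OD1", "OD2"),
  C = c("CB", "SG"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  G = character(0),
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  L = c("CB", "CG", "CD1", "CD2"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  M = c("CB", "CG", "SD", "CE"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  P = c("CB", "CG", "CD"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  V = c("CB", "CG1", "CG2"))

#' Load the rotamer library
#'
#' @param path TSV path; defaults to the library shipped with the package.
#' @return Object of class `rotamer_set`: named list over one-letter residue
#'   types; each element is a list of rotamers, each rotamer a matrix of
#'   local-frame coordinates with atom-name rownames. Glycine is present
#'   with a single empty rotamer.
#' @export
rotamer_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rotamers.tsv", package = "hxskel",
                        mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- list()
  for (ty in unique(df$restype)) {
    sub <- df[df$restype == ty, ]
    rots <- lapply(sort(unique(sub$rotamer)), function(r) {
      rr <- sub[sub$rotamer == r, ]
      m <- as.matrix(rr[, c("x", "y", "z")])
      rownames(m) <- rr$atom
      want <- SIDECHAIN_ATOMS[[ty]]
      if (!identical(rownames(m), want))
        stop("rotamer atoms for ", ty, " do not match the canonical set")
      m
    })
    out[[ty]] <- rots
  }
  out$G <- list(matrix(numeric(0), ncol = 3,
                       dimnames = list(NULL, c("x", "y", "z"))))
  missing <- setdiff(strsplit(AA_LETTERS, "")[[1]], names(out))
  if (length(missing))
    stop("rotamer library misses residue type(s): ",
         paste(missing, collapse = ", "))
  structure(out, class = "rotamer_set")
}

# Local backbone frame of one residue: origin CA, x along CA->N,
# y = component of CA->C orthogonal to x, z = x cross y.
# Returns list(origin, basis) with basis columns x, y, z.
residue_frame <- function(N, CA, C) {
  x <- unitv(N - CA)
  cv <- C - CA
  y <- unitv(cv - sum(cv * x) * x)
  z <- cross3(x, y)
  list(origin = CA, basis = cbind(x, y, z))
}

# World coordinates of one rotamer attached to a residue backbone.
rotamer_world <- function(rot, frame) {
  if (nrow(rot) == 0) return(rot)
  out <- t(frame$basis %*% t(rot)) + rep(frame$origin, each = nrow(rot))
  rownames(out) <- rownames(rot)
  out
}

#' Attach side chains to a placed backbone
#'
#' Greedy, deterministic: residues are visited in sequence order and for
#' each the rotamer with the fewest heavy-atom clashes (pair distance below
#' `clash_cutoff`) against all backbone atoms of other residues and all
#' side chains placed so far is kept; ties go to the first rotamer in
#' library order. `select = "first"` skips the clash search and always
#' takes the first rotamer (the approximation used inside annealing).
#'
#' @param model A `structure_model`.
#' @param rotamers A [rotamer_library()] object.
#' @param select `"clash"` (default) or `"first"`.
#' @param clash_cutoff Heavy-atom clash distance, Angstrom.
#' @return The model with `sc` coordinate matrices filled in per residue.
#' @export
attach_side_chains <- function(model, rotamers = rotamer_library(),
                               select = c("clash", "first"),
                               clash_cutoff = 2.8) {
  select <- match.arg(select)
  res <- model_residue_table(model)
  n_res <- length(res$resno)
  unknown <- setdiff(unique(res$restype), names(rotamers))
  if (length(unknown))
    stop("no rotamers for residue letter(s): ", paste(unknown, collapse = ", "))

  frames <- lapply(seq_len(n_res), function(i) {
    bb <- res$bb[[i]]
    residue_frame(bb["N", ], bb["CA", ], bb["C", ])
  })
  # backbone atoms of all residues, for clash counting
  bb_all <- do.call(rbind, res$bb)
  bb_owner <- rep(seq_len(n_res), each = 4L)

  placed <- NULL   # side-chain atoms already placed
  chosen <- integer(n_res)
  sc <- vector("list", n_res)
  ord <- order(res$resno)
  for (i in ord) {
    rots <- rotamers[[res$restype[i]]]
    if (select == "first" || length(rots) == 1L) {
      pick <- 1L
    } else {
      nclash <- vapply(rots, function(rot) {
        w <- rotamer_world(rot, frames[[i]])
        if (nrow(w) == 0) return(0L)
        others <- bb_all[bb_owner != i, , drop = FALSE]
        if (!is.null(placed)) others <- rbind(others, placed)
        sum(pair_dist_lt(w, others, clash_cutoff))
      }, integer(1))
      pick <- which.min(nclash)   # first minimum = library-order tie-break
    }
    chosen[i] <- pick
    w <- rotamer_world(rots[[pick]], frames[[i]])
    sc[[i]] <- w
    if (nrow(w) > 0 && select == "clash")
      placed <- if (is.null(placed)) w else rbind(placed, w)
  }
  set_model_sidechains(model, sc)
}

# Count of pairs (rows of a x rows of b) closer than cutoff.
pair_dist_lt <- function(a, b, cutoff) {
  if (nrow(a) == 0 || nrow(b) == 0) return(logical(0))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2 < cutoff^2
}

#' Side-chain centroid of one residue
#'
#' Mean of the side-chain heavy atoms; falls back to CA when the side chain
#' is empty (glycine, or not yet attached).
#'
#' @param residue List with `bb` (4 x 3 matrix, rows N/CA/C/O) and
#'   optionally `sc` (side-chain coordinate matrix).
#' @return Length-3 numeric vector.
#' @export
side_chain_centroid <- function(residue) {
  sc <- residue$sc
  if (is.null(sc) || nrow(sc) == 0) return(residue$bb["CA", ])
  colMeans(sc)
}

# First-rotamer local-frame centroid per residue type, used to precompute
# annealing centroids without a clash search.
rotamer_centroid_table <- function(rotamers) {
  t(vapply(names(rotamers), function(ty) {
    rot <- rotamers[[ty]][[1]]
    if (nrow(rot) == 0) c(0, 0, 0) else colMeans(rot)
  }, numeric(3)))
}
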