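# The structure_model container: per-helix backbone (+ optional side
# chains) for the helix portion of the chain only. Residue numbers are the
# assigned 1-based sequence indices.

#' Build a structure model for one topology and placement
#'
#' For every skeleton, the assigned sequence window is derived from the
#' topology and the shift `s`, an ideal helix with the skeleton's estimated
#' residue count is built, and the helix is placed on the fitted axis with
#' the rotation `theta` and axis translation `t`.
#'
#' @param topology List with `segments` and `directions` (one entry per
#'   skeleton, skeleton file order).
#' @param skeletons List of skeleton records.
#' @param segments List of segment records.
#' @param sequence Amino-acid string.
#' @param s,theta,t Numeric vectors, one value per skeleton.
#' @param screening [screening_params()] (controls the residue-count
#'   estimate and the shift bound).
#' @param geom [helix_geometry()].
#' @param rotamers [rotamer_library()] or `NULL` to skip side chains.
#' @param select Side-chain selection mode, see [attach_side_chains()].
#' @return Object of class `structure_model`.
#' @export
build_model <- function(topology, skeletons, segments, sequence,
                        s = NULL, theta = NULL, t = NULL,
                        screening = screening_params(),
                        geom = helix_geometry(),
                        rotamers = rotamer_library(),
                        select = "clash") {
  K <- length(skeletons)
  if (is.null(s)) s <- rep(0L, K)
  if (is.null(theta)) theta <- rep(0, K)
  if (is.null(t)) t <- rep(0, K)
  stopifnot(length(topology$segments) == K, length(s) == K,
            length(theta) == K, length(t) == K)
  seq_len_ <- nchar(sequence)
  helices <- vector("list", K)
  for (k in seq_len(K)) {
    seg <- segments[[topology$segments[k]]]
    ax <- fit_axis_line(skeletons[[k]])
    m <- estimate_skeleton_residues(skeletons[[k]], screening)
    win <- assign_window(seg, m, s[k], seq_len_, screening$s_max)
    if (is.null(win))
      stop("window for skeleton ", k, " cannot be placed on the sequence")
    ideal <- build_ideal_helix(m, geom)
    xyz <- place_helix(ideal, ax, as.integer(topology$directions[k]),
                       theta[k], t[k])
    bb <- aperm(array(t(xyz), dim = c(3L, 4L, m)), c(3L, 2L, 1L))
    dimnames(bb) <- list(NULL, c("N", "CA", "C", "O"), NULL)
    resno <- win[1]:win[2]
    helices[[k]] <- list(
      skeleton_id = skeletons[[k]]$skeleton_id,
      segment_id = seg$segment_id,
      segment_index = topology$segments[k],
      direction = as.integer(topology$directions[k]),
      s = as.integer(s[k]), theta = theta[k], t = t[k],
      resno = resno,
      restype = strsplit(substr(sequence, win[1], win[2]), "")[[1]],
      bb = bb,
      sc = rep(list(NULL), m))
  }
  model <- structure(list(helices = helices, sequence = sequence),
                     class = "structure_model")
  if (!is.null(rotamers))
    model <- attach_side_chains(model, rotamers, select = select)
  model
}

#' @export
print.structure_model <- function(x, ...) {
  n <- sum(vapply(x$helices, function(h) length(h$resno), integer(1)))
  cat(sprintf("structure_model: %d helices, %d residues\n",
              length(x$helices), n))
  invisible(x)
}

# Flat per-residue view: resno, restype, helix index, bb matrices, sc.
model_residue_table <- function(model) {
  resno <- integer(0); restype <- character(0); helix <- integer(0)
  bb <- list(); sc <- list()
  for (k in seq_along(model$helices)) {
    h <- model$helices[[k]]
    for (i in seq_along(h$resno)) {
      resno <- c(resno, h$resno[i]); restype <- c(restype, h$restype[i])
      helix <- c(helix, k)
      m <- h$bb[i, , ]
      rownames(m) <- c("N", "CA", "C", "O")
      bb <- c(bb, list(m))
      sc <- c(sc, list(h$sc[[i]]))
    }
  }
  list(resno = resno, restype = restype, helix = helix, bb = bb, sc = sc)
}

# Write side chains (flat list in model_residue_table row order) back.
set_model_sidechains <- function(model, sc) {
  pos <- 0L
  for (k in seq_along(model$helices)) {
    n <- length(model$helices[[k]]$resno)
    model$helices[[k]]$sc <- sc[pos + seq_len(n)]
    pos <- pos + n
  }
  model
}

# Atom table for PDB output: backbone then side-chain atoms per residue,
# residues in ascending sequence order (helices ordered by first residue).
model_atoms <- function(model) {
  ord <- order(vapply(model$helices, function(h) h$resno[1], integer(1)))
  rows <- list()
  for (k in ord) {
    h <- model$helices[[k]]
    for (i in seq_along(h$resno)) {
      xyz <- h$bb[i, , ]
      elety <- c("N", "CA", "C", "O")
      if (!is.null(h$sc[[i]]) && nrow(h$sc[[i]]) > 0) {
        xyz <- rbind(xyz, h$sc[[i]])
        elety <- c(elety, rownames(h$sc[[i]]))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        resno = h$resno[i], resid = bio3d::aa123(h$restype[i]),
        elety = elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Backbone RMSD between two models over shared helix residues
#'
#' Residues are matched by assigned sequence index; the deviation is
#' computed over the four backbone atoms of every shared residue. By
#' default no superposition is applied, since predicted and reference
#' structures share the density-map frame; with `superpose = TRUE` the
#' optimal rigid superposition (Kabsch) is applied first.
#'
#' @param model,reference A `structure_model`, a [read_backbone_pdb()]
#'   result, or a PDB file path.
#' @param superpose Logical.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(model, reference, superpose = FALSE) {
  a <- backbone_coords(model)
  b <- backbone_coords(reference)
  shared <- intersect(a$resno, b$resno)
  if (length(shared) == 0) stop("models share no residue indices")
  P <- do.call(rbind, lapply(shared, function(r) a$bb[[match(r, a$resno)]]))
  Q <- do.call(rbind, lapply(shared, function(r) b$bb[[match(r, b$resno)]]))
  if (superpose) P <- kabsch_transform(P, Q)
  sqrt(mean(rowSums((P - Q)^2)))
}

# Normalise the accepted reference types to list(resno, bb = list of 4x3).
backbone_coords <- function(x) {
  if (is.character(x)) x <- read_backbone_pdb(x)
  if (inherits(x, "structure_model")) {
    tab <- model_residue_table(x)
    keep <- !duplicated(tab$resno)
    return(list(resno = tab$resno[keep], bb = tab$bb[keep]))
  }
  if (is.list(x) && !is.null(x$resno) && length(dim(x$bb)) == 3) {
    bb <- lapply(seq_along(x$resno), function(i) x$bb[i, , ])
    return(list(resno = x$resno, bb = bb))
  }
  stop("unsupported reference type")
}

# Optimal rigid superposition of P onto Q (rows are matched points).
kabsch_transform <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv <- svd(t(P0) %*% Q0)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(P0 %*% t(R), 2, cq, "+")
}
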