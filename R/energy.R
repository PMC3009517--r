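# Multi-well inter-helix contact energy. Pairwise over residues of
# different helices: a hard-core clash penalty on backbone atoms, then an
# attractive two-step square well on side-chain centroid distances with
# depths set by a residue-class (hydrophobic / polar / charged) table.
# Lower is better; within-helix pairs are excluded because they are
# constant across placements on the same window.

ENERGY_CLASSES <- c("hydrophobic", "polar", "charged")

#' Contact-energy parameters
#'
#' @param r_core Hard-core radius for backbone-backbone clashes, Angstrom.
#' @param r0 Inner edge of the attractive well, Angstrom.
#' @param r1 Outer edge of the deep well, Angstrom.
#' @param r2 Outer edge of the shallow well, Angstrom.
#' @param e_clash Penalty added per clashing residue pair (> 0).
#' @param shallow_factor Depth of the shallow well relative to the deep one.
#' @param eps_hh,eps_hp,eps_hc,eps_pp,eps_pc,eps_cc Symmetric well depths
#'   for the residue-class pairs hydrophobic/polar/charged.
#' @return Object of class `energy_params`; `$eps` is the symmetric 3x3
#'   depth matrix.
#' @export
energy_params <- function(r_core = 3.0, r0 = 4.0, r1 = 8.0, r2 = 10.0,
                          e_clash = 10.0, shallow_factor = 0.5,
                          eps_hh = 2.0, eps_hp = 0.5, eps_hc = 0.3,
                          eps_pp = 0.2, eps_pc = 0.2, eps_cc = 0.1) {
  stopifnot(r_core < r0, r0 < r1, r1 < r2, e_clash > 0,
            min(eps_hh, eps_hp, eps_hc, eps_pp, eps_pc, eps_cc) >= 0)
  eps <- matrix(c(eps_hh, eps_hp, eps_hc,
                  eps_hp, eps_pp, eps_pc,
                  eps_hc, eps_pc, eps_cc), 3, 3,
                dimnames = list(ENERGY_CLASSES, ENERGY_CLASSES))
  structure(list(r_core = r_core, r0 = r0, r1 = r1, r2 = r2,
                 e_clash = e_clash, shallow_factor = shallow_factor,
                 eps = eps),
            class = "energy_params")
}

#' Residue hydrophobicity class
#'
#' Fixed three-way partition: A, V, L, I, M, F, W, C are hydrophobic;
#' D, E, K, R, H are charged; the rest are polar.
#'
#' @param letter One-letter residue code(s).
#' @return Character vector over `"hydrophobic"`, `"polar"`, `"charged"`.
#' @export
classify_residue <- function(letter) {
  letter <- toupper(letter)
  out <- ifelse(letter %in% c("A", "V", "L", "I", "M", "F", "W", "C"),
                "hydrophobic",
                ifelse(letter %in% c("D", "E", "K", "R", "H"),
                       "charged", "polar"))
  bad <- !grepl(sprintf("^[%s]$", AA_LETTERS), letter)
  if (any(bad)) stop("unknown residue letter: ", paste(letter[bad],
                                                       collapse = ", "))
  out
}

class_index <- function(letter) match(classify_residue(letter),
                                      ENERGY_CLASSES)

#' Multi-well inter-helix contact energy of a model
#'
#' For every residue pair (i, j) on different helices: if any of the 16
#' backbone atom pairs is closer than `r_core` the pair contributes
#' `+e_clash`; otherwise the side-chain centroid distance d contributes
#' `-eps` for `r0 <= d < r1`, `-shallow_factor * eps` for `r1 <= d < r2`,
#' and 0 beyond. A single-helix model scores 0.
#'
#' @param model A `structure_model` (side-chain centroids fall back to CA
#'   where side chains are absent).
#' @param params [energy_params()].
#' @return Total energy (dimensionless; lower is better).
#' @export
contact_energy <- function(model, params = energy_params()) {
  hs <- model$helices
  if (length(hs) < 2) return(0)
  per <- lapply(hs, function(h) {
    n <- length(h$resno)
    bb <- matrix(aperm(h$bb, c(2, 1, 3)), nrow = 4L * n)  # atom-major rows
    cent <- t(vapply(seq_len(n), function(i)
      side_chain_centroid(list(bb = {
        m <- h$bb[i, , ]; rownames(m) <- c("N", "CA", "C", "O"); m
      }, sc = h$sc[[i]])), numeric(3)))
    cls <- class_index(h$restype)
    list(n = n, bb = bb, cent = cent, cls = cls)
  })
  total <- 0
  for (a in seq_along(per)) for (b in seq_along(per)) {
    if (a >= b) next
    total <- total + helix_pair_energy(per[[a]], per[[b]], params)
  }
  total
}

helix_pair_energy <- function(A, B, params) {
  # backbone clash: min over the 4x4 atom block per residue pair
  d2 <- sq_dist_matrix(A$bb, B$bb)
  arr <- array(d2, dim = c(4L, A$n, 4L, B$n))
  mind2 <- apply(arr, c(2L, 4L), min)
  clash <- mind2 < params$r_core^2
  # centroid wells
  dc <- sqrt(sq_dist_matrix(A$cent, B$cent))
  depth <- params$eps[A$cls, B$cls, drop = FALSE]
  well <- matrix(0, A$n, B$n)
  well[dc >= params$r0 & dc < params$r1] <- -1
  well[dc >= params$r1 & dc < params$r2] <- -params$shallow_factor
  sum(ifelse(clash, params$e_clash, depth * well))
}

sq_dist_matrix <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  pmax(d2, 0)
}
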