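# Synthetic helix-bundle generator with known ground truth. Emulates the
# inputs the pipeline sees in practice -- axis traces detected in a density
# map plus sequence-predicted helix segments -- at desk scale, so every
# stage is testable without a density map.
#
# Design: an up-down bundle of ideal helices on a circle of axes
# ~10 Angstrom apart, consecutive helices antiparallel so short loops can
# connect them. Sequences follow a coiled-coil-like core pattern:
# residues whose side chains face the bundle core are hydrophobic, the
# rest polar/charged, which gives the contact energy a real signal to
# rank on.

HYDROPHOBIC_POOL <- c("L", "V", "I", "F", "M")
POLAR_POOL <- c("S", "Q", "N", "T", "E", "K")
LOOP_POOL <- c("G", "S", "N")

#' Specification of a synthetic helix bundle
#'
#' @param n_helices Number of helices (2-8).
#' @param helix_lengths Residues per helix; `NULL` draws lengths spread
#'   across 8-20 (evenly spaced targets with +-1 jitter, in random
#'   sequence order). Real helical proteins mix short and long helices,
#'   and the spread is what makes the length screen informative.
#' @param spacing Distance between neighbouring axes, Angstrom.
#' @param loop_range Range the loop lengths are drawn from, residues.
#' @param stagger Standard deviation of the per-helix axial offset of the
#'   helix midpoints, Angstrom. Default 0 (mid-aligned bundle): the
#'   contact energy then has its registration optimum at the native shift,
#'   which is what the recovery experiments probe. Non-zero stagger makes
#'   bundles look more like real proteins but rewards compensating
#'   (non-native) window shifts under a purely pairwise contact score.
#' @param noise Per-point Gaussian sigma added to skeleton points, Angstrom.
#' @param shift_err Maximum magnitude of the integer error added to each
#'   reported segment window (emulates secondary-structure-prediction
#'   inaccuracy); the actual error is drawn from `[-shift_err, shift_err]`.
#' @param drop_shortest Drop the shortest helix from the skeleton file
#'   (emulates an undetectable short helix, giving K < N).
#' @param pad Polar padding residues added at each sequence terminus.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return Object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 3L, helix_lengths = NULL, spacing = 10,
                        loop_range = c(3L, 8L), stagger = 0, noise = 0,
                        shift_err = 0L, drop_shortest = FALSE, pad = 3L,
                        seed = 1L) {
  stopifnot(n_helices >= 2, n_helices <= 8, spacing > 0, stagger >= 0,
            noise >= 0, shift_err >= 0, pad >= 0)
  if (!is.null(helix_lengths))
    stopifnot(length(helix_lengths) == n_helices, all(helix_lengths >= 8),
              all(helix_lengths <= 20))
  structure(list(n_helices = as.integer(n_helices),
                 helix_lengths = helix_lengths, spacing = spacing,
                 loop_range = as.integer(loop_range), stagger = stagger,
                 noise = noise,
                 shift_err = as.integer(shift_err),
                 drop_shortest = isTRUE(drop_shortest),
                 pad = as.integer(pad), seed = as.integer(seed)),
            class = "bundle_spec")
}

#' Generate a synthetic bundle with ground truth
#'
#' @param spec A [bundle_spec()].
#' @param dir Output directory; when given, writes `skeletons.tsv`,
#'   `sequence.fasta`, `segments.tsv`, `native.pdb` and `truth.yaml`.
#' @param geom [helix_geometry()] used for the native helices.
#' @return List with `skeletons`, `sequence`, `segments`, and `truth`
#'   (list: `topology` for the emitted skeletons, `windows` of the native
#'   helices, `native` structure model, `dropped` index or `NULL`).
#' @export
make_bundle <- function(spec, dir = NULL, geom = helix_geometry()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  for (attempt in 1:20) {
    b <- build_bundle_once(spec, geom)
    if (!is.null(b)) break
    b <- NULL
  }
  if (is.null(b)) stop("could not generate a collision-free bundle")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_skeletons(b$skeletons, file.path(dir, "skeletons.tsv"))
    write_sequence(b$sequence, file.path(dir, "sequence.fasta"), "bundle")
    write_segments(b$segments, file.path(dir, "segments.tsv"))
    write_model_pdb(b$truth$native, file.path(dir, "native.pdb"))
    yaml::write_yaml(list(topology = topology_string(b$truth$topology),
                          windows = lapply(b$truth$windows, as.integer),
                          dropped = b$truth$dropped),
                     file.path(dir, "truth.yaml"))
  }
  b
}

build_bundle_once <- function(spec, geom) {
  n <- spec$n_helices
  lens <- spec$helix_lengths
  if (is.null(lens)) {
    lens <- round(seq(8, 20, length.out = n)) + sample(-1:1, n,
                                                       replace = TRUE)
    lens <- pmin(20L, pmax(8L, as.integer(lens)))[sample.int(n)]
  }
  loops <- sample(seq(spec$loop_range[1], spec$loop_range[2]),
                  n - 1L, replace = TRUE)

  # axis layout: circle with neighbour spacing `spacing`, axes along z,
  # consecutive helices antiparallel
  r <- if (n == 2) spec$spacing / 2 else spec$spacing / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  centers <- cbind(r * cos(ang), r * sin(ang))
  dirs <- ifelse(seq_len(n) %% 2L == 1L, 1L, -1L)

  z_off <- stats::rnorm(n, 0, spec$stagger)

  ideals <- lapply(lens, build_ideal_helix, geom = geom)
  axes <- vector("list", n)
  native_xyz <- vector("list", n)
  for (j in seq_len(n)) {
    L <- ideals[[j]]$rise * (lens[j] - 1L)
    p0 <- c(centers[j, ], z_off[j] - L / 2)
    p1 <- c(centers[j, ], z_off[j] + L / 2)
    axes[[j]] <- list(point = c(centers[j, ], z_off[j]), dir = c(0, 0, 1),
                      length = L, p0 = p0, p1 = p1, residual = 0)
    native_xyz[[j]] <- place_helix(ideals[[j]], axes[[j]], dirs[j],
                                   theta = 0, t = 0)
  }

  # collision check: inter-helix backbone atoms must stay >= 4 Angstrom
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    d2 <- sq_dist_matrix(native_xyz[[a]], native_xyz[[b]])
    if (min(d2) < 16) return(NULL)
  }

  # sequence design: hydrophobic where the side chain faces the core.
  # The ~65 degree inward sector corresponds to the heptad a/d positions
  # plus their natural wobble; at ~10 A spacing every such residue packs
  # against the neighbouring helices' core stripes.
  cand <- vector("list", n)
  for (j in seq_len(n)) {
    xyz <- native_xyz[[j]]
    facing <- logical(lens[j])
    for (i in seq_len(lens[j])) {
      rows <- (i - 1L) * 4L + 1:3
      fr <- residue_frame(xyz[rows[1], ], xyz[rows[2], ], xyz[rows[3], ])
      ca <- xyz[rows[2], ]
      cb <- fr$origin + as.vector(fr$basis %*% CB_LOCAL)
      v <- (cb - ca)[1:2]
      core <- -ca[1:2]                       # towards the bundle axis
      facing[i] <- sum(v * core) / sqrt(sum(v^2) * sum(core^2)) >
        cos(65 * pi / 180)
    }
    cand[[j]] <- facing
  }
  helix_seq <- vector("list", n)
  for (j in seq_len(n)) {
    letters <- character(lens[j])
    for (i in seq_len(lens[j]))
      letters[i] <- if (cand[[j]][i]) sample(HYDROPHOBIC_POOL, 1)
                    else sample(POLAR_POOL, 1)
    helix_seq[[j]] <- letters
  }

  # assemble sequence: pad + helix1 + loop1 + helix2 + ... + pad
  pad <- function(k) sample(POLAR_POOL, k, replace = TRUE)
  pieces <- list(pad(spec$pad))
  windows <- vector("list", n)
  pos <- spec$pad
  for (j in seq_len(n)) {
    windows[[j]] <- c(pos + 1L, pos + lens[j])
    pieces <- c(pieces, list(helix_seq[[j]]))
    pos <- pos + lens[j]
    if (j < n) {
      pieces <- c(pieces, list(sample(LOOP_POOL, loops[j], replace = TRUE)))
      pos <- pos + loops[j]
    }
  }
  pieces <- c(pieces, list(pad(spec$pad)))
  sequence <- paste0(unlist(pieces), collapse = "")

  # reported segments, with optional SSP-style shift error
  segments <- vector("list", n)
  for (j in seq_len(n)) {
    err <- if (spec$shift_err > 0)
      sample(seq(-spec$shift_err, spec$shift_err), 1) else 0L
    segments[[j]] <- structure(list(segment_id = paste0("H", j),
                                    start = windows[[j]][1] + err,
                                    end = windows[[j]][2] + err,
                                    sstype = "H"), class = "segment")
  }
  names(segments) <- paste0("H", seq_len(n))

  # skeleton polylines sampled along each axis, low z to high z. Stick
  # length uses 1.3 A per residue: detector sticks end where the helix
  # density tapers, which is what the 1.3 A/residue estimation constant
  # is calibrated to (the backbone itself rises ~1.5 A/residue).
  skeletons <- vector("list", n)
  for (j in seq_len(n)) {
    stick <- 1.3 * (lens[j] - 1L)
    mid <- (axes[[j]]$p0 + axes[[j]]$p1) / 2
    sp0 <- mid - c(0, 0, stick / 2)
    sp1 <- mid + c(0, 0, stick / 2)
    npts <- max(3L, ceiling(stick / 3))
    tt <- seq(0, 1, length.out = npts)
    pts <- outer(rep(1, npts), sp0) + outer(tt, sp1 - sp0)
    if (spec$noise > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$noise),
                          nrow = npts)
    skeletons[[j]] <- structure(list(skeleton_id = paste0("S", j),
                                     points = pts), class = "skeleton")
  }

  # native model (for truth / RMSD): exact windows on the native axes
  helices <- vector("list", n)
  for (j in seq_len(n)) {
    bb <- aperm(array(t(native_xyz[[j]]), dim = c(3L, 4L, lens[j])),
                c(3L, 2L, 1L))
    dimnames(bb) <- list(NULL, c("N", "CA", "C", "O"), NULL)
    helices[[j]] <- list(skeleton_id = paste0("S", j),
                         segment_id = paste0("H", j), segment_index = j,
                         direction = dirs[j], s = 0L, theta = 0, t = 0,
                         resno = windows[[j]][1]:windows[[j]][2],
                         restype = helix_seq[[j]], bb = bb,
                         sc = rep(list(NULL), lens[j]))
  }
  native <- structure(list(helices = helices, sequence = sequence),
                      class = "structure_model")
  native <- attach_side_chains(native)

  dropped <- NULL
  truth_topology <- list(segments = seq_len(n), directions = dirs)
  if (spec$drop_shortest) {
    dropped <- which.min(lens)
    skeletons <- skeletons[-dropped]
    truth_topology <- list(segments = setdiff(seq_len(n), dropped),
                           directions = dirs[-dropped])
  }
  names(skeletons) <- vapply(skeletons, function(s) s$skeleton_id,
                             character(1))

  list(skeletons = skeletons, sequence = sequence, segments = segments,
       truth = list(topology = truth_topology, windows = windows,
                    native = native, dropped = dropped))
}

# Idealised CB position in the residue backbone frame (origin CA, x along
# CA->N, y from CA->C): tetrahedral branch at 1.53 Angstrom.
CB_LOCAL <- local({
  a <- cos(110.5 * pi / 180)
  g <- 111.2 * pi / 180
  b <- (cos(110.1 * pi / 180) - a * cos(g)) / sin(g)
  cc <- sqrt(max(0, 1 - a^2 - b^2))
  1.53 * c(a, b, cc)
})
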