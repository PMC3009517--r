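# Simulated-annealing sampling of placements per valid topology, pool
# ranking, rank percentiles, and lazy two-region combination.

#' Annealing schedule
#'
#' Geometric cooling from `T0` by factor `alpha` down to `T_min`, with
#' `steps_per_T` Metropolis moves per temperature. Each move perturbs one
#' skeleton's placement: the shift by +-1 residue, the axis rotation by a
#' Gaussian step, or (when enabled) the axis translation by a Gaussian
#' step.
#'
#' @param T0 Initial temperature, energy units. The default (2.0) sits
#'   just above the acceptance knee of typical contact-energy move sizes,
#'   so the whole schedule is spent in the productive range rather than in
#'   free diffusion.
#' @param alpha Geometric cooling factor in (0, 1).
#' @param steps_per_T Moves per temperature level.
#' @param T_min Final temperature; at 0.02 a typical uphill move is
#'   accepted with probability well below 1e-5, i.e. the run ends in a
#'   quench.
#' @param sigma_theta Rotation proposal width, degrees.
#' @param sigma_t Translation proposal width, Angstrom.
#' @param t_max Bound on the axial translation when it is sampled,
#'   Angstrom (moves beyond `[-t_max, t_max]` are rejected). One helical
#'   rise: the translation covers sub-residue axial adjustment, while
#'   whole-residue re-registration is the shift's job.
#' @param t_enabled Sample the axis translation as well (default `FALSE`:
#'   translation stays 0, the usual simplification for rod-like density).
#' @return Object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T0 = 2.0, alpha = 0.95, steps_per_T = 30L,
                            T_min = 0.02, sigma_theta = 20, sigma_t = 0.5,
                            t_max = 1.5, t_enabled = FALSE) {
  stopifnot(alpha > 0, alpha < 1, T_min > 0, T_min < T0, steps_per_T >= 1,
            t_max >= 0)
  structure(list(T0 = T0, alpha = alpha,
                 steps_per_T = as.integer(steps_per_T), T_min = T_min,
                 sigma_theta = sigma_theta, sigma_t = sigma_t,
                 t_max = t_max, t_enabled = isTRUE(t_enabled)),
            class = "anneal_schedule")
}

# Per-topology precomputation handed to the C++ annealer: placement bases,
# local backbone coordinates, and per-shift residue classes / local
# side-chain centroids (first rotamer, no clash search).
topology_precompute <- function(topology, skeletons, segments, sequence,
                                screening = screening_params(),
                                geom = helix_geometry(),
                                rotamers = rotamer_library(),
                                cache = new.env(parent = emptyenv())) {
  K <- length(skeletons)
  seq_len_ <- nchar(sequence)
  cent_tab <- get_cached(cache, ".cent_tab", rotamer_centroid_table(rotamers))
  s_grid <- -screening$s_max:screening$s_max
  out <- vector("list", K)
  for (k in seq_len(K)) {
    ax <- get_cached(cache, paste0("ax", k), fit_axis_line(skeletons[[k]]))
    m <- get_cached(cache, paste0("m", k),
                    estimate_skeleton_residues(skeletons[[k]], screening))
    ideal <- get_cached(cache, paste0("ideal", m), build_ideal_helix(m, geom))
    frames <- get_cached(cache, paste0("frames", m), local_frames(ideal))
    seg <- segments[[topology$segments[k]]]
    cls <- vector("list", length(s_grid))
    cent <- vector("list", length(s_grid))
    svalid <- logical(length(s_grid))
    win_start <- integer(length(s_grid))
    win_end <- rep(-1L, length(s_grid))   # empty window when invalid
    for (si in seq_along(s_grid)) {
      win <- assign_window(seg, m, s_grid[si], seq_len_, screening$s_max)
      if (is.null(win)) next
      svalid[si] <- TRUE
      win_start[si] <- win[1]
      win_end[si] <- win[2]
      letters <- strsplit(substr(sequence, win[1], win[2]), "")[[1]]
      cls[[si]] <- class_index(letters)
      loc <- matrix(0, m, 3)
      for (i in seq_len(m)) {
        off <- cent_tab[letters[i], ]
        loc[i, ] <- frames[[i]]$origin + as.vector(frames[[i]]$basis %*% off)
      }
      cent[[si]] <- loc
    }
    if (!any(svalid))
      stop("no valid shift for skeleton ", k, " under this topology")
    out[[k]] <- list(B = placement_basis(ax, as.integer(topology$directions[k])),
                     u = ax$dir, center = (ax$p0 + ax$p1) / 2,
                     m = as.integer(m), bb = ideal$xyz,
                     cls = cls, cent = cent, svalid = svalid,
                     win_start = win_start, win_end = win_end)
  }
  out
}

get_cached <- function(cache, key, value) {
  if (!exists(key, envir = cache, inherits = FALSE))
    assign(key, value, envir = cache)
  get(key, envir = cache, inherits = FALSE)
}

# Backbone frames of every residue of an ideal helix, in its local frame.
local_frames <- function(ideal) {
  lapply(seq_len(ideal$n), function(i) {
    rows <- (i - 1L) * 4L + 1:3
    residue_frame(ideal$xyz[rows[1], ], ideal$xyz[rows[2], ],
                  ideal$xyz[rows[3], ])
  })
}

#' Sample placements for one topology by simulated annealing
#'
#' Runs `n_samples` independent annealing runs; run `r` of topology
#' `topo_index` under master seed `seed` uses a deterministically derived
#' sub-seed, so results are bit-reproducible and independent of how
#' topologies are distributed over workers.
#'
#' @param topology List with `segments` and `directions`.
#' @param skeletons,segments,sequence Inputs as elsewhere.
#' @param n_samples Number of annealing runs.
#' @param schedule [anneal_schedule()].
#' @param energy [energy_params()].
#' @param screening [screening_params()].
#' @param geom [helix_geometry()].
#' @param rotamers [rotamer_library()].
#' @param seed Master seed (non-negative integer).
#' @param topo_index Index of this topology in the enumeration order.
#' @return List with matrices `s`, `theta`, `t` (rows = samples, columns =
#'   skeletons) and vectors `energy`, `energy0` (initial-state energy).
#' @export
sample_topology <- function(topology, skeletons, segments, sequence,
                            n_samples = 500L,
                            schedule = anneal_schedule(),
                            energy = energy_params(),
                            screening = screening_params(),
                            geom = helix_geometry(),
                            rotamers = rotamer_library(),
                            seed = 1L, topo_index = 1L) {
  pre <- topology_precompute(topology, skeletons, segments, sequence,
                             screening, geom, rotamers)
  res <- anneal_topology_cpp(pre, unclass(schedule), unclass(energy),
                             as.integer(n_samples), as.double(seed),
                             as.integer(topo_index))
  s_grid <- -screening$s_max:screening$s_max
  list(s = matrix(s_grid[res$s_index + 1L], nrow = n_samples),
       theta = res$theta, t = res$t,
       energy = as.vector(res$energy), energy0 = as.vector(res$energy0))
}

#' Rank a pool of sampled placements by energy
#'
#' Stable ascending sort; ties broken by topology enumeration order, then
#' sample index.
#'
#' @param entries Data frame with columns `topo_index`, `sample`, `energy`
#'   and per-skeleton `s_<k>`, `theta_<k>`, `t_<k>` columns.
#' @param meta List of pool metadata (topologies, skeletons, segments,
#'   counts); assembled by [predict_structures()].
#' @return Object of class `ranked_pool`.
#' @export
rank_pool <- function(entries, meta = list()) {
  ord <- order(entries$energy, entries$topo_index, entries$sample)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  entries$rank <- seq_len(nrow(entries))
  structure(list(entries = entries, meta = meta), class = "ranked_pool")
}

#' @export
length.ranked_pool <- function(x) nrow(x$entries)

#' @export
print.ranked_pool <- function(x, ...) {
  cat(sprintf("ranked_pool: %d structures", length(x)))
  if (!is.null(x$meta$n_valid))
    cat(sprintf(" (%g possible topologies, %d valid)",
                x$meta$n_possible, x$meta$n_valid))
  cat("\n")
  if (length(x) > 0)
    cat(sprintf("  best energy %.3f, worst %.3f\n",
                x$entries$energy[1], x$entries$energy[length(x)]))
  invisible(x)
}

#' @export
as.data.frame.ranked_pool <- function(x, ...) {
  e <- x$entries
  K <- x$meta$K
  out <- data.frame(rank = e$rank, topology = e$topology,
                    stringsAsFactors = FALSE)
  if (!is.null(K)) {
    ids <- x$meta$skeleton_ids
    segids <- vapply(x$meta$segments, function(s) s$segment_id, character(1))
    for (k in seq_len(K)) {
      out[[paste0(ids[k], "_segment")]] <- segids[e[[paste0("seg_", k)]]]
      out[[paste0(ids[k], "_dir")]] <- e[[paste0("dir_", k)]]
      out[[paste0(ids[k], "_s")]] <- e[[paste0("s_", k)]]
      out[[paste0(ids[k], "_theta")]] <- e[[paste0("theta_", k)]]
      out[[paste0(ids[k], "_t")]] <- e[[paste0("t_", k)]]
    }
  }
  out$energy <- e$energy
  if (!is.null(e$rmsd)) out$rmsd <- e$rmsd
  out
}

#' Rank percentile
#'
#' @param rank 1-based rank in the pool.
#' @param pool_size Pool size.
#' @return `100 * rank / pool_size`, rounded to 2 decimals.
#' @export
percentile_of_rank <- function(rank, pool_size) {
  stopifnot(pool_size >= 1, rank >= 1)
  round(100 * rank / pool_size, 2)
}

#' Candidate pair count when combining two region pools
#'
#' The Cartesian product size before conflict screening.
#' @param n_a,n_b Pool sizes.
#' @return Double (exact below 2^53).
#' @export
combined_pool_size <- function(n_a, n_b) as.numeric(n_a) * as.numeric(n_b)

#' End-to-end prediction for one set of skeletons
#'
#' Screens the topology space, runs `samples` annealing runs for every
#' valid topology, and returns the energy-ranked pool. With `workers > 1`
#' topologies are annealed in parallel (forked processes); results are
#' identical for any worker count because every run's sub-seed depends only
#' on (seed, topology index, run index).
#'
#' @param skeletons List of skeleton records (or a skeleton TSV path).
#' @param sequence Amino-acid string (or a FASTA path).
#' @param segments List of segment records (or a segment TSV path).
#' @param config Parameter set from [read_config()].
#' @param samples Annealing runs per valid topology.
#' @param seed Master seed.
#' @param workers Number of parallel workers.
#' @return A `ranked_pool`; `$meta` carries the run report
#'   (`n_possible`, `n_valid`, `n_generated`) and enough metadata to
#'   rebuild any entry's model via [pool_model()].
#' @export
predict_structures <- function(skeletons, sequence, segments,
                               config = read_config(), samples = 500L,
                               seed = 1L, workers = 1L) {
  if (is.character(skeletons)) skeletons <- read_skeletons(skeletons)
  if (is.character(sequence) && file.exists(sequence) &&
      grepl("\\.(fa|fasta|fsa)$", sequence, ignore.case = TRUE))
    sequence <- read_sequence(sequence)
  if (is.character(segments)) segments <- read_segments(segments,
                                                        nchar(sequence))
  rotamers <- rotamer_library()
  vt <- valid_topologies(skeletons, segments, config$screening)
  K <- length(skeletons)
  nv <- length(vt)
  run_one <- function(i) {
    tp <- topology_at(vt, i)
    sample_topology(tp, skeletons, segments, sequence, samples,
                    config$sampling, config$energy, config$screening,
                    config$geometry, rotamers, seed = seed, topo_index = i)
  }
  res <- if (workers > 1L && nv > 1L)
    parallel::mclapply(seq_len(nv), run_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  else lapply(seq_len(nv), run_one)

  entries <- do.call(rbind, lapply(seq_len(nv), function(i) {
    r <- res[[i]]
    tp <- topology_at(vt, i)
    df <- data.frame(topo_index = i, sample = seq_len(samples),
                     topology = topology_string(tp),
                     energy = r$energy, energy0 = r$energy0,
                     stringsAsFactors = FALSE)
    for (k in seq_len(K)) {
      df[[paste0("seg_", k)]] <- tp$segments[k]
      df[[paste0("dir_", k)]] <- tp$directions[k]
      df[[paste0("s_", k)]] <- r$s[, k]
      df[[paste0("theta_", k)]] <- r$theta[, k]
      df[[paste0("t_", k)]] <- r$t[, k]
    }
    df
  }))
  meta <- list(K = K,
               skeleton_ids = vapply(skeletons, function(s) s$skeleton_id,
                                     character(1)),
               skeletons = skeletons, segments = segments,
               sequence = sequence, config = config,
               skeleton_residues = vapply(skeletons, function(sk)
                 estimate_skeleton_residues(sk, config$screening),
                 integer(1)),
               topologies = vt, samples = samples, seed = seed,
               n_possible = attr(vt, "n_possible"),
               n_valid = attr(vt, "n_valid"),
               n_generated = attr(vt, "n_valid") * samples)
  rank_pool(entries, meta)
}

#' Rebuild the structure model of one pool entry
#'
#' @param pool A `ranked_pool` from [predict_structures()].
#' @param rank Rank of the entry to rebuild.
#' @param select Side-chain selection mode, see [attach_side_chains()].
#' @return A `structure_model`.
#' @export
pool_model <- function(pool, rank = 1L, select = "clash") {
  e <- pool$entries[pool$entries$rank == rank, ]
  if (nrow(e) != 1) stop("no entry with rank ", rank)
  m <- pool$meta
  K <- m$K
  tp <- list(segments = as.integer(unlist(e[paste0("seg_", seq_len(K))])),
             directions = as.integer(unlist(e[paste0("dir_", seq_len(K))])))
  build_model(tp, m$skeletons, m$segments, m$sequence,
              s = as.integer(unlist(e[paste0("s_", seq_len(K))])),
              theta = as.numeric(unlist(e[paste0("theta_", seq_len(K))])),
              t = as.numeric(unlist(e[paste0("t_", seq_len(K))])),
              screening = m$config$screening, geom = m$config$geometry,
              select = select)
}

#' Combine two independently predicted local regions
#'
#' Candidate pairs form the Cartesian product of the two pools, ranked by
#' summed energy; the product is never materialised. Pairs in which the two
#' regions claim a common sequence residue (after shifts) conflict and are
#' dropped. The two regions must use disjoint skeleton sets.
#'
#' @param pool_a,pool_b `ranked_pool`s for the two regions.
#' @param top_pairs Number of surviving pairs to return.
#' @return Object of class `combined_pool`: `$pairs` data frame with rank,
#'   the two entry ranks, and summed energy; `$prescreen_pairs` the
#'   Cartesian product size; `$n_conflict` conflicts skipped on the way.
#' @export
combine_regions <- function(pool_a, pool_b, top_pairs = 100L) {
  if (length(intersect(pool_a$meta$skeleton_ids,
                       pool_b$meta$skeleton_ids)) > 0)
    stop("regions share skeleton ids")
  na <- length(pool_a); nb <- length(pool_b)
  if (na == 0 || nb == 0) stop("empty pool")
  wa <- lapply(seq_len(na), function(i) entry_residues(pool_a, i))
  wb <- lapply(seq_len(nb), function(i) entry_residues(pool_b, i))
  ea <- pool_a$entries$energy; eb <- pool_b$entries$energy

  # lazy k-smallest-sums walk over the two sorted lists
  heap_key <- numeric(0); heap_i <- integer(0); heap_j <- integer(0)
  seen <- new.env(parent = emptyenv())
  push <- function(i, j) {
    if (i > na || j > nb) return()
    key <- paste0(i, "_", j)
    if (exists(key, envir = seen, inherits = FALSE)) return()
    assign(key, TRUE, envir = seen)
    heap_key <<- c(heap_key, ea[i] + eb[j])
    heap_i <<- c(heap_i, i); heap_j <<- c(heap_j, j)
  }
  push(1L, 1L)
  out <- list(); n_conflict <- 0L
  while (length(out) < top_pairs && length(heap_key) > 0) {
    w <- which.min(heap_key)
    i <- heap_i[w]; j <- heap_j[w]; esum <- heap_key[w]
    heap_key <- heap_key[-w]; heap_i <- heap_i[-w]; heap_j <- heap_j[-w]
    if (length(intersect(wa[[i]], wb[[j]])) == 0)
      out[[length(out) + 1L]] <- c(i, j, esum)
    else n_conflict <- n_conflict + 1L
    push(i + 1L, j)
    push(i, j + 1L)
  }
  pairs <- if (length(out))
    data.frame(rank = seq_along(out),
               rank_a = vapply(out, `[`, numeric(1), 1),
               rank_b = vapply(out, `[`, numeric(1), 2),
               energy = vapply(out, `[`, numeric(1), 3))
  else data.frame(rank = integer(0), rank_a = numeric(0),
                  rank_b = numeric(0), energy = numeric(0))
  structure(list(pairs = pairs,
                 prescreen_pairs = combined_pool_size(na, nb),
                 n_conflict = n_conflict),
            class = "combined_pool")
}

# Sequence residues occupied by pool entry at rank i (all skeleton windows).
entry_residues <- function(pool, i) {
  e <- pool$entries[i, ]
  m <- pool$meta
  res <- integer(0)
  for (k in seq_len(m$K)) {
    seg <- m$segments[[e[[paste0("seg_", k)]]]]
    win <- assign_window(seg, m$skeleton_residues[k], e[[paste0("s_", k)]],
                         nchar(m$sequence), m$config$screening$s_max)
    if (!is.null(win)) res <- c(res, win[1]:win[2])
  }
  unique(res)
}
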