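# Readers and writers for every external representation the pipeline
# touches: skeleton polylines (TSV), sequences (FASTA), predicted helix
# segments (TSV), structure models (PDB), ranked pools (CSV) and the
# parameter config (YAML). All residue indices in external files are
# 1-based inclusive.

#' Read helix-axis skeletons from a TSV file
#'
#' Expected columns (tab-separated, with header):
#' `skeleton_id  point_index  x  y  z`, coordinates in Angstrom, points
#' grouped by id and ordered by `point_index`.
#'
#' @param path File path.
#' @return List of `skeleton` records, each a list with `skeleton_id` and a
#'   point matrix `points` (rows ordered by point index).
#' @export
read_skeletons <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "numeric",
                                         "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  need <- c("skeleton_id", "point_index", "x", "y", "z")
  if (!identical(names(df), need))
    stop("skeleton file must have columns: ", paste(need, collapse = ", "))
  if (anyNA(df)) stop("non-numeric or missing value in skeleton file")
  if (anyDuplicated(df[, c("skeleton_id", "point_index")]))
    stop("duplicate (skeleton_id, point_index) row")
  ids <- unique(df$skeleton_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$skeleton_id == id, ]
    rows <- rows[order(rows$point_index), ]
    pts <- as.matrix(rows[, c("x", "y", "z")])
    dimnames(pts) <- NULL
    if (nrow(pts) < 2) stop("skeleton '", id, "' has fewer than 2 points")
    if (any(sqrt(rowSums(diff(pts)^2)) < 1e-9))
      stop("skeleton '", id, "' has coincident consecutive points")
    structure(list(skeleton_id = id, points = pts), class = "skeleton")
  })
  names(out) <- ids
  out
}

#' Write skeleton records to TSV
#' @param skeletons List of skeleton records.
#' @param path Output path.
#' @export
write_skeletons <- function(skeletons, path) {
  rows <- do.call(rbind, lapply(skeletons, function(s) {
    data.frame(skeleton_id = s$skeleton_id,
               point_index = seq_len(nrow(s$points)),
               x = s$points[, 1], y = s$points[, 2], z = s$points[, 3])
  }))
  write_tsv_fixed(rows, path, num_format = "%.4f")
  invisible(NULL)
}

#' Read a single-record FASTA protein sequence
#'
#' @param path File path.
#' @return Uppercase amino-acid string.
#' @export
read_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file")
  headers <- grep("^>", lines)
  if (length(headers) != 1 || headers[1] != 1)
    stop("expected exactly one FASTA record")
  seq <- toupper(paste0(trimws(lines[-1]), collapse = ""))
  if (nchar(seq) < 1) stop("empty sequence")
  if (grepl(sprintf("[^%s]", AA_LETTERS), seq))
    stop("sequence contains letters outside the 20 standard amino acids")
  seq
}

AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWY"

#' Write a sequence as single-record FASTA
#' @param sequence Amino-acid string.
#' @param path Output path.
#' @param name Record name.
#' @export
write_sequence <- function(sequence, path, name = "seq") {
  writeLines(c(paste0(">", name),
               substring(sequence, seq(1, nchar(sequence), 60),
                         pmin(seq(1, nchar(sequence), 60) + 59,
                              nchar(sequence)))), path)
  invisible(NULL)
}

#' Read predicted helix segments from TSV
#'
#' Expected columns `segment_id  start  end  sstype` (tab-separated,
#' header), indices 1-based inclusive, `sstype` must be `H`. Segments must
#' be non-overlapping and listed in increasing start order.
#'
#' @param path File path.
#' @param seq_len Length of the sequence the indices refer to.
#' @return List of `segment` records (`segment_id`, `start`, `end`,
#'   `sstype`).
#' @export
read_segments <- function(path, seq_len) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "character"),
                          stringsAsFactors = FALSE)
  need <- c("segment_id", "start", "end", "sstype")
  if (!identical(names(df), need))
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  if (anyNA(df)) stop("missing or malformed value in segment file")
  if (any(df$sstype != "H")) stop("only helix ('H') segments are accepted")
  if (any(df$start < 1 | df$end > seq_len | df$start > df$end))
    stop("segment indices out of range for sequence of length ", seq_len)
  if (is.unsorted(df$start, strictly = TRUE))
    stop("segments must be listed in increasing start order")
  if (any(utils::head(df$end, -1) >= utils::tail(df$start, -1)))
    stop("segments overlap")
  out <- lapply(seq_len(nrow(df)), function(i)
    structure(list(segment_id = df$segment_id[i], start = df$start[i],
                   end = df$end[i], sstype = "H"), class = "segment"))
  names(out) <- df$segment_id
  out
}

#' Write segment records to TSV
#' @param segments List of segment records.
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  rows <- do.call(rbind, lapply(segments, function(s)
    data.frame(segment_id = s$segment_id, start = s$start, end = s$end,
               sstype = s$sstype)))
  write_tsv_fixed(rows, path)
  invisible(NULL)
}

#' Write a structure model as PDB
#'
#' ATOM records for the helix residues only (the method never builds
#' loops), chain A, residue numbers equal to the assigned sequence indices.
#'
#' @param model A `structure_model` (see [build_model()]).
#' @param path Output path.
#' @export
write_model_pdb <- function(model, path) {
  at <- model_atoms(model)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, elety = at$elety,
                   chain = rep("A", nrow(at)), eleno = seq_len(nrow(at)))
  invisible(NULL)
}

#' Read a PDB file into per-residue backbone records
#'
#' Used both for model round trips and for reference structures in RMSD
#' evaluation. Only N, CA, C, O atoms are retained.
#'
#' @param path PDB file path.
#' @return List with `resno`, `restype` (one-letter) and `bb`, an
#'   `n x 4 x 3` array (atom order N, CA, C, O).
#' @export
read_backbone_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$elety %in% c("N", "CA", "C", "O"), ]
  resnos <- unique(at$resno)
  bb <- array(NA_real_, dim = c(length(resnos), 4L, 3L),
              dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  restype <- character(length(resnos))
  for (i in seq_along(resnos)) {
    rows <- at[at$resno == resnos[i], ]
    restype[i] <- bio3d::aa321(rows$resid[1])
    for (a in c("N", "CA", "C", "O")) {
      r <- rows[rows$elety == a, ][1, ]
      bb[i, a, ] <- c(r$x, r$y, r$z)
    }
  }
  if (anyNA(bb)) stop("incomplete backbone in ", path)
  list(resno = resnos, restype = restype, bb = bb)
}

#' Write a ranked pool to CSV
#'
#' Columns: `rank`, `topology`, per-skeleton `<id>_segment`, `<id>_dir`,
#' `<id>_s`, `<id>_theta`, `<id>_t`, then `energy` and (when present)
#' `rmsd`. Rows ascend in energy; numeric columns use fixed formatting so
#' identical pools serialise to identical bytes.
#'
#' @param pool A `ranked_pool`.
#' @param path Output path.
#' @export
write_ranked_csv <- function(pool, path) {
  df <- as.data.frame(pool)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.6f", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

# Fixed-format TSV writer shared by the skeleton/segment writers.
write_tsv_fixed <- function(df, path, num_format = NULL) {
  if (!is.null(num_format))
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf(num_format, df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a YAML parameter config
#'
#' Recognised sections: `screening`, `geometry`, `energy`, `sampling`.
#' Every entry overrides the corresponding default parameter; unknown keys
#' are an error.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with elements `screening` ([screening_params()]),
#'   `geometry` ([helix_geometry()]), `energy` ([energy_params()]) and
#'   `sampling` ([anneal_schedule()]).
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), c("screening", "geometry", "energy", "sampling"))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  build <- function(fn, args) {
    if (is.null(args)) return(fn())
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  list(screening = build(screening_params, cfg$screening),
       geometry = build(helix_geometry, cfg$geometry),
       energy = build(energy_params, cfg$energy),
       sampling = build(anneal_schedule, cfg$sampling))
}
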