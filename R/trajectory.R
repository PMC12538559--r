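#' Trajectory container
#'
#' Time-ordered coordinate frames with a periodic box and a uniform frame
#' interval. Coordinates are stored as an `n_atoms x 3 x n_frames` array in
#' nm, times in ps.
#'
#' @param coords `n_atoms x 3 x n_frames` numeric array (nm).
#' @param times Frame times in ps, strictly increasing and equally spaced.
#' @param box Length-3 box vector (nm) or an `n_frames x 3` matrix.
#' @param periodic Logical: apply minimum-image convention in distance
#'   computations.
#' @param dt_tol Relative tolerance on frame-interval uniformity.
#' @return An object of class `stack_trajectory` with a `dt_frame` element.
#' @export
stack_trajectory <- function(coords, times, box, periodic = TRUE,
                             dt_tol = 1e-6) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_frames <- dim(coords)[3]
  if (length(times) != n_frames) stop("times length must match frame count")
  if (n_frames > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) {
      stop("frame times not strictly increasing at frame ",
           which(dts <= 0)[1] + 1L)
    }
    dt <- stats::median(dts)
    bad <- which(abs(dts - dt) > dt_tol * max(dt, 1))
    if (length(bad)) {
      stop("non-uniform frame sampling at frame ", bad[1] + 1L,
           " (dt = ", signif(dts[bad[1]], 6), ", expected ", signif(dt, 6), ")")
    }
  } else dt <- NA_real_
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 periodic = isTRUE(periodic), dt_frame = dt),
            class = "stack_trajectory")
}

#' @export
print.stack_trajectory <- function(x, ...) {
  cat("stack_trajectory:", dim(x$coords)[1], "atoms x", dim(x$coords)[3],
      "frames, dt =", x$dt_frame, "ps, box =",
      paste(signif(x$box[1, ], 4), collapse = " x "), "nm\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
frame_coords <- function(traj, i) traj$coords[, , i]

#' Read a coordinate trajectory
#'
#' Supported formats: self-describing XYZ (comment line carries
#' `t=<ps> box=<bx>,<by>,<bz>`), multi-frame PDB (via \pkg{bio3d}), and DCD
#' (via \pkg{bio3d}; requires `times`/`box` arguments since DCD headers do
#' not carry them reliably). XTC is not supported; convert to DCD or XYZ.
#'
#' @param files One or more trajectory files (concatenated in order).
#' @param selection Optional integer atom subset applied on read.
#' @param stride Keep every `stride`-th frame.
#' @param n_atoms Optional expected atom count; mismatch is a hard error.
#' @param times,box Overrides for formats that do not store them.
#' @param periodic Passed to [stack_trajectory()].
#' @return A [stack_trajectory()].
#' @export
read_trajectory <- function(files, selection = NULL, stride = 1L,
                            n_atoms = NULL, times = NULL, box = NULL,
                            periodic = TRUE) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  parts <- lapply(files, function(f) {
    ext <- tolower(tools::file_ext(f))
    switch(ext,
      xyz = read_xyz_frames(f),
      pdb = {
        pdb <- bio3d::read.pdb(f, multi = TRUE)
        nat <- nrow(pdb$atom)
        nf <- nrow(pdb$xyz)
        co <- array(NA_real_, c(nat, 3, nf))
        for (i in seq_len(nf)) co[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
        list(coords = co, times = NULL, box = NULL)
      },
      dcd = {
        xyz <- bio3d::read.dcd(f, verbose = FALSE)
        nf <- nrow(xyz)
        nat <- ncol(xyz) / 3
        co <- array(NA_real_, c(nat, 3, nf))
        for (i in seq_len(nf)) co[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
        list(coords = co, times = NULL, box = NULL)
      },
      xtc = stop("XTC reading is not supported; convert to DCD or XYZ"),
      stop("unsupported trajectory format: .", ext))
  })
  nat <- vapply(parts, function(p) dim(p$coords)[1], numeric(1))
  if (length(unique(nat)) != 1L) stop("atom count differs between trajectory files")
  if (!is.null(n_atoms) && nat[1] != n_atoms) {
    stop("atom-count mismatch: trajectory has ", nat[1],
         " atoms, topology expects ", n_atoms)
  }
  coords <- array(unlist(lapply(parts, `[[`, "coords")),
                  c(nat[1], 3, sum(vapply(parts, function(p) dim(p$coords)[3], numeric(1)))))
  tt <- unlist(lapply(parts, `[[`, "times"))
  if (!is.null(times)) tt <- times
  if (is.null(tt) || !length(tt)) tt <- seq_len(dim(coords)[3]) - 1
  bx <- do.call(rbind, lapply(parts, `[[`, "box"))
  if (!is.null(box)) bx <- box
  if (is.null(bx)) bx <- rep(Inf, 3)

  keep <- seq(1L, dim(coords)[3], by = stride)
  coords <- coords[, , keep, drop = FALSE]
  tt <- tt[keep]
  if (!is.null(dim(bx))) bx <- bx[keep, , drop = FALSE]
  if (!is.null(selection)) coords <- coords[selection, , , drop = FALSE]
  stack_trajectory(coords, tt, bx, periodic = periodic)
}

# XYZ reader. Frame blocks: natoms / comment ("t=<ps> box=x,y,z") / atoms.
read_xyz_frames <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat < 1L) stop("malformed XYZ: bad atom count header")
  block <- nat + 2L
  if (length(lines) %% block != 0L) {
    stop("truncated XYZ file: ", length(lines), " lines is not a multiple of ",
         block, " (", nat, " atoms + 2 header lines per frame)")
  }
  nf <- length(lines) %/% block
  counts <- suppressWarnings(as.integer(trimws(lines[(seq_len(nf) - 1L) * block + 1L])))
  if (any(counts != nat)) stop("XYZ atom count changes at frame ", which(counts != nat)[1])
  comments <- lines[(seq_len(nf) - 1L) * block + 2L]
  atom_idx <- as.vector(outer(3:block, (seq_len(nf) - 1L) * block, `+`))
  toks <- strsplit(trimws(lines[atom_idx]), "\\s+")
  xyz <- vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))
  if (anyNA(xyz)) stop("non-numeric coordinates in XYZ file")
  coords <- array(NA_real_, c(nat, 3, nf))
  for (i in seq_len(nf)) {
    coords[, , i] <- t(xyz[, ((i - 1L) * nat + 1L):(i * nat)])
  }
  times <- vapply(comments, function(cm) {
    m <- regmatches(cm, regexec("t=([-0-9.eE+]+)", cm))[[1]]
    if (length(m) == 2L) as.numeric(m[2]) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(times)) times <- NULL
  box <- t(vapply(comments, function(cm) {
    m <- regmatches(cm, regexec("box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)", cm))[[1]]
    if (length(m) == 4L) as.numeric(m[2:4]) else rep(NA_real_, 3)
  }, numeric(3), USE.NAMES = FALSE))
  if (anyNA(box)) box <- NULL
  list(coords = coords, times = times, box = box)
}

#' Write a trajectory as self-describing XYZ
#'
#' The comment line of each frame records time and box so the file
#' round-trips through [read_trajectory()] without a sidecar.
#'
#' @param traj A [stack_trajectory()].
#' @param file Output path.
#' @param element Atom label written in column 1.
#' @param digits Coordinate precision.
#' @return `file`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, file, element = "C", digits = 6) {
  nat <- dim(traj$coords)[1]
  con <- file(file, open = "wt")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (i in seq_len(n_frames(traj))) {
    writeLines(as.character(nat), con)
    writeLines(sprintf("t=%.6f box=%g,%g,%g", traj$times[i],
                       traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]), con)
    xyz <- traj$coords[, , i]
    writeLines(sprintf(fmt, element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(file)
}

# --- minimum-image helpers ------------------------------------------------

# Displacements under the minimum-image convention for an orthorhombic box.
# `d` is an n x 3 matrix of raw displacements; box a length-3 vector (Inf or
# NA entries mean non-periodic in that direction).
mic_displacement <- function(d, box) {
  for (k in 1:3) {
    b <- box[k]
    if (is.finite(b) && b > 0) d[, k] <- d[, k] - b * round(d[, k] / b)
  }
  d
}

# Pairwise minimum-image distances between rows of X (and rows of Y if given).
mic_dist <- function(X, Y = NULL, box = c(Inf, Inf, Inf)) {
  if (is.null(Y)) Y <- X
  nx <- nrow(X); ny <- nrow(Y)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    d <- sweep(Y, 2, X[i, ])
    d <- mic_displacement(d, box)
    out[i, ] <- sqrt(rowSums(d * d))
  }
  out
}

# Distances between matched rows of A and B (both n x 3).
mic_pair_dist <- function(A, B, box = c(Inf, Inf, Inf)) {
  d <- mic_displacement(B - A, box)
  sqrt(rowSums(d * d))
}
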