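#' Stack topology: monomers, hydrogen-bond quadruples, dimer pairing
#'
#' A `stack_topology` records the static annotation of a supramolecular
#' polymer system: which atoms belong to each monomer, which four atoms form
#' the monomer's dimerization hydrogen-bond array (the DDAA donor/acceptor
#' row), which monomers are paired as dimers at t = 0, how monomers partition
#' into stacks, and the order of dimers along each stack axis.
#'
#' @param monomers A list of monomer records. Each record is a list with
#'   elements `id` (character), `stack` (character), `atoms` (integer atom
#'   indices), `hb` (exactly 4 distinct atom indices, the H-bond quadruple),
#'   and optionally `core` (atom subset used for geometric centers and
#'   planarity; defaults to all atoms) and `side` (side-chain subset;
#'   defaults to atoms outside `hb` and `core`).
#' @param dimers0 A list of length-2 character vectors: the monomer pairs
#'   dimerized at t = 0.
#' @param axis_order Optional named list (one entry per stack id) of ordered
#'   dimer index vectors (indices into `dimers0`) giving the dimer sequence
#'   along the stacking axis. When omitted it can be derived from frame-0
#'   coordinates by [infer_axis_order()].
#' @param n_atoms Total number of atoms in the system (defaults to the
#'   largest annotated index).
#'
#' @return An object of class `stack_topology`.
#' @seealso [load_topology()], [label_tips()], [build_stack()]
#' @export
stack_topology <- function(monomers, dimers0, axis_order = NULL, n_atoms = NULL) {
  stopifnot(is.list(monomers), length(monomers) >= 1)
  ids <- vapply(monomers, function(m) as.character(m$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate monomer ids")
  monomers <- lapply(monomers, function(m) {
    m$id <- as.character(m$id)
    m$stack <- as.character(m$stack)
    m$atoms <- as.integer(m$atoms)
    if (is.null(m$hb) || length(m$hb) != 4L || anyDuplicated(m$hb)) {
      stop("monomer '", m$id, "': hb quadruple must be 4 distinct atom indices")
    }
    m$hb <- as.integer(m$hb)
    if (!all(m$hb %in% m$atoms)) {
      stop("monomer '", m$id, "': hb atoms not among the monomer's atoms")
    }
    if (is.null(m$core)) m$core <- m$atoms else m$core <- as.integer(m$core)
    # anything not claimed by the hb quadruple or the core annotation is
    # side chain by convention
    if (is.null(m$side)) m$side <- setdiff(m$atoms, union(m$hb, m$core))
    m
  })
  names(monomers) <- ids

  dimers0 <- lapply(dimers0, as.character)
  for (d in dimers0) {
    if (length(d) != 2L) stop("each dimers0 entry must pair exactly 2 monomers")
    unknown <- setdiff(d, ids)
    if (length(unknown)) stop("dimers0 references unknown monomer '", unknown[1], "'")
    if (monomers[[d[1]]]$stack != monomers[[d[2]]]$stack) {
      stop("dimer (", d[1], ", ", d[2], ") spans two stacks")
    }
  }
  paired <- unlist(dimers0)
  if (anyDuplicated(paired)) stop("a monomer appears in more than one dimers0 pair")

  stacks <- split(ids, vapply(monomers, function(m) m$stack, character(1)))

  if (is.null(n_atoms)) n_atoms <- max(unlist(lapply(monomers, `[[`, "atoms")))

  topo <- structure(
    list(monomers = monomers, dimers0 = dimers0, stacks = stacks,
         axis_order = axis_order, n_atoms = as.integer(n_atoms)),
    class = "stack_topology")
  if (!is.null(axis_order)) validate_axis_order(topo)
  topo
}

validate_axis_order <- function(topo) {
  dimer_stack <- vapply(topo$dimers0,
                        function(d) topo$monomers[[d[1]]]$stack, character(1))
  for (sid in names(topo$axis_order)) {
    ord <- topo$axis_order[[sid]]
    expect <- which(dimer_stack == sid)
    if (!setequal(ord, expect) || length(ord) != length(expect)) {
      stop("axis_order for stack '", sid,
           "' is not a permutation of that stack's dimers")
    }
  }
  invisible(topo)
}

#' @export
print.stack_topology <- function(x, ...) {
  cat("stack_topology:", length(x$monomers), "monomers,",
      length(x$dimers0), "initial dimers,",
      length(x$stacks), "stack(s),", x$n_atoms, "atoms\n")
  invisible(x)
}

n_monomers <- function(topo) length(topo$monomers)
monomer_ids <- function(topo) names(topo$monomers)

#' Order dimers along each stack's principal axis
#'
#' Projects dimer centers (mean of both partners' core atoms) onto the first
#' principal axis of the stack's dimer centers at the supplied frame and
#' sorts along it. Used when the annotation does not state an axis order.
#'
#' @param topo A [stack_topology()].
#' @param coords Frame coordinates, an `n_atoms x 3` matrix in nm.
#' @return The topology with `axis_order` filled in.
#' @export
infer_axis_order <- function(topo, coords) {
  dimer_stack <- vapply(topo$dimers0,
                        function(d) topo$monomers[[d[1]]]$stack, character(1))
  centers <- t(vapply(topo$dimers0, function(d) {
    at <- c(topo$monomers[[d[1]]]$core, topo$monomers[[d[2]]]$core)
    colMeans(coords[at, , drop = FALSE])
  }, numeric(3)))
  axis_order <- list()
  for (sid in names(topo$stacks)) {
    idx <- which(dimer_stack == sid)
    if (length(idx) == 0L) next
    if (length(idx) == 1L) { axis_order[[sid]] <- idx; next }
    cc <- scale(centers[idx, , drop = FALSE], scale = FALSE)
    ax <- svd(cc)$v[, 1]
    axis_order[[sid]] <- idx[order(cc %*% ax)]
  }
  topo$axis_order <- axis_order
  validate_axis_order(topo)
  topo
}

#' Load a stack topology from a coordinate file plus an annotation
#'
#' The coordinate file (PDB via \pkg{bio3d}, GRO, or XYZ) supplies frame-0
#' positions; the annotation (a JSON file or an equivalent list) names each
#' monomer's atoms, its 4-atom hydrogen-bond quadruple, the initial dimer
#' pairing and the stack membership. Atoms of a monomer not claimed by the
#' quadruple or the core annotation are assigned to the side-chain subset.
#'
#' @param topology_file Path to a PDB/GRO/XYZ coordinate file.
#' @param annotation Path to a JSON annotation or an already-parsed list with
#'   elements `monomers`, `dimers0` and optionally `axis_order`.
#' @return A validated [stack_topology()] with `axis_order` populated (taken
#'   from the annotation when given, otherwise inferred from the frame-0
#'   principal axis).
#' @export
load_topology <- function(topology_file, annotation) {
  if (is.character(annotation)) annotation <- jsonlite::read_json(annotation)
  monomers <- lapply(annotation$monomers, function(m) {
    if (is.null(m$hb)) {
      stop("annotation: missing hb quadruple for monomer '", m$id, "'")
    }
    list(id = m$id, stack = if (is.null(m$stack)) "S1" else m$stack,
         atoms = unlist(m$atoms), hb = unlist(m$hb),
         core = if (is.null(m$core)) NULL else unlist(m$core),
         side = if (is.null(m$side)) NULL else unlist(m$side))
  })
  dimers0 <- lapply(annotation$dimers0, unlist)
  axis_order <- if (is.null(annotation$axis_order)) NULL else
    lapply(annotation$axis_order, unlist)
  coords <- read_coords(topology_file)
  topo <- stack_topology(monomers, dimers0, axis_order = axis_order,
                         n_atoms = nrow(coords))
  if (is.null(topo$axis_order)) topo <- infer_axis_order(topo, coords)
  topo
}

# Read a single coordinate frame (nm) from PDB, GRO or XYZ.
read_coords <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(file)
    m <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
    return(m / 10) # PDB is in Angstrom
  }
  if (ext == "gro") return(read_gro(file)$coords)
  if (ext == "xyz") {
    fr <- read_xyz_frames(file)
    return(fr$coords[, , 1])
  }
  stop("unsupported topology format: .", ext)
}

# Minimal GRO reader (fixed-width, nm). Returns coords and box.
read_gro <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[2]))
  if (length(lines) < n + 3L) stop("truncated GRO file: expected ", n, " atoms")
  at <- lines[3:(n + 2)]
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (anyNA(c(x, y, z))) stop("non-numeric coordinates in GRO file")
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
  list(coords = cbind(x, y, z), box = box)
}

#' Label monomers as tip or backbone
#'
#' Monomers belonging to the first or last `depth` dimers of each stack's
#' axis order are labelled `"tip"`; all others `"backbone"`. With a 2-dimer
#' stack and depth 1 all four monomers are formally tips.
#'
#' @param topo A [stack_topology()] with `axis_order` populated.
#' @param depth Number of terminal dimers per end counted as tip (1 = end
#'   dimers only; 2 = end dimers and their first neighbours). Must satisfy
#'   `1 <= depth <= floor(D/2)` for every stack with D dimers (a 1-dimer or
#'   2-dimer stack accepts depth 1, labelling everything tip).
#' @return A named character vector (`"tip"`/`"backbone"`) over monomer ids.
#' @export
label_tips <- function(topo, depth = 1L) {
  if (is.null(topo$axis_order)) stop("axis_order not populated; see infer_axis_order()")
  depth <- as.integer(depth)
  labels <- setNames(rep("backbone", n_monomers(topo)), monomer_ids(topo))
  for (sid in names(topo$axis_order)) {
    ord <- topo$axis_order[[sid]]
    D <- length(ord)
    max_depth <- max(1L, D %/% 2L)
    if (depth < 1L || depth > max_depth) {
      stop("tip depth ", depth, " out of bounds for stack '", sid,
           "' with ", D, " dimers (allowed 1..", max_depth, ")")
    }
    sel <- unique(c(ord[seq_len(min(depth, D))],
                    ord[seq.int(D, max(1L, D - depth + 1L))]))
    for (di in sel) labels[topo$dimers0[[di]]] <- "tip"
  }
  labels
}

#' Write a topology annotation to JSON
#'
#' Inverse of the annotation half of [load_topology()]; used by the synthetic
#' generator to persist datasets.
#'
#' @param topo A [stack_topology()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_topology_json <- function(topo, file) {
  ann <- list(
    monomers = lapply(unname(topo$monomers), function(m)
      list(id = m$id, stack = m$stack, atoms = m$atoms, hb = m$hb,
           core = m$core, side = m$side)),
    dimers0 = lapply(topo$dimers0, identity),
    axis_order = topo$axis_order,
    n_atoms = topo$n_atoms)
  jsonlite::write_json(ann, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
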