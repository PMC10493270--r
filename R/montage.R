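#' The 18-electrode clinical 10-20 montage
#'
#' Channel names of the acquisition montage: 16 scalp electrodes plus the two
#' ear reference electrodes A1 and A2. The scalp subset (A1/A2 excluded) is
#' the node set of the electrode graph and the channel set of all model
#' inputs after re-referencing.
#'
#' @return Character vector of channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6", "A1", "A2")
}

#' @rdname montage_1020
#' @export
montage_scalp16 <- function() setdiff(montage_1020(), c("A1", "A2"))

# Channel-name aliases seen across EDF exports (modern vs classic 10-20 names).
channel_aliases <- function() {
  c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6", M1 = "A1", M2 = "A2")
}

normalize_channel_names <- function(nms) {
  al <- channel_aliases()
  # strip common "EEG " prefixes and reference suffixes such as "-REF"
  nms <- sub("^EEG[ _]*", "", nms, ignore.case = TRUE)
  nms <- sub("[-_](REF|LE|AV).*$", "", nms, ignore.case = TRUE)
  hit <- nms %in% names(al)
  nms[hit] <- al[nms[hit]]
  nms
}

#' Unit-sphere coordinates of the 16 scalp electrodes
#'
#' Standard 10-20 positions parameterized by polar angle from the frontal
#' midline and radial fraction of the nasion-inion arc (0 = vertex,
#' 0.5 = the ear-level equator). Returned as 3-D unit vectors with +x to the
#' subject's right, +y anterior, +z up.
#'
#' @return A data.frame with columns `name`, `x`, `y`, `z`.
#' @export
electrode_positions_1020 <- function() {
  # (theta degrees from anterior midline, negative = left; radius fraction)
  tab <- rbind(
    Fp1 = c(-18, .511), Fp2 = c(18, .511),
    F7  = c(-54, .511), F8  = c(54, .511),
    T3  = c(-90, .511), T4  = c(90, .511),
    T5  = c(-126, .511), T6 = c(126, .511),
    O1  = c(-162, .511), O2 = c(162, .511),
    F3  = c(-39, .333), F4  = c(39, .333),
    C3  = c(-90, .256), C4  = c(90, .256),
    P3  = c(-141, .333), P4 = c(141, .333)
  )
  incl <- tab[, 2] * pi          # inclination from vertex (radius 1 = 180 deg)
  az <- tab[, 1] * pi / 180
  out <- data.frame(
    name = rownames(tab),
    x = sin(incl) * sin(az),
    y = sin(incl) * cos(az),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[match(montage_scalp16(), out$name), , drop = FALSE]
}

#' Default electrode adjacency edges
#'
#' Connects each scalp electrode to every other electrode whose great-circle
#' (geodesic) distance on the unit sphere is below `threshold` radians. The
#' default threshold gives each node degree >= 2 and links each electrode to
#' its spatial neighbors only; any hand-curated edge list can be supplied to
#' [build_graph()] instead (two-column text file, see [read_edge_list()]).
#'
#' @param threshold Geodesic distance cut-off in radians.
#' @return A two-column character matrix of electrode-name pairs.
#' @export
default_electrode_edges <- function(threshold = 1.0) {
  pos <- electrode_positions_1020()
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  dots <- pmin(pmax(tcrossprod(xyz), -1), 1)
  geo <- acos(dots)
  n <- nrow(pos)
  idx <- which(upper.tri(geo) & geo < threshold, arr.ind = TRUE)
  cbind(pos$name[idx[, 1]], pos$name[idx[, 2]])
}

#' Read / write an edge list as two-column plain text
#'
#' @param path File path; whitespace-separated electrode-name pairs, one edge
#'   per line.
#' @return Character matrix with two columns.
#' @export
read_edge_list <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("edge list must have two columns")
  as.matrix(tab[, 1:2])
}

#' @rdname read_edge_list
#' @param edges Two-column matrix of electrode-name pairs.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the electrode graph
#'
#' Assembles the binary adjacency matrix A (A_ij = 1 iff an edge connects
#' electrodes i and j), adds self-connections (A_hat = A + I), computes the
#' degree matrix D_hat of A_hat, and caches the symmetric normalization
#' A_norm = D_hat^{-1/2} A_hat D_hat^{-1/2} used by the graph convolution.
#'
#' @param montage Ordered character vector of node (electrode) names.
#' @param edges Two-column matrix of electrode-name pairs; defaults to the
#'   distance-threshold neighbor set of [default_electrode_edges()].
#' @return An object of class `electrode_graph` with elements `nodes`, `A`,
#'   `A_hat`, `D_hat`, `A_norm`.
#' @export
build_graph <- function(montage = montage_scalp16(),
                        edges = default_electrode_edges()) {
  n <- length(montage)
  if (anyDuplicated(montage)) stop("duplicate electrode names in montage")
  A <- matrix(0, n, n, dimnames = list(montage, montage))
  if (length(edges)) {
    edges <- as.matrix(edges)
    bad <- setdiff(c(edges), montage)
    if (length(bad)) {
      stop("unknown electrode(s) in edge list: ", paste(bad, collapse = ", "))
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
    for (k in seq_len(nrow(edges))) {
      i <- match(edges[k, 1], montage)
      j <- match(edges[k, 2], montage)
      A[i, j] <- 1
      A[j, i] <- 1
    }
  }
  A_hat <- A + diag(n)
  d <- rowSums(A_hat)
  A_norm <- A_hat * tcrossprod(1 / sqrt(d))
  structure(
    list(nodes = montage, A = A, A_hat = A_hat,
         D_hat = diag(d, n), A_norm = A_norm),
    class = "electrode_graph"
  )
}

#' @export
print.electrode_graph <- function(x, ...) {
  cat("<electrode_graph> ", length(x$nodes), " nodes, ",
      sum(x$A) / 2, " edges\n", sep = "")
  invisible(x)
}
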