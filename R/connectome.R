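#' Construct a weighted, spatially embedded brain network
#'
#' A `connectome` bundles everything the SIR engine needs about the network:
#' an ordered region table (labels, sizes, centroid coordinates), a symmetric
#' nonnegative matrix of connection strengths `weights` (streamline density
#' normalised by target volume, or any undirected strength), and a matrix of
#' edge lengths `distances` (mm) defined wherever a weight is nonzero. The
#' region order of the weight matrix is canonical: every downstream vector
#' (sizes, expression, observed atrophy) is validated against it, because
#' silent misalignment is the dominant failure mode in this kind of analysis.
#'
#' If `distances` is omitted it falls back to pairwise Euclidean distances
#' between region centroids; streamline-geometry distances can be supplied
#' when available. The full centroid distance matrix is always kept alongside
#' (`centroid_distances`) because surrogate-map generation and repositioned
#' null models need distances between *all* region pairs, not only connected
#' ones.
#'
#' @param regions data frame with columns `label`, `size`, `x`, `y`, `z`.
#'   Labels must be unique and sizes strictly positive.
#' @param weights square numeric matrix of nonnegative connection strengths,
#'   symmetric with a zero diagonal; dimnames, if present, must match
#'   `regions$label` in order.
#' @param distances optional square matrix of positive edge lengths (mm) on
#'   every edge with nonzero weight; defaults to centroid Euclidean distances.
#' @return An object of class `connectome` with elements `regions` (tibble),
#'   `weights`, `distances`, `centroid_distances`.
#' @examples
#' reg <- tibble::tibble(label = c("a", "b", "c"), size = c(10, 20, 30),
#'                       x = c(0, 3, 0), y = c(0, 4, 8), z = 0)
#' w <- matrix(c(0, 1, 0, 1, 0, 2, 0, 2, 0), 3, 3)
#' cn <- connectome(reg, w)
#' cn$distances[1, 2]  # 5: the 3-4-5 triangle
#' @export
connectome <- function(regions, weights, distances = NULL) {
  regions <- tibble::as_tibble(regions)
  required <- c("label", "size", "x", "y", "z")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("region table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  regions$label <- as.character(regions$label)
  if (anyDuplicated(regions$label)) stop("region labels must be unique")
  if (any(!is.finite(regions$size)) || any(regions$size <= 0)) {
    stop("region sizes must be finite and > 0")
  }
  n <- nrow(regions)
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n) {
    stop("weights must be a ", n, " x ", n, " numeric matrix to match the region table")
  }
  if (!is.null(rownames(weights)) && !identical(rownames(weights), regions$label)) {
    stop("weight matrix row labels do not match the region table order")
  }
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be nonnegative")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-8) {
    stop("weight matrix is not symmetric (max asymmetry ", format(asym), ")")
  } else if (asym > 0) {
    if (asym < 1e-6) {
      warning("symmetrizing weights by averaging (max asymmetry ", format(asym), ")")
      weights <- (weights + t(weights)) / 2
    } else {
      stop("weight matrix asymmetry ", format(asym), " exceeds tolerance")
    }
  }
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal")
  dimnames(weights) <- list(regions$label, regions$label)

  cdist <- euclidean_distances(regions)
  if (is.null(distances)) {
    distances <- cdist
  } else {
    distances <- as.matrix(distances)
    if (!identical(dim(distances), dim(weights))) {
      stop("distance matrix dimensions do not match the weight matrix")
    }
    if (max(abs(distances - t(distances))) > 1e-8) stop("distances must be symmetric")
    onedge <- weights > 0
    if (any(!is.finite(distances[onedge])) || any(distances[onedge] <= 0)) {
      stop("distances must be finite and > 0 on every edge with nonzero weight")
    }
    dimnames(distances) <- dimnames(weights)
  }

  structure(
    list(regions = regions, weights = weights, distances = distances,
         centroid_distances = cdist),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$regions)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<connectome> ", n, " regions, ", ne, " undirected edges (density ",
      sprintf("%.3f", ne / choose(n, 2)), ")\n", sep = "")
  invisible(x)
}

#' Number of regions in a connectome
#' @param x a `connectome`
#' @return integer region count
#' @export
n_regions <- function(x) {
  stopifnot(inherits(x, "connectome"))
  nrow(x$regions)
}

#' Pairwise Euclidean distances between region centroids
#'
#' @param regions data frame with columns `x`, `y`, `z` (and usually `label`).
#' @return symmetric matrix of centroid distances (mm) with a zero diagonal.
#'   A warning flags degenerate geometry (two regions at the same point).
#' @export
euclidean_distances <- function(regions) {
  xyz <- as.matrix(regions[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("region coordinates must be finite")
  d <- as.matrix(stats::dist(xyz))
  if (!is.null(regions$label)) dimnames(d) <- list(regions$label, regions$label)
  if (nrow(d) > 1 && any(d[upper.tri(d)] == 0)) {
    warning("degenerate geometry: some regions share identical coordinates")
  }
  d
}

#' Read a connectome from delimited text files
#'
#' Expects the dialect the companion writers emit: weight and distance
#' matrices as delimited text with a header row and an index column of region
#' labels, and a region table with columns `label,size,x,y,z`. Label order is
#' taken from the weights header; the distance matrix and region table are
#' reconciled (reordered) by label and any mismatch is an error.
#'
#' @param weights_path,regions_path,distances_path file paths;
#'   `distances_path` may be `NULL` to use centroid Euclidean distances.
#' @param sep field separator (default `","`).
#' @return a validated [connectome()].
#' @seealso [write_connectome()]
#' @export
read_connectome <- function(weights_path, regions_path, distances_path = NULL,
                            sep = ",") {
  w <- read_labeled_matrix(weights_path, sep)
  regions <- utils::read.table(regions_path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  regions$label <- as.character(regions$label)
  if (!setequal(regions$label, rownames(w)) ||
      length(regions$label) != nrow(w)) {
    stop("region table labels do not match the weights header")
  }
  regions <- regions[match(rownames(w), regions$label), , drop = FALSE]
  distances <- NULL
  if (!is.null(distances_path)) {
    distances <- read_labeled_matrix(distances_path, sep)
    if (!identical(rownames(distances), rownames(w))) {
      if (!setequal(rownames(distances), rownames(w))) {
        stop("distance matrix labels do not match the weights header")
      }
      idx <- match(rownames(w), rownames(distances))
      distances <- distances[idx, idx, drop = FALSE]
    }
  }
  connectome(regions, w, distances)
}

#' Write a connectome to delimited text files
#'
#' Emits the same dialect [read_connectome()] reads, so read-write-read is
#' the identity on valid inputs.
#'
#' @param x a `connectome`
#' @param weights_path,regions_path,distances_path output paths;
#'   `distances_path` may be `NULL` to skip the distance matrix.
#' @param sep field separator
#' @return `x`, invisibly.
#' @export
write_connectome <- function(x, weights_path, regions_path,
                             distances_path = NULL, sep = ",") {
  stopifnot(inherits(x, "connectome"))
  write_labeled_matrix(x$weights, weights_path, sep)
  reg <- as.data.frame(lapply(x$regions, fmt_full))
  utils::write.table(reg, regions_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(distances_path)) write_labeled_matrix(x$distances, distances_path, sep)
  invisible(x)
}

read_labeled_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels disagree in ", path)
  }
  m
}

# full 17-significant-digit formatting so write -> read is the identity on
# doubles
fmt_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

write_labeled_matrix <- function(m, path, sep = ",") {
  body <- apply(m, 2, fmt_full)
  df <- data.frame(label = rownames(m), body, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Group-consensus thresholding of a stack of subject connectomes
#'
#' Given per-subject weight matrices (all region-aligned), ranks undirected
#' edges by how many subjects express them (weight > 0) and keeps the top
#' `density` fraction of all possible off-diagonal undirected edges; the
#' retained edge weight is the mean weight over all subjects. Ties in
#' occurrence are broken by higher mean weight, then by lexicographic index
#' pair, so the result is deterministic.
#'
#' @param stack list of square numeric matrices, one per subject, identical
#'   dimensions, nonnegative.
#' @param density fraction of possible undirected edges to retain, in (0, 1].
#' @return a symmetric, zero-diagonal consensus weight matrix.
#' @export
consensus_threshold <- function(stack, density) {
  if (!is.list(stack) || length(stack) == 0) stop("stack must be a non-empty list of matrices")
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1) {
    stop("density must be a single value in (0, 1]")
  }
  dims <- unique(lapply(stack, dim))
  if (length(dims) != 1 || dims[[1]][1] != dims[[1]][2]) {
    stop("all subject matrices must be square and the same shape")
  }
  if (any(vapply(stack, function(m) any(m < 0), logical(1)))) {
    stop("subject weights must be nonnegative")
  }
  n <- dims[[1]][1]
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  occ <- Reduce(`+`, lapply(stack, function(m) (m[ut] > 0) + (t(m)[ut] > 0) > 0))
  mean_w <- Reduce(`+`, lapply(stack, function(m) (m[ut] + t(m)[ut]) / 2)) / length(stack)
  n_keep <- round(density * nrow(ut))
  ord <- order(-occ, -mean_w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(n_keep, sum(occ > 0)))]
  out <- matrix(0, n, n, dimnames = dimnames(stack[[1]]))
  out[ut[keep, , drop = FALSE]] <- mean_w[keep]
  out <- out + t(out)
  out
}
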