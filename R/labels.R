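# Compensation label space. Y = 0 Trunk Forward (TF), 1 Trunk Rotation (TR),
# 2 Shoulder Elevation (SE), 3 Other (trunk backward / trunk tilt), 4 Normal.
# A frame's labels are a subset of {0,1,2,3}; the empty subset is encoded by
# the exclusive Normal label 4.

LABEL_NAMES <- c("TF", "TR", "SE", "O", "Normal")
N_LABELS <- 5L

#' Build a frame-by-label one-hot matrix from per-frame label sets
#'
#' Each element of `sets` is an integer vector holding the active compensation
#' labels (subset of 0:3) for one frame; an empty vector means Normal and is
#' encoded on the exclusive fifth slot (Y = 4). The result is the canonical
#' label container used throughout the package: an `n x 5` binary matrix with
#' columns `TF`, `TR`, `SE`, `O`, `Normal`.
#'
#' @param sets list of integer vectors, each a subset of `0:3` (possibly empty).
#' @return binary matrix of dimension `length(sets) x 5`.
#' @examples
#' as_label_matrix(list(integer(0), c(1L, 2L), 0L))
#' @export
as_label_matrix <- function(sets) {
  if (!is.list(sets)) stop("`sets` must be a list of integer vectors")
  m <- matrix(0L, nrow = length(sets), ncol = N_LABELS,
              dimnames = list(NULL, LABEL_NAMES))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) == 0L) {
      m[i, 5L] <- 1L
    } else {
      if (any(!s %in% 0:3)) stop("labels must be a subset of 0:3 (frame ", i, ")")
      m[i, unique(s) + 1L] <- 1L
    }
  }
  m
}

#' Recover per-frame label sets from a one-hot label matrix
#'
#' Inverse of [as_label_matrix()]: rows with the Normal slot active map to the
#' empty set.
#'
#' @param m binary `n x 5` label matrix.
#' @return list of integer vectors (subsets of 0:3).
#' @export
label_sets <- function(m) {
  check_label_matrix(m)
  lapply(seq_len(nrow(m)), function(i) which(m[i, 1:4] == 1L) - 1L)
}

check_label_matrix <- function(m, n = NULL) {
  if (!is.matrix(m) || ncol(m) != N_LABELS)
    stop("label matrix must have 5 columns (TF, TR, SE, O, Normal)")
  if (!all(m %in% c(0L, 1L))) stop("label matrix must be binary")
  bad <- (m[, 5L] == 1L & rowSums(m[, 1:4, drop = FALSE]) > 0L) |
    (m[, 5L] == 0L & rowSums(m[, 1:4, drop = FALSE]) == 0L)
  if (any(bad))
    stop("Normal exclusivity violated in row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  if (!is.null(n) && nrow(m) != n)
    stop("label matrix has ", nrow(m), " rows, expected ", n)
  invisible(m)
}

# Map a set of active labels to a one-hot row (internal, vector of 5).
onehot_row <- function(active) {
  r <- integer(N_LABELS)
  if (length(active) == 0L) r[5L] <- 1L else r[unique(active) + 1L] <- 1L
  r
}
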