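# 22-channel motor-imagery montage of the BCI Competition IV-2a layout.
# The numeric labels follow the dataset's electrode numbering; only the
# two representative sensorimotor electrodes carry their 10-20 names
# (position 8 = C3, position 12 = C4) so that the literature's channel
# groups stay addressable by the labels used there.
.iv2aLayout <- local({
  nm <- c("1", "2", "3", "4", "5", "6",
          "7", "C3", "9", "10", "11", "C4", "13",
          "14", "15", "16", "17", "18",
          "19", "20", "21", "22")
  xs <- c(0,
          -0.4, -0.2, 0, 0.2, 0.4,
          -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6,
          -0.4, -0.2, 0, 0.2, 0.4,
          -0.2, 0, 0.2,
          0)
  ys <- c(0.6,
          rep(0.3, 5),
          rep(0, 7),
          rep(-0.3, 5),
          rep(-0.6, 3),
          -0.85)
  m <- cbind(x = xs, y = ys)
  rownames(m) <- nm
  m
})

.sensorimotorGroups <- list(
  left = c("C3", "9", "14", "15"),
  right = c("C4", "11", "18", "17"),
  midline = c("10", "16")
)

# symmetric k-nearest-neighbor adjacency from 2-D positions
.knnAdjacency <- function(pos, k = 4L) {
  nm <- rownames(pos)
  n <- nrow(pos)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(pos))
  adj <- stats::setNames(vector("list", n), nm)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i]
    adj[[nm[i]]] <- nm[ord[seq_len(k)]]
  }
  # symmetrize: neighborhood is the union of the directed kNN relations
  for (i in nm) for (j in adj[[i]]) {
    if (!(i %in% adj[[j]])) adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Default electrode montage
#'
#' Builds a [Montage-class] (2-D positions plus symmetric
#' 4-nearest-neighbor adjacency) for the requested channels. Channels
#' drawn from the bundled 22-electrode motor-imagery layout get their
#' standard positions; any other channel must come with a user-supplied
#' position.
#'
#' @param channelNames channel labels.
#' @param positions optional channels x 2 matrix of positions (row names
#'   or the order of \code{channelNames}); required for channels outside
#'   the bundled layout.
#' @param k number of nearest neighbors before symmetrization.
#' @return A [Montage-class].
#' @examples
#' m <- defaultMontage()
#' neighbors(m, "C3")
#' sensorimotorChannels(m, "left")
#' @export
defaultMontage <- function(channelNames = rownames(.iv2aLayout),
                           positions = NULL, k = 4L) {
  channelNames <- as.character(channelNames)
  if (is.null(positions)) {
    unknown <- setdiff(channelNames, rownames(.iv2aLayout))
    if (length(unknown))
      stop("no default position for channel(s) ",
           paste(unknown, collapse = ", "),
           "; supply `positions` for non-standard channels")
    pos <- .iv2aLayout[channelNames, , drop = FALSE]
  } else {
    positions <- as.matrix(positions)
    if (is.null(rownames(positions))) {
      if (nrow(positions) != length(channelNames))
        stop("positions must have one row per channel")
      rownames(positions) <- channelNames
    }
    miss <- setdiff(channelNames, rownames(positions))
    if (length(miss))
      stop("missing positions for channel(s) ", paste(miss, collapse = ", "))
    pos <- positions[channelNames, , drop = FALSE]
  }
  if (nrow(pos) < 2L) stop("a montage needs at least two channels")
  new("Montage", positions = pos, adjacency = .knnAdjacency(pos, k = k))
}

#' Sensorimotor channel groups
#'
#' The sensorimotor electrode groups used when restricting analyses to
#' the cortex area engaged by hand motor imagery: left hemisphere
#' (C3, 9, 14, 15), right hemisphere (C4, 11, 18, 17), and the
#' longitudinal-fissure midline (10, 16).
#'
#' @param montage a [Montage-class] (only its channel set is consulted).
#' @param group one of \code{"left"}, \code{"right"}, \code{"midline"},
#'   or \code{"all"} for the union.
#' @return Character vector of channel labels present in the montage.
#' @export
sensorimotorChannels <- function(montage, group = c("all", "left", "right",
                                                    "midline")) {
  group <- match.arg(group)
  want <- if (group == "all") unlist(.sensorimotorGroups, use.names = FALSE)
          else .sensorimotorGroups[[group]]
  intersect(want, channelNames(montage))
}
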