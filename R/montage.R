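# Idealized 10-10 montage geometry, mirror-pair bookkeeping and the spatial
# adjacency graph used by the cluster tests.

.slerp <- function(u, v, f) {
  w <- acos(max(-1, min(1, sum(u * v))))
  if (w < 1e-12) return(u)
  (sin((1 - f) * w) * u + sin(f * w) * v) / sin(w)
}

.deg <- pi / 180

# unit vector at polar angle (from vertex) and ring azimuth (0 = front,
# 180 = back), on the given hemisphere ("L", "R" or "Z" for midline)
.sphPos <- function(polar, azimuth, side) {
  s <- switch(side, L = -1, R = 1, Z = 0)
  c(x = s * sin(polar * .deg) * sin(azimuth * .deg),
    y = sin(polar * .deg) * cos(azimuth * .deg),
    z = cos(polar * .deg))
}

#' Idealized 10-10 montage coordinates
#'
#' Constructs idealized unit-sphere coordinates for the 64-channel 10-10
#' montage used throughout the package. Electrodes on the 10% circumference
#' ring sit on the equator at multiples of 18 degrees of azimuth, the
#' below-ring electrodes (FT9/FT10, TP9/TP10, PO9/PO10) 18 degrees below it,
#' midline electrodes on the front-back great circle, and intermediate
#' electrodes on great-circle (geodesic) interpolations between their midline
#' and ring anchors. These are synthetic, idealized positions -- adequate for
#' neighbourhood structure and simulation, not digitised head measurements.
#'
#' @return data.frame with columns `channel`, `x`, `y`, `z` (unit sphere;
#'   x right, y anterior, z superior), 64 rows.
#' @seealso [readMontage()], [buildAdjacency()], [mirrorPairs()]
#' @export
#' @examples
#' m <- buildMontage()
#' head(m)
buildMontage <- function() {
  pos <- list()
  add <- function(name, p) pos[[name]] <<- p

  ring <- c(Fp = 18, AF = 36, F = 54, FT = 72, T = 90, TP = 108, P = 126,
            PO = 144, O = 162)
  ringLab <- c(Fp = "Fp1", AF = "AF7", F = "F7", FT = "FT7", T = "T7",
               TP = "TP7", P = "P7", PO = "PO7", O = "O1")
  for (row in names(ring)) {
    lab <- ringLab[[row]]
    add(lab, .sphPos(90, ring[[row]], "L"))
    add(.mirrorLabel(lab), .sphPos(90, ring[[row]], "R"))
  }
  # ring below the equator
  for (lab in c("FT9", "TP9", "PO9")) {
    row <- sub("9$", "", lab)
    add(lab, .sphPos(108, ring[[row]], "L"))
    add(.mirrorLabel(lab), .sphPos(108, ring[[row]], "R"))
  }
  # midline (front positive polar toward nasion)
  midline <- c(Fz = 36, Cz = 0, CPz = -18, Pz = -36, POz = -54, Oz = -72)
  for (lab in names(midline)) {
    ang <- midline[[lab]]
    add(lab, .sphPos(abs(ang), if (ang >= 0) 0 else 180, "Z"))
  }
  # virtual midline anchors for rows whose z electrode is not in the set
  virt <- list(AFz = .sphPos(54, 0, "Z"), FCz = .sphPos(18, 0, "Z"))

  interp <- list(
    list(mid = "Fz",  ringL = "F7",  labs = c("F1", "F3", "F5")),
    list(mid = "FCz", ringL = "FT7", labs = c("FC1", "FC3", "FC5")),
    list(mid = "Cz",  ringL = "T7",  labs = c("C1", "C3", "C5")),
    list(mid = "CPz", ringL = "TP7", labs = c("CP1", "CP3", "CP5")),
    list(mid = "Pz",  ringL = "P7",  labs = c("P1", "P3", "P5")),
    list(mid = "POz", ringL = "PO7", labs = "PO3"),
    list(mid = "AFz", ringL = "AF7", labs = "AF3")
  )
  for (it in interp) {
    m <- if (it$mid %in% names(virt)) virt[[it$mid]] else pos[[it$mid]]
    r <- pos[[it$ringL]]
    fr <- if (length(it$labs) == 1L) 0.5 else c(0.25, 0.5, 0.75)
    for (k in seq_along(it$labs)) {
      pL <- .slerp(m, r, fr[k])
      add(it$labs[k], pL)
      pR <- pL * c(-1, 1, 1)
      add(.mirrorLabel(it$labs[k]), pR)
    }
  }

  out <- data.frame(channel = names(pos),
                    do.call(rbind, pos),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(match(out$channel, .montageOrder())), , drop = FALSE]
}

.montageOrder <- function() {
  c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
    "O1", "Oz", "O2")
}

# label of the mirror electrode: odd index <-> odd index + 1; midline maps to
# itself
.mirrorLabel <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1]]
  if (length(m) == 0L) return(label)  # midline ("z") labels
  idx <- as.integer(m[3])
  paste0(m[2], if (idx %% 2L == 1L) idx + 1L else idx - 1L)
}

#' Read a montage table
#'
#' Reads a tab-separated montage table (columns `channel`, `x`, `y`, `z`).
#' With no argument, the idealized 10-10 montage shipped with the package is
#' returned.
#'
#' @param file path to a TSV file; default: the shipped `montage_1010.tsv`.
#' @return data.frame with columns `channel`, `x`, `y`, `z`.
#' @export
readMontage <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "montage_1010.tsv", package = "prioEEG",
                        mustWork = TRUE)
  m <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("channel", "x", "y", "z")
  if (!all(need %in% names(m)))
    stop("montage table must have columns: ", paste(need, collapse = ", "))
  m
}

#' Mirror electrode pairs of a montage
#'
#' Pairs every left-hemisphere channel with its right-hemisphere mirror by
#' label (odd index with the following even index); midline channels are
#' excluded and no channel appears in two pairs.
#'
#' @param channels character vector of channel labels.
#' @return data.frame with columns `left`, `right`.
#' @seealso [posteriorPairs()]
#' @export
#' @examples
#' mirrorPairs(c("C3", "C4", "Cz", "O1", "O2"))
mirrorPairs <- function(channels) {
  m <- regmatches(channels, regexec("^([A-Za-z]+)([0-9]+)$", channels))
  idx <- vapply(m, function(x) if (length(x)) as.integer(x[3]) else NA_integer_,
                integer(1))
  left <- channels[!is.na(idx) & idx %% 2L == 1L]
  right <- vapply(left, .mirrorLabel, character(1))
  keep <- right %in% channels
  data.frame(left = left[keep], right = right[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior electrode pairs for lateralization pooling
#'
#' The 17 mirror pairs over temporal, centro-parietal, parietal,
#' parieto-occipital and occipital sites whose lateralization indices are
#' averaged into the pooled alpha-asymmetry time course.
#'
#' @return data.frame with columns `left`, `right` (17 rows).
#' @export
posteriorPairs <- function() {
  left <- c("T7", "C5", "C3", "C1", "TP9", "TP7", "CP5", "CP3", "CP1",
            "P7", "P5", "P3", "P1", "PO7", "PO3", "PO9", "O1")
  data.frame(left = left,
             right = vapply(left, .mirrorLabel, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Channel adjacency from montage geometry
#'
#' Declares two channels neighbours when their Euclidean distance on the unit
#' sphere falls below `threshold`. The default threshold was fixed so that the
#' median neighbour count on the shipped 64-channel montage is about 6,
#' a typical density for EEG cluster statistics.
#'
#' @param montage data.frame as returned by [readMontage()].
#' @param threshold Euclidean distance threshold (unit-sphere units).
#' @return an [AdjacencyGraph-class] object.
#' @export
#' @examples
#' g <- buildAdjacency(readMontage())
#' g
buildAdjacency <- function(montage, threshold = 0.55) {
  xyz <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  nb <- lapply(seq_len(nrow(d)), function(i) {
    which(d[i, ] < threshold & seq_len(ncol(d)) != i)
  })
  iso <- lengths(nb) == 0L
  if (any(iso))
    warning("isolated channel(s): ",
            paste(montage$channel[iso], collapse = ", "))
  new("AdjacencyGraph", channels = montage$channel,
      neighbors = lapply(nb, as.integer), threshold = threshold)
}
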