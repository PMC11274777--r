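## Idealized 10-10 electrode geometry on a sphere.
##
## Positions are constructed from the standard proportional scheme rather
## than digitized: the vertex Cz sits at the pole, the outer 10% ring
## (Fpz, Fp1/2, AF7/8, F7/8, FT7/8, T7/8, TP7/8, P7/8, PO7/8, O1/2, Oz)
## lies 72 deg from the vertex at 18 deg azimuthal spacing, the midline and
## the central coronal arc step in 18 deg increments, intermediate
## electrodes are placed by great-circle interpolation between the lateral
## ring and the midline, and the inferior ring (TP9/10, P9/10, PO9/10) lies
## on the equator below the corresponding 10% ring sites.

# great-circle (slerp) interpolation between unit vectors
slerp <- function(u, v, t) {
  om <- acos(max(-1, min(1, sum(u * v))))
  if (om < 1e-12) return(u)
  (sin((1 - t) * om) * u + sin(t * om) * v) / sin(om)
}

sph_pos <- function(polar_deg, azim_deg) {
  # polar angle from vertex (Cz); azimuth from anterior midline,
  # positive toward the left ear; head frame: +x right, +y anterior, +z up
  p <- polar_deg * pi / 180
  a <- azim_deg * pi / 180
  c(-sin(p) * sin(a), sin(p) * cos(a), cos(p))
}

build_1010_positions <- function() {
  pos <- list()
  pos[["Cz"]] <- c(0, 0, 1)

  # midline: front to back in 18 deg steps
  mid_front <- c(FCz = 18, Fz = 36, AFz = 54, Fpz = 72)
  mid_back  <- c(CPz = 18, Pz = 36, POz = 54, Oz = 72)
  for (l in names(mid_front)) pos[[l]] <- sph_pos(mid_front[[l]], 0)
  for (l in names(mid_back))  pos[[l]] <- sph_pos(mid_back[[l]], 180)

  # outer 10% ring at polar 72 deg, azimuth steps of 18 deg (left side);
  # right-side labels mirror in x
  ring <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
            TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  ring_r <- c(Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
              TP8 = 108, P8 = 126, PO8 = 144, O2 = 162)
  for (l in names(ring))   pos[[l]] <- sph_pos(72, ring[[l]])
  for (l in names(ring_r)) pos[[l]] <- sph_pos(72, -ring_r[[l]])

  # intermediate rows: interpolate between the lateral ring electrode and
  # the midline electrode of the row; electrode "5" sits 1/4 of the way,
  # "3" halfway, "1" 3/4 of the way in toward the midline
  rows <- list(F = c("F7", "Fz"), FC = c("FT7", "FCz"), C = c("T7", "Cz"),
               CP = c("TP7", "CPz"), P = c("P7", "Pz"),
               AF = c("AF7", "AFz"), PO = c("PO7", "POz"))
  fracs <- c("5" = 0.25, "3" = 0.5, "1" = 0.75)
  af_po <- c("AF", "PO")  # these rows carry only the "3"/"4" electrodes
  for (row in names(rows)) {
    lat <- pos[[rows[[row]][1]]]
    med <- pos[[rows[[row]][2]]]
    use <- if (row %in% af_po) fracs["3"] else fracs
    for (k in names(use)) {
      p <- slerp(lat, med, use[[k]])
      pos[[paste0(row, k)]] <- p
      # mirror for even-numbered right-hemisphere partner
      kr <- as.character(as.integer(k) + 1L)
      pos[[paste0(row, kr)]] <- c(-p[1], p[2], p[3])
    }
  }

  # inferior ring on the equator, below the corresponding 10% ring sites
  inf_l <- c(TP9 = 108, P9 = 126, PO9 = 144)
  for (l in names(inf_l)) {
    pos[[l]] <- sph_pos(90, inf_l[[l]])
    r <- sub("9$", "10", l)
    pos[[r]] <- c(-pos[[l]][1], pos[[l]][2], pos[[l]][3])
  }
  pos
}

# canonical label aliases: tokens that appear in channel lists or printed
# cluster definitions but are resolved to another montage position when the
# literal label is absent
.label_aliases <- c(
  FP1 = "Fp1", FP2 = "Fp2", FPZ = "Fpz",
  FC7 = "FT7", FC8 = "FT8",   # non-standard lab naming of the FT sites
  P9 = "PO9", P10 = "PO10"    # printed cluster tokens absent from some caps
)

#' Standard 10-10 montage on a spherical head
#'
#' Returns the package's idealized 10-10 montage: unit-vector positions on
#' a sphere for the canonical label set covering both supported 64-channel
#' laboratory setups, plus the head sphere radius in millimetres.
#'
#' @param labels optional character vector restricting the montage to a
#'   subset of labels (aliases such as `FP1`, `FC7`, `P10` are resolved).
#' @param head_radius_mm scalp sphere radius in mm.
#' @return a `montage` object: list with `labels`, `pos` (n x 3 matrix of
#'   unit vectors) and `head_radius_mm`.
#' @export
standard_montage <- function(labels = NULL, head_radius_mm = 85) {
  all_pos <- build_1010_positions()
  if (is.null(labels)) {
    labels <- names(all_pos)
    canon <- labels
  } else {
    canon <- canonical_labels(labels, names(all_pos))
  }
  pos <- t(vapply(canon, function(l) all_pos[[l]], numeric(3)))
  pos <- pos / sqrt(rowSums(pos^2))
  rownames(pos) <- labels
  structure(list(labels = as.character(labels), canonical = canon, pos = pos,
                 head_radius_mm = head_radius_mm),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes on a %g mm sphere\n",
              length(x$labels), x$head_radius_mm))
  invisible(x)
}

# map possibly aliased labels to canonical montage names; error on unknowns
canonical_labels <- function(labels, known) {
  out <- as.character(labels)
  miss <- !(out %in% known)
  ali <- .label_aliases[out[miss]]
  bad <- miss
  bad[miss] <- is.na(ali) | !(ali %in% known)
  if (any(bad)) {
    stop("unknown electrode label(s): ", paste(unique(labels[bad]), collapse = ", "))
  }
  out[miss] <- ali
  out
}

#' Look up electrode positions
#'
#' @param montage a [standard_montage()] object.
#' @param labels labels to resolve (aliases allowed).
#' @return matrix of unit positions, one row per requested label.
#' @export
montage_positions <- function(montage, labels = montage$labels) {
  canon <- canonical_labels(labels, montage$canonical)
  idx <- match(canon, montage$canonical)
  out <- montage$pos[idx, , drop = FALSE]
  rownames(out) <- labels
  out
}

#' Channel sets of the two supported laboratory recordings
#'
#' The two 64-channel 10-10 setups whose union defines the canonical label
#' namespace of the package.
#'
#' @return character vector of channel labels.
#' @export
bremen_channels <- function() {
  c("FP1", "FP2", "AFz", "AF3", "AF4", "AF7", "AF8", "Fz", "F1", "F2", "F3",
    "F4", "F5", "F6", "F7", "F8", "FCz", "FC1", "FC2", "FC3", "FC4", "FC5",
    "FC6", "FC7", "FC8", "Cz", "C1", "C2", "C3", "C4", "C5", "C6", "T7",
    "T8", "CPz", "CP1", "CP2", "CP3", "CP4", "CP5", "CP6", "TP7", "TP8",
    "TP9", "TP10", "Pz", "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
    "POz", "PO3", "PO4", "PO7", "PO8", "PO9", "PO10", "Oz", "O1", "O2")
}

#' @rdname bremen_channels
#' @export
cologne_channels <- function() {
  c("Cz", "FC2", "CP2", "CP1", "FC1", "F4", "C4", "P4", "Pz", "P3", "C3",
    "F3", "Fz", "FC6", "CP6", "CP5", "FC5", "FP2", "F8", "T8", "P8", "O2",
    "Oz", "O1", "P7", "T7", "F7", "FP1", "TP10", "PO10", "PO9", "TP9",
    "FCz", "C2", "CPz", "C1", "F2", "FC4", "CP4", "P2", "P1", "CP3", "FC3",
    "F1", "AFz", "AF4", "F6", "C6", "P6", "PO4", "POz", "PO3", "P5", "C5",
    "F5", "AF3", "AF8", "FT8", "TP8", "PO8", "PO7", "TP7", "FT7", "AF7")
}

#' The ten electrode clusters used for topographical band-power analyses
#'
#' Ten named clusters of 10-10 electrodes: four midline (frontal `f`,
#' central `c`, parietal `p`, occipital `o`) and six lateral
#' (fronto-/parieto-/occipitotemporal, left and right). Membership follows
#' the printed definitions verbatim; the occipitotemporal clusters list the
#' inferior sites `P9`/`P10`, which resolve to `PO9`/`PO10` on caps that do
#' not carry those positions.
#'
#' @return named list of character vectors.
#' @export
electrode_clusters <- function() {
  list(
    f   = c("AF3", "AFz", "AF4", "F1", "Fz", "F2"),
    c   = c("FC1", "FCz", "FC2", "C1", "Cz", "C2"),
    p   = c("CP1", "CPz", "CP2", "P1", "Pz", "P2"),
    o   = c("PO3", "POz", "PO4", "O1", "Oz", "O2"),
    ftl = c("F7", "F5", "F3", "FT7", "FC5", "FC3"),
    ftr = c("F4", "F6", "F8", "FC4", "FC6", "FT8"),
    ptl = c("T7", "C5", "C3", "TP7", "CP5", "CP3"),
    ptr = c("C4", "C6", "T8", "CP4", "CP6", "TP8"),
    otl = c("P7", "P5", "P3", "P9", "PO7"),
    otr = c("P4", "P6", "P8", "PO8", "P10")
  )
}

#' Members of a named electrode cluster
#'
#' @param clusters a cluster set as returned by [electrode_clusters()].
#' @param name cluster name, one of `f, c, p, o, ftl, ftr, ptl, ptr, otl, otr`.
#' @return character vector of member labels.
#' @export
cluster_members <- function(clusters = electrode_clusters(), name) {
  if (!name %in% names(clusters)) {
    stop("unknown cluster name: ", name)
  }
  clusters[[name]]
}
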