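## Analytic spherical head model.
##
## The forward solution uses three concentric shells (brain, skull, scalp)
## with piecewise-constant conductivity. For each spherical-harmonic degree
## n the radial two-point boundary problem is solved exactly (a small
## linear system in the shell coefficients), which yields a per-degree gain
## g_n relative to the infinite-medium dipole expansion; for equal
## conductivities g_n reduces to the classical (2n+1)/n of a homogeneous
## sphere with insulating boundary. The series over n is truncated once the
## term ratio falls below `tol`. Potentials are expressed in microvolts per
## nanoampere-meter and average-referenced.

#' The 28-source default-mode-network source model
#'
#' Fourteen anatomical structures of the default mode network, mirrored
#' over both hemispheres, each represented as a regional source (three
#' orthogonal unit dipoles) at a fixed approximate Talairach center.
#'
#' @return a `source_model`: data.frame with columns `index`, `label`,
#'   `short`, `x`, `y`, `z` (Talairach mm).
#' @export
load_dmnsm <- function() {
  m <- data.frame(
    index = 1:28,
    label = c(
      "Ventromedial Prefrontal left", "Ventromedial Prefrontal right",
      "Anterior Ventrolateral Inferior Frontal left",
      "Anterior Ventrolateral Inferior Frontal right",
      "Medial Superior Frontal Gyrus left", "Medial Superior Frontal Gyrus right",
      "Middle Frontal Gyrus left", "Middle Frontal Gyrus right",
      "Anterior Cingulate Cortex left", "Anterior Cingulate Cortex right",
      "Intraparietal Sulcus left", "Intraparietal Sulcus right",
      "Inferior Parietal Lobule left", "Inferior Parietal Lobule right",
      "Precuneus left", "Precuneus right",
      "Middle Temporal Gyrus left", "Middle Temporal Gyrus right",
      "Medial Temporal Cortex left", "Medial Temporal Cortex right",
      "Hippocampus left", "Hippocampus right",
      "Posterior Cingulate Cortex left", "Posterior Cingulate right",
      "Thalamus left", "Thalamus right",
      "Occipitotemporal junction left", "Occipitotemporal junction right"
    ),
    short = c("lvmP", "rvmP", "lantVIF", "rantVIF", "lmSFG", "rmSFG",
              "lMFG", "rMFG", "lACC", "rACC", "lIPS", "rIPS", "lIPL",
              "rIPL", "lPC", "rPC", "lMTG", "rMTG", "lMTC", "rMTC",
              "lHIP", "rHIP", "lPCC", "rPCC", "lTHA", "rTHA", "lOTJ",
              "rOTJ"),
    x = c(-8, 8, -28, 28, -10, 10, -38, 38, -10, 10, -35, 35, -56, 56,
          -15, 15, -44, 44, -55, 55, -31, 31, -10, 10, -13, 13, -44, 44),
    y = c(30, 30, 25, 25, 19, 19, 40, 40, 45, 45, -60, -60, -36, -36,
          -58, -58, -66, -66, 14, 14, -25, -25, -58, -58, -17, -17,
          -71, -71),
    z = c(-24, -24, -24, -24, 52, 52, 20, 20, 17, 17, 50, 50, 28, 28,
          36, 36, 17, 17, 10, 10, -8, -8, 11, 11, 8, 8, 2, 2),
    stringsAsFactors = FALSE
  )
  class(m) <- c("source_model", "data.frame")
  attr(m, "name") <- "DMNSM"
  m
}

#' Default spherical head parameters
#'
#' Three concentric shells (scalp, skull, brain) with conventional radii
#' and conductivities, plus the affine placement of Talairach coordinates
#' inside the brain shell: positions are re-centered on the sphere center
#' at Talairach (0, -15, 0) mm and isotropically scaled.
#'
#' @param radii_mm shell radii, outside-in: scalp, skull, brain (mm).
#' @param conductivities shell conductivities, same order (S/m).
#' @param tal_center_mm Talairach coordinate of the sphere center.
#' @param tal_scale isotropic scale applied after re-centering.
#' @return a `head_parameters` list.
#' @export
default_head <- function(radii_mm = c(85, 79, 73),
                         conductivities = c(0.33, 0.0042, 0.33),
                         tal_center_mm = c(0, -15, 0),
                         tal_scale = 0.9) {
  stopifnot(length(radii_mm) == 3, all(diff(radii_mm) < 0),
            length(conductivities) == 3, all(conductivities > 0))
  structure(list(radii_mm = radii_mm, conductivities = conductivities,
                 tal_center_mm = tal_center_mm, tal_scale = tal_scale),
            class = "head_parameters")
}

#' Map Talairach coordinates into the head sphere
#'
#' Applies the affine placement `pos = tal_scale * (coord - tal_center)`
#' and checks that every mapped point lies strictly inside the brain
#' (inner) shell.
#'
#' @param coords numeric vector (length 3) or n x 3 matrix of Talairach mm.
#' @param head a [default_head()] parameter set.
#' @param labels optional labels used in the error message.
#' @return matrix of head-frame positions in mm.
#' @export
talairach_to_headframe <- function(coords, head = default_head(),
                                   labels = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  pos <- sweep(as.matrix(coords), 2, head$tal_center_mm) * head$tal_scale
  r <- sqrt(rowSums(pos^2))
  inner <- min(head$radii_mm)
  if (any(r >= inner)) {
    off <- which(r >= inner)
    nm <- if (!is.null(labels)) labels[off] else off
    stop("source(s) outside the inner shell after mapping: ",
         paste(nm, collapse = ", "))
  }
  pos
}

# per-degree gain of the 3-shell sphere relative to the infinite-medium
# expansion evaluated at the scalp surface (normalized radius 1)
shell_gains <- function(nmax, head) {
  R <- max(head$radii_mm)
  rho1 <- min(head$radii_mm) / R        # brain/skull interface
  rho2 <- sort(head$radii_mm)[2] / R    # skull/scalp interface
  sig <- rev(head$conductivities)       # inside-out: brain, skull, scalp
  g <- numeric(nmax)
  for (n in seq_len(nmax)) {
    # unknowns: A1, A2, B2, A3, B3 ; source term rho^-(n+1) with unit
    # coefficient lives in region 1
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    p <- function(rho) rho^n
    q <- function(rho) rho^(-(n + 1))
    dp <- function(rho) n * rho^(n - 1)
    dq <- function(rho) -(n + 1) * rho^(-(n + 2))
    # continuity of V at rho1:  A1 p - A2 p - B2 q = -q
    A[1, ] <- c(p(rho1), -p(rho1), -q(rho1), 0, 0); b[1] <- -q(rho1)
    # continuity of sigma dV at rho1
    A[2, ] <- c(sig[1] * dp(rho1), -sig[2] * dp(rho1), -sig[2] * dq(rho1), 0, 0)
    b[2] <- -sig[1] * dq(rho1)
    # continuity of V at rho2
    A[3, ] <- c(0, p(rho2), q(rho2), -p(rho2), -q(rho2)); b[3] <- 0
    # continuity of sigma dV at rho2
    A[4, ] <- c(0, sig[2] * dp(rho2), sig[2] * dq(rho2),
                -sig[3] * dp(rho2), -sig[3] * dq(rho2)); b[4] <- 0
    # insulating outer boundary: dV3(1) = 0
    A[5, ] <- c(0, 0, 0, dp(1), dq(1)); b[5] <- 0
    # equilibrate: the radial powers span many orders of magnitude at
    # large n, so scale rows and columns before solving
    dr <- apply(abs(A), 1, max)
    A <- A / dr; b <- b / dr
    dc <- apply(abs(A), 2, max)
    sol <- solve(sweep(A, 2, dc, `/`), b) / dc
    g[n] <- sol[4] + sol[5]  # V at the scalp surface for unit source term
  }
  g
}

#' Lead field of a seeded source model
#'
#' Computes the channels x (3 * n_sources) forward matrix of the model's
#' regional sources: three columns per source holding the scalp potentials
#' of unit dipoles along x, y, z at the mapped Talairach center, in
#' microvolts per nAm, average-referenced over channels.
#'
#' @param model a [load_dmnsm()]-style source model.
#' @param montage a [standard_montage()].
#' @param head a [default_head()] parameter set.
#' @param tol series truncation: stop when the ratio of the current term
#'   bound to the accumulated sum falls below `tol`.
#' @param nmax hard cap on the harmonic degree.
#' @return a `leadfield`: list with `matrix` (channels x 3n, uV/nAm),
#'   `labels`, `source_short`, `head`.
#' @export
compute_leadfield <- function(model, montage, head = default_head(),
                              tol = 1e-8, nmax = 400) {
  stopifnot(inherits(model, "source_model"), inherits(montage, "montage"))
  pos_mm <- talairach_to_headframe(as.matrix(model[, c("x", "y", "z")]),
                                   head, labels = model$short)
  elec <- montage_positions(montage)          # unit vectors
  R_m <- max(head$radii_mm) / 1000            # scalp radius in metres
  sigma1 <- rev(head$conductivities)[1]       # brain conductivity
  nch <- nrow(elec)
  ns <- nrow(pos_mm)
  gains <- shell_gains(nmax, head)
  L <- matrix(0, nch, 3 * ns)
  for (s in seq_len(ns)) {
    b_mm <- sqrt(sum(pos_mm[s, ]^2))
    f <- b_mm / max(head$radii_mm)            # source eccentricity
    bhat <- pos_mm[s, ] / b_mm
    cosg <- as.vector(elec %*% bhat)
    # tangential direction term t_k = e_k - cos(g) bhat, one per channel
    tk <- elec - outer(cosg, bhat)
    # decide the truncation degree from the geometric decay f^(n-1)
    nuse <- min(nmax, max(10L, ceiling(log(tol) / log(max(f, 0.05))) + 5L))
    leg <- legendre_table(nuse, cosg)
    fpow <- f^(seq_len(nuse) - 1)
    for (d in 1:3) {
      u <- c(0, 0, 0); u[d] <- 1
      mr <- sum(u * bhat)
      qt <- as.vector(tk %*% u)
      # V_k = K * sum_n g_n f^(n-1) [ n mr P_n(c_k) + P_n'(c_k) qt_k ]
      radial <- as.vector(crossprod(gains[seq_len(nuse)] * fpow * seq_len(nuse) * mr,
                                    leg$P))
      tangential <- as.vector(crossprod(gains[seq_len(nuse)] * fpow, leg$dP)) * qt
      V <- (radial + tangential) / (4 * pi * sigma1 * R_m^2)
      # volts per A*m -> microvolts per nAm
      L[, 3 * (s - 1) + d] <- V * 1e-3
    }
  }
  # average reference
  L <- sweep(L, 2, colMeans(L))
  colnames(L) <- paste0(rep(model$short, each = 3), "_", rep(c("x", "y", "z"), ns))
  rownames(L) <- montage$labels
  structure(list(matrix = L, labels = montage$labels,
                 source_short = model$short, n_sources = ns, head = head),
            class = "leadfield")
}

#' Export or load a lead field as flat binary plus JSON sidecar
#'
#' `write_leadfield()` stores the matrix as little-endian float64 in
#' `<prefix>.bin` (column-major) and the channel order, source order,
#' units and head parameters in `<prefix>.json`; `read_leadfield()`
#' restores the object.
#'
#' @param leadfield a [compute_leadfield()] result.
#' @param prefix output path prefix (without extension).
#' @return the prefix (write) or a `leadfield` object (read), invisibly
#'   for the writer.
#' @export
write_leadfield <- function(leadfield, prefix) {
  stopifnot(inherits(leadfield, "leadfield"))
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(as.vector(leadfield$matrix), con, size = 8, endian = "little")
  close(con)
  meta <- list(
    n_channels = nrow(leadfield$matrix),
    n_columns = ncol(leadfield$matrix),
    channels = leadfield$labels,
    sources = leadfield$source_short,
    units = "uV per nAm",
    storage = "float64 little-endian column-major",
    head = list(radii_mm = leadfield$head$radii_mm,
                conductivities = leadfield$head$conductivities,
                tal_center_mm = leadfield$head$tal_center_mm,
                tal_scale = leadfield$head$tal_scale))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  vals <- readBin(con, "numeric", n = meta$n_channels * meta$n_columns,
                  size = 8, endian = "little")
  close(con)
  L <- matrix(vals, meta$n_channels, meta$n_columns)
  rownames(L) <- meta$channels
  colnames(L) <- paste0(rep(meta$sources, each = 3), "_",
                        rep(c("x", "y", "z"), length(meta$sources)))
  head <- default_head(radii_mm = meta$head$radii_mm,
                       conductivities = meta$head$conductivities,
                       tal_center_mm = meta$head$tal_center_mm,
                       tal_scale = meta$head$tal_scale)
  structure(list(matrix = L, labels = meta$channels,
                 source_short = meta$sources,
                 n_sources = length(meta$sources), head = head),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d channels x %d source components (%d regional sources)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_sources))
  invisible(x)
}
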