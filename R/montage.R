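#' Idealized spherical 10-10 electrode montage
#'
#' Unit-sphere coordinates for the 64-channel scalp montage used throughout
#' the package, built geometrically rather than read from a digitized file:
#' the midline and the 10\% circumferential ring are placed at the standard
#' 10-10 inclinations (multiples of 18 degrees from the vertex), and interior
#' electrodes are placed by great-circle interpolation between their midline
#' and ring anchors. The frame is x rightward, y anterior, z superior.
#'
#' Positions are anatomically idealized (exact sphere, exact 10-10 fractions);
#' they are intended for spherical-spline interpolation and simulation, not
#' for source analysis.
#'
#' @return A data.frame with columns \code{channel}, \code{x}, \code{y},
#'   \code{z}; 64 rows, unit-norm coordinates.
#' @examples
#' m <- standardMontage()
#' stopifnot(nrow(m) == 64, all(abs(m$x^2 + m$y^2 + m$z^2 - 1) < 1e-12))
#' @export
standardMontage <- function() {
  sph <- function(incl, az) {
    # incl: polar angle from vertex (deg); az: azimuth from +x (right ear),
    # counter-clockwise seen from above (deg); front = 90.
    ti <- incl * pi / 180
    ta <- az * pi / 180
    c(sin(ti) * cos(ta), sin(ti) * sin(ta), cos(ti))
  }
  slerp <- function(a, b, t) {
    om <- acos(max(-1, min(1, sum(a * b))))
    v <- (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
    v / sqrt(sum(v^2))
  }
  pos <- list()
  # 10% circumferential ring (inclination 72), 18-degree azimuth steps.
  ring <- c(Fpz = 90, Fp2 = 72, AF8 = 54, F8 = 36, FT8 = 18, T8 = 0,
            TP8 = -18, P8 = -36, PO8 = -54, O2 = -72, Oz = -90, O1 = -108,
            PO7 = -126, P7 = -144, TP7 = -162, T7 = 180, FT7 = 162,
            F7 = 144, AF7 = 126, Fp1 = 108)
  for (ch in names(ring)) pos[[ch]] <- sph(72, ring[[ch]])
  # Midline electrodes at 18-degree steps along the nasion-inion arc.
  mid <- list(AFz = c(54, 90), Fz = c(36, 90), FCz = c(18, 90), Cz = c(0, 90),
              CPz = c(18, -90), Pz = c(36, -90), POz = c(54, -90))
  for (ch in names(mid)) pos[[ch]] <- sph(mid[[ch]][1], mid[[ch]][2])
  # Interior rows: great-circle interpolation midline anchor -> ring anchor.
  rows <- list(
    F  = list(mid = "Fz",  L = "F7",  R = "F8",
              lab = list(L = c(F1 = .25, F3 = .5, F5 = .75),
                         R = c(F2 = .25, F4 = .5, F6 = .75))),
    FC = list(mid = "FCz", L = "FT7", R = "FT8",
              lab = list(L = c(FC1 = .25, FC3 = .5, FC5 = .75),
                         R = c(FC2 = .25, FC4 = .5, FC6 = .75))),
    C  = list(mid = "Cz",  L = "T7",  R = "T8",
              lab = list(L = c(C1 = .25, C3 = .5, C5 = .75),
                         R = c(C2 = .25, C4 = .5, C6 = .75))),
    CP = list(mid = "CPz", L = "TP7", R = "TP8",
              lab = list(L = c(CP1 = .25, CP3 = .5, CP5 = .75),
                         R = c(CP2 = .25, CP4 = .5, CP6 = .75))),
    P  = list(mid = "Pz",  L = "P7",  R = "P8",
              lab = list(L = c(P1 = .25, P3 = .5, P5 = .75),
                         R = c(P2 = .25, P4 = .5, P6 = .75))),
    AF = list(mid = "AFz", L = "AF7", R = "AF8",
              lab = list(L = c(AF3 = .5), R = c(AF4 = .5))),
    PO = list(mid = "POz", L = "PO7", R = "PO8",
              lab = list(L = c(PO3 = .5), R = c(PO4 = .5)))
  )
  for (rw in rows) {
    for (side in c("L", "R")) {
      anchor <- pos[[rw[[side]]]]
      for (ch in names(rw$lab[[side]]))
        pos[[ch]] <- slerp(pos[[rw$mid]], anchor, rw$lab[[side]][[ch]])
    }
  }
  # Sub-ring electrodes at the equator.
  pos[["P9"]]  <- sph(90, -144)
  pos[["P10"]] <- sph(90, -36)
  pos[["Iz"]]  <- sph(90, -90)
  m <- do.call(rbind, pos)
  data.frame(channel = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Canonical channel ordering: 64 scalp + earlobe references + bipolar EOG.
scalpChannels <- function() standardMontage()$channel
refChannels   <- function() c("EXG1", "EXG2")
eogChannels   <- function() c("VEOG", "HEOG")
allChannels   <- function() c(scalpChannels(), refChannels(), eogChannels())
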