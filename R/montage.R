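#' Electrode montage utilities
#'
#' The package ships a programmatically generated 10/10 montage on the unit
#' sphere.  The geometry is a deliberately simple spherical model: Cz sits at
#' the vertex, the outer ring (Fpz, Fp1/2, AF7/8, F7/8, FT7/8, T7/8, TP7/8,
#' P7/8, PO7/8, O1/2, Oz) lies on the equator at 18 degree azimuth steps, the
#' midline runs from Fpz to Oz in 22.5 degree inclination steps, and inner
#' electrodes are placed by spherical linear interpolation between the outer
#' ring and the midline.  TP9/TP10 and Iz sit 18 degrees below the equator.
#' This is not a digitized head shape; it is adequate for simulating scalp
#' topographies and for spherical-spline interpolation.
#'
#' The full montage has 64 labels.  FCz is treated as the recording reference
#' and is excluded from analysis, leaving 63 analysis channels.
#'
#' @param analysis_only logical; drop the reference channel (FCz)?
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit sphere;
#'   x = right, y = anterior, z = superior).
#' @export
default_montage <- function(analysis_only = TRUE) {
  m <- .build_montage_1010()
  if (analysis_only) m <- m[m$label != "FCz", , drop = FALSE]
  rownames(m) <- NULL
  m
}

# unit vector from inclination (deg from vertex) and azimuth
# (deg from nose, positive toward the right ear)
.sph <- function(incl_deg, az_deg) {
  th <- incl_deg * pi / 180
  ph <- az_deg * pi / 180
  c(x = sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

# spherical linear interpolation between unit vectors p and q
.slerp <- function(p, q, f) {
  om <- acos(max(-1, min(1, sum(p * q))))
  if (om < 1e-12) return(p)
  (sin((1 - f) * om) * p + sin(f * om) * q) / sin(om)
}

.build_montage_1010 <- function() {
  pos <- list()
  add <- function(label, v) pos[[label]] <<- v

  # midline, 22.5 degree steps Fpz -> Cz -> Oz; Iz below the equator
  add("Fpz", .sph(90, 0));   add("AFz", .sph(67.5, 0))
  add("Fz",  .sph(45, 0));   add("FCz", .sph(22.5, 0))
  add("Cz",  .sph(0, 0))
  add("CPz", .sph(22.5, 180)); add("Pz", .sph(45, 180))
  add("POz", .sph(67.5, 180)); add("Oz", .sph(90, 180))
  add("Iz",  .sph(108, 180))

  # equatorial ring, 18 degree azimuth steps
  ring <- c(Fp1 = -18, AF7 = -36, F7 = -54, FT7 = -72, T7 = -90,
            TP7 = -108, P7 = -126, PO7 = -144, O1 = -162)
  for (lab in names(ring)) add(lab, .sph(90, ring[[lab]]))
  mirror <- c(Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8", T7 = "T8",
              TP7 = "TP8", P7 = "P8", PO7 = "PO8", O1 = "O2")
  for (lab in names(ring)) add(mirror[[lab]], .sph(90, -ring[[lab]]))

  # inner electrodes: slerp between the lateral ring electrode and the midline
  rows4 <- list(  # four intervals: ring, 5, 3, 1, midline
    c("F7", "F5", "F3", "F1", "Fz"),
    c("FT7", "FC5", "FC3", "FC1", "FCz"),
    c("T7", "C5", "C3", "C1", "Cz"),
    c("TP7", "CP5", "CP3", "CP1", "CPz"),
    c("P7", "P5", "P3", "P1", "Pz"))
  rows4r <- list(
    c("F8", "F6", "F4", "F2", "Fz"),
    c("FT8", "FC6", "FC4", "FC2", "FCz"),
    c("T8", "C6", "C4", "C2", "Cz"),
    c("TP8", "CP6", "CP4", "CP2", "CPz"),
    c("P8", "P6", "P4", "P2", "Pz"))
  for (row in c(rows4, rows4r)) {
    p <- pos[[row[1]]]; q <- pos[[row[5]]]
    for (k in 2:4) add(row[k], .slerp(p, q, (k - 1) / 4))
  }
  add("AF3", .slerp(pos[["AF7"]], pos[["AFz"]], 0.5))
  add("AF4", .slerp(pos[["AF8"]], pos[["AFz"]], 0.5))
  add("PO3", .slerp(pos[["PO7"]], pos[["POz"]], 0.5))
  add("PO4", .slerp(pos[["PO8"]], pos[["POz"]], 0.5))

  # infra-equatorial temporo-parietal pair
  add("TP9", .sph(108, -108)); add("TP10", .sph(108, 108))

  labs <- names(pos)
  xyz <- do.call(rbind, pos)
  data.frame(label = labs, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Select a reduced analysis montage
#'
#' Returns a deterministic subset of the 63 analysis channels.  `n = 63`
#' returns the full analysis montage; `n = 16` returns a fixed fronto-central
#' / temporal / parietal subset (always containing Cz, T7 and T8) used by the
#' reduced test profile; other sizes take evenly spaced channels while always
#' retaining Cz.
#'
#' @param n number of channels (1..63)
#' @return montage data.frame (see [default_montage()])
#' @export
montage_subset <- function(n = 63) {
  m <- default_montage(analysis_only = TRUE)
  stopifnot(n >= 1, n <= nrow(m))
  if (n == nrow(m)) return(m)
  if (n == 16) {
    keep <- c("F3", "Fz", "F4", "FC1", "FC2", "T7", "C3", "Cz", "C4", "T8",
              "CP1", "CP2", "P3", "Pz", "P4", "Oz")
  } else {
    others <- setdiff(m$label, "Cz")
    keep <- c("Cz", others[unique(round(seq(1, length(others),
                                            length.out = n - 1)))])
  }
  out <- m[match(keep, m$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a montage as CSV (`label,x,y,z`, unit sphere)
#'
#' @param path file path
#' @param montage montage data.frame
#' @return `read_montage` returns a montage data.frame.
#' @export
read_montage <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(m)))
  m
}

#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(montage, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
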