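#' EEG montage presets
#'
#' 16- and 32-channel active-electrode caps (10-20 layout) with left/right
#' mastoid externals. Positions are schematic 2-D scalp projections (unit
#' head radius, x = right, y = front) used for neighbour interpolation and
#' topography construction. Each preset carries the list of posterior
#' channels excluded from analysis (head-movement artifacts): 6 channels on
#' the 16-channel cap, 10 on the 32-channel cap.
#'
#' @param preset `"biosemi16"` or `"biosemi32"`.
#' @return object of class `montage`: list with `channels` (data.frame
#'   `name`, `x`, `y`), `mastoids`, `posterior`, `preset`.
#' @export
montage <- function(preset = c("biosemi32", "biosemi16")) {
  preset <- match.arg(preset)
  pos32 <- data.frame(
    name = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
             "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
             "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
             "PO3", "PO4", "O1", "Oz", "O2", "M1", "M2"),
    x = c(-0.31, 0.31, -0.22, 0.22, -0.81, -0.40, 0, 0.40, 0.81,
          -0.65, -0.22, 0.22, 0.65, -1, -0.5, 0, 0.5, 1,
          -0.65, -0.22, 0.22, 0.65, -0.81, -0.40, 0, 0.40, 0.81,
          -0.22, 0.22, -0.31, 0, 0.31, -1.05, 1.05),
    y = c(0.95, 0.95, 0.82, 0.82, 0.59, 0.52, 0.50, 0.52, 0.59,
          0.28, 0.27, 0.27, 0.28, 0, 0, 0, 0, 0,
          -0.28, -0.27, -0.27, -0.28, -0.59, -0.52, -0.50, -0.52, -0.59,
          -0.82, -0.82, -0.95, -0.95, -0.95, -0.35, -0.35),
    stringsAsFactors = FALSE
  )
  if (preset == "biosemi16") {
    keep <- c("Fp1", "Fp2", "F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
              "P3", "Pz", "P4", "O1", "Oz", "O2", "M1", "M2")
    channels <- pos32[match(keep, pos32$name), ]
    posterior <- c("O1", "Oz", "O2", "P3", "Pz", "P4")
  } else {
    channels <- pos32
    posterior <- c("O1", "Oz", "O2", "P3", "Pz", "P4",
                   "PO3", "PO4", "P7", "P8")
  }
  rownames(channels) <- NULL
  structure(list(channels = channels, mastoids = c("M1", "M2"),
                 posterior = posterior, preset = preset),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage %s: %d channels (%d posterior excluded), mastoids %s>\n",
              x$preset, nrow(x$channels), length(x$posterior),
              paste(x$mastoids, collapse = "/")))
  invisible(x)
}

# Scalp weight map: sum of Gaussians centred at `centres` (rows of x,y),
# width sigma, evaluated at the montage positions; normalized to unit max.
scalp_gaussian <- function(mont, centres, sigma) {
  p <- mont$channels
  w <- rep(0, nrow(p))
  for (i in seq_len(nrow(centres))) {
    d2 <- (p$x - centres[i, 1])^2 + (p$y - centres[i, 2])^2
    w <- w + exp(-d2 / (2 * sigma^2))
  }
  setNames(w / max(w), p$name)
}
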