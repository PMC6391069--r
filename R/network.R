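#' ROI network specification
#'
#' A network is a set of named spherical regions of interest (ROIs) with
#' MNI-space centers: cortical nodes use 5 mm radius spheres and
#' subcortical nodes 2 mm spheres. Networks are plain data frames so they
#' can be read from and written to CSV configuration files.
#'
#' @param name character vector of unique node names.
#' @param x,y,z MNI center coordinates in mm.
#' @param cortical logical; cortical nodes get `radius_default_cortical`,
#'   subcortical nodes `radius_default_subcortical`, unless `radius` is
#'   given explicitly.
#' @param radius sphere radius in mm (optional).
#' @return A `network_spec` data frame with columns `name`, `x`, `y`, `z`,
#'   `cortical`, `radius`.
#' @export
network_spec <- function(name, x, y, z, cortical = TRUE, radius = NULL) {
  if (anyDuplicated(name)) stop("node names must be unique")
  n <- length(name)
  cortical <- rep_len(cortical, n)
  if (is.null(radius)) radius <- ifelse(cortical, 5, 2)
  out <- data.frame(name = as.character(name), x = x, y = y, z = z,
                    cortical = cortical, radius = radius,
                    stringsAsFactors = FALSE)
  class(out) <- c("network_spec", "data.frame")
  out
}

#' Default 16-node extended voice-processing network (synthetic)
#'
#' A synthetic stand-in for an a-priori voice/reward/salience network:
#' 16 nodes spanning bilateral superior temporal sulcus, auditory
#' association cortex, salience (anterior insula, anterior cingulate),
#' reward (nucleus accumbens, ventromedial prefrontal, orbitofrontal),
#' affective/memory (amygdala, hippocampus), and fusiform regions.
#' Coordinates are plausible MNI locations chosen for simulation and
#' testing; they are not the coordinate table of any published study.
#' Real analyses should load their own network with [read_network_csv()].
#'
#' @return A 16-row `network_spec`.
#' @export
default_voice_network <- function() {
  network_spec(
    name = c("pSTS_L", "pSTS_R", "aSTS_L", "aSTS_R",
             "PP_R", "HG_L",
             "AI_L", "AI_R", "rACC_R", "vmPFC", "OFC_R",
             "NAc_L", "NAc_R",
             "Amygdala_L", "Hippocampus_R", "Fusiform_R"),
    x = c(-58, 60, -56, 58, 48, -42,
          -34, 36, 8, 2, 28, -10, 10, -24, 28, 42),
    y = c(-40, -38, -8, -6, -6, -22,
          20, 22, 38, 46, 34, 12, 12, -4, -24, -50),
    z = c(6, 8, -8, -10, -6, 8,
          2, 0, 18, -12, -14, -8, -8, -18, -12, -18),
    cortical = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Read or write a network specification as CSV
#'
#' The CSV has columns `name, x, y, z, cortical` and optionally `radius`.
#'
#' @param path file path.
#' @param network a `network_spec`.
#' @export
read_network_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  network_spec(d$name, d$x, d$y, d$z,
               cortical = if ("cortical" %in% names(d)) d$cortical else TRUE,
               radius = d$radius)
}

#' @rdname read_network_csv
#' @export
write_network_csv <- function(network, path) {
  write.csv(as.data.frame(network), path, row.names = FALSE)
  invisible(path)
}
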