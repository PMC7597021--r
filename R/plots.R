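#' Plot haplotype-class frequency trajectories
#'
#' Replicate-mean class frequencies over generations, one line per class
#' (1a, 1b, 2), in base graphics.
#'
#' @param traj A `ClassTrajectorySet`.
#' @param main Plot title.
#' @return Invisibly, the matrix of plotted means (generation x class).
#' @export
plot_trajectories <- function(traj, main = "Haplotype-class trajectories") {
  gens <- sort(unique(traj$generation))
  classes <- c("1a", "1b", "2")
  cols <- c(`1a` = "darkorange", `1b` = "magenta3", `2` = "steelblue")
  m <- sapply(classes, function(cl) {
    vapply(gens, function(g) {
      mean(traj$frequency[traj$class == cl & traj$generation == g])
    }, numeric(1))
  })
  graphics::matplot(gens, m, type = "b", pch = 19, lty = 1, col = cols,
                    xlab = "Generation", ylab = "Class frequency",
                    ylim = c(0, 1), main = main)
  graphics::legend("topleft", legend = classes, col = cols, lty = 1, pch = 19,
                   bty = "n")
  invisible(m)
}

#' Manhattan plot of a CMH scan
#'
#' Plots -log10 p along the chromosome; marker and resistance sites can be
#' highlighted.
#'
#' @param scan A `CmhResult`.
#' @param markers Optional `MarkerSet` (plotted black).
#' @param resistance_sites Optional data.frame of resistance sites (plotted
#'   orange).
#' @param main Plot title.
#' @return Invisibly, `scan`.
#' @export
plot_manhattan <- function(scan, markers = NULL, resistance_sites = NULL,
                           main = "CMH scan") {
  ok <- !is.na(scan$p)
  graphics::plot(scan$pos[ok] / 1e6, -log10(scan$p[ok]), pch = 16,
                 col = "grey60", cex = 0.6, xlab = "Position (Mb)",
                 ylab = expression(-log[10] ~ italic(p)), main = main)
  hi <- function(sites, col) {
    i <- ok & paste(scan$chrom, scan$pos) %in% paste(sites$chrom, sites$pos)
    graphics::points(scan$pos[i] / 1e6, -log10(scan$p[i]), pch = 16,
                     col = col, cex = 0.8)
  }
  if (!is.null(markers)) hi(markers, "black")
  if (!is.null(resistance_sites)) hi(resistance_sites, "darkorange")
  invisible(scan)
}
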