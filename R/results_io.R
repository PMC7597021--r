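# schema tag written at the top of every CSV the package emits
SCHEMA_HEADER <- "# erhaplo results schema v1"

write_csv_schema <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%s: %s", SCHEMA_HEADER, what)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_schema <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write haplotype-class trajectories to a tidy CSV
#'
#' Columns (fixed order): `replicate`, `generation`, `regime`, `class`,
#' `frequency`, `frequency_raw`, `n_markers`, under a schema-versioned
#' comment header. Frequencies round-trip through [read_trajectories()] at
#' full precision.
#'
#' @param traj A `ClassTrajectorySet`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  cols <- c("replicate", "generation", "regime", "class", "frequency",
            "frequency_raw", "n_markers")
  write_csv_schema(as.data.frame(traj)[, cols], path, "class trajectories")
}

#' Read back a trajectory CSV written by [write_trajectories()]
#'
#' @param path CSV path.
#' @return A `ClassTrajectorySet` data.frame.
#' @export
read_trajectories <- function(path) {
  out <- read_csv_schema(path)
  class(out) <- c("ClassTrajectorySet", "data.frame")
  out
}

#' Write selection fits (with metadata) to JSON
#'
#' Serializes per-replicate selection fits including `h`, `Ne`, `s`, `p0`
#' and fit diagnostics.
#'
#' @param fits data.frame from [fit_all_classes()], or a list of
#'   `SelectionFit` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_fits <- function(fits, path) {
  if (is.data.frame(fits)) {
    payload <- list(schema = "erhaplo selection fits v1", fits = fits)
  } else {
    payload <- list(schema = "erhaplo selection fits v1",
                    fits = lapply(fits, function(f) {
                      f[c("replicate", "class_label", "s", "p0", "h", "Ne",
                          "rss", "n_points")]
                    }))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a CMH scan to CSV
#'
#' @param scan A `CmhResult` from [cmh_scan()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  cols <- c("chrom", "pos", "statistic", "df", "p", "mode", "na_reason")
  write_csv_schema(as.data.frame(scan)[, cols], path, "CMH scan")
}

#' Write probit LD50 fits to CSV
#'
#' @param fits A single `ProbitFit` or a named list of them (names become
#'   the `population` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ld50 <- function(fits, path) {
  if (inherits(fits, "ProbitFit")) fits <- list(fit = fits)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(population = nm, ld50 = f$ld50, ci_lower = f$ci[1],
               ci_upper = f$ci[2], slope = f$slope, intercept = f$intercept,
               converged = f$converged, separated = f$separated)
  })
  write_csv_schema(do.call(rbind, rows), path, "probit LD50 fits")
}
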