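## Particle trajectory tables: the common tabular input of all coordinate
## analyses. One row per particle per frame, coordinates in nm.

.roles <- c("head", "tail_carbon", "carbonyl_glycerol", "acyl_chain",
            "peptide", "water")
.leaflets <- c("inner", "outer", "none")

#' Build and validate a particle trajectory table
#'
#' A trajectory table is an ordinary tibble with one row per particle per
#' frame and columns `frame` (integer, >= 0), `particle` (integer id, unique
#' within a frame), `role` (one of `"head"`, `"tail_carbon"`,
#' `"carbonyl_glycerol"`, `"acyl_chain"`, `"peptide"`, `"water"`), `leaflet`
#' (`"inner"`, `"outer"` or `"none"`), and Cartesian coordinates `x`, `y`,
#' `z` in nm. An optional `lipid` column groups a head particle with its
#' tail-carbon particles so that per-lipid vectors can be formed.
#'
#' @param df A data frame with at least the columns above.
#' @return A validated tibble (class `trajectory_tbl`), sorted by frame and
#'   particle.
#' @export
#' @examples
#' as_trajectory(tibble::tibble(
#'   frame = 0L, particle = 1:2, role = "head",
#'   leaflet = c("inner", "outer"), x = 0, y = 0, z = c(18, 22)
#' ))
as_trajectory <- function(df) {
  required <- c("frame", "particle", "role", "leaflet", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  df$frame <- as.integer(df$frame)
  df$particle <- as.integer(df$particle)
  df$role <- as.character(df$role)
  df$leaflet <- as.character(df$leaflet)
  bad_role <- setdiff(unique(df$role), .roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  bad_leaf <- setdiff(unique(df$leaflet), .leaflets)
  if (length(bad_leaf) > 0) {
    abort(paste0("unknown leaflet label(s): ", paste(bad_leaf, collapse = ", ")))
  }
  if (any(df$frame < 0L)) abort("frame indices must be >= 0")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("coordinates must be finite")
  }
  ## avoid a full-table copy when the table is already frame/particle sorted
  ## (the generators emit sorted tables; ensembles can reach 1e7+ rows)
  n <- nrow(df)
  sorted <- n <= 1 ||
    all(diff(df$frame) > 0L |
          (diff(df$frame) == 0L & diff(df$particle) > 0L))
  if (!sorted) {
    if (anyDuplicated(df[c("frame", "particle")]) > 0) {
      abort("(frame, particle) pairs must be unique")
    }
    df <- arrange(df, .data$frame, .data$particle)
  }
  if (!inherits(df, "trajectory_tbl")) {
    class(df) <- c("trajectory_tbl", class(df))
  }
  df
}

#' Read / write trajectory tables
#'
#' CSV columns are `frame,particle,role,leaflet,x,y,z` (plus `lipid` when
#' present); coordinates are nm. `format = "parquet"` writes the same table
#' as a compressed binary container via the arrow package.
#'
#' @param path File path.
#' @param df A trajectory table ([as_trajectory()] is applied on read and
#'   before write).
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `read_trajectory()` returns a validated trajectory tibble;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  df <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("the 'arrow' package is required for parquet trajectories")
      }
      arrow::read_parquet(path)
    }
  )
  as_trajectory(df)
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(df, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  df <- as_trajectory(df)
  switch(format,
    csv = readr::write_csv(df, path, progress = FALSE),
    parquet = {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("the 'arrow' package is required for parquet trajectories")
      }
      arrow::write_parquet(df, path)
    }
  )
  invisible(path)
}

## Split row indices of a trajectory by frame, in frame order.
.frame_index <- function(df) {
  split(seq_len(nrow(df)), df$frame)
}
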